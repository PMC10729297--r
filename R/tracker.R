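# Campaign state machine: colony registration from picker output, NGS
# submission with expected sequences, verdict ingestion, cherry-pick
# consolidation and the per-stage funnel report.

#' Create an empty campaign state
#'
#' The state is the campaign ledger: every stage appends records that
#' may only reference entities already present from earlier stages
#' (forward-only provenance). It serializes to versioned JSON snapshots
#' with [save_state()].
#'
#' @param design a `pf_design`.
#' @return object of class `build_state`.
#' @export
new_build_state <- function(design) {
  structure(list(
    version = 1L,
    design = design,
    plan = NULL,            # demand plan
    reactions = NULL,       # all reaction attempts, every round
    calls = NULL,           # QC calls, every round
    fragment_status = NULL,
    feasible = character(0),
    assembly_attempted = character(0),
    assembly_growth = character(0),      # live yeast observed
    transformation_growth = character(0), # E. coli colonies observed
    plating_layout = NULL,  # construct -> agar tray/well
    colonies = NULL,        # registry from the picker
    colony_calls = NULL,    # colony-PCR size verification
    verdicts = NULL,        # sequencing verdicts
    verified = character(0),
    consolidation = NULL
  ), class = "build_state")
}

#' @export
print.build_state <- function(x, ...) {
  fr <- funnel_report(x)
  cat(sprintf("<build_state> %s\n", x$design$design_id))
  print(fr$counts, row.names = FALSE)
  invisible(x)
}

check_provenance <- function(state) {
  ok <- function(sub, super) length(setdiff(sub, super)) == 0
  des <- state$design$constructs$construct_id
  stopifnot(
    ok(state$feasible, des),
    ok(state$assembly_attempted, state$feasible),
    ok(state$assembly_growth, state$assembly_attempted),
    ok(state$transformation_growth, state$assembly_growth),
    is.null(state$colonies) ||
      ok(state$colonies$construct_id, state$transformation_growth),
    ok(state$verified,
       if (is.null(state$colonies)) character(0)
       else state$colonies$construct_id)
  )
  invisible(state)
}

#' Register picked colonies
#'
#' Joins the colony picker's source-to-culture well map against the
#' plating layout to learn which construct each colony came from.
#' Unknown source wells are set aside on the `unknown` attribute with a
#' warning; a construct yielding more rows than `picks_per_construct`
#' is kept in full with a warning (pickers occasionally over-pick);
#' two rows claiming the same culture well is an integrity error.
#'
#' @param picker data.frame with `source_plate`, `source_well`,
#'   `dest_plate`, `dest_well` (the picker's native CSV shape).
#' @param plating_layout data.frame `sample_id` (construct), `plate_id`,
#'   `well` — where each construct was plated.
#' @param picks_per_construct nominal colonies per construct.
#' @return colony registry: `colony_id`, `construct_id`,
#'   `source_plate`, `source_well`, `culture_plate`, `culture_well`,
#'   `picked_at`.
#' @export
register_colonies <- function(picker, plating_layout,
                              picks_per_construct = 3L) {
  key <- paste(picker$source_plate, picker$source_well)
  lkey <- paste(plating_layout$plate_id, plating_layout$well)
  construct <- plating_layout$sample_id[match(key, lkey)]
  unknown <- picker[is.na(construct), , drop = FALSE]
  if (nrow(unknown)) warning(sprintf(
    "%d picker row(s) reference unplated source wells", nrow(unknown)))
  reg <- picker[!is.na(construct), , drop = FALSE]
  construct <- construct[!is.na(construct)]
  ckey <- paste(reg$dest_plate, reg$dest_well)
  if (anyDuplicated(ckey)) pf_stop(
    sprintf("culture well collision: %s",
            paste(unique(ckey[duplicated(ckey)]), collapse = ", ")),
    "pf_integrity_error")
  per <- table(construct)
  over <- names(per)[per > picks_per_construct]
  if (length(over)) warning(sprintf(
    "construct(s) with more than %d picked colonies: %s",
    picks_per_construct, paste(over, collapse = ", ")))
  n_within <- as.integer(stats::ave(seq_along(construct), construct,
                                    FUN = seq_along))
  out <- data.frame(
    colony_id = sprintf("%s_c%d", construct, n_within),
    construct_id = construct,
    source_plate = reg$source_plate, source_well = reg$source_well,
    culture_plate = reg$dest_plate, culture_well = reg$dest_well,
    picked_at = seq_len(nrow(reg)),
    stringsAsFactors = FALSE)
  attr(out, "unknown") <- unknown
  out
}

# colony-PCR reactions across the cargo/insert region: same scoring
# machinery as fragment QC, with the insert size as expected product
colony_pcr_reactions <- function(registry, design) {
  ids <- unique(registry$construct_id)
  ins <- stats::setNames(
    vapply(ids, function(id) insert_size(design, id), integer(1)), ids)
  data.frame(
    reaction_id = registry$colony_id,
    fragment_id = registry$construct_id,
    expected_size_bp = unname(ins[registry$construct_id]),
    plate_id = registry$culture_plate,
    well = registry$culture_well,
    round = rep(1L, nrow(registry)),
    stringsAsFactors = FALSE)
}

#' NGS submission sheet with expected sequences
#'
#' One row per colony (sample id, culture plate and well, construct,
#' expected-sequence record id) plus a FASTA sidecar of the expected
#' assembled sequence for every construct in the registry.
#'
#' @param registry [register_colonies()] output (optionally restricted
#'   to the colonies actually submitted).
#' @param design a `pf_design`.
#' @param path optional directory; writes `ngs_samples.csv` and
#'   `expected_sequences.fasta` there.
#' @return list with `sheet` (data.frame) and `sequences` (named
#'   character vector, one per construct). Junction errors propagate.
#' @export
ngs_submission <- function(registry, design, path = NULL) {
  sheet <- data.frame(
    sample_id = registry$colony_id,
    plate_id = registry$culture_plate,
    well = registry$culture_well,
    construct_id = registry$construct_id,
    sequence_id = registry$construct_id,
    stringsAsFactors = FALSE)
  ids <- unique(registry$construct_id)
  seqs <- vapply(ids, function(id)
    expected_assembly(design, id)$sequence, character(1))
  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    write_table_utf8(sheet, file.path(path, "ngs_samples.csv"))
    export_expected_sequences(design,
                              file.path(path, "expected_sequences.fasta"),
                              "fasta", construct_ids = ids)
  }
  list(sheet = sheet, sequences = seqs)
}

#' Ingest sequencing verdicts
#'
#' Default policy: a colony qualifies if it has full coverage of the
#' expected sequence and zero mutations; a construct is verified when
#' at least one of its colonies qualifies. Both thresholds are
#' configurable.
#'
#' @param verdicts data.frame `colony_id`, `coverage_full` (logical),
#'   `mutation_count` (integer >= 0).
#' @param registry colony registry the verdicts refer to.
#' @param policy list with `require_full_coverage` (default TRUE) and
#'   `max_mutations` (default 0).
#' @return data.frame `construct_id`, `verified` over the registry's
#'   constructs; the qualifying flag per colony on the `colonies`
#'   attribute. Unknown colony ids are an error.
#' @export
ingest_ngs <- function(verdicts, registry,
                       policy = list(require_full_coverage = TRUE,
                                     max_mutations = 0L)) {
  bad <- setdiff(verdicts$colony_id, registry$colony_id)
  if (length(bad)) pf_stop(
    sprintf("verdict(s) for unregistered colonies: %s",
            paste(bad, collapse = ", ")),
    "pf_integrity_error", list(offenders = bad))
  qual <- (!isTRUE(policy$require_full_coverage) | verdicts$coverage_full) &
    verdicts$mutation_count <= (policy$max_mutations %||% 0L)
  cq <- data.frame(colony_id = verdicts$colony_id, qualifies = qual,
                   stringsAsFactors = FALSE)
  cq$construct_id <- registry$construct_id[match(cq$colony_id,
                                                 registry$colony_id)]
  ids <- unique(registry$construct_id)
  verified <- vapply(ids, function(id)
    any(cq$qualifies[cq$construct_id == id]), logical(1))
  out <- data.frame(construct_id = ids, verified = unname(verified),
                    stringsAsFactors = FALSE)
  attr(out, "colonies") <- cq
  out
}

#' Cherry-pick one verified colony per construct into archive plates
#'
#' For every verified construct, exactly one qualifying colony — the
#' one at the lowest (culture plate, well index) position — is
#' transferred to sequentially allocated archive plates. Deterministic
#' and idempotent: rerunning on the same state reproduces the same
#' picklist. Verified constructs with no qualifying colony are listed
#' on `unfulfilled`, never silently skipped.
#'
#' @param registry colony registry.
#' @param verdicts sequencing verdicts (see [ingest_ngs()]).
#' @param policy verdict policy, as in [ingest_ngs()].
#' @param kind archive labware kind.
#' @param volume_ul culture volume to transfer.
#' @param prefix archive plate prefix.
#' @return list with `picklist`, `manifest` (`construct_id`,
#'   `colony_id`, source and destination), and `unfulfilled`.
#' @export
consolidate_constructs <- function(registry, verdicts,
                                   policy = list(require_full_coverage = TRUE,
                                                 max_mutations = 0L),
                                   kind = "archive96", volume_ul = 50,
                                   prefix = "archive") {
  ver <- ingest_ngs(verdicts, registry, policy)
  cq <- attr(ver, "colonies")
  verified_ids <- sort(ver$construct_id[ver$verified])
  chosen <- character(0)
  unfulfilled <- character(0)
  for (id in verified_ids) {
    cand <- cq$colony_id[cq$construct_id == id & cq$qualifies]
    if (length(cand) == 0) { unfulfilled <- c(unfulfilled, id); next }
    ri <- match(cand, registry$colony_id)
    widx <- address_to_index(registry$culture_well[ri], "deep96")
    ord <- order(registry$culture_plate[ri], widx)
    chosen <- c(chosen, cand[ord[1]])
  }
  take <- verified_ids[!(verified_ids %in% unfulfilled)]
  ri <- match(chosen, registry$colony_id)
  dest <- allocate_wells(take, kind, prefix = prefix)
  picklist <- data.frame(
    source_plate = registry$culture_plate[ri],
    source_well = registry$culture_well[ri],
    dest_plate = dest$plate_id, dest_well = dest$well,
    volume_ul = rep(volume_ul, length(take)), sample_id = take,
    stringsAsFactors = FALSE)
  manifest <- data.frame(construct_id = take, colony_id = chosen,
                         source_plate = registry$culture_plate[ri],
                         source_well = registry$culture_well[ri],
                         dest_plate = dest$plate_id,
                         dest_well = dest$well, stringsAsFactors = FALSE)
  list(picklist = picklist, manifest = manifest,
       unfulfilled = unfulfilled)
}

#' Per-stage counts and survival rates of a build campaign
#'
#' The funnel: designed constructs, fragment demand, reactions run,
#' fragments verified, feasible constructs, live yeast assemblies,
#' E. coli transformations, colonies picked, colony-PCR passes,
#' sequenced samples, full-coverage and zero-mutation colonies, and
#' unique verified constructs. Rates compare each stage with the stage
#' it conditions on; the construct-level counts are non-increasing by
#' construction.
#'
#' @param state a `build_state`.
#' @return list with `counts`, `rates` (both data.frames) and
#'   `overall_success` (unique verified / designed).
#' @export
funnel_report <- function(state) {
  n <- function(x) if (is.null(x)) 0L else
    if (is.data.frame(x)) nrow(x) else length(x)
  counts <- c(
    designed = nrow(state$design$constructs),
    fragments_demanded = if (is.null(state$plan)) 0L else
      sum(state$plan$n_reactions > 0),
    reactions_run = n(state$reactions),
    fragments_verified = if (is.null(state$fragment_status)) 0L else
      sum(state$fragment_status$status == "verified"),
    feasible = n(state$feasible),
    assembly_growth = n(state$assembly_growth),
    transformation_growth = n(state$transformation_growth),
    colonies_picked = n(state$colonies),
    colony_pcr_pass = if (is.null(state$colony_calls)) 0L else
      sum(state$colony_calls$verdict == "pass"),
    sequenced = if (is.null(state$verdicts)) 0L else
      nrow(state$verdicts),
    fully_covered = if (is.null(state$verdicts)) 0L else
      sum(state$verdicts$coverage_full),
    zero_mutation = if (is.null(state$verdicts)) 0L else
      sum(state$verdicts$coverage_full & state$verdicts$mutation_count == 0),
    unique_verified = n(state$verified)
  )
  rate <- function(a, b) if (b > 0) unname(a / b) else NA_real_
  rates <- data.frame(
    stage = c("fragment_verification", "feasibility", "assembly",
              "transformation", "colony_pcr", "coverage",
              "zero_mutation", "consolidation", "overall"),
    rate = c(
      rate(counts[["fragments_verified"]], counts[["fragments_demanded"]]),
      rate(counts[["feasible"]], counts[["designed"]]),
      rate(counts[["assembly_growth"]], counts[["feasible"]]),
      rate(counts[["transformation_growth"]], counts[["assembly_growth"]]),
      rate(counts[["colony_pcr_pass"]], counts[["colonies_picked"]]),
      rate(counts[["fully_covered"]], counts[["sequenced"]]),
      rate(counts[["zero_mutation"]], counts[["fully_covered"]]),
      rate(counts[["unique_verified"]],
           counts[["transformation_growth"]]),
      rate(counts[["unique_verified"]], counts[["designed"]])),
    stringsAsFactors = FALSE)
  list(counts = data.frame(stage = names(counts),
                           count = as.integer(unname(counts)),
                           stringsAsFactors = FALSE),
       rates = rates,
       overall_success = rate(counts[["unique_verified"]],
                              counts[["designed"]]))
}

#' Save and load campaign state snapshots
#'
#' Versioned JSON snapshots: diff-able provenance with no database.
#' `load_state` restores the design and all stage tables losslessly.
#'
#' @param state a `build_state`.
#' @param path JSON file path.
#' @return `save_state` returns `path` invisibly; `load_state` a
#'   `build_state`.
#' @export
save_state <- function(state, path) {
  payload <- unclass(state)
  payload$design <- unclass(payload$design)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- raw$design
  design <- new_design(d$design_id, as.data.frame(d$parts),
                       as.data.frame(d$oligos), as.data.frame(d$fragments),
                       as.data.frame(d$constructs),
                       homology_bp = d$homology_bp,
                       oligo_max_nt = d$oligo_max_nt, validate = FALSE)
  state <- new_build_state(design)
  chr0 <- function(x) if (is.null(x)) character(0) else as.character(x)
  df_or_null <- function(x) {
    if (is.null(x) || (is.list(x) && length(x) == 0)) NULL
    else as.data.frame(x, stringsAsFactors = FALSE)
  }
  state$plan <- df_or_null(raw$plan)
  state$reactions <- df_or_null(raw$reactions)
  state$calls <- df_or_null(raw$calls)
  state$fragment_status <- df_or_null(raw$fragment_status)
  state$feasible <- chr0(raw$feasible)
  state$assembly_attempted <- chr0(raw$assembly_attempted)
  state$assembly_growth <- chr0(raw$assembly_growth)
  state$transformation_growth <- chr0(raw$transformation_growth)
  state$plating_layout <- df_or_null(raw$plating_layout)
  state$colonies <- df_or_null(raw$colonies)
  state$colony_calls <- df_or_null(raw$colony_calls)
  state$verdicts <- df_or_null(raw$verdicts)
  state$verified <- chr0(raw$verified)
  state$consolidation <- if (is.null(raw$consolidation)) NULL else
    list(picklist = df_or_null(raw$consolidation$picklist),
         manifest = df_or_null(raw$consolidation$manifest),
         unfulfilled = chr0(raw$consolidation$unfulfilled))
  check_provenance(state)
  state
}
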