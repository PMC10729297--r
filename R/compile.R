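# From a design (plus current stocks) to executable instructions:
# vendor order sheets, PCR-setup picklists, thermocycler groupings,
# assembly mixes and the bench worklists in between.

#' Default PCR setup recipe
#'
#' Per-reaction dispense volumes and the acoustic droplet quantum.
#' Master mix and water are dispensed in bulk by a plate filler and are
#' not part of the acoustic picklist.
#'
#' @param primer_ul volume of each primer per reaction.
#' @param template_ul template volume per reaction.
#' @param quantum_ul acoustic droplet quantum (25 nL class instrument).
#' @return named list.
#' @export
default_recipe <- function(primer_ul = 0.5, template_ul = 0.5,
                           quantum_ul = 0.025) {
  list(primer_ul = primer_ul, template_ul = template_ul,
       quantum_ul = quantum_ul)
}

#' How many PCR replicates each fragment needs
#'
#' Combinatorial designs reuse fragments across many constructs; one
#' PCR yields enough product for a limited number of downstream
#' assembly uses. The replicate count is `ceiling(uses / capacity)`
#' where `uses` is the number of target constructs containing the
#' fragment.
#'
#' @param design a `pf_design`.
#' @param capacity_uses_per_reaction assembly uses one PCR can supply.
#' @return data.frame `fragment_id`, `uses`, `n_reactions`; the total
#'   reaction requirement of the campaign is `sum(n_reactions)`.
#' @export
demand_plan <- function(design, capacity_uses_per_reaction = 4L) {
  stopifnot(capacity_uses_per_reaction >= 1)
  frag_lists <- strsplit(design$constructs$fragment_ids, ";", fixed = TRUE)
  uses <- table(factor(unlist(frag_lists),
                       levels = design$fragments$fragment_id))
  data.frame(
    fragment_id = design$fragments$fragment_id,
    uses = as.integer(uses),
    n_reactions = as.integer(ceiling(as.integer(uses) /
                                     capacity_uses_per_reaction)),
    stringsAsFactors = FALSE
  )
}

#' Expand the demand plan into concrete round-1 PCR reactions
#'
#' One reaction per required replicate, laid out sequentially on 96-well
#' PCR plates. Annealing temperatures are taken from an `annealing_c`
#' column on the fragment table when present (j5 reports per-reaction
#' conditions), else a default.
#'
#' @param design a `pf_design`.
#' @param capacity_uses_per_reaction see [demand_plan()].
#' @param annealing_default fallback annealing temperature, Celsius.
#' @param plate_prefix prefix for destination PCR plates.
#' @return data.frame of reactions: `reaction_id`, `fragment_id`,
#'   `template_id`, `forward_oligo_id`, `reverse_oligo_id`,
#'   `expected_size_bp`, `annealing_c`, `round`, `plate_id`, `well`.
#' @export
plan_reactions <- function(design, capacity_uses_per_reaction = 4L,
                           annealing_default = 60,
                           plate_prefix = "pcr_round1") {
  plan <- demand_plan(design, capacity_uses_per_reaction)
  f <- design$fragments
  idx <- rep(seq_len(nrow(plan)), plan$n_reactions)
  rep_no <- sequence(plan$n_reactions)
  fi <- match(plan$fragment_id[idx], f$fragment_id)
  ann <- if ("annealing_c" %in% names(f)) f$annealing_c[fi]
         else rep(annealing_default, length(fi))
  rx <- data.frame(
    reaction_id = sprintf("%s_R1_%d", plan$fragment_id[idx], rep_no),
    fragment_id = plan$fragment_id[idx],
    template_id = f$template_id[fi],
    forward_oligo_id = f$forward_oligo_id[fi],
    reverse_oligo_id = f$reverse_oligo_id[fi],
    expected_size_bp = f$length_bp[fi],
    annealing_c = ann,
    round = 1L,
    stringsAsFactors = FALSE
  )
  layout <- allocate_wells(rx$reaction_id, "pcr96", prefix = plate_prefix)
  rx$plate_id <- layout$plate_id
  rx$well <- layout$well
  rx
}

#' Vendor oligo order sheet
#'
#' One row per unique oligo with its assigned 96-well position, in the
#' upload format synthesis vendors take (Plate, Well, Name, Sequence).
#' Distinct oligo ids sharing a sequence trigger a warning and can be
#' collapsed to the first id on request.
#'
#' @param design a `pf_design`.
#' @param collapse_duplicates drop rows whose sequence already appeared.
#' @param prefix order-plate name prefix.
#' @return data.frame `plate_id`, `well`, `oligo_id`, `name`,
#'   `sequence`.
#' @export
purchase_order <- function(design, collapse_duplicates = FALSE,
                           prefix = "oligo_order") {
  o <- design$oligos
  dup <- duplicated(o$sequence)
  if (any(dup)) {
    warning(sprintf("%d oligo id(s) duplicate an earlier sequence: %s",
                    sum(dup), paste(o$oligo_id[dup], collapse = ", ")))
    if (collapse_duplicates) o <- o[!dup, , drop = FALSE]
  }
  layout <- allocate_wells(o$oligo_id, "pcr96", prefix = prefix)
  data.frame(plate_id = layout$plate_id, well = layout$well,
             oligo_id = o$oligo_id, name = o$name, sequence = o$sequence,
             stringsAsFactors = FALSE)
}

#' Write an order sheet in the vendor 96-well upload format
#' @param order output of [purchase_order()].
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_order_sheet <- function(order, file) {
  out <- data.frame(Plate = order$plate_id, Well = order$well,
                    Name = order$name, Sequence = order$sequence)
  write_table_utf8(out, file)
  invisible(file)
}

#' Array reagents into acoustic source plates
#'
#' Lays samples out on 384-well acoustic source plates, splitting a
#' sample across several wells when its campaign-wide draw exceeds one
#' well's usable volume (capacity minus dead volume). High-use templates
#' in combinatorial builds routinely need this.
#'
#' @param samples data.frame with `sample_id` plus any annotation
#'   columns (e.g. `conc_ng_ul`, `length_bp`, `conc_um`) carried through
#'   to the locations table.
#' @param required_ul named or per-row total volume each sample must
#'   supply (defaults to one well's usable volume).
#' @param kind source labware kind.
#' @param fill_ul volume loaded per well (default: capacity).
#' @param prefix source plate name prefix.
#' @return list with `locations` (one row per physical well:
#'   `sample_id`, `plate_id`, `well`, `volume_ul`, annotations) and
#'   `plates` (a filled `plate_set`).
#' @export
make_source_plates <- function(samples, required_ul = NULL,
                               kind = "echo_source_384", fill_ul = NULL,
                               prefix = "src") {
  spec <- labware_specs(kind)
  fill_ul <- fill_ul %||% spec$capacity_ul
  usable <- fill_ul - spec$dead_ul
  stopifnot(usable > 0)
  req <- required_ul %||% rep(usable, nrow(samples))
  n_wells <- pmax(1L, as.integer(ceiling(req / usable)))
  idx <- rep(seq_len(nrow(samples)), n_wells)
  ids <- samples$sample_id[idx]
  layout <- allocate_wells(ids, kind, prefix = prefix)
  locations <- cbind(layout,
                     volume_ul = fill_ul,
                     samples[idx, setdiff(names(samples), "sample_id"),
                             drop = FALSE])
  rownames(locations) <- NULL
  plates <- new_plate_set(unique(layout$plate_id), kind)
  plates <- add_liquid(plates, data.frame(
    plate_id = layout$plate_id, well = layout$well, sample_id = ids,
    volume_ul = fill_ul))
  list(locations = locations, plates = plates)
}

# Greedy source selection with depletion tracking: each request draws
# from the first location of its sample that still covers volume + dead.
draw_transfers <- function(requests, locations, dead_ul) {
  remaining <- locations$volume_ul
  rows <- split(seq_len(nrow(locations)), locations$sample_id)
  out <- requests[0, c("dest_plate", "dest_well", "volume_ul")]
  src_plate <- character(nrow(requests))
  src_well <- character(nrow(requests))
  for (k in seq_len(nrow(requests))) {
    cand <- rows[[requests$sample_id[k]]]
    j <- cand[remaining[cand] >= requests$volume_ul[k] + dead_ul - 1e-9][1]
    if (is.na(j) || length(j) == 0) pf_stop(
      sprintf("insufficient stock of %s: %.3f uL requested beyond remaining usable volume",
              requests$sample_id[k], requests$volume_ul[k]),
      "pf_volume_error", list(sample_id = requests$sample_id[k]))
    remaining[j] <- remaining[j] - requests$volume_ul[k]
    src_plate[k] <- locations$plate_id[j]
    src_well[k] <- locations$well[j]
  }
  data.frame(source_plate = src_plate, source_well = src_well,
             dest_plate = requests$dest_plate,
             dest_well = requests$dest_well,
             volume_ul = requests$volume_ul,
             sample_id = requests$sample_id,
             stringsAsFactors = FALSE)
}

#' Compile the PCR-setup picklist
#'
#' Per reaction: one transfer each of forward primer, reverse primer and
#' template from the acoustic source plates into the reaction's PCR
#' plate well, at recipe volumes snapped up to the droplet quantum.
#' Compilation validates before emitting: missing stocks abort with the
#' full list of blocked reactions, and the finished picklist is
#' simulated against the source plates so volume shortfalls (including
#' dead volume) surface at compile time, not on the deck.
#'
#' @param reactions reaction table from [plan_reactions()] or
#'   [redo_plan()].
#' @param oligo_stocks,template_stocks outputs of
#'   [make_source_plates()].
#' @param recipe see [default_recipe()].
#' @return list with `picklist` and `plates_after` (source plate set
#'   after the simulated run).
#' @export
pcr_setup <- function(reactions, oligo_stocks, template_stocks,
                      recipe = default_recipe()) {
  have_oligo <- unique(oligo_stocks$locations$sample_id)
  have_tmpl <- unique(template_stocks$locations$sample_id)
  blocked <- reactions$reaction_id[
    !(reactions$forward_oligo_id %in% have_oligo) |
    !(reactions$reverse_oligo_id %in% have_oligo) |
    !(reactions$template_id %in% have_tmpl)]
  if (length(blocked)) pf_stop(
    sprintf("reaction(s) blocked by missing stocks: %s",
            paste(blocked, collapse = ", ")),
    "pf_compile_error", list(blocked = blocked))
  pv <- quantize_up(recipe$primer_ul, recipe$quantum_ul)
  tv <- quantize_up(recipe$template_ul, recipe$quantum_ul)
  requests <- rbind(
    data.frame(sample_id = reactions$forward_oligo_id,
               dest_plate = reactions$plate_id, dest_well = reactions$well,
               volume_ul = pv),
    data.frame(sample_id = reactions$reverse_oligo_id,
               dest_plate = reactions$plate_id, dest_well = reactions$well,
               volume_ul = pv),
    data.frame(sample_id = reactions$template_id,
               dest_plate = reactions$plate_id, dest_well = reactions$well,
               volume_ul = tv)
  )
  locations <- rbind(
    oligo_stocks$locations[c("sample_id", "plate_id", "well", "volume_ul")],
    template_stocks$locations[c("sample_id", "plate_id", "well",
                                "volume_ul")])
  dead <- labware_specs("echo_source_384")$dead_ul
  picklist <- draw_transfers(requests, locations, dead)
  # compile-then-simulate: the emitted picklist must run cleanly
  plates <- merge_plate_sets(oligo_stocks$plates, template_stocks$plates)
  dest <- new_plate_set(unique(reactions$plate_id), "pcr96")
  plates_after <- apply_transfers(merge_plate_sets(plates, dest), picklist)
  list(picklist = picklist, plates_after = plates_after)
}

#' Group PCRs onto thermocyclers by annealing temperature
#'
#' Greedy span-limited 1-D clustering: reactions sorted by annealing
#' temperature are cut into a new group whenever the within-group span
#' would exceed `span_c`. If that yields more groups than `max_groups`,
#' an exact dynamic program finds the contiguous partition into
#' `max_groups` groups minimizing the largest within-group span. Each
#' group runs at the mean of its member temperatures, with extension
#' time sized for its largest product (`extension_step_s` seconds per
#' `extension_rate_bp` base pairs, rounded up).
#'
#' @param reactions reaction table with `annealing_c` and
#'   `expected_size_bp`.
#' @param max_groups thermocycler blocks available.
#' @param span_c maximum within-group temperature span, Celsius.
#' @param extension_rate_bp,extension_step_s polymerase speed.
#' @return list with `assignments` (`reaction_id`, `group`) and
#'   `groups` (`group`, `annealing_c`, `span_c`, `extension_s`, `n`).
#' @export
thermocycler_groups <- function(reactions, max_groups = Inf, span_c = 2,
                                extension_rate_bp = 1000,
                                extension_step_s = 30) {
  stopifnot(max_groups >= 1)
  ord <- order(reactions$annealing_c, reactions$reaction_id)
  t_sorted <- reactions$annealing_c[ord]
  n <- length(t_sorted)
  grp <- integer(n)
  if (n > 0) {
    g <- 1L; start <- t_sorted[1]
    for (i in seq_len(n)) {
      if (t_sorted[i] - start > span_c + 1e-9) {
        g <- g + 1L; start <- t_sorted[i]
      }
      grp[i] <- g
    }
    if (max(grp) > max_groups) {
      grp <- min_span_partition(t_sorted, as.integer(max_groups))
    }
  }
  assignments <- data.frame(reaction_id = reactions$reaction_id[ord],
                            group = grp, stringsAsFactors = FALSE)
  size_sorted <- reactions$expected_size_bp[ord]
  groups <- do.call(rbind, lapply(unique(grp), function(g) {
    in_g <- grp == g
    data.frame(
      group = g,
      annealing_c = round(mean(t_sorted[in_g]), 1),
      span_c = max(t_sorted[in_g]) - min(t_sorted[in_g]),
      extension_s = extension_step_s *
        ceiling(max(size_sorted[in_g]) / extension_rate_bp),
      n = sum(in_g))
  }))
  list(assignments = assignments, groups = groups)
}

# contiguous partition of sorted temps into exactly k groups minimizing
# the maximum within-group span (DP over prefix boundaries)
min_span_partition <- function(t_sorted, k) {
  n <- length(t_sorted)
  k <- min(k, n)
  cost <- matrix(Inf, n, k)   # cost[i, g]: first i temps in g groups
  cut <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) cost[i, 1] <- t_sorted[i] - t_sorted[1]
  if (k > 1) for (g in 2:k) for (i in g:n) {
    for (j in (g - 1):(i - 1)) {
      v <- max(cost[j, g - 1], t_sorted[i] - t_sorted[j + 1])
      if (v < cost[i, g]) { cost[i, g] <- v; cut[i, g] <- j }
    }
  }
  grp <- integer(n)
  i <- n
  for (g in k:1) {
    j <- if (g == 1) 0L else cut[i, g]
    grp[(j + 1):i] <- g
    i <- j
  }
  grp
}

#' Assembly mix specification
#'
#' @param mode `"equimolar"` (same molar amount of every part) or
#'   `"equivolume"` (same volume of every part).
#' @param total_ul target total reaction volume; the remainder after
#'   DNA parts is made up with water.
#' @param target_fmol molar target per part (equimolar mode),
#'   femtomoles.
#' @param vector_excess dimensionless multiplier on the vector part's
#'   molar amount (1 = true equimolar).
#' @param quantum_ul droplet quantum for mix dispenses (2.5 nL
#'   resolution class).
#' @return named list of class `mix_spec`.
#' @export
mix_spec <- function(mode = c("equimolar", "equivolume"), total_ul = 10,
                     target_fmol = 10, vector_excess = 1,
                     quantum_ul = 0.0025) {
  mode <- match.arg(mode)
  stopifnot(total_ul > 0, vector_excess >= 0)
  structure(list(mode = mode, total_ul = total_ul,
                 target_fmol = target_fmol,
                 vector_excess = vector_excess, quantum_ul = quantum_ul),
            class = "mix_spec")
}

#' Per-part volumes for one assembly reaction
#'
#' Equimolar mode converts the molar target to a volume with the
#' average double-stranded DNA molecular weight `MW(L) = 617.96 L +
#' 36.04` g/mol: `v = target_fmol * MW(L) / conc`, rounded UP to the
#' droplet quantum so each part meets at least its molar target; the
#' vector part's target is scaled by `vector_excess`. Equivolume mode
#' splits the total evenly, rounded DOWN so the reaction never
#' overflows. Either way the remainder up to `total_ul` is reported as
#' water; if the part volumes alone exceed the total, compilation fails
#' rather than silently rescaling.
#'
#' @param parts data.frame with `sample_id`, `conc_ng_ul`, `length_bp`,
#'   and logical `is_vector` (concentration and length may be omitted in
#'   equivolume mode).
#' @param spec a [mix_spec()].
#' @return data.frame `sample_id`, `volume_ul`, plus a `water` row
#'   padding to `total_ul`.
#' @export
equimolar_volumes <- function(parts, spec) {
  stopifnot(inherits(spec, "mix_spec"))
  is_vec <- parts$is_vector %||% rep(FALSE, nrow(parts))
  if (spec$mode == "equimolar") {
    if (is.null(parts$conc_ng_ul) || is.null(parts$length_bp) ||
        anyNA(parts$conc_ng_ul) || anyNA(parts$length_bp)) pf_stop(
      "equimolar mode requires concentration and length for every part",
      "pf_compile_error")
    mw <- 617.96 * parts$length_bp + 36.04          # g/mol, dsDNA average
    fmol <- spec$target_fmol * ifelse(is_vec, spec$vector_excess, 1)
    v <- fmol * mw / parts$conc_ng_ul * 1e-6        # fmol * g/mol / (ng/uL)
    v <- quantize_up(v, spec$quantum_ul)
  } else {
    v <- rep(quantize_down(spec$total_ul / nrow(parts), spec$quantum_ul),
             nrow(parts))
  }
  if (sum(v) > spec$total_ul + 1e-9) pf_stop(
    sprintf("part volumes (%.3f uL) exceed the %.3f uL reaction total",
            sum(v), spec$total_ul),
    "pf_volume_error", list(total_ul = sum(v)))
  out <- data.frame(sample_id = parts$sample_id, volume_ul = v,
                    stringsAsFactors = FALSE)
  water <- spec$total_ul - sum(v)
  if (water > 1e-12) out <- rbind(out, data.frame(sample_id = "water",
                                                  volume_ul = water))
  out
}

#' Compile assembly-mix picklists
#'
#' One destination well per construct, receiving each of its fragments
#' at the volume [equimolar_volumes()] computes from the fragment
#' stocks. Only feasible, stocked constructs may be requested; asking
#' for a construct whose fragments are not all in stock names the
#' missing fragments. Water backfill is left to a bulk dispenser and is
#' not part of the acoustic picklist.
#'
#' @param design a `pf_design`.
#' @param construct_ids constructs to assemble.
#' @param fragment_stocks [make_source_plates()] output whose locations
#'   carry `conc_ng_ul` and `length_bp`.
#' @param spec a [mix_spec()].
#' @param plate_prefix destination (assembly) plate prefix.
#' @return list with `picklist`, `destinations` (construct layout) and
#'   `mix` (per construct+fragment volumes incl. water).
#' @export
assembly_picklists <- function(design, construct_ids, fragment_stocks,
                               spec = mix_spec(), plate_prefix = "assembly") {
  locations <- fragment_stocks$locations
  frag_lists <- lapply(construct_ids,
                       function(id) construct_fragments(design, id))
  missing <- lapply(frag_lists, function(f)
    setdiff(f, locations$sample_id))
  bad <- lengths(missing) > 0
  if (any(bad)) pf_stop(
    sprintf("construct(s) not stocked: %s",
            paste(sprintf("%s (missing %s)", construct_ids[bad],
                          vapply(missing[bad], paste, character(1),
                                 collapse = "/")),
                  collapse = "; ")),
    "pf_compile_error",
    list(constructs = construct_ids[bad]))
  dest <- allocate_wells(construct_ids, "pcr96", prefix = plate_prefix)
  role <- design$parts$role[match(design$fragments$part_id,
                                  design$parts$part_id)]
  names(role) <- design$fragments$fragment_id
  requests <- NULL
  mixes <- NULL
  for (k in seq_along(construct_ids)) {
    frs <- frag_lists[[k]]
    li <- match(frs, locations$sample_id)   # first location annotates
    part_tab <- data.frame(sample_id = frs,
                           conc_ng_ul = locations$conc_ng_ul[li],
                           length_bp = locations$length_bp[li],
                           is_vector = unname(role[frs]) == "vector")
    mix <- equimolar_volumes(part_tab, spec)
    mixes <- rbind(mixes, cbind(construct_id = construct_ids[k], mix))
    dna <- mix[mix$sample_id != "water", , drop = FALSE]
    requests <- rbind(requests, data.frame(
      sample_id = dna$sample_id, dest_plate = dest$plate_id[k],
      dest_well = dest$well[k], volume_ul = dna$volume_ul))
  }
  dead <- labware_specs("echo_source_384")$dead_ul
  picklist <- draw_transfers(requests, locations, dead)
  list(picklist = picklist, destinations = dest, mix = mixes)
}

#' Plate-to-plate bench worklists
#'
#' Deterministic worklists for the fixed-pattern bench stages between
#' PCR and sequencing:
#' \describe{
#'   \item{consolidate_pcr}{collapse all passing reactions (across redo
#'     rounds) onto one plate per set of verified fragments — one well
#'     per distinct fragment, sourced from its first passing replicate.}
#'   \item{bead_purify, dpni_digest, transform}{1:1 same-well stamps
#'     onto a fresh plate at a constant volume.}
#'   \item{plate_qtray}{spread each 96-well plate onto two 48-well agar
#'     trays (rows A-D to the first, E-H to the second).}
#' }
#'
#' @param stage one of `"consolidate_pcr"`, `"bead_purify"`,
#'   `"dpni_digest"`, `"transform"`, `"plate_qtray"`.
#' @param layout for `consolidate_pcr`: passing reactions
#'   (`fragment_id`, `plate_id`, `well`); otherwise a sample layout
#'   (`sample_id`, `plate_id`, `well`).
#' @param config list; `volume_ul` (default 20) and `dest_prefix`.
#' @return list with `picklist` and `destinations`.
#' @export
bench_worklist <- function(stage = c("consolidate_pcr", "bead_purify",
                                     "dpni_digest", "transform",
                                     "plate_qtray"),
                           layout, config = list()) {
  stage <- match.arg(stage)
  vol <- config$volume_ul %||% 20
  prefix <- config$dest_prefix %||% stage
  if (stage == "consolidate_pcr") {
    first <- layout[!duplicated(layout$fragment_id), , drop = FALSE]
    dest <- allocate_wells(first$fragment_id, "pcr96", prefix = prefix)
    picklist <- data.frame(
      source_plate = first$plate_id, source_well = first$well,
      dest_plate = dest$plate_id, dest_well = dest$well,
      volume_ul = vol, sample_id = first$fragment_id,
      stringsAsFactors = FALSE)
    return(list(picklist = picklist, destinations = dest))
  }
  if (stage == "plate_qtray") {
    src_plates <- unique(layout$plate_id)
    idx <- address_to_index(layout$well, c(8, 12))
    if (any(is.na(idx))) pf_stop("qtray plating needs 96-well sources",
                                 "pf_address_error")
    plate_no <- match(layout$plate_id, src_plates) - 1L
    tray_no <- plate_no * 2L + idx %/% 48L + 1L
    dest_well <- index_to_address(idx %% 48L, c(6, 8))
    picklist <- data.frame(
      source_plate = layout$plate_id, source_well = layout$well,
      dest_plate = sprintf("%s_%d", prefix, tray_no),
      dest_well = dest_well, volume_ul = vol,
      sample_id = layout$sample_id, stringsAsFactors = FALSE)
    dest <- data.frame(sample_id = layout$sample_id,
                       plate_id = picklist$dest_plate,
                       well = picklist$dest_well, stringsAsFactors = FALSE)
    return(list(picklist = picklist, destinations = dest))
  }
  # 1:1 same-well stamp stages
  g <- resolve_geometry("pcr96")
  parse_well(layout$well, g)   # geometry check
  dest_plate <- sprintf("%s_%s", prefix, layout$plate_id)
  picklist <- data.frame(
    source_plate = layout$plate_id, source_well = layout$well,
    dest_plate = dest_plate, dest_well = layout$well, volume_ul = vol,
    sample_id = layout$sample_id, stringsAsFactors = FALSE)
  dest <- data.frame(sample_id = layout$sample_id, plate_id = dest_plate,
                     well = layout$well, stringsAsFactors = FALSE)
  list(picklist = picklist, destinations = dest)
}
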