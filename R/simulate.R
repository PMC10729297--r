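# Seeded synthetic campaigns: a combinatorial design generator plus a
# stage-structured simulator that emits exactly the artifacts the
# pipeline consumes (peak tables, picker output, sequencing verdicts)
# together with the latent ground truth for every outcome.

#' Campaign simulation configuration
#'
#' Defaults emulate a large combinatorial plasmid build: a vector bin
#' plus three insert bins whose full-factorial expansion is 882 target
#' constructs, 60 bp homologous overlaps between adjacent parts,
#' multi-kb fragments, up to six PCR rounds with three colonies picked
#' per transformed construct. Stage probabilities default to the
#' empirical attrition of such a campaign: PCR success 0.88, yeast
#' assembly growth 0.66, E. coli transformation growth 0.70, colony-PCR
#' pass 0.41, full sequencing coverage 0.76, zero mutations 0.65.
#'
#' @param n_bins number of bins (>= 2); bin 1 holds the vectors.
#' @param parts_per_bin integer vector (recycled to `n_bins`).
#' @param fragment_length_range part/fragment length range, bp.
#' @param homology_bp exact overlap shared by adjacent parts.
#' @param stage_probs named probabilities `pcr_pass`, `yeast_growth`,
#'   `coli_growth`, `colony_pcr_pass`, `full_coverage`,
#'   `zero_mutation`, each in \[0, 1\].
#' @param size_noise_sd relative sd of observed peak sizes.
#' @param capacity_uses_per_reaction assembly uses one PCR supplies.
#' @param max_rounds PCR redo budget (including round 1).
#' @param picks_per_construct colonies picked per transformed
#'   construct.
#' @param tolerance,min_conc_ng_ul QC call thresholds.
#' @param marker_sizes alignment-marker sizes injected into every lane.
#' @param seed integer; seeded runs are reproducible bit for bit.
#' @return named list of class `campaign_config`.
#' @export
campaign_config <- function(n_bins = 4L,
                            parts_per_bin = c(2L, 7L, 7L, 9L),
                            fragment_length_range = c(1500L, 3500L),
                            homology_bp = 60L,
                            stage_probs = c(pcr_pass = 0.88,
                                            yeast_growth = 0.66,
                                            coli_growth = 0.70,
                                            colony_pcr_pass = 0.41,
                                            full_coverage = 0.76,
                                            zero_mutation = 0.65),
                            size_noise_sd = 0.03,
                            capacity_uses_per_reaction = 4L,
                            max_rounds = 6L, picks_per_construct = 3L,
                            tolerance = 0.10, min_conc_ng_ul = 1,
                            marker_sizes = c(15, 7000), seed = 1L) {
  stopifnot(n_bins >= 2, all(stage_probs >= 0), all(stage_probs <= 1),
            length(fragment_length_range) == 2,
            fragment_length_range[1] >= 2 * homology_bp + 40,
            max_rounds >= 1)
  need <- c("pcr_pass", "yeast_growth", "coli_growth", "colony_pcr_pass",
            "full_coverage", "zero_mutation")
  stopifnot(all(need %in% names(stage_probs)))
  structure(list(
    n_bins = as.integer(n_bins),
    parts_per_bin = rep_len(as.integer(parts_per_bin), n_bins),
    fragment_length_range = as.integer(fragment_length_range),
    homology_bp = as.integer(homology_bp),
    stage_probs = stage_probs[need],
    size_noise_sd = size_noise_sd,
    capacity_uses_per_reaction = as.integer(capacity_uses_per_reaction),
    max_rounds = as.integer(max_rounds),
    picks_per_construct = as.integer(picks_per_construct),
    tolerance = tolerance, min_conc_ng_ul = min_conc_ng_ul,
    marker_sizes = marker_sizes, seed = as.integer(seed)
  ), class = "campaign_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a full-factorial combinatorial design
#'
#' Each of the `n_bins` junctions (including the wrap-around back to
#' the vector) gets a random homology sequence of exactly
#' `homology_bp`; every part in a bin carries its flanking homology
#' arms, so all adjacent fragment pairs share exact overlaps by
#' construction and every expected assembly validates. One fragment
#' (and primer pair) per part; the target constructs are the full
#' factorial over bins, so the construct count is the product of the
#' bin sizes. Seeded and byte-deterministic.
#'
#' @param config a [campaign_config()].
#' @param path optional directory; the design bundle is written there.
#' @return a `pf_design` whose fragment table carries an `annealing_c`
#'   metadata column.
#' @export
generate_design <- function(config, path = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed)
  h <- config$homology_bp
  nb <- config$n_bins
  ppb <- config$parts_per_bin
  # junction j sits between bin j and bin j+1 (junction nb wraps to bin 1)
  junction <- vapply(seq_len(nb), function(j) rand_dna(h), character(1))
  parts <- NULL
  for (j in seq_len(nb)) {
    left <- junction[if (j == 1) nb else j - 1]
    for (k in seq_len(ppb[j])) {
      len <- sample(config$fragment_length_range[1]:
                    config$fragment_length_range[2], 1)
      core <- rand_dna(len - 2L * h)
      parts <- rbind(parts, data.frame(
        part_id = sprintf("bin%d_p%d", j, k),
        bin_id = sprintf("bin%d", j),
        role = if (j == 1) "vector" else "insert",
        sequence = paste0(left, core, junction[j]),
        stringsAsFactors = FALSE))
    }
  }
  core_of <- substring(parts$sequence, h + 1L,
                       nchar(parts$sequence) - h)
  oligos <- data.frame(
    oligo_id = c(paste0(parts$part_id, "_F"), paste0(parts$part_id, "_R")),
    name = c(paste0(parts$part_id, "_fwd"), paste0(parts$part_id, "_rev")),
    sequence = c(substring(core_of, 1L, 20L),
                 revcomp(substring(core_of, nchar(core_of) - 19L,
                                   nchar(core_of)))),
    stringsAsFactors = FALSE)
  fragments <- data.frame(
    fragment_id = paste0("frag_", parts$part_id),
    part_id = parts$part_id,
    length_bp = nchar(parts$sequence),
    left_overlap_bp = h, right_overlap_bp = h,
    template_id = paste0("tmpl_", parts$part_id),
    forward_oligo_id = paste0(parts$part_id, "_F"),
    reverse_oligo_id = paste0(parts$part_id, "_R"),
    annealing_c = sample(seq(55, 68, by = 0.5), nrow(parts),
                         replace = TRUE),
    stringsAsFactors = FALSE)
  combos <- expand.grid(lapply(seq_len(nb), function(j)
    fragments$fragment_id[parts$bin_id == sprintf("bin%d", j)]),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  constructs <- data.frame(
    construct_id = sprintf("pl%0*d", nchar(nrow(combos)),
                           seq_len(nrow(combos))),
    fragment_ids = apply(combos, 1, paste, collapse = ";"),
    circular = TRUE,
    stringsAsFactors = FALSE)
  d <- new_design(sprintf("sim_design_seed%d", config$seed),
                  parts, oligos, fragments, constructs,
                  homology_bp = h, validate = FALSE)
  validate_design(d, check_junctions = nrow(constructs) <= 2000)
  if (!is.null(path)) write_design(d, path)
  d
}

# one lane of simulated peaks: the good band, a failure artifact, or
# nothing; alignment markers are always present
simulate_lane <- function(plate, well, expected, good, config) {
  rows <- data.frame(plate_id = plate, well = well,
                     size_bp = config$marker_sizes,
                     conc_ng_ul = 10)
  if (good) {
    rows <- rbind(rows, data.frame(
      plate_id = plate, well = well,
      size_bp = round(expected * (1 + stats::rnorm(1, 0,
                                                   config$size_noise_sd))),
      conc_ng_ul = round(stats::runif(1, 5, 50), 2)))
  } else {
    mode <- sample(c("empty", "wrong_size", "weak"), 1,
                   prob = c(0.4, 0.4, 0.2))
    if (mode == "wrong_size") rows <- rbind(rows, data.frame(
      plate_id = plate, well = well,
      size_bp = round(expected * stats::runif(1, 0.2, 0.7)),
      conc_ng_ul = round(stats::runif(1, 5, 50), 2)))
    if (mode == "weak") rows <- rbind(rows, data.frame(
      plate_id = plate, well = well,
      size_bp = round(expected * (1 + stats::rnorm(1, 0,
                                                   config$size_noise_sd))),
      conc_ng_ul = round(stats::runif(1, 0.01,
                                      0.9 * config$min_conc_ng_ul), 3)))
  }
  rows
}

#' Simulate a full build campaign
#'
#' Every planned PCR lineage succeeds with probability `pcr_pass`; a
#' succeeding lineage shows its product (at the expected size times
#' `1 + Normal(0, size_noise_sd)` relative noise) from its latent
#' success round onward, earlier rounds and failing lineages show an
#' empty lane, an off-size artifact or a sub-threshold band. Redo
#' rounds follow the package's own redo planner, so the emitted peak
#' tables line up with what the QC module will schedule. Downstream
#' stages (yeast growth per feasible construct, E. coli growth, colony
#' PCR per picked colony, sequencing coverage and mutations) are
#' independent Bernoulli draws at the configured rates. All latent
#' outcomes are recorded in a ground-truth log.
#'
#' @param design a `pf_design` from [generate_design()].
#' @param config the [campaign_config()] used to generate it.
#' @return list with `reactions_by_round`, `peak_tables` (one per
#'   round, markers included), `growth` (per-construct yeast/coli
#'   observations), `picker` (colony-picker CSV shape), `colony_peaks`,
#'   `verdicts`, the deterministic `assembly_layout` /
#'   `plating_layout`, and `truth`.
#' @export
simulate_campaign <- function(design, config) {
  stopifnot(inherits(config, "campaign_config"))
  set.seed(config$seed + 500009L)
  p <- config$stage_probs
  plan <- demand_plan(design, config$capacity_uses_per_reaction)
  rx1 <- plan_reactions(design, config$capacity_uses_per_reaction)
  lineage <- sub("_R1_", "_", rx1$reaction_id)
  pass <- stats::rbinom(nrow(rx1), 1, p[["pcr_pass"]]) == 1
  # success round: front-loaded geometric, truncated to the budget
  w <- 0.6 * 0.4^(seq_len(config$max_rounds) - 1)
  pass_round <- ifelse(pass,
                       sample(seq_len(config$max_rounds), nrow(rx1),
                              replace = TRUE, prob = w / sum(w)),
                       NA_integer_)
  names(pass_round) <- lineage
  truth_pcr <- data.frame(lineage = lineage, fragment_id = rx1$fragment_id,
                          pass = pass, pass_round = unname(pass_round),
                          stringsAsFactors = FALSE)

  reactions_by_round <- list()
  peak_tables <- list()
  cur <- rx1
  for (r in seq_len(config$max_rounds)) {
    reactions_by_round[[r]] <- cur
    lin <- sub(sprintf("_R%d_", r), "_", cur$reaction_id)
    good <- !is.na(pass_round[lin]) & pass_round[lin] <= r
    peaks_r <- do.call(rbind, lapply(seq_len(nrow(cur)), function(k)
      simulate_lane(cur$plate_id[k], cur$well[k],
                    cur$expected_size_bp[k], good[k], config)))
    peak_tables[[r]] <- peaks_r
    calls_r <- call_reactions(
      cur,
      parse_peak_table(peaks_r, "pcr96",
                       mapping = c(well = "well", size_bp = "size_bp",
                                   conc_ng_ul = "conc_ng_ul",
                                   plate_id = "plate_id"),
                       marker_sizes = config$marker_sizes),
      config$tolerance, config$min_conc_ng_ul)
    nxt <- redo_plan(calls_r, r)
    if (r == config$max_rounds || nrow(nxt) == 0) break
    cur <- nxt
  }
  all_calls <- NULL
  for (r in seq_along(reactions_by_round)) {
    all_calls <- rbind(all_calls, call_reactions(
      reactions_by_round[[r]],
      parse_peak_table(peak_tables[[r]], "pcr96",
                       mapping = c(well = "well", size_bp = "size_bp",
                                   conc_ng_ul = "conc_ng_ul",
                                   plate_id = "plate_id"),
                       marker_sizes = config$marker_sizes),
      config$tolerance, config$min_conc_ng_ul))
  }
  status <- fragment_status(all_calls, plan, config$max_rounds)
  feasible <- feasible_constructs(design, status)

  assembly_layout <- allocate_wells(feasible, "pcr96",
                                    prefix = "assembly")
  yeast <- stats::rbinom(length(feasible), 1, p[["yeast_growth"]]) == 1
  grown <- feasible[yeast]
  coli <- stats::rbinom(length(grown), 1, p[["coli_growth"]]) == 1
  transformed <- grown[coli]
  growth <- data.frame(
    construct_id = feasible,
    yeast_growth = yeast,
    coli_growth = replace(rep(FALSE, length(feasible)),
                          match(transformed, feasible), TRUE),
    stringsAsFactors = FALSE)

  extract_layout <- allocate_wells(grown, "pcr96", prefix = "extract")
  plating <- if (length(grown)) {
    bench_worklist("plate_qtray", extract_layout,
                   list(dest_prefix = "qtray"))$destinations
  } else {
    data.frame(sample_id = character(0), plate_id = character(0),
               well = character(0))
  }

  picks <- config$picks_per_construct
  src <- plating[match(rep(transformed, each = picks),
                       plating$sample_id), , drop = FALSE]
  culture <- allocate_wells(
    sprintf("pick_%d", seq_len(picks * length(transformed))),
    "deep96", prefix = "culture")
  picker <- data.frame(source_plate = src$plate_id,
                       source_well = src$well,
                       dest_plate = culture$plate_id,
                       dest_well = culture$well,
                       stringsAsFactors = FALSE)
  registry <- register_colonies(picker, plating, picks)

  cpcr_ok <- stats::rbinom(nrow(registry), 1,
                           p[["colony_pcr_pass"]]) == 1
  crx <- colony_pcr_reactions(registry, design)
  colony_peaks <- if (nrow(registry)) do.call(rbind, lapply(
    seq_len(nrow(crx)), function(k)
      simulate_lane(crx$plate_id[k], crx$well[k], crx$expected_size_bp[k],
                    cpcr_ok[k], config)))
  else data.frame(plate_id = character(0), well = character(0),
                  size_bp = numeric(0), conc_ng_ul = numeric(0))
  colony_calls <- call_reactions(
    crx,
    parse_peak_table(colony_peaks, "deep96",
                     mapping = c(well = "well", size_bp = "size_bp",
                                 conc_ng_ul = "conc_ng_ul",
                                 plate_id = "plate_id"),
                     marker_sizes = config$marker_sizes),
    config$tolerance, config$min_conc_ng_ul)
  sequenced <- colony_calls$reaction_id[colony_calls$verdict == "pass"]

  covered <- stats::rbinom(length(sequenced), 1,
                           p[["full_coverage"]]) == 1
  zero_mut <- stats::rbinom(length(sequenced), 1,
                            p[["zero_mutation"]]) == 1
  mutation_count <- ifelse(covered & zero_mut, 0L,
                           1L + stats::rpois(length(sequenced), 1.5))
  verdicts <- data.frame(colony_id = sequenced,
                         coverage_full = covered,
                         mutation_count = as.integer(mutation_count),
                         stringsAsFactors = FALSE)

  truth <- list(
    pcr = truth_pcr,
    fragments = data.frame(
      fragment_id = plan$fragment_id,
      verified = vapply(plan$fragment_id, function(f)
        any(truth_pcr$pass[truth_pcr$fragment_id == f]), logical(1)),
      stringsAsFactors = FALSE),
    constructs = growth,
    colonies = data.frame(colony_id = registry$colony_id,
                          construct_id = registry$construct_id,
                          colony_pcr_pass = cpcr_ok,
                          stringsAsFactors = FALSE),
    sequencing = data.frame(colony_id = sequenced,
                            coverage_full = covered,
                            zero_mutation = covered & zero_mut,
                            stringsAsFactors = FALSE)
  )
  list(reactions_by_round = reactions_by_round,
       peak_tables = peak_tables, growth = growth, picker = picker,
       colony_peaks = colony_peaks, verdicts = verdicts,
       assembly_layout = assembly_layout, plating_layout = plating,
       truth = truth)
}

#' Run the tracking pipeline over simulated (or uploaded) campaign data
#'
#' Consumes exactly the artifacts a real campaign uploads — per-round
#' peak tables, growth observations, the colony-picker file, colony-PCR
#' peaks and sequencing verdicts — and drives the full state machine:
#' QC calls, fragment status, feasibility, colony registration, NGS
#' ingestion and consolidation.
#'
#' @param design a `pf_design`.
#' @param sim output of [simulate_campaign()] (or equivalently shaped
#'   real data).
#' @param config the [campaign_config()] in force.
#' @return a completed `build_state`.
#' @export
run_campaign <- function(design, sim, config) {
  pk_map <- c(well = "well", size_bp = "size_bp",
              conc_ng_ul = "conc_ng_ul", plate_id = "plate_id")
  state <- new_build_state(design)
  state$plan <- demand_plan(design, config$capacity_uses_per_reaction)
  calls <- NULL
  reactions <- NULL
  for (r in seq_along(sim$reactions_by_round)) {
    cur <- sim$reactions_by_round[[r]]
    peaks <- parse_peak_table(sim$peak_tables[[r]], "pcr96",
                              mapping = pk_map,
                              marker_sizes = config$marker_sizes)
    calls <- rbind(calls, call_reactions(cur, peaks, config$tolerance,
                                         config$min_conc_ng_ul))
    reactions <- rbind(reactions, cur)
  }
  state$reactions <- reactions
  state$calls <- calls
  state$fragment_status <- fragment_status(calls, state$plan,
                                           config$max_rounds)
  state$feasible <- feasible_constructs(design, state$fragment_status)
  state$assembly_attempted <- state$feasible
  g <- sim$growth
  state$assembly_growth <- g$construct_id[g$yeast_growth]
  state$transformation_growth <- g$construct_id[g$coli_growth]
  grown <- state$assembly_growth
  extract_layout <- allocate_wells(grown, "pcr96", prefix = "extract")
  state$plating_layout <- if (length(grown)) {
    bench_worklist("plate_qtray", extract_layout,
                   list(dest_prefix = "qtray"))$destinations
  } else {
    data.frame(sample_id = character(0), plate_id = character(0),
               well = character(0))
  }
  state$colonies <- register_colonies(sim$picker, state$plating_layout,
                                      config$picks_per_construct)
  crx <- colony_pcr_reactions(state$colonies, design)
  state$colony_calls <- call_reactions(
    crx,
    parse_peak_table(sim$colony_peaks, "deep96", mapping = pk_map,
                     marker_sizes = config$marker_sizes),
    config$tolerance, config$min_conc_ng_ul)
  state$verdicts <- sim$verdicts
  if (nrow(sim$verdicts)) {
    ver <- ingest_ngs(sim$verdicts, state$colonies)
    state$verified <- ver$construct_id[ver$verified]
    state$consolidation <- consolidate_constructs(state$colonies,
                                                  sim$verdicts)
  } else {
    state$verified <- character(0)
    state$consolidation <- NULL
  }
  check_provenance(state)
  state
}
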