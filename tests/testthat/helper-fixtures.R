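# Small campaign configurations and independent brute-force oracles.
# Oracles deliberately avoid the code paths they check.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_bins = 3L, parts_per_bin = c(2L, 3L, 4L),
               fragment_length_range = c(200L, 400L), homology_bp = 30L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(campaign_config, args)
}

all_success_probs <- c(pcr_pass = 1, yeast_growth = 1, coli_growth = 1,
                       colony_pcr_pass = 1, full_coverage = 1,
                       zero_mutation = 1)

random_config <- function(seed) {
  set.seed(seed)
  nb <- sample(2:5, 1)
  tiny_config(seed = seed, n_bins = nb,
              parts_per_bin = sample(1:4, nb, replace = TRUE))
}

# naive string merge: find the longest exact suffix/prefix match at each
# junction by direct comparison, never consulting declared overlaps
oracle_merge <- function(seqs, circular, min_ov = 1) {
  overlap_of <- function(a, b) {
    for (k in seq(min(nchar(a), nchar(b)), min_ov)) {
      if (substring(a, nchar(a) - k + 1, nchar(a)) ==
          substring(b, 1, k)) return(k)
    }
    0L
  }
  out <- seqs[1]
  for (i in seq_along(seqs)[-1]) {
    k <- overlap_of(out, seqs[i])
    out <- paste0(out, substring(seqs[i], k + 1))
  }
  if (circular) {
    k <- overlap_of(out, seqs[1])
    out <- substring(out, 1, nchar(out) - k)
  }
  out
}

# replicate counts from the expanded construct x fragment incidence
oracle_demand <- function(design, capacity) {
  counts <- integer(nrow(design$fragments))
  names(counts) <- design$fragments$fragment_id
  for (cid in design$constructs$construct_id) {
    for (f in construct_fragments(design, cid)) {
      counts[f] <- counts[f] + 1L
    }
  }
  ceiling(counts / capacity)
}

# subset check per construct, one at a time
oracle_feasible <- function(design, verified) {
  out <- character(0)
  for (cid in design$constructs$construct_id) {
    frs <- construct_fragments(design, cid)
    ok <- TRUE
    for (f in frs) if (!(f %in% verified)) ok <- FALSE
    if (ok) out <- c(out, cid)
  }
  out
}

# brute force: does any assignment of sorted temps into <= k contiguous
# groups achieve max span <= bound? (small n only)
oracle_best_span <- function(temps, k) {
  t_sorted <- sort(temps)
  n <- length(t_sorted)
  if (k >= n) return(0)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    span <- max(vapply(seq_len(k), function(g)
      t_sorted[bounds[g + 1]] - t_sorted[bounds[g] + 1], numeric(1)))
    best <- min(best, span)
  }
  best
}

make_peaks <- function(well, size, conc, plate = NULL) {
  df <- data.frame(well = well, size_bp = size, conc_ng_ul = conc,
                   stringsAsFactors = FALSE)
  if (!is.null(plate)) df$plate_id <- plate
  df
}
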