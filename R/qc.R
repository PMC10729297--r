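# Capillary-electrophoresis QC: parse peak tables, score each PCR
# against its expected product size, aggregate replicate calls into
# fragment verification, and roll failures into redo rounds.

#' Parse a capillary-electrophoresis peak table
#'
#' Reads a delimited peak export (one row per peak), applies a column
#' mapping for the instrument's dialect, drops configured
#' alignment-marker sizes, and returns peaks grouped by well and sorted
#' by size. Rows that cannot be parsed (bad well address, non-numeric
#' size, non-positive size, negative concentration) are collected on the
#' `bad_rows` attribute and reported with a warning — never silently
#' dropped.
#'
#' @param file path or a data.frame already in memory.
#' @param geometry labware kind or c(rows, cols) the wells must fit.
#' @param mapping named character vector mapping canonical columns
#'   `well`, `size_bp`, `conc_ng_ul` (and optional `plate_id`) to the
#'   file's column names.
#' @param marker_sizes ladder/alignment marker sizes (bp) to remove.
#' @return data.frame `plate_id` (if mapped), `well`, `size_bp`,
#'   `conc_ng_ul`, class `peak_table`.
#' @export
parse_peak_table <- function(file, geometry = "pcr96",
                             mapping = c(well = "well",
                                         size_bp = "size_bp",
                                         conc_ng_ul = "conc_ng_ul"),
                             marker_sizes = numeric(0)) {
  raw <- if (is.data.frame(file)) file else read_table_utf8(file)
  miss <- mapping[!(mapping %in% names(raw))]
  if (length(miss)) pf_stop(
    sprintf("peak table missing column(s): %s",
            paste(miss, collapse = ", ")), "pf_format_error")
  df <- data.frame(
    well = as.character(raw[[mapping[["well"]]]]),
    size_bp = suppressWarnings(as.numeric(raw[[mapping[["size_bp"]]]])),
    conc_ng_ul = suppressWarnings(
      as.numeric(raw[[mapping[["conc_ng_ul"]]]])),
    stringsAsFactors = FALSE)
  if ("plate_id" %in% names(mapping))
    df$plate_id <- as.character(raw[[mapping[["plate_id"]]]])
  g <- resolve_geometry(geometry)
  well_ok <- grepl("^[A-Pa-p]0*[0-9]+$", df$well)
  well_ok[well_ok] <- !vapply(df$well[well_ok], function(w)
    inherits(tryCatch(parse_well(w, g), error = identity), "error"),
    logical(1))
  bad <- !well_ok | is.na(df$size_bp) | df$size_bp <= 0 |
    is.na(df$conc_ng_ul) | df$conc_ng_ul < 0
  if (any(bad)) {
    warning(sprintf("%d unparseable peak row(s) set aside", sum(bad)))
  }
  bad_rows <- raw[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  df$well <- toupper(sub("^([A-Pa-p])0+", "\\1", df$well))
  df <- df[!(df$size_bp %in% marker_sizes), , drop = FALSE]
  ord <- if ("plate_id" %in% names(df))
    order(df$plate_id, df$well, df$size_bp) else order(df$well, df$size_bp)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, bad_rows = bad_rows, class = c("peak_table", "data.frame"))
}

#' @rdname parse_peak_table
#' @param peaks a peak table to serialize.
#' @export
write_peak_table <- function(peaks, file) {
  write_table_utf8(as.data.frame(peaks), file)
  invisible(file)
}

#' Score PCR reactions against expected product sizes
#'
#' A reaction passes if its lane holds a peak within the relative size
#' tolerance at or above the minimum concentration. The matched peak is
#' the one with the smallest relative size error, ties broken toward
#' higher concentration. A lane with no peaks at all is an
#' `empty_lane`; passing at tolerance t implies passing at any larger
#' tolerance (monotonicity).
#'
#' @param reactions data.frame with `reaction_id`, `well`,
#'   `expected_size_bp` (plus optional `plate_id`, `fragment_id`,
#'   `round`, carried through).
#' @param peaks a [parse_peak_table()] result (or equivalent
#'   data.frame).
#' @param tolerance relative size tolerance, in (0, 1).
#' @param min_conc_ng_ul minimum matched-peak concentration.
#' @return data.frame of calls: `reaction_id`, `verdict` (`pass`,
#'   `fail`, `empty_lane`), `matched_size_bp`, `matched_conc_ng_ul`,
#'   `relative_error`, plus carried columns.
#' @export
call_reactions <- function(reactions, peaks, tolerance = 0.10,
                           min_conc_ng_ul = 1) {
  stopifnot(tolerance > 0, tolerance < 1)
  pk_key <- if ("plate_id" %in% names(peaks) &&
                "plate_id" %in% names(reactions))
    paste(peaks$plate_id, peaks$well) else peaks$well
  rx_key <- if ("plate_id" %in% names(peaks) &&
                "plate_id" %in% names(reactions))
    paste(reactions$plate_id, reactions$well) else reactions$well
  by_lane <- split(seq_len(nrow(peaks)), pk_key)
  n <- nrow(reactions)
  verdict <- character(n)
  m_size <- rep(NA_real_, n); m_conc <- rep(NA_real_, n)
  rel_err <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    lane <- by_lane[[rx_key[k]]]
    if (is.null(lane) || length(lane) == 0) {
      verdict[k] <- "empty_lane"
      next
    }
    err <- abs(peaks$size_bp[lane] - reactions$expected_size_bp[k]) /
      reactions$expected_size_bp[k]
    ok <- err <= tolerance & peaks$conc_ng_ul[lane] >= min_conc_ng_ul
    if (any(ok)) {
      cand <- lane[ok]
      cerr <- err[ok]
      best <- cand[order(cerr, -peaks$conc_ng_ul[cand])][1]
      verdict[k] <- "pass"
      m_size[k] <- peaks$size_bp[best]
      m_conc[k] <- peaks$conc_ng_ul[best]
      rel_err[k] <- min(cerr)
    } else {
      verdict[k] <- "fail"
    }
  }
  out <- data.frame(reaction_id = reactions$reaction_id, verdict = verdict,
                    matched_size_bp = m_size, matched_conc_ng_ul = m_conc,
                    relative_error = rel_err, stringsAsFactors = FALSE)
  for (col in intersect(c("fragment_id", "round", "plate_id", "well",
                          "expected_size_bp", "annealing_c", "template_id",
                          "forward_oligo_id", "reverse_oligo_id"),
                        names(reactions))) {
    out[[col]] <- reactions[[col]]
  }
  out
}

#' Aggregate replicate calls into fragment verification status
#'
#' A fragment is `verified` once any replicate passed in any round;
#' `exhausted` when the allowed redo rounds have all been called without
#' a pass; otherwise `pending`.
#'
#' @param calls accumulated [call_reactions()] output across rounds
#'   (needs `fragment_id`, `verdict`, `round`).
#' @param plan the campaign [demand_plan()].
#' @param max_rounds redo budget, including the first round.
#' @return data.frame `fragment_id`, `status`.
#' @export
fragment_status <- function(calls, plan, max_rounds = 6L) {
  frags <- plan$fragment_id[plan$n_reactions > 0]
  status <- vapply(frags, function(f) {
    mine <- calls[!is.na(calls$fragment_id) & calls$fragment_id == f, ,
                  drop = FALSE]
    if (nrow(mine) && any(mine$verdict == "pass")) return("verified")
    if (nrow(mine) && max(mine$round) >= max_rounds) return("exhausted")
    "pending"
  }, character(1))
  data.frame(fragment_id = frags, status = unname(status),
             stringsAsFactors = FALSE)
}

#' Plan the next redo round for failed PCRs
#'
#' Exactly the non-passing calls of the current round come back as new
#' reactions with the round number incremented and a fresh consolidated
#' plate layout. Under the default strategy conditions are copied
#' verbatim; under `"gradient"` the annealing temperature is perturbed
#' by +2/-2 Celsius, alternating across the redo set.
#'
#' @param calls [call_reactions()] output for round `round_n` (must
#'   carry the reaction columns through).
#' @param round_n the round just analyzed.
#' @param strategy `"repeat"` or `"gradient"`.
#' @param plate_prefix prefix for the redo plates (default
#'   `pcr_round<n+1>`).
#' @return reaction table for round `round_n + 1` (possibly 0 rows).
#'   Together with the passing calls it partitions the input set.
#' @export
redo_plan <- function(calls, round_n, strategy = c("repeat", "gradient"),
                      plate_prefix = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(round_n >= 1)
  cur <- calls[calls$round == round_n, , drop = FALSE]
  failed <- cur[cur$verdict != "pass", , drop = FALSE]
  prefix <- plate_prefix %||% sprintf("pcr_round%d", round_n + 1L)
  if (nrow(failed) == 0) {
    rx <- failed
  } else {
    rx <- failed
    rx$round <- round_n + 1L
    rx$reaction_id <- sub("_R[0-9]+_", sprintf("_R%d_", round_n + 1L),
                          rx$reaction_id)
    if (strategy == "gradient") {
      rx$annealing_c <- rx$annealing_c +
        rep(c(2, -2), length.out = nrow(rx))
    }
    layout <- allocate_wells(rx$reaction_id, "pcr96", prefix = prefix)
    rx$plate_id <- layout$plate_id
    rx$well <- layout$well
  }
  keep <- c("reaction_id", "fragment_id", "template_id",
            "forward_oligo_id", "reverse_oligo_id", "expected_size_bp",
            "annealing_c", "round", "plate_id", "well")
  rx[, intersect(keep, names(rx)), drop = FALSE]
}

#' Constructs buildable from the verified fragments
#'
#' A construct is feasible exactly when every fragment on its ordered
#' list is verified. Pure function of the design and the status table;
#' monotone in the verified set.
#'
#' @param design a `pf_design`.
#' @param status [fragment_status()] output.
#' @return character vector of feasible construct ids (design order).
#' @export
feasible_constructs <- function(design, status) {
  verified <- status$fragment_id[status$status == "verified"]
  frag_lists <- strsplit(design$constructs$fragment_ids, ";", fixed = TRUE)
  ok <- vapply(frag_lists, function(f) all(f %in% verified), logical(1))
  design$constructs$construct_id[ok]
}
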