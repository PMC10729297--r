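# Combinatorial assembly designs: parts arranged in bins, PCR fragments
# carrying homology arms, and the full set of target constructs. The
# native bundle dialect is four CSV tables plus a small JSON header; a
# column-mapping config adapts external (j5-style) exports.

design_tables <- c("parts", "oligos", "fragments", "constructs")

design_required_cols <- list(
  parts = c("part_id", "bin_id", "role", "sequence"),
  oligos = c("oligo_id", "name", "sequence"),
  fragments = c("fragment_id", "part_id", "length_bp", "left_overlap_bp",
                "right_overlap_bp", "template_id", "forward_oligo_id",
                "reverse_oligo_id"),
  constructs = c("construct_id", "fragment_ids", "circular")
)

#' The native design-bundle dialect
#'
#' File names and required columns of the four tables a design bundle is
#' made of. A user-supplied mapping (same shape) adapts differently
#' named exports: `files` maps table -> file name, `columns` maps, per
#' table, canonical column name -> source column name. Unmapped extra
#' columns are preserved untouched as opaque metadata.
#'
#' @return nested list with `files` and `columns`.
#' @export
design_dialect <- function() {
  list(
    files = c(parts = "parts.csv", oligos = "oligos.csv",
              fragments = "fragments.csv", constructs = "constructs.csv",
              meta = "design.json"),
    columns = lapply(design_required_cols, function(x) stats::setNames(x, x))
  )
}

#' Construct a design object
#'
#' @param design_id identifier.
#' @param parts,oligos,fragments,constructs the four design tables (see
#'   [design_dialect()] for required columns). `constructs$fragment_ids`
#'   is a `;`-joined ordered fragment list; `constructs$circular` is
#'   logical (plasmids default to circular).
#' @param homology_bp campaign-level minimum homologous overlap between
#'   adjacent parts, in base pairs.
#' @param oligo_max_nt maximum oligo length accepted by the vendor.
#' @param validate run [validate_design()].
#' @return object of class `pf_design`.
#' @export
new_design <- function(design_id, parts, oligos, fragments, constructs,
                       homology_bp = 60L, oligo_max_nt = 60L,
                       validate = TRUE) {
  norm_seq <- function(x) toupper(gsub("[[:space:]]", "", x))
  parts$sequence <- norm_seq(parts$sequence)
  oligos$sequence <- norm_seq(oligos$sequence)
  constructs$circular <- as.logical(constructs$circular)
  d <- structure(list(
    design_id = design_id,
    homology_bp = as.integer(homology_bp),
    oligo_max_nt = as.integer(oligo_max_nt),
    parts = canonical_df(parts, "part_id"),
    oligos = canonical_df(oligos, "oligo_id"),
    fragments = canonical_df(fragments, "fragment_id"),
    constructs = canonical_df(constructs, "construct_id")
  ), class = "pf_design")
  if (validate) validate_design(d)
  d
}

#' @export
print.pf_design <- function(x, ...) {
  cat(sprintf(
    "<pf_design> %s: %d parts in %d bins, %d oligos, %d fragments, %d constructs (homology %d bp)\n",
    x$design_id, nrow(x$parts), length(unique(x$parts$bin_id)),
    nrow(x$oligos), nrow(x$fragments), nrow(x$constructs), x$homology_bp))
  invisible(x)
}

#' Split a construct's ordered fragment list
#' @param design a `pf_design`.
#' @param construct_id one construct identifier.
#' @return character vector of fragment ids in assembly order.
#' @export
construct_fragments <- function(design, construct_id) {
  i <- match(construct_id, design$constructs$construct_id)
  if (is.na(i)) pf_stop(sprintf("unknown construct '%s'", construct_id),
                        "pf_integrity_error")
  strsplit(design$constructs$fragment_ids[i], ";", fixed = TRUE)[[1]]
}

# fragment sequence = sequence of the part it amplifies (a PCR product
# physically contains the homology arms, which the part sequence includes)
fragment_sequences <- function(design, fragment_ids) {
  fi <- match(fragment_ids, design$fragments$fragment_id)
  design$parts$sequence[match(design$fragments$part_id[fi],
                              design$parts$part_id)]
}

#' Check the structural invariants of a design
#'
#' Referential integrity across all four tables, sequence alphabet,
#' oligo length limits, per-construct fragment lists (length >= 2, no
#' duplicates) and — when part sequences are present — that every
#' adjacent fragment pair shares an exact overlap of at least the
#' campaign homology length.
#'
#' @param design a `pf_design`.
#' @param check_junctions verify junction overlaps against sequences.
#' @return the design, invisibly; integrity violations raise classed
#'   errors listing every offender.
#' @export
validate_design <- function(design, check_junctions = TRUE) {
  p <- design$parts; o <- design$oligos
  f <- design$fragments; co <- design$constructs
  if (anyDuplicated(p$part_id)) pf_stop(
    "duplicate part_id", "pf_integrity_error")
  if (anyDuplicated(o$oligo_id)) pf_stop(
    "duplicate oligo_id", "pf_integrity_error")
  if (anyDuplicated(f$fragment_id)) pf_stop(
    "duplicate fragment_id", "pf_integrity_error")
  if (anyDuplicated(co$construct_id)) pf_stop(
    "duplicate construct_id", "pf_integrity_error")
  if (any(!nzchar(p$sequence)) || any(grepl("[^ACGT]", p$sequence)))
    pf_stop("part sequences must be non-empty and ACGT only",
            "pf_format_error")
  if (nrow(o)) {
    len <- nchar(o$sequence)
    bad <- o$oligo_id[len < 10 | len > design$oligo_max_nt]
    if (length(bad)) pf_stop(
      sprintf("oligo length outside [10, %d] nt: %s", design$oligo_max_nt,
              paste(bad, collapse = ", ")), "pf_format_error")
  }
  if (any(f$length_bp <= 0) || any(f$left_overlap_bp < 0) ||
      any(f$right_overlap_bp < 0))
    pf_stop("fragment lengths must be positive, overlaps non-negative",
            "pf_format_error")
  dangle <- c(
    setdiff(f$part_id, p$part_id),
    setdiff(c(f$forward_oligo_id, f$reverse_oligo_id), o$oligo_id)
  )
  frag_lists <- strsplit(co$fragment_ids, ";", fixed = TRUE)
  dup <- vapply(frag_lists, anyDuplicated, integer(1)) > 0
  if (any(dup)) pf_stop(
    sprintf("construct(s) with duplicated fragments: %s",
            paste(co$construct_id[dup], collapse = ", ")),
    "pf_integrity_error")
  short <- lengths(frag_lists) < 2
  if (any(short)) pf_stop(
    sprintf("construct(s) with fewer than 2 fragments: %s",
            paste(co$construct_id[short], collapse = ", ")),
    "pf_integrity_error")
  dangle <- c(dangle, setdiff(unique(unlist(frag_lists)), f$fragment_id))
  if (length(dangle)) pf_stop(
    sprintf("dangling reference(s): %s",
            paste(unique(dangle), collapse = ", ")),
    "pf_integrity_error", list(offenders = unique(dangle)))
  if (check_junctions && nrow(co)) {
    for (i in seq_len(nrow(co))) {
      expected_assembly(design, co$construct_id[i], .frags = frag_lists[[i]])
    }
  }
  invisible(design)
}

#' Read a design bundle
#'
#' Reads the four delimited-text tables (plus the JSON header carrying
#' `design_id` and `homology_bp`) from a directory, applying a column
#' mapping for non-native exports. Row order is never semantically
#' significant; tables are canonically re-ordered by id. Unknown columns
#' ride along untouched.
#'
#' @param path directory holding the bundle.
#' @param mapping dialect description, see [design_dialect()].
#' @param homology_bp,design_id overrides when the bundle has no JSON
#'   header (e.g. raw external exports).
#' @return a `pf_design`.
#' @export
parse_design <- function(path, mapping = design_dialect(),
                         homology_bp = NULL, design_id = NULL) {
  tabs <- list()
  for (t in design_tables) {
    file <- file.path(path, mapping$files[[t]])
    if (!file.exists(file)) pf_stop(
      sprintf("bundle table '%s' not found (%s)", t, file),
      "pf_format_error")
    raw <- read_table_utf8(file)
    colmap <- mapping$columns[[t]]
    miss <- colmap[!(colmap %in% names(raw))]
    if (length(miss)) pf_stop(
      sprintf("table '%s' is missing required column(s): %s", t,
              paste(miss, collapse = ", ")),
      "pf_format_error", list(table = t, columns = unname(miss)))
    # rename mapped columns to canonical names, keep extras as-is
    for (canon in names(colmap)) {
      names(raw)[names(raw) == colmap[[canon]]] <- canon
    }
    raw <- raw[, c(names(colmap), setdiff(names(raw), names(colmap))),
               drop = FALSE]
    tabs[[t]] <- raw
  }
  meta_file <- file.path(path, mapping$files[["meta"]] %||% "design.json")
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file)
          else list()
  new_design(
    design_id = design_id %||% meta$design_id %||% basename(path),
    parts = tabs$parts, oligos = tabs$oligos, fragments = tabs$fragments,
    constructs = tabs$constructs,
    homology_bp = homology_bp %||% meta$homology_bp %||% 60L,
    oligo_max_nt = meta$oligo_max_nt %||% 60L
  )
}

#' Write a design bundle
#'
#' Emits the native dialect: four CSV tables plus `design.json`.
#' `parse_design(write_design(d))` reproduces `d` field for field.
#'
#' @param design a `pf_design`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- design_dialect()$files
  for (t in design_tables) {
    write_table_utf8(design[[t]], file.path(path, files[[t]]))
  }
  jsonlite::write_json(
    list(design_id = design$design_id, homology_bp = design$homology_bp,
         oligo_max_nt = design$oligo_max_nt),
    file.path(path, files[["meta"]]), auto_unbox = TRUE)
  invisible(path)
}

#' Expected assembled sequence and size of a construct
#'
#' Adjacent fragments share a homologous overlap: the suffix of each
#' fragment equals the prefix of the next over the declared overlap
#' length (and, for circular constructs, the last fragment wraps onto
#' the first). The assembled sequence joins the fragments with each
#' shared overlap emitted once, so the size closed form is
#' `sum(lengths) - sum(junction overlaps)` with n junctions for n
#' fragments when circular, n-1 when linear.
#'
#' @param design a `pf_design` whose parts carry sequences.
#' @param construct_id one construct.
#' @param .frags pre-split fragment list (internal fast path).
#' @return list with `sequence` (character) and `size_bp` (integer).
#'   Fragments whose terminal regions do not match exactly over at least
#'   `homology_bp` raise a junction error naming the pair.
#' @export
expected_assembly <- function(design, construct_id, .frags = NULL) {
  frs <- .frags %||% construct_fragments(design, construct_id)
  fi <- match(frs, design$fragments$fragment_id)
  circular <- design$constructs$circular[
    match(construct_id, design$constructs$construct_id)] %||% TRUE
  if (is.na(circular)) circular <- TRUE
  seqs <- fragment_sequences(design, frs)
  n <- length(frs)
  lens <- nchar(seqs)
  right <- design$fragments$right_overlap_bp[fi]
  left <- design$fragments$left_overlap_bp[fi]
  pairs <- if (circular) cbind(seq_len(n), c(seq_len(n)[-1], 1L))
           else cbind(seq_len(n - 1), seq_len(n)[-1])
  ovs <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ov <- right[i]
    if (ov != left[j] || ov < design$homology_bp ||
        ov > min(lens[i], lens[j]) ||
        substring(seqs[i], lens[i] - ov + 1L, lens[i]) !=
        substring(seqs[j], 1L, ov)) {
      pf_stop(sprintf(
        "construct %s: fragments %s and %s do not share an exact overlap of >= %d bp",
        construct_id, frs[i], frs[j], design$homology_bp),
        "pf_junction_error",
        list(construct = construct_id, pair = c(frs[i], frs[j])))
    }
    ovs[k] <- ov
  }
  pieces <- c(seqs[1],
              mapply(function(s, ov) substring(s, ov + 1L, nchar(s)),
                     seqs[-1], ovs[seq_len(n - 1)]))
  out <- paste(pieces, collapse = "")
  if (circular) out <- substring(out, 1L, nchar(out) - ovs[n])
  size <- sum(lens) - sum(ovs)
  stopifnot(nchar(out) == size)
  list(sequence = out, size_bp = as.integer(size))
}

#' Closed-form expected sizes for all constructs
#'
#' Computes `sum(fragment lengths) - sum(junction overlaps)` per
#' construct from the fragment table alone (no sequences needed).
#'
#' @param design a `pf_design`.
#' @return named integer vector, one entry per construct.
#' @export
expected_sizes <- function(design) {
  f <- design$fragments
  co <- design$constructs
  out <- integer(nrow(co))
  for (i in seq_len(nrow(co))) {
    frs <- strsplit(co$fragment_ids[i], ";", fixed = TRUE)[[1]]
    fi <- match(frs, f$fragment_id)
    n_j <- if (isTRUE(as.logical(co$circular[i]))) length(frs)
           else length(frs) - 1L
    ovs <- f$right_overlap_bp[fi][seq_len(n_j)]
    out[i] <- sum(f$length_bp[fi]) - sum(ovs)
  }
  stats::setNames(as.integer(out), co$construct_id)
}

# size of the insert chain (all non-vector fragments, in order), i.e.
# what a colony PCR across the cargo region is expected to amplify
insert_size <- function(design, construct_id) {
  frs <- construct_fragments(design, construct_id)
  fi <- match(frs, design$fragments$fragment_id)
  role <- design$parts$role[match(design$fragments$part_id[fi],
                                  design$parts$part_id)]
  ins <- which(role != "vector")
  if (length(ins) == 0) ins <- seq_along(frs)
  lens <- design$fragments$length_bp[fi][ins]
  # junction overlaps between consecutive insert fragments
  ovs <- design$fragments$right_overlap_bp[fi][ins]
  ovs <- ovs[seq_len(length(ins) - 1)][diff(ins) == 1L]
  as.integer(sum(lens) - sum(ovs))
}

#' Export expected construct sequences
#'
#' One record per construct, record id = construct id. FASTA is written
#' with Biostrings; GenBank records carry the construct's topology
#' (circular/linear) on the LOCUS line.
#'
#' @param design a `pf_design`.
#' @param file output path.
#' @param format `"fasta"` or `"genbank"`.
#' @param construct_ids subset to export (default all).
#' @return `file`, invisibly. A design with no constructs yields an
#'   empty file, not an error; junction errors propagate.
#' @export
export_expected_sequences <- function(design, file,
                                      format = c("fasta", "genbank"),
                                      construct_ids = NULL) {
  format <- match.arg(format)
  ids <- construct_ids %||% design$constructs$construct_id
  seqs <- lapply(ids, function(id) expected_assembly(design, id))
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(
      stats::setNames(vapply(seqs, `[[`, character(1), "sequence"), ids))
    Biostrings::writeXStringSet(set, file)
  } else {
    con <- file(file, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (k in seq_along(ids)) {
      circ <- design$constructs$circular[
        match(ids[k], design$constructs$construct_id)]
      write_genbank_record(con, ids[k], seqs[[k]]$sequence,
                           circular = isTRUE(as.logical(circ)))
    }
  }
  invisible(file)
}

# Minimal GenBank flat-file writer (LOCUS/DEFINITION/ORIGIN blocks) —
# enough for sequence-verification services that want topology + bases.
write_genbank_record <- function(con, id, sequence, circular) {
  topo <- if (circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     id, nchar(sequence), topo,
                     toupper(format(Sys.Date(), "%d-%b-%Y"))), con)
  writeLines(sprintf("DEFINITION  expected assembly of construct %s.", id),
             con)
  writeLines(sprintf("ACCESSION   %s", id), con)
  writeLines("ORIGIN", con)
  s <- tolower(sequence)
  pos <- seq(1, nchar(s), by = 60)
  for (p in pos) {
    line <- substring(s, p, min(p + 59, nchar(s)))
    chunks <- substring(line, seq(1, nchar(line), 10),
                        pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
    writeLines(sprintf("%9d %s", p, paste(chunks, collapse = " ")), con)
  }
  writeLines("//", con)
}
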