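# Labware geometry, well addressing, 96<->384 quadrant stamping, volume
# accounting and layout allocation. Everything downstream (picklists,
# worklists, peak-table joins) sits on these primitives.

#' Built-in labware definitions
#'
#' Geometry, well capacity and dead volume for the plate kinds the
#' compiler emits instructions for. Dead volume is liquid an instrument
#' cannot aspirate; usable volume = capacity - dead. All values are
#' defaults and can be overridden with [read_labware_config()].
#'
#' @param kind optional labware kind; if given, the single matching row.
#' @return data.frame with columns `kind`, `rows`, `cols`, `capacity_ul`,
#'   `dead_ul`.
#' @export
labware_specs <- function(kind = NULL) {
  specs <- data.frame(
    kind        = c("pcr96", "echo_source_384", "deep96", "qtray48",
                    "archive96"),
    rows        = c(8L, 16L, 8L, 6L, 8L),
    cols        = c(12L, 24L, 12L, 8L, 12L),
    capacity_ul = c(200, 65, 2000, 5000, 2000),
    dead_ul     = c(5, 2.5, 50, 0, 50),
    stringsAsFactors = FALSE
  )
  if (is.null(kind)) return(specs)
  hit <- specs[specs$kind == kind, , drop = FALSE]
  if (nrow(hit) == 0) pf_stop(sprintf("unknown labware kind '%s'", kind),
                              "pf_address_error")
  hit
}

#' Load labware overrides from a YAML/JSON config
#'
#' The file maps labware kinds to any of `rows`, `cols`, `capacity_ul`,
#' `dead_ul`; unspecified fields keep their built-in defaults.
#'
#' @param path YAML (or JSON, which YAML parses) file.
#' @return labware spec data.frame as from [labware_specs()].
#' @export
read_labware_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- labware_specs()
  for (k in names(cfg)) {
    i <- match(k, specs$kind)
    if (is.na(i)) {
      row <- list(kind = k, rows = NA_integer_, cols = NA_integer_,
                  capacity_ul = NA_real_, dead_ul = NA_real_)
      specs <- rbind(specs, as.data.frame(row))
      i <- nrow(specs)
    }
    for (f in intersect(names(cfg[[k]]),
                        c("rows", "cols", "capacity_ul", "dead_ul"))) {
      specs[[f]][i] <- cfg[[k]][[f]]
    }
  }
  bad <- specs$kind[!(specs$rows * specs$cols) %in% c(48L, 96L, 384L)]
  if (length(bad)) pf_stop(
    sprintf("labware %s: rows x cols must be 48, 96 or 384",
            paste(bad, collapse = ", ")), "pf_address_error")
  specs
}

resolve_geometry <- function(geometry) {
  if (is.character(geometry)) {
    s <- labware_specs(geometry)
    c(rows = s$rows, cols = s$cols)
  } else {
    stopifnot(length(geometry) == 2)
    c(rows = as.integer(geometry[[1]]), cols = as.integer(geometry[[2]]))
  }
}

#' Parse well addresses into row/column numbers
#'
#' Accepts zero-padded and unpadded addresses ("A1", "A01"); rows are
#' single letters (A..P covers up to 384-well).
#'
#' @param address character vector of well addresses.
#' @param geometry labware kind name or c(rows, cols).
#' @return data.frame with `row`, `col` (1-based).
#' @export
parse_well <- function(address, geometry) {
  g <- resolve_geometry(geometry)
  m <- regmatches(address, regexec("^([A-Pa-p])0*([0-9]+)$", address))
  bad <- vapply(m, length, integer(1)) != 3
  row <- rep(NA_integer_, length(address))
  col <- rep(NA_integer_, length(address))
  row[!bad] <- match(toupper(vapply(m[!bad], `[`, character(1), 2)), LETTERS)
  col[!bad] <- as.integer(vapply(m[!bad], `[`, character(1), 3))
  oob <- bad | row > g[["rows"]] | col > g[["cols"]] | col < 1
  if (any(oob)) pf_stop(
    sprintf("address(es) %s invalid for %dx%d geometry",
            paste(unique(address[oob]), collapse = ", "),
            g[["rows"]], g[["cols"]]),
    "pf_address_error", list(addresses = address[oob]))
  data.frame(row = row, col = col)
}

#' Convert between well addresses and linear indices
#'
#' `address_to_index` maps "A1" to 0 and walks the plate in the given
#' fill order; `index_to_address` is its inverse. Addresses are emitted
#' unpadded.
#'
#' @param address,index well addresses / 0-based indices.
#' @param geometry labware kind name or c(rows, cols).
#' @param order `"row_major"` (A1, A2, ...) or `"column_major"`
#'   (A1, B1, ...).
#' @return integer indices in `[0, rows*cols)`, or addresses.
#' @export
address_to_index <- function(address, geometry,
                             order = c("row_major", "column_major")) {
  order <- match.arg(order)
  g <- resolve_geometry(geometry)
  rc <- parse_well(address, g)
  if (order == "row_major") (rc$row - 1L) * g[["cols"]] + (rc$col - 1L)
  else (rc$col - 1L) * g[["rows"]] + (rc$row - 1L)
}

#' @rdname address_to_index
#' @export
index_to_address <- function(index, geometry,
                             order = c("row_major", "column_major")) {
  order <- match.arg(order)
  g <- resolve_geometry(geometry)
  n <- g[["rows"]] * g[["cols"]]
  if (any(index < 0 | index >= n)) pf_stop(
    "index outside plate", "pf_address_error")
  if (order == "row_major") {
    row <- index %/% g[["cols"]] + 1L
    col <- index %% g[["cols"]] + 1L
  } else {
    col <- index %/% g[["rows"]] + 1L
    row <- index %% g[["rows"]] + 1L
  }
  paste0(LETTERS[row], col)
}

#' Map a 96-well address onto a 384-well plate quadrant
#'
#' Interleaved stamping convention used when condensing four 96-well
#' plates onto one 384-well plate: row384 = 2*row96 + floor(q/2),
#' col384 = 2*col96 + (q mod 2), quadrants numbered 0..3. The map is a
#' bijection over (address, quadrant).
#'
#' @param address96 96-well addresses.
#' @param quadrant integer 0..3 (recycled).
#' @return 384-well addresses.
#' @export
quadrant_map <- function(address96, quadrant) {
  if (any(quadrant < 0 | quadrant > 3)) pf_stop(
    "quadrant must be in 0..3", "pf_address_error")
  rc <- parse_well(address96, c(8, 12))
  row384 <- 2L * (rc$row - 1L) + quadrant %/% 2L + 1L
  col384 <- 2L * (rc$col - 1L) + quadrant %% 2L + 1L
  paste0(LETTERS[row384], col384)
}

#' Lay samples out across as many plates as needed
#'
#' Deterministic sequential allocation: sample i always lands on plate
#' `i %/% wells_per_plate`, so appending samples never moves earlier
#' assignments and the plate count is `ceiling(n / wells_per_plate)`.
#'
#' @param sample_ids character vector (order defines layout).
#' @param kind labware kind for the destination plates.
#' @param fill_order `"row_major"` or `"column_major"`.
#' @param prefix plate-name prefix; plates are numbered from 1.
#' @param labware spec table, see [labware_specs()].
#' @return data.frame `sample_id`, `plate_id`, `well`.
#' @export
allocate_wells <- function(sample_ids, kind = "pcr96",
                           fill_order = "row_major", prefix = "plate",
                           labware = labware_specs()) {
  spec <- labware[labware$kind == kind, , drop = FALSE]
  if (nrow(spec) == 0) pf_stop(sprintf("unknown labware kind '%s'", kind),
                               "pf_address_error")
  n <- length(sample_ids)
  if (n == 0) {
    return(data.frame(sample_id = character(0), plate_id = character(0),
                      well = character(0)))
  }
  per <- spec$rows * spec$cols
  idx <- seq_len(n) - 1L
  data.frame(
    sample_id = sample_ids,
    plate_id  = sprintf("%s_%d", prefix, idx %/% per + 1L),
    well      = index_to_address(idx %% per, c(spec$rows, spec$cols),
                                 fill_order),
    stringsAsFactors = FALSE
  )
}

#' Create an empty set of plates
#'
#' A plate set tracks, per well, the total liquid volume and the set of
#' sample identities it contains; it is the substrate that picklists are
#' validated and simulated against.
#'
#' @param plate_ids plate names.
#' @param kind labware kind (recycled across `plate_ids`).
#' @param labware spec table.
#' @return object of class `plate_set` with elements `labware`
#'   (per-plate geometry/capacity) and `contents` (per-well volume and
#'   `;`-joined sample ids).
#' @export
new_plate_set <- function(plate_ids, kind, labware = labware_specs()) {
  spec <- labware[match(rep_len(kind, length(plate_ids)), labware$kind), ,
                  drop = FALSE]
  if (anyNA(spec$kind)) pf_stop("unknown labware kind", "pf_address_error")
  structure(list(
    labware = data.frame(plate_id = plate_ids, spec, row.names = NULL,
                         stringsAsFactors = FALSE),
    contents = data.frame(plate_id = character(0), well = character(0),
                          volume_ul = numeric(0), samples = character(0),
                          stringsAsFactors = FALSE)
  ), class = "plate_set")
}

#' Combine two plate sets into one
#' @param a,b plate sets with disjoint plate ids.
#' @return merged `plate_set`.
#' @export
merge_plate_sets <- function(a, b) {
  if (any(b$labware$plate_id %in% a$labware$plate_id)) pf_stop(
    "plate id collision when merging plate sets", "pf_integrity_error")
  structure(list(labware = rbind(a$labware, b$labware),
                 contents = rbind(a$contents, b$contents)),
            class = "plate_set")
}

#' Fill wells of a plate set
#'
#' @param plates a `plate_set`.
#' @param fills data.frame with `plate_id`, `well`, `sample_id`,
#'   `volume_ul`.
#' @return updated `plate_set`; filling past capacity is an error.
#' @export
add_liquid <- function(plates, fills) {
  stopifnot(inherits(plates, "plate_set"))
  lw <- plates$labware
  i <- match(fills$plate_id, lw$plate_id)
  if (anyNA(i)) pf_stop(
    sprintf("unknown plate(s): %s",
            paste(unique(fills$plate_id[is.na(i)]), collapse = ", ")),
    "pf_address_error")
  for (k in seq_len(nrow(fills))) {
    parse_well(fills$well[k], c(lw$rows[i[k]], lw$cols[i[k]]))
  }
  ct <- plates$contents
  for (k in seq_len(nrow(fills))) {
    j <- which(ct$plate_id == fills$plate_id[k] & ct$well == fills$well[k])
    if (length(j) == 0) {
      ct <- rbind(ct, data.frame(plate_id = fills$plate_id[k],
                                 well = fills$well[k],
                                 volume_ul = fills$volume_ul[k],
                                 samples = fills$sample_id[k]))
    } else {
      ct$volume_ul[j] <- ct$volume_ul[j] + fills$volume_ul[k]
      have <- strsplit(ct$samples[j], ";", fixed = TRUE)[[1]]
      ct$samples[j] <- paste(union(have, fills$sample_id[k]),
                             collapse = ";")
    }
  }
  over <- ct$volume_ul > lw$capacity_ul[match(ct$plate_id, lw$plate_id)]
  if (any(over)) pf_stop(
    sprintf("well(s) %s filled past capacity",
            paste(paste0(ct$plate_id[over], ":", ct$well[over]),
                  collapse = ", ")),
    "pf_volume_error")
  plates$contents <- ct
  plates
}

#' Total liquid volume held by a plate set
#' @param plates a `plate_set`.
#' @return total volume in microliters.
#' @export
total_volume <- function(plates) sum(plates$contents$volume_ul)

#' Execute a picklist against a plate set
#'
#' Transfers are validated in order before anything is mutated: every
#' source well must retain at least its dead volume after aspiration,
#' destinations must stay within capacity, and all addresses must exist
#' in their plate's geometry. A single violation aborts the whole batch
#' (all-or-nothing), naming the offending well and the shortfall. Sample
#' identities propagate: a destination well accumulates the union of the
#' sample ids ever transferred into it. Total liquid is conserved.
#'
#' @param plates a `plate_set` holding both source and destination
#'   plates.
#' @param picklist data.frame with `source_plate`, `source_well`,
#'   `dest_plate`, `dest_well`, `volume_ul` (> 0).
#' @return the updated `plate_set`.
#' @export
apply_transfers <- function(plates, picklist) {
  stopifnot(inherits(plates, "plate_set"))
  if (nrow(picklist) == 0) return(plates)
  if (any(picklist$volume_ul <= 0)) pf_stop(
    "transfer volumes must be positive", "pf_volume_error")
  lw <- plates$labware
  si <- match(picklist$source_plate, lw$plate_id)
  di <- match(picklist$dest_plate, lw$plate_id)
  if (anyNA(si) || anyNA(di)) pf_stop(
    sprintf("picklist references unknown plate(s): %s",
            paste(unique(c(picklist$source_plate[is.na(si)],
                           picklist$dest_plate[is.na(di)])),
                  collapse = ", ")),
    "pf_address_error")
  for (k in seq_len(nrow(picklist))) {
    parse_well(picklist$source_well[k], c(lw$rows[si[k]], lw$cols[si[k]]))
    parse_well(picklist$dest_well[k], c(lw$rows[di[k]], lw$cols[di[k]]))
  }

  ct <- plates$contents
  key <- function(p, w) paste(p, w, sep = "\r")
  vol <- ct$volume_ul
  names(vol) <- key(ct$plate_id, ct$well)
  skey <- key(picklist$source_plate, picklist$source_well)
  dkey <- key(picklist$dest_plate, picklist$dest_well)
  # simulate the whole batch before committing anything
  sim <- vol
  for (k in seq_len(nrow(picklist))) {
    avail <- if (skey[k] %in% names(sim)) sim[[skey[k]]] else 0
    need <- picklist$volume_ul[k] + lw$dead_ul[si[k]]
    if (avail < need - 1e-9) pf_stop(
      sprintf(
        "insufficient volume in %s:%s for transfer %d: need %.3f uL (incl. %.3f uL dead volume), have %.3f uL (short %.3f uL)",
        picklist$source_plate[k], picklist$source_well[k], k, need,
        lw$dead_ul[si[k]], avail, need - avail),
      "pf_volume_error",
      list(plate = picklist$source_plate[k],
           well = picklist$source_well[k],
           shortfall_ul = need - avail))
    sim[[skey[k]]] <- avail - picklist$volume_ul[k]
    dnow <- if (dkey[k] %in% names(sim)) sim[[dkey[k]]] else 0
    dnew <- dnow + picklist$volume_ul[k]
    if (dnew > lw$capacity_ul[di[k]] + 1e-9) pf_stop(
      sprintf("destination %s:%s overflows capacity (%.1f uL)",
              picklist$dest_plate[k], picklist$dest_well[k],
              lw$capacity_ul[di[k]]),
      "pf_volume_error")
    sim[dkey[k]] <- dnew
  }

  # commit: volumes and sample-identity propagation
  samples <- as.list(ct$samples)
  names(samples) <- key(ct$plate_id, ct$well)
  vol <- as.list(vol)
  for (k in seq_len(nrow(picklist))) {
    vol[[skey[k]]] <- vol[[skey[k]]] - picklist$volume_ul[k]
    vol[[dkey[k]]] <- (vol[[dkey[k]]] %||% 0) + picklist$volume_ul[k]
    src_s <- strsplit(samples[[skey[k]]] %||% "", ";", fixed = TRUE)[[1]]
    dst_s <- strsplit(samples[[dkey[k]]] %||% "", ";", fixed = TRUE)[[1]]
    samples[[dkey[k]]] <- paste(union(dst_s, src_s), collapse = ";")
  }
  keys <- names(vol)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  plates$contents <- data.frame(
    plate_id = vapply(parts, `[`, character(1), 1),
    well = vapply(parts, `[`, character(1), 2),
    volume_ul = unlist(vol, use.names = FALSE),
    samples = unlist(samples[keys], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  plates
}

#' Read and write liquid-handler picklists
#'
#' Picklists use the vendor header `Source Plate Name, Source Well,
#' Destination Plate Name, Destination Well, Transfer Volume`. Acoustic
#' instruments take volumes in nanoliters, tip-based ones in
#' microliters; the unit is declared per file.
#'
#' @param picklist data.frame with columns `source_plate`,
#'   `source_well`, `dest_plate`, `dest_well`, `volume_ul`.
#' @param file path.
#' @param units `"nL"` (acoustic) or `"uL"` (tip-based).
#' @return `write_picklist` returns `file` invisibly; `read_picklist`
#'   returns the picklist data.frame in microliters.
#' @export
write_picklist <- function(picklist, file, units = c("nL", "uL")) {
  units <- match.arg(units)
  vol <- if (units == "nL") picklist$volume_ul * 1000 else picklist$volume_ul
  out <- data.frame(
    `Source Plate Name` = picklist$source_plate,
    `Source Well` = picklist$source_well,
    `Destination Plate Name` = picklist$dest_plate,
    `Destination Well` = picklist$dest_well,
    `Transfer Volume` = vol,
    check.names = FALSE
  )
  write_table_utf8(out, file)
  invisible(file)
}

#' @rdname write_picklist
#' @export
read_picklist <- function(file, units = c("nL", "uL")) {
  units <- match.arg(units)
  raw <- read_table_utf8(file)
  need <- c("Source Plate Name", "Source Well", "Destination Plate Name",
            "Destination Well", "Transfer Volume")
  miss <- setdiff(need, names(raw))
  if (length(miss)) pf_stop(
    sprintf("picklist missing column(s): %s", paste(miss, collapse = ", ")),
    "pf_format_error")
  data.frame(
    source_plate = raw[["Source Plate Name"]],
    source_well = raw[["Source Well"]],
    dest_plate = raw[["Destination Plate Name"]],
    dest_well = raw[["Destination Well"]],
    volume_ul = raw[["Transfer Volume"]] /
      if (units == "nL") 1000 else 1,
    stringsAsFactors = FALSE
  )
}
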