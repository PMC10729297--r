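make_registry_fixture <- function() {
  plating <- data.frame(sample_id = c("c1", "c2"),
                        plate_id = "qtray_1", well = c("A1", "A2"))
  picker <- data.frame(
    source_plate = "qtray_1",
    source_well = c("A1", "A1", "A1", "A2", "A2", "A2"),
    dest_plate = "culture_1",
    dest_well = c("A1", "A2", "A3", "A4", "A5", "A6"))
  list(plating = plating, picker = picker)
}

test_that("colony registration joins picker output to constructs", {
  fx <- make_registry_fixture()
  reg <- register_colonies(fx$picker, fx$plating, 3L)
  expect_equal(nrow(reg), 6L)
  expect_equal(as.integer(table(reg$construct_id)), c(3L, 3L))
  expect_equal(anyDuplicated(reg$colony_id), 0L)

  # a construct with a single colony registers without error
  reg1 <- register_colonies(fx$picker[c(1, 4:6), ], fx$plating, 3L)
  expect_equal(sum(reg1$construct_id == "c1"), 1L)

  # registry construct coverage = plated n picked
  expect_setequal(unique(reg$construct_id),
                  intersect(fx$plating$sample_id,
                            fx$plating$sample_id[
                              match(paste(fx$picker$source_plate,
                                          fx$picker$source_well),
                                    paste(fx$plating$plate_id,
                                          fx$plating$well))]))

  # unknown source wells are reported, not silently dropped
  pk <- rbind(fx$picker, data.frame(source_plate = "qtray_9",
                                    source_well = "F8",
                                    dest_plate = "culture_1",
                                    dest_well = "B1"))
  expect_warning(reg2 <- register_colonies(pk, fx$plating, 3L),
                 "unplated")
  expect_equal(nrow(attr(reg2, "unknown")), 1L)

  # over-picking warns but keeps the rows
  pk2 <- rbind(fx$picker, data.frame(source_plate = "qtray_1",
                                     source_well = "A1",
                                     dest_plate = "culture_1",
                                     dest_well = "B2"))
  expect_warning(reg3 <- register_colonies(pk2, fx$plating, 3L),
                 "more than 3")
  expect_equal(sum(reg3$construct_id == "c1"), 4L)

  # culture-well collisions are an integrity error
  pk3 <- fx$picker
  pk3$dest_well[2] <- "A1"
  expect_error(register_colonies(pk3, fx$plating, 3L),
               class = "pf_integrity_error")
})

test_that("NGS sheets reference a sequence for every sample", {
  d <- generate_design(tiny_config(seed = 10))
  ids <- d$constructs$construct_id[1:2]
  plating <- data.frame(sample_id = ids, plate_id = "qtray_1",
                        well = c("A1", "A2"))
  picker <- data.frame(source_plate = "qtray_1",
                       source_well = rep(c("A1", "A2"), each = 3),
                       dest_plate = "culture_1",
                       dest_well = sprintf("A%d", 1:6))
  reg <- register_colonies(picker, plating, 3L)
  sub <- ngs_submission(reg, d)
  expect_equal(nrow(sub$sheet), 6L)
  expect_length(sub$sequences, 2L)
  expect_true(all(sub$sheet$sequence_id %in% names(sub$sequences)))
  expect_equal(unname(nchar(sub$sequences[ids])),
               unname(expected_sizes(d)[ids]))

  # empty registry gives a header-only sheet
  sub0 <- ngs_submission(reg[0, ], d)
  expect_equal(nrow(sub0$sheet), 0L)

  path <- withr::local_tempdir()
  ngs_submission(reg, d, path = path)
  expect_true(file.exists(file.path(path, "ngs_samples.csv")))
  fa <- Biostrings::readDNAStringSet(
    file.path(path, "expected_sequences.fasta"))
  expect_setequal(names(fa), ids)
})

test_that("verdict ingestion applies the coverage/mutation policy", {
  fx <- make_registry_fixture()
  reg <- register_colonies(fx$picker, fx$plating, 3L)
  verdicts <- data.frame(
    colony_id = reg$colony_id,
    coverage_full = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    mutation_count = c(0L, 0L, 2L, 3L, 1L, 0L))
  ver <- ingest_ngs(verdicts, reg)
  expect_true(ver$verified[ver$construct_id == "c1"])   # colony 1 clean
  expect_false(ver$verified[ver$construct_id == "c2"])  # mutations only
  # relaxed mutation threshold flips c2
  ver2 <- ingest_ngs(verdicts, reg,
                     policy = list(require_full_coverage = TRUE,
                                   max_mutations = 1L))
  expect_true(ver2$verified[ver2$construct_id == "c2"])
  expect_error(
    ingest_ngs(data.frame(colony_id = "ghost", coverage_full = TRUE,
                          mutation_count = 0L), reg),
    class = "pf_integrity_error")
})

test_that("consolidation picks one lowest-position colony per construct", {
  fx <- make_registry_fixture()
  reg <- register_colonies(fx$picker, fx$plating, 3L)
  verdicts <- data.frame(
    colony_id = reg$colony_id,
    coverage_full = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    mutation_count = c(5L, 0L, 0L, 0L, 0L, 0L))
  out <- consolidate_constructs(reg, verdicts)
  expect_equal(nrow(out$picklist), 2L)  # exactly one per construct
  # c1: colonies 2 and 3 qualify; colony 2 sits at the lower well
  expect_equal(out$manifest$colony_id[out$manifest$construct_id == "c1"],
               "c1_c2")
  expect_setequal(out$manifest$construct_id, c("c1", "c2"))
  # deterministic and idempotent
  expect_identical(consolidate_constructs(reg, verdicts), out)
})

test_that("97 verified constructs consolidate onto two archive plates", {
  n <- 97
  plating <- data.frame(sample_id = sprintf("c%03d", 1:n),
                        plate_id = sprintf("qtray_%d", (0:(n - 1)) %/% 48 + 1),
                        well = index_to_address((0:(n - 1)) %% 48, c(6, 8)))
  picker <- data.frame(source_plate = plating$plate_id,
                       source_well = plating$well,
                       dest_plate = sprintf("culture_%d", (0:(n - 1)) %/% 96 + 1),
                       dest_well = index_to_address((0:(n - 1)) %% 96, c(8, 12)))
  reg <- register_colonies(picker, plating, 3L)
  verdicts <- data.frame(colony_id = reg$colony_id, coverage_full = TRUE,
                         mutation_count = 0L)
  out <- consolidate_constructs(reg, verdicts)
  expect_equal(length(unique(out$picklist$dest_plate)), 2L)
  expect_setequal(out$manifest$construct_id, plating$sample_id)
})

test_that("funnel counts shrink monotonically along construct stages", {
  cfg <- tiny_config(seed = 13)
  d <- generate_design(cfg)
  st <- run_campaign(d, simulate_campaign(d, cfg), cfg)
  fr <- funnel_report(st)
  cts <- stats::setNames(fr$counts$count, fr$counts$stage)
  stages <- c("designed", "feasible", "assembly_growth",
              "transformation_growth", "unique_verified")
  expect_true(all(diff(cts[stages]) <= 0))
  expect_true(all(diff(cts[c("colonies_picked", "colony_pcr_pass",
                             "fully_covered", "zero_mutation")]) <= 0))
  # empty state reports all zero
  fr0 <- funnel_report(new_build_state(d))
  expect_true(all(fr0$counts$count[fr0$counts$stage != "designed"] == 0))
})

test_that("state snapshots round-trip through JSON", {
  cfg <- tiny_config(seed = 14)
  d <- generate_design(cfg)
  st <- run_campaign(d, simulate_campaign(d, cfg), cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_state(st, f)
  st2 <- load_state(f)
  expect_equal(st2$design$parts, st$design$parts)
  expect_equal(st2$design$constructs, st$design$constructs)
  expect_equal(st2$fragment_status, st$fragment_status)
  expect_equal(st2$feasible, st$feasible)
  expect_equal(st2$verified, st$verified)
  expect_equal(st2$colonies, st$colonies, ignore_attr = TRUE)
  expect_equal(st2$consolidation$manifest, st$consolidation$manifest)
  expect_equal(funnel_report(st2)$counts, funnel_report(st)$counts)
})
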