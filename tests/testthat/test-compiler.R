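test_that("demand plan takes the ceiling of uses over capacity", {
  d <- generate_design(tiny_config(seed = 1))
  plan <- demand_plan(d, 4L)
  # bin sizes (2,3,4): a bin-1 fragment is used in 3*4 = 12 constructs
  f1 <- plan[plan$fragment_id == "frag_bin1_p1", ]
  expect_equal(f1$uses, 12L)
  expect_equal(f1$n_reactions, 3L)
  # a fragment used once needs one reaction at any capacity
  d1 <- d
  d1$constructs <- d$constructs[1, ]
  p1 <- demand_plan(d1, 100L)
  expect_true(all(p1$n_reactions[p1$uses > 0] == 1L))
})

test_that("demand plan matches the incidence-matrix oracle", {
  for (seed in 1:6) {
    d <- generate_design(random_config(seed))
    for (cap in c(1L, 3L, 7L)) {
      plan <- demand_plan(d, cap)
      expect_equal(stats::setNames(plan$n_reactions, plan$fragment_id),
                   oracle_demand(d, cap))
    }
  }
})

test_that("purchase order lists every reaction's oligo exactly once", {
  d <- generate_design(tiny_config(seed = 2))
  po <- purchase_order(d)
  rx <- plan_reactions(d)
  used <- unique(c(rx$forward_oligo_id, rx$reverse_oligo_id))
  expect_setequal(intersect(po$oligo_id, used), used)
  expect_equal(anyDuplicated(po$oligo_id), 0L)
  expect_equal(anyDuplicated(paste(po$plate_id, po$well)), 0L)

  # 97 oligos pigeonhole onto two plates
  d97 <- d
  d97$oligos <- data.frame(
    oligo_id = sprintf("o%03d", 1:97), name = sprintf("o%03d", 1:97),
    sequence = vapply(1:97, function(i) {
      set.seed(i); paste(sample(c("A","C","G","T"), 20, TRUE),
                         collapse = "")
    }, character(1)))
  expect_equal(length(unique(purchase_order(d97)$plate_id)), 2L)

  # duplicate sequences under distinct ids warn and can collapse
  ddup <- d
  ddup$oligos$sequence[2] <- ddup$oligos$sequence[1]
  expect_warning(po2 <- purchase_order(ddup, collapse_duplicates = TRUE),
                 "duplicate")
  expect_equal(nrow(po2), nrow(ddup$oligos) - 1L)
})

test_that("PCR setup emits three quantized transfers per reaction", {
  d <- generate_design(tiny_config(seed = 3))
  rx <- plan_reactions(d, 4L)
  oligo_st <- make_source_plates(data.frame(sample_id = d$oligos$oligo_id),
                                 prefix = "oligo_src")
  tmpl_st <- make_source_plates(
    data.frame(sample_id = unique(rx$template_id)), prefix = "tmpl_src")
  ps <- pcr_setup(rx, oligo_st, tmpl_st)
  expect_equal(nrow(ps$picklist), 3L * nrow(rx))
  expect_true(all(abs(ps$picklist$volume_ul / 0.025 -
                      round(ps$picklist$volume_ul / 0.025)) < 1e-9))
  per_dest <- tapply(ps$picklist$volume_ul,
                     paste(ps$picklist$dest_plate, ps$picklist$dest_well),
                     sum)
  expect_true(all(abs(per_dest - 1.5) < 1e-9))

  # two reactions sharing a template decrement the same source well twice
  shared <- rx[rx$template_id == rx$template_id[1], ][1:2, ]
  ps2 <- pcr_setup(shared, oligo_st, tmpl_st)
  tmpl_rows <- ps2$picklist[ps2$picklist$sample_id == shared$template_id[1], ]
  expect_equal(nrow(tmpl_rows), 2L)
  expect_equal(length(unique(tmpl_rows$source_well)), 1L)
  left <- ps2$plates_after$contents
  well <- left[left$plate_id == tmpl_rows$source_plate[1] &
               left$well == tmpl_rows$source_well[1], ]
  expect_equal(well$volume_ul, 65 - 2 * 0.5)

  # a missing stock blocks compilation and names the reactions
  err <- expect_error(
    pcr_setup(rx, oligo_st,
              make_source_plates(data.frame(sample_id = "tmpl_none"))),
    class = "pf_compile_error")
  expect_match(conditionMessage(err), rx$reaction_id[1], fixed = TRUE)
})

test_that("thermocycler grouping respects the span rule", {
  rx <- data.frame(reaction_id = c("a", "b", "c"),
                   annealing_c = c(60, 60.5, 66),
                   expected_size_bp = c(900, 1500, 2600))
  tg <- thermocycler_groups(rx, span_c = 2)
  expect_equal(nrow(tg$groups), 2L)
  expect_true(all(tg$groups$span_c <= 2))
  # extension sized for the largest product in the group (30 s / kb)
  g1 <- tg$assignments$group[tg$assignments$reaction_id == "b"]
  expect_equal(tg$groups$extension_s[tg$groups$group == g1], 60)
  # single reaction: one group with its own conditions
  tg1 <- thermocycler_groups(rx[1, ])
  expect_equal(nrow(tg1$groups), 1L)
  expect_equal(tg1$groups$annealing_c, 60)
})

test_that("capped grouping is as tight as exhaustive search allows", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    k <- sample(2:3, 1)
    rx <- data.frame(reaction_id = sprintf("r%d", 1:n),
                     annealing_c = round(runif(n, 55, 70), 1),
                     expected_size_bp = 1000)
    tg <- thermocycler_groups(rx, max_groups = k, span_c = 0.01)
    expect_lte(nrow(tg$groups), k)
    expect_equal(max(tg$groups$span_c),
                 oracle_best_span(rx$annealing_c, k), tolerance = 1e-9)
  }
})

test_that("equimolar volumes follow the dsDNA molecular-weight formula", {
  # 1000 bp at 50 ng/uL, 10 fmol target, 2.5 nL quantum:
  # MW = 617.96*1000 + 36.04 = 617996.04 g/mol -> 6.17996 ng
  # -> 123.599 nL, rounded up to the quantum -> 125 nL
  v <- equimolar_volumes(
    data.frame(sample_id = "p", conc_ng_ul = 50, length_bp = 1000,
               is_vector = FALSE),
    mix_spec(total_ul = 1, target_fmol = 10, quantum_ul = 0.0025))
  expect_equal(v$volume_ul[v$sample_id == "p"], 0.125)

  # equal length and concentration -> equal volumes (symmetry)
  v2 <- equimolar_volumes(
    data.frame(sample_id = c("a", "b"), conc_ng_ul = 30, length_bp = 2000,
               is_vector = FALSE),
    mix_spec(total_ul = 10, target_fmol = 10))
  expect_equal(v2$volume_ul[1], v2$volume_ul[2])

  # vector excess scales the vector part only
  v3 <- equimolar_volumes(
    data.frame(sample_id = c("vec", "ins"), conc_ng_ul = 30,
               length_bp = 2000, is_vector = c(TRUE, FALSE)),
    mix_spec(total_ul = 10, target_fmol = 10, vector_excess = 2,
             quantum_ul = 1e-9))
  expect_equal(v3$volume_ul[v3$sample_id == "vec"],
               2 * v3$volume_ul[v3$sample_id == "ins"], tolerance = 1e-6)

  # equivolume: total split evenly, rounded down, remainder to water
  v4 <- equimolar_volumes(
    data.frame(sample_id = c("a", "b", "c"), is_vector = FALSE),
    mix_spec("equivolume", total_ul = 10, quantum_ul = 0.0025))
  expect_equal(v4$volume_ul[1:3], rep(quantize_down(10 / 3, 0.0025), 3))
  expect_equal(sum(v4$volume_ul), 10)

  # overflow errors instead of silently rescaling
  expect_error(
    equimolar_volumes(
      data.frame(sample_id = "big", conc_ng_ul = 1, length_bp = 10000,
                 is_vector = FALSE),
      mix_spec(total_ul = 1, target_fmol = 50)),
    class = "pf_volume_error")
  # equimolar without concentrations is a compile error
  expect_error(
    equimolar_volumes(data.frame(sample_id = "a", is_vector = FALSE),
                      mix_spec(total_ul = 10)),
    class = "pf_compile_error")
})

test_that("achieved moles stay within one droplet of the target", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    parts <- data.frame(sample_id = sprintf("p%d", 1:n),
                        conc_ng_ul = runif(n, 10, 120),
                        length_bp = sample(500:9000, n),
                        is_vector = FALSE)
    spec <- mix_spec(total_ul = 20, target_fmol = 10)
    v <- equimolar_volumes(parts, spec)
    v <- v[v$sample_id != "water", ]
    mw <- 617.96 * parts$length_bp + 36.04
    fmol <- v$volume_ul * parts$conc_ng_ul / mw * 1e6
    droplet_fmol <- spec$quantum_ul * parts$conc_ng_ul / mw * 1e6
    expect_true(all(fmol >= 10 - 1e-9))
    expect_true(all(fmol <= 10 + droplet_fmol + 1e-9))
  }
})

test_that("assembly picklists hit one destination well per construct", {
  d <- generate_design(tiny_config(seed = 4))
  fs <- make_source_plates(
    data.frame(sample_id = d$fragments$fragment_id, conc_ng_ul = 50,
               length_bp = d$fragments$length_bp),
    required_ul = rep(30, nrow(d$fragments)), prefix = "frag_src")
  spec <- mix_spec(total_ul = 10)
  ap <- assembly_picklists(d, d$constructs$construct_id, fs, spec)
  expect_equal(nrow(ap$destinations), nrow(d$constructs))
  per_dest <- tapply(ap$picklist$volume_ul,
                     paste(ap$picklist$dest_plate, ap$picklist$dest_well),
                     sum)
  expect_equal(length(per_dest), nrow(d$constructs))
  expect_true(all(per_dest <= spec$total_ul + 1e-9))
  frag_per_dest <- table(paste(ap$picklist$dest_plate,
                               ap$picklist$dest_well))
  expect_true(all(frag_per_dest == 3))  # one transfer per fragment

  err <- expect_error(
    assembly_picklists(d, d$constructs$construct_id,
                       list(locations = fs$locations[-1, ]), spec),
    class = "pf_compile_error")
  expect_match(conditionMessage(err), fs$locations$sample_id[1],
               fixed = TRUE)
})

test_that("bench worklists map plates deterministically", {
  # 96 assemblies spread over exactly two 48-well agar trays
  lay <- allocate_wells(sprintf("c%02d", 1:96), "pcr96", prefix = "asm")
  qt <- bench_worklist("plate_qtray", lay)
  expect_equal(length(unique(qt$picklist$dest_plate)), 2L)
  expect_equal(as.integer(table(qt$picklist$dest_plate)), c(48L, 48L))
  expect_true(all(address_to_index(qt$picklist$dest_well, c(6, 8)) %in%
                  0:47))

  # bead purification: 1:1 same-well stamp at constant volume
  bp <- bench_worklist("bead_purify", lay, list(volume_ul = 45))
  expect_equal(nrow(bp$picklist), 96L)
  expect_identical(bp$picklist$dest_well, bp$picklist$source_well)
  expect_true(all(bp$picklist$volume_ul == 45))

  # consolidation collapses passing replicates to distinct fragments
  passing <- data.frame(
    fragment_id = c("f1", "f2", "f1", "f3", "f2"),
    plate_id = "pcr_1", well = c("A1", "A2", "B1", "B2", "C1"))
  cons <- bench_worklist("consolidate_pcr", passing)
  expect_equal(nrow(cons$picklist), length(unique(passing$fragment_id)))
  expect_setequal(cons$picklist$sample_id, c("f1", "f2", "f3"))
  # first passing replicate wins
  expect_equal(cons$picklist$source_well[cons$picklist$sample_id == "f1"],
               "A1")
})
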