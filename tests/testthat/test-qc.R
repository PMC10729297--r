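test_that("peak tables parse, drop markers and report bad rows", {
  raw <- data.frame(
    well = c("A1", "A1", "A1", "B2", "ZZ9", "B2"),
    size_bp = c(15, 980, 7000, 1500, 500, -3),
    conc_ng_ul = c(10, 22, 10, 8, 5, 1))
  expect_warning(
    pt <- parse_peak_table(raw, "pcr96", marker_sizes = c(15, 7000)),
    "2 unparseable")
  expect_equal(nrow(pt), 2L)                    # markers removed
  expect_equal(pt$size_bp[pt$well == "A1"], 980)
  expect_equal(nrow(attr(pt, "bad_rows")), 2L)  # collected, not dropped

  # round-trips through write/parse
  f <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(pt, f)
  pt2 <- parse_peak_table(f, "pcr96")
  expect_equal(as.data.frame(pt), as.data.frame(pt2),
               ignore_attr = TRUE)

  expect_error(parse_peak_table(raw[, 1:2, drop = FALSE], "pcr96"),
               class = "pf_format_error")
})

test_that("reaction calls follow the tolerance and concentration rules", {
  rx <- data.frame(reaction_id = "r1", well = "A1",
                   expected_size_bp = 1000)
  # in-tolerance peak passes with its relative error
  calls <- call_reactions(rx, make_peaks("A1", 995, 5), 0.10, 1)
  expect_equal(calls$verdict, "pass")
  expect_equal(calls$relative_error, 0.005)
  expect_equal(calls$matched_size_bp, 995)
  # only off-size peaks fail
  expect_equal(call_reactions(rx, make_peaks(c("A1", "A1"), c(1500, 400),
                                             c(9, 9)))$verdict, "fail")
  # no peaks at all is an empty lane
  expect_equal(call_reactions(rx, make_peaks(character(0), numeric(0),
                                             numeric(0)))$verdict,
               "empty_lane")
  # sub-threshold concentration cannot pass
  expect_equal(call_reactions(rx, make_peaks("A1", 1000, 0.4),
                              min_conc_ng_ul = 1)$verdict, "fail")
  # matched peak: smallest relative error, ties to higher concentration
  calls <- call_reactions(rx, make_peaks(c("A1", "A1", "A1"),
                                         c(990, 1010, 1010), c(40, 5, 30)))
  expect_equal(calls$matched_size_bp, 990)
  calls <- call_reactions(rx, make_peaks(c("A1", "A1"), c(990, 1010),
                                         c(5, 30)))
  expect_equal(calls$matched_conc_ng_ul, 30)
})

test_that("a pass at tolerance t passes at every larger tolerance", {
  set.seed(31)
  rx <- data.frame(reaction_id = sprintf("r%d", 1:50),
                   well = index_to_address(0:49, c(8, 12)),
                   expected_size_bp = sample(300:3000, 50))
  peaks <- make_peaks(rep(rx$well, 2),
                      c(round(rx$expected_size_bp * runif(50, 0.8, 1.2)),
                        sample(100:5000, 50)),
                      runif(100, 0.5, 40))
  tols <- c(0.02, 0.05, 0.10, 0.25)
  passed <- sapply(tols, function(t)
    call_reactions(rx, peaks, t)$verdict == "pass")
  for (j in seq_along(tols)[-1]) {
    expect_true(all(passed[, j] >= passed[, j - 1]))
  }
})

test_that("fragment status aggregates replicates across rounds", {
  plan <- data.frame(fragment_id = c("f1", "f2", "f3"),
                     uses = 1L, n_reactions = c(2L, 1L, 1L))
  calls <- data.frame(
    reaction_id = c("a", "b", "c", "d"),
    fragment_id = c("f1", "f1", "f2", "f3"),
    verdict = c("fail", "pass", "fail", "fail"),
    round = c(1L, 1L, 1L, 6L))
  st <- fragment_status(calls, plan, max_rounds = 6L)
  expect_equal(st$status[st$fragment_id == "f1"], "verified")
  expect_equal(st$status[st$fragment_id == "f2"], "pending")
  expect_equal(st$status[st$fragment_id == "f3"], "exhausted")
})

test_that("redo plans partition the round into passed and retried", {
  d <- generate_design(tiny_config(seed = 8))
  cfg <- tiny_config(seed = 8)
  rx <- plan_reactions(d)
  sim <- simulate_campaign(d, cfg)
  for (r in seq_along(sim$reactions_by_round)) {
    cur <- sim$reactions_by_round[[r]]
    peaks <- parse_peak_table(sim$peak_tables[[r]], "pcr96",
                              mapping = c(well = "well",
                                          size_bp = "size_bp",
                                          conc_ng_ul = "conc_ng_ul",
                                          plate_id = "plate_id"),
                              marker_sizes = cfg$marker_sizes)
    calls <- call_reactions(cur, peaks)
    redo <- redo_plan(calls, r)
    passed <- calls$reaction_id[calls$verdict == "pass"]
    redo_lineage <- sub(sprintf("_R%d_", r + 1L), "_", redo$reaction_id)
    cur_lineage <- sub(sprintf("_R%d_", r), "_", cur$reaction_id)
    pass_lineage <- sub(sprintf("_R%d_", r), "_", passed)
    # redo u passed = original; redo n passed = empty
    expect_setequal(c(redo_lineage, pass_lineage), cur_lineage)
    expect_length(intersect(redo_lineage, pass_lineage), 0L)
    expect_true(all(redo$round == r + 1L))
  }
  # no failures -> empty redo plan
  calls <- data.frame(reaction_id = "f_R1_1", fragment_id = "f",
                      verdict = "pass", round = 1L, annealing_c = 60,
                      plate_id = "p", well = "A1",
                      expected_size_bp = 100L, template_id = "t",
                      forward_oligo_id = "o1", reverse_oligo_id = "o2")
  expect_equal(nrow(redo_plan(calls, 1L)), 0L)
  # gradient strategy alternates +2/-2 on annealing
  calls$verdict <- "fail"
  calls <- rbind(calls, transform(calls, reaction_id = "g_R1_1",
                                  fragment_id = "g"))
  redo <- redo_plan(calls, 1L, strategy = "gradient")
  expect_equal(sort(redo$annealing_c), c(58, 62))
})

test_that("feasibility is the all-fragments-verified subset", {
  d <- generate_design(tiny_config(seed = 9))
  all_frags <- d$fragments$fragment_id
  st_all <- data.frame(fragment_id = all_frags, status = "verified")
  expect_setequal(feasible_constructs(d, st_all),
                  d$constructs$construct_id)
  # a fragment used by every construct fails -> nothing is feasible
  st_none <- st_all
  st_none$status[st_none$fragment_id == "frag_bin1_p1"] <- "exhausted"
  st_none$status[st_none$fragment_id == "frag_bin1_p2"] <- "exhausted"
  expect_length(feasible_constructs(d, st_none), 0L)
})

test_that("feasibility matches brute force and is monotone", {
  for (seed in 1:6) {
    d <- generate_design(random_config(seed))
    set.seed(seed + 100)
    frags <- d$fragments$fragment_id
    verified <- sample(frags, rbinom(1, length(frags), 0.6))
    st <- data.frame(fragment_id = frags,
                     status = ifelse(frags %in% verified, "verified",
                                     "exhausted"))
    got <- feasible_constructs(d, st)
    expect_setequal(got, oracle_feasible(d, verified))
    # adding a verified fragment never shrinks the feasible set
    extra <- setdiff(frags, verified)
    if (length(extra)) {
      st2 <- st
      st2$status[st2$fragment_id == extra[1]] <- "verified"
      expect_true(all(got %in% feasible_constructs(d, st2)))
    }
  }
})
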