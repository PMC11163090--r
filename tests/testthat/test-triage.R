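test_that("published class-level index rows all satisfy the four-index rule", {
  ref <- reference_values()$class_indices
  for (i in seq_len(nrow(ref))) {
    d <- evaluate_signal(ref[i, ], n = ref$n[i])
    expect_true(d$is_signal, info = ref$class[i])
    expect_true(d$pass_ror && d$pass_prr && d$pass_ebgm && d$pass_ic)
  }
})

test_that("each criterion can individually veto a signal", {
  base <- list(ror = 9.65, prr = 9.40, ebgm = 8.64, ic = 3.11)
  n <- 1624
  expect_true(evaluate_signal(base, n)$is_signal)
  fail_one <- list(
    modifyList(base, list(ror = 1.0)),     # ROR must exceed 1
    modifyList(base, list(prr = 2.0)),     # PRR must exceed 2
    modifyList(base, list(ebgm = 1.99)),   # EBGM threshold is inclusive at 2
    modifyList(base, list(ic = 0)))        # IC must exceed 0
  for (m in fail_one) expect_false(evaluate_signal(m, n)$is_signal)
  # EBGM exactly 2 passes (inclusive), IC exactly 0 fails (exclusive)
  expect_true(evaluate_signal(modifyList(base, list(ebgm = 2)), n)$pass_ebgm)
  expect_false(evaluate_signal(modifyList(base, list(ic = 0)), n)$pass_ic)
})

test_that("minimum report counts gate the indices", {
  m <- list(ror = 5, prr = 5, ebgm = 5, ic = 2)
  d1 <- evaluate_signal(m, n = 1)
  expect_false(d1$pass_ror)   # needs n >= 2
  expect_false(d1$pass_prr)   # needs n >= 3
  expect_true(d1$pass_ebgm)   # needs n >= 1
  d2 <- evaluate_signal(m, n = 2)
  expect_true(d2$pass_ror)
  expect_false(d2$pass_prr)
  expect_true(evaluate_signal(m, n = 3)$is_signal)
})

test_that("threshold arithmetic matches the worked example", {
  d <- evaluate_signal(list(ror = 1.5, prr = 1.5, ebgm = 1.2, ic = 0.3),
                       n = 10)
  expect_true(d$pass_ror)
  expect_false(d$pass_prr)
  expect_false(d$pass_ebgm)
  expect_true(d$pass_ic)
  expect_false(d$is_signal)
})

test_that("a missing index is an error naming the index", {
  expect_error(evaluate_signal(list(ror = 2, prr = 3, ic = 1), n = 10),
               "ebgm")
})

test_that("raising any threshold never turns a non-signal into a signal", {
  set.seed(9)
  for (i in 1:100) {
    m <- list(ror = runif(1, 0.5, 4), prr = runif(1, 0.5, 4),
              ebgm = runif(1, 0.5, 4), ic = runif(1, -1, 2))
    n <- sample(1:20, 1)
    base <- evaluate_signal(m, n)$is_signal
    harder <- signal_criteria(ror_threshold = 1.5, prr_threshold = 3,
                              ebgm_threshold = 3, ic_threshold = 0.5,
                              min_n_ror = 5, min_n_prr = 5, min_n_bayes = 3)
    stricter <- evaluate_signal(m, n, harder)$is_signal
    if (!base) expect_false(stricter)
  }
})

test_that("class shares reproduce the published percentages", {
  expect_equal(class_share(1624, 2313), 70.2)
  expect_equal(class_share(348, 2313), 15.0)
  expect_equal(class_share(341, 2313), 14.7)
  expect_equal(class_share(0, 10), 0)
  expect_error(class_share(5, 0), "positive")
  expect_error(class_share(11, 10), "exceeds")
})

test_that("descriptive summaries count sex over the recorded denominator", {
  reports <- c(
    lapply(1:7, function(i) rpt(paste0("f", i), sex = "F",
                                pts = "Pancreatitis")),
    lapply(1:7, function(i) rpt(paste0("m", i), sex = "M",
                                pts = "Pancreatitis")),
    list(rpt("u1", sex = NA, pts = "Pancreatitis")))
  coh <- build_cohort(make_bundle(reports), filter_config())
  s <- summarize_descriptives(coh)
  expect_equal(s$by_sex$count, c(7L, 7L))
  expect_equal(s$by_sex$percent, c(50, 50))
  expect_equal(s$sex_missing, 1L)
  expect_equal(sum(s$by_sex$percent), 100, tolerance = 0.1)
})

test_that("outcome tallies count one per case-code occurrence and seriousness excludes OT", {
  reports <- list(
    rpt("1", pts = "Pancreatitis", outcomes = "HO"),
    rpt("2", pts = "Pancreatitis", outcomes = c("HO", "DE")),
    rpt("3", pts = "Pancreatitis", outcomes = "OT"),
    rpt("4", pts = "Pancreatitis"))
  coh <- build_cohort(make_bundle(reports), filter_config())
  s <- summarize_descriptives(coh)
  expect_equal(s$by_outcome$count[s$by_outcome$code == "HO"], 2L)
  expect_equal(s$by_outcome$count[s$by_outcome$code == "DE"], 1L)
  expect_equal(s$by_outcome$count[s$by_outcome$code == "OT"], 1L)
  expect_equal(s$serious_count, 2L)  # cases 1 and 2; OT-only case 3 is not serious
  expect_equal(s$serious_percent, 50)
})

test_that("year distribution matches generator ground truth", {
  cfg <- synthetic_config(n_drugs = 10, n_events = 6, n_reports = 800,
                          injected_signals = NULL, duplicate_rate = 0,
                          version_rate = 0, missing_date_rate = 0,
                          seed = 55)
  db <- generate_database(cfg)
  coh <- build_cohort(db$bundles, filter_config(target_pt = "EVT_002"))
  s <- summarize_descriptives(coh, cases_only = FALSE)
  truth_years <- table(db$truth$case_truth$report_year)
  got <- setNames(s$by_year$count, s$by_year$year)
  expect_equal(got[names(truth_years)],
               setNames(as.integer(truth_years), names(truth_years)))
})
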