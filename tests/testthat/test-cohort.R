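test_that("deduplication keeps the highest case version and collapses duplicates", {
  b <- make_bundle(list(
    rpt("11", caseid = "C1", caseversion = 1, pts = "Pancreatitis"),
    rpt("12", caseid = "C1", caseversion = 2, pts = "Pancreatitis"),
    rpt("21", caseid = "C2", pts = "Nausea"),
    rpt("31", caseid = "C3", pts = "Rash"),
    # same case, same version, different primaryid, identical key -> duplicate
    rpt("32", caseid = "C3", pts = "Rash")))
  dd <- deduplicate_reports(list(b))
  expect_equal(nrow(dd), 3L)
  expect_equal(dd$primaryid[dd$caseid == "C1"], "12")   # version 2 won
  a <- attr(dd, "audit")
  expect_equal(a$n_removed_versions, 1L)
  expect_equal(a$n_removed_duplicates, 1L)
  # idempotent
  dd2 <- deduplicate_reports(dd)
  expect_equal(nrow(dd2), nrow(dd))
  expect_equal(attr(dd2, "audit")$n_removed_versions, 0L)
})

test_that("three distinct cases with distinct keys survive deduplication", {
  b <- make_bundle(list(rpt("1", caseid = "A"), rpt("2", caseid = "B"),
                        rpt("3", caseid = "C")))
  expect_equal(nrow(deduplicate_reports(list(b))), 3L)
})

test_that("deduplication is invariant to bundle order", {
  b1 <- make_bundle(list(rpt("11", caseid = "C1", caseversion = 1),
                         rpt("21", caseid = "C2")), label = "2019Q1")
  b2 <- make_bundle(list(rpt("12", caseid = "C1", caseversion = 2),
                         rpt("31", caseid = "C3")), label = "2019Q2")
  d12 <- deduplicate_reports(list(b1, b2))
  d21 <- deduplicate_reports(list(b2, b1))
  attr(d12, "audit") <- attr(d21, "audit") <- NULL
  expect_identical(d12, d21)
  expect_equal(d12$primaryid[d12$caseid == "C1"], "12")
})

test_that("literal mode drops only exact (primaryid, event date, pt) duplicates", {
  b <- make_bundle(list(
    rpt("11", caseid = "C1", caseversion = 1),
    rpt("12", caseid = "C1", caseversion = 2)))
  dd <- deduplicate_reports(list(b), mode = "literal")
  expect_equal(nrow(dd), 2L)  # different primaryids: both kept
})

test_that("the window filter keeps 2019-2021 and tallies undatable reports", {
  b <- make_bundle(list(
    rpt("1", event_dt = "20180601"),
    rpt("2", event_dt = "20190601"),
    rpt("3", event_dt = "20210601"),
    rpt("4", event_dt = "20220601"),
    rpt("5", event_dt = NA, fda_dt = NA)))
  r <- assemble_reports(b)
  fw <- filter_window(r, filter_config(2019, 2021))
  expect_setequal(fw$report_year, c(2019, 2021))
  a <- attr(fw, "audit")
  expect_equal(a$n_out_of_window, 2L)
  expect_equal(a$n_missing_year, 1L)
  # all-inside window is the identity
  allin <- assemble_reports(make_bundle(list(rpt("1"), rpt("2"))))
  expect_equal(nrow(filter_window(allin, filter_config(2019, 2021))), 2L)
})

test_that("report year falls back to the FDA receipt date", {
  b <- make_bundle(list(rpt("1", event_dt = NA, fda_dt = "20200315")))
  r <- assemble_reports(b)
  expect_equal(r$report_year, 2020L)
  expect_equal(r$year_source, "fda_dt")
})

test_that("drug-class mapping resolves brands, unions classes, and ignores non-PS roles", {
  cm <- default_class_map()
  expect_equal(map_drug_classes("VICTOZA", cm), "GLP-1 RA")
  expect_equal(map_drug_classes(c("liraglutide", "empagliflozin"), cm),
               c("GLP-1 RA", "SGLT2 inhibitor"))
  expect_equal(map_drug_classes("ibuprofen", cm), character(0))
  # SS role never contributes: exercised through the cohort
  b <- make_bundle(list(
    rpt("1", drugs = data.frame(name = "sitagliptin", role = "SS"))))
  coh <- build_cohort(b, filter_config())
  expect_equal(coh$drug_classes, "")
})

test_that("event flagging is exact-match, not substring", {
  expect_true(flag_event(c("Pancreatitis", "Nausea"), "pancreatitis"))
  expect_false(flag_event("Pancreatitis acute", "pancreatitis"))
  expect_false(flag_event(character(0), "pancreatitis"))
  # term-list mode
  expect_true(flag_event("Pancreatitis acute",
                         c("pancreatitis", "pancreatitis acute")))
})

test_that("ages convert to years by unit and implausible values go missing", {
  b <- make_bundle(list(
    rpt("1", age = "720", age_cod = "MON"),
    rpt("2", age = "104", age_cod = "WK"),
    rpt("3", age = "365", age_cod = "DY"),
    rpt("4", age = "200", age_cod = "YR"),
    rpt("5", age = "60", age_cod = NA)))
  r <- assemble_reports(b)
  expect_equal(r$age_years[1:3], c(60, 2, 365 / 365.25), tolerance = 1e-10)
  expect_true(is.na(r$age_years[4]))     # > 120 y
  expect_equal(r$age_years[5], 60)       # blank unit treated as years
})

test_that("cohort audit counts match generator ground truth and conserve totals", {
  cfg <- synthetic_config(n_drugs = 15, n_events = 8, n_reports = 2000,
                          injected_signals = NULL,
                          duplicate_rate = 0.05, version_rate = 0.05,
                          missing_date_rate = 0.08,
                          year_range = c(2018, 2022), seed = 77)
  db <- generate_database(cfg)
  coh <- build_cohort(db$bundles, filter_config(target_pt = "EVT_001"))
  a <- attr(coh, "audit")
  tr <- db$truth
  expect_equal(a$n_removed_versions, tr$n_versions)
  expect_equal(a$n_removed_duplicates, tr$n_duplicates)
  expect_equal(a$n_removed_out_of_window, tr$n_out_of_window)
  expect_equal(a$n_removed_missing_year, tr$n_missing_year)
  expect_equal(a$n_cohort, tr$n_in_window)
  # audit conservation: input = output + all exclusions
  expect_equal(a$n_input,
               a$n_cohort + a$n_removed_versions + a$n_removed_duplicates +
                 a$n_removed_out_of_window + a$n_removed_missing_year)
})

test_that("an empty bundle yields an empty cohort with a zeroed audit", {
  b <- make_bundle(list(rpt("1")))
  b <- apply_deletions(quarter_bundle(b$demo, b$drug, b$reac, b$outc,
                                      "1", "2019Q1"))
  coh <- build_cohort(b, filter_config())
  expect_equal(nrow(coh), 0L)
  expect_equal(attr(coh, "audit")$n_input, 0L)
})

test_that("multi-class reports count toward each class and are audited", {
  b <- make_bundle(list(
    rpt("1", drugs = data.frame(name = c("liraglutide", "empagliflozin"),
                                role = c("PS", "PS")),
        pts = "Pancreatitis"),
    rpt("2", drugs = data.frame(name = "sitagliptin", role = "PS"))))
  coh <- build_cohort(b, filter_config())
  expect_equal(attr(coh, "audit")$n_multiclass, 1L)
  t_glp <- build_contingency(coh, "GLP-1 RA")
  t_sglt <- build_contingency(coh, "SGLT2 inhibitor")
  expect_equal(t_glp$a, 1); expect_equal(t_sglt$a, 1)
})

test_that("the pair grid counts each case once per drug-event pair", {
  b <- make_bundle(list(
    rpt("1", drugs = data.frame(name = c("d1", "d2"), role = c("PS", "PS")),
        pts = c("p1", "p2")),
    rpt("2", drugs = data.frame(name = "d1", role = "PS"), pts = "p1")))
  g <- pair_count_grid(b, filter_config())
  expect_equal(nrow(g), 4L)   # d1/d2 x p1/p2 from case 1; d1-p1 again from 2
  expect_equal(g$n[g$drug == "D1" & g$event == "P1"], 2L)
  expect_equal(sum(g$n), 5L)
  expect_equal(attr(g, "n_reports"), 2L)
})
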