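toy_cohort <- function() {
  # 8 reports: 2 exposed with event, 1 exposed without, 2 unexposed with,
  # 3 unexposed without
  reports <- list(
    rpt("1", drugs = data.frame(name = "victoza", role = "PS"),
        pts = "Pancreatitis"),
    rpt("2", drugs = data.frame(name = "liraglutide", role = "PS"),
        pts = "Pancreatitis"),
    rpt("3", drugs = data.frame(name = "victoza", role = "PS"),
        pts = "Nausea"),
    rpt("4", drugs = data.frame(name = "ibuprofen", role = "PS"),
        pts = "Pancreatitis"),
    rpt("5", drugs = data.frame(name = "aspirin", role = "PS"),
        pts = "Pancreatitis"),
    rpt("6", drugs = data.frame(name = "aspirin", role = "PS"),
        pts = "Rash"),
    rpt("7", drugs = data.frame(name = "metformin", role = "PS"),
        pts = "Rash"),
    rpt("8", drugs = data.frame(name = "metformin", role = "PS"),
        pts = "Nausea"))
  build_cohort(make_bundle(reports), filter_config())
}

test_that("the 2x2 cells are direct counts with conserved margins", {
  coh <- toy_cohort()
  tab <- build_contingency(coh, "GLP-1 RA")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 2, 3))
  expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(coh))
  # a known-but-absent exposure yields a zero-exposure table
  tab0 <- build_contingency(coh, "DPP-4 inhibitor",
                            class_map = default_class_map())
  expect_equal(c(tab0$a, tab0$b), c(0, 0))
  expect_equal(tab0$c, 4)
  # an exposure known nowhere is a lookup error
  expect_error(build_contingency(coh, "no-such-thing"), "neither")
})

test_that("ROR and PRR match high-precision arithmetic on the toy table", {
  tab <- contingency_table(10, 90, 100, 9900)
  r <- ror(tab)
  expect_equal(r$ror, 11.0, tolerance = 1e-12)
  expect_equal(r$ror_lo, 5.5595149289, tolerance = 1e-9)
  expect_equal(r$ror_hi, 21.7644887274, tolerance = 1e-9)
  expect_false(r$correction_applied)
  p <- prr(tab)
  expect_equal(p$prr, 10.0, tolerance = 1e-12)
  expect_equal(p$prr_lo, 5.3821539275, tolerance = 1e-9)
  expect_equal(p$prr_hi, 18.5799219693, tolerance = 1e-9)
  expect_equal(p$n, 10)
})

test_that("a symmetric table gives ROR = PRR = 1", {
  tab <- contingency_table(25, 25, 25, 25)
  expect_equal(ror(tab)$ror, 1)
  expect_equal(prr(tab)$prr, 1)
})

test_that("zero cells trigger the continuity correction, reproducing the +0.5 arithmetic", {
  tab <- contingency_table(1, 0, 5, 20)
  r <- ror(tab)
  expect_true(r$correction_applied)
  a <- 1.5; b <- 0.5; c <- 5.5; d <- 20.5
  expect_equal(r$ror, (a * d) / (b * c), tolerance = 1e-12)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expect_equal(r$ror_lo, exp(log((a * d) / (b * c)) - 1.96 * se),
               tolerance = 1e-12)
  expect_true(is.finite(r$ror_hi))
  expect_error(ror(contingency_table(0, 0, 0, 0)), "undefined")
})

test_that("PRR is invariant to scaling the comparator arm", {
  t1 <- contingency_table(10, 90, 100, 9900)
  t2 <- contingency_table(10, 90, 300, 29700)
  expect_equal(prr(t1)$prr, prr(t2)$prr, tolerance = 1e-12)
})

test_that("increasing a with other cells fixed strictly increases both indices", {
  vals <- vapply(5:15, function(a) {
    tab <- contingency_table(a, 90, 100, 9900)
    c(ror(tab)$ror, prr(tab)$prr)
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
})

test_that("ROR approximates PRR for rare events", {
  set.seed(11)
  for (i in 1:200) {
    ab <- sample(200:5000, 1)
    cd <- sample(5000:50000, 1)
    a <- rbinom(1, ab, 0.01); c_ <- rbinom(1, cd, 0.01)
    if (a == 0 || c_ == 0) next
    tab <- contingency_table(a, ab - a, c_, cd - c_)
    expect_lt(abs(ror(tab)$ror - prr(tab)$prr) / prr(tab)$prr, 0.02)
  }
})

test_that("the 95% ROR interval covers the null about 95% of the time under independence", {
  set.seed(2024)
  nsim <- 2000
  N <- 10000
  p_drug <- 0.2; p_event <- 0.1
  probs <- c(p_drug * p_event, p_drug * (1 - p_event),
             (1 - p_drug) * p_event, (1 - p_drug) * (1 - p_event))
  covered <- logical(nsim)
  for (i in seq_len(nsim)) {
    cells <- as.vector(stats::rmultinom(1, N, probs))
    r <- ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    covered[i] <- r$ror_lo <= 1 && 1 <= r$ror_hi
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("the within-class ROR against a reference drug matches hand arithmetic", {
  reports <- c(
    lapply(1:20, function(i) rpt(paste0("d", i),
                                 drugs = data.frame(name = "semaglutide", role = "PS"),
                                 pts = "Pancreatitis")),
    lapply(1:80, function(i) rpt(paste0("dn", i),
                                 drugs = data.frame(name = "semaglutide", role = "PS"),
                                 pts = "Nausea")),
    lapply(1:10, function(i) rpt(paste0("r", i),
                                 drugs = data.frame(name = "exenatide", role = "PS"),
                                 pts = "Pancreatitis")),
    lapply(1:90, function(i) rpt(paste0("rn", i),
                                 drugs = data.frame(name = "exenatide", role = "PS"),
                                 pts = "Nausea")))
  coh <- build_cohort(make_bundle(reports), filter_config())
  res <- pairwise_ror(coh, "semaglutide", "exenatide")
  expect_equal(res$ror, (20 * 90) / (80 * 10), tolerance = 1e-12)  # 2.25
  # reciprocity
  rev <- pairwise_ror(coh, "exenatide", "semaglutide")
  expect_equal(rev$ror, 1 / res$ror, tolerance = 1e-12)
  # identical counts give ROR 1 (drug vs a same-count comparator)
  expect_error(pairwise_ror(coh, "semaglutide", "semaglutide"), "differ")
  expect_error(pairwise_ror(coh, "semaglutide", "albiglutide"), "absent")
})
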