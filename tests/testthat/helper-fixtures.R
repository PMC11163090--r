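# Shared fixtures and independent oracles, all built in code.

# Write "$"-delimited lines to a fresh temp file and return its path.
write_faers_lines <- function(lines, dir = NULL, name = "DEMO0000Q0.txt") {
  if (is.null(dir)) {
    dir <- tempfile("faers")
    dir.create(dir)
  }
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

demo_header <- "primaryid$caseid$caseversion$event_dt$fda_dt$sex$age$age_cod$occr_country"

demo_line <- function(primaryid, caseid = primaryid, caseversion = 1,
                      event_dt = "20190215", fda_dt = "20190301",
                      sex = "F", age = "60", age_cod = "YR",
                      country = "US") {
  paste(primaryid, caseid, caseversion, event_dt, fda_dt, sex, age,
        age_cod, country, sep = "$")
}

# Build a small in-memory quarter bundle from per-report specs.
# reports: list of lists with fields primaryid, caseid, caseversion,
# event_dt, fda_dt, sex, age, age_cod, country, drugs (data.frame name/role),
# pts (character), outcomes (character).
make_bundle <- function(reports, deleted = character(0), label = "2019Q1") {
  g <- function(r, f, d) if (is.null(r[[f]])) d else r[[f]]
  demo <- do.call(rbind, lapply(reports, function(r) data.frame(
    primaryid = r$primaryid,
    caseid = g(r, "caseid", r$primaryid),
    caseversion = g(r, "caseversion", 1),
    event_dt = g(r, "event_dt", "20190215"),
    fda_dt = g(r, "fda_dt", "20190301"),
    sex = g(r, "sex", "F"),
    age = suppressWarnings(as.numeric(g(r, "age", "60"))),
    age_cod = g(r, "age_cod", "YR"),
    occr_country = g(r, "country", "US"),
    stringsAsFactors = FALSE)))
  drug <- do.call(rbind, lapply(reports, function(r) {
    d <- g(r, "drugs", data.frame(name = "aspirin", role = "PS"))
    data.frame(primaryid = r$primaryid, drug_seq = seq_len(nrow(d)),
               role_cod = d$role, drugname = d$name,
               stringsAsFactors = FALSE)
  }))
  reac <- do.call(rbind, lapply(reports, function(r) {
    p <- g(r, "pts", "Nausea")
    data.frame(primaryid = r$primaryid, pt = p, stringsAsFactors = FALSE)
  }))
  outc <- do.call(rbind, lapply(reports, function(r) {
    oc <- g(r, "outcomes", character(0))
    if (!length(oc)) return(NULL)
    data.frame(primaryid = r$primaryid, outc_cod = oc,
               stringsAsFactors = FALSE)
  }))
  if (is.null(outc)) {
    outc <- data.frame(primaryid = character(0), outc_cod = character(0),
                       stringsAsFactors = FALSE)
  }
  quarter_bundle(demo, drug, reac, outc, deleted, label)
}

# A compact report spec constructor.
rpt <- function(primaryid, ...) c(list(primaryid = primaryid), list(...))

# Independent EBGM oracle: adaptive quadrature of the unnormalized
# posterior density prior(lambda) * Poisson(n | lambda * e). Shares no code
# with the conjugate closed form under test.
oracle_ebgm <- function(n, e, prior) {
  dens <- function(l) {
    (prior$p * dgamma(l, prior$alpha1, rate = prior$beta1) +
       (1 - prior$p) * dgamma(l, prior$alpha2, rate = prior$beta2)) *
      dpois(n, l * e)
  }
  upper <- max(200, 20 * (n + 10) / e)
  Z <- integrate(dens, 0, upper, rel.tol = 1e-10, abs.tol = 0,
                 subdivisions = 500L)$value
  El <- integrate(function(l) log(l) * dens(l), 0, upper,
                  rel.tol = 1e-10, abs.tol = 0,
                  subdivisions = 500L)$value / Z
  list(ebgm = exp(El),
       cdf = function(x) integrate(dens, 0, x, rel.tol = 1e-10,
                                   abs.tol = 0,
                                   subdivisions = 500L)$value / Z)
}
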