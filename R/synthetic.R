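# Synthetic FAERS-schema generator with known ground truth: a drug-by-event
# Poisson grid with multiplicative injected relative risks over independence
# expectations, expanded to DEMO/DRUG/REAC/OUTC rows with case versioning,
# duplicate reports and missing demographics at configurable rates.

#' Synthetic database configuration
#'
#' The defaults define the package's reference simulation scenario: a
#' 200 x 100 drug-by-event grid with 200,000 expected reports, margins
#' drawn once from a symmetric Dirichlet, one injected signal at relative
#' risk 10 placed (automatically) on a margin-balanced pair whose expected
#' in-window count is about 20, reports spread uniformly over the
#' 2019--2021 study years, and missingness/duplication rates in the range
#' seen in spontaneous-report data (about 14% missing sex, 5% missing
#' dates, 15% missing age, 2% duplicate emissions, 3% superseded case
#' versions). Widening `year_range` beyond `window_years` (as the stress
#' preset does) exercises the window filter.
#'
#' @param n_drugs,n_events grid dimensions.
#' @param n_reports expected total number of cases.
#' @param drug_margin_weights,event_margin_weights optional positive weight
#'   vectors; drawn from a symmetric Dirichlet (seeded) when NULL.
#' @param injected_signals `"auto"` (one pair at `injected_rr` with
#'   in-window expectation near `injected_e_target`), `NULL` (pure null),
#'   or a data.frame with columns `drug`, `event` (labels or indices) and
#'   `true_rr`.
#' @param injected_rr,injected_e_target parameters of the automatic
#'   injection.
#' @param duplicate_rate fraction of cases re-emitted with the same
#'   (caseid, event date, preferred term) under a new report identifier.
#' @param version_rate fraction of cases re-emitted with an incremented
#'   case version (the earlier version should be discarded by
#'   deduplication).
#' @param missing_sex_rate,missing_date_rate,missing_age_rate missingness
#'   fractions; `missing_date_rate` applies independently to the event and
#'   the FDA receipt date.
#' @param multi_drug_rate,multi_pt_rate fraction of cases given a second
#'   primary-suspect drug / second preferred term (off by default so pair
#'   counts stay directly interpretable).
#' @param year_range inclusive span of report years.
#' @param window_years the analysis window assumed when auto-placing the
#'   injected signal and when reporting in-window ground truth.
#' @param seed mandatory integer seed; every random draw derives from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 200, n_events = 100,
                             n_reports = 200000,
                             drug_margin_weights = NULL,
                             event_margin_weights = NULL,
                             injected_signals = "auto",
                             injected_rr = 10, injected_e_target = 20,
                             duplicate_rate = 0.02, version_rate = 0.03,
                             missing_sex_rate = 0.14,
                             missing_date_rate = 0.05,
                             missing_age_rate = 0.15,
                             multi_drug_rate = 0, multi_pt_rate = 0,
                             year_range = c(2019, 2021),
                             window_years = c(2019, 2021),
                             seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  rates <- c(duplicate_rate, version_rate, missing_sex_rate,
             missing_date_rate, missing_age_rate, multi_drug_rate,
             multi_pt_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), n_drugs >= 2, n_events >= 2,
            n_reports >= 1, length(year_range) == 2,
            year_range[1] <= year_range[2])
  if (!is.null(drug_margin_weights)) {
    stopifnot(length(drug_margin_weights) == n_drugs,
              all(drug_margin_weights > 0))
  }
  if (!is.null(event_margin_weights)) {
    stopifnot(length(event_margin_weights) == n_events,
              all(event_margin_weights > 0))
  }
  structure(list(n_drugs = n_drugs, n_events = n_events,
                 n_reports = n_reports,
                 drug_margin_weights = drug_margin_weights,
                 event_margin_weights = event_margin_weights,
                 injected_signals = injected_signals,
                 injected_rr = injected_rr,
                 injected_e_target = injected_e_target,
                 duplicate_rate = duplicate_rate,
                 version_rate = version_rate,
                 missing_sex_rate = missing_sex_rate,
                 missing_date_rate = missing_date_rate,
                 missing_age_rate = missing_age_rate,
                 multi_drug_rate = multi_drug_rate,
                 multi_pt_rate = multi_pt_rate,
                 year_range = as.integer(year_range),
                 window_years = as.integer(window_years),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Scenario presets
#'
#' `"null"`: no injected signal, 50 x 30 grid, 50,000 reports.
#' `"default"`: the reference scenario (see [synthetic_config()]).
#' `"stress"`: three injected signals, higher duplication/missingness and
#' 10% multi-drug / multi-PT cases.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a `synthetic_config`.
#' @export
scenario_preset <- function(name = c("default", "null", "stress"), seed) {
  name <- match.arg(name)
  switch(name,
    default = synthetic_config(seed = seed),
    null = synthetic_config(n_drugs = 50, n_events = 30, n_reports = 50000,
                            injected_signals = NULL, seed = seed),
    stress = synthetic_config(
      injected_signals = data.frame(drug = c(7L, 12L, 40L),
                                    event = c(3L, 9L, 21L),
                                    true_rr = c(10, 5, 3)),
      duplicate_rate = 0.08, version_rate = 0.08,
      missing_sex_rate = 0.25, missing_date_rate = 0.15,
      missing_age_rate = 0.3, multi_drug_rate = 0.1, multi_pt_rate = 0.1,
      year_range = c(2018, 2022), seed = seed))
}

.quarter_of_month <- function(m) (m - 1L) %/% 3L + 1L

#' Generate a synthetic FAERS database with ground truth
#'
#' Pair counts are drawn Poisson with mean
#' `n_reports * w_drug * w_event * true_rr` (`true_rr = 1` off the injected
#' list); each case is expanded to DEMO/DRUG/REAC/OUTC rows with the drug
#' in the primary-suspect role, then case versions, duplicate emissions and
#' missingness are applied at the configured rates. Fully reproducible from
#' the seed: identical configs give byte-identical files after
#' [write_normalized()].
#'
#' @param config a [synthetic_config()].
#' @return list with `bundles` (list of `quarter_bundle`s, one per
#'   calendar quarter present) and `truth` (a `synthetic_truth` list: the
#'   per-pair table, per-case table and realized audit counts).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nd <- config$n_drugs; ne <- config$n_events
  wd <- config$drug_margin_weights
  if (is.null(wd)) wd <- rgamma(nd, shape = 1)
  wd <- wd / sum(wd)
  we <- config$event_margin_weights
  if (is.null(we)) we <- rgamma(ne, shape = 1)
  we <- we / sum(we)
  drug_labels <- sprintf("DRUG_%03d", seq_len(nd))
  event_labels <- sprintf("EVT_%03d", seq_len(ne))

  years <- seq(config$year_range[1], config$year_range[2])
  in_win <- years >= config$window_years[1] & years <= config$window_years[2]
  f_window <- mean(in_win)

  rr <- matrix(1, nd, ne)
  inj <- config$injected_signals
  if (identical(inj, "auto")) {
    mu0 <- config$n_reports * outer(wd, we)
    target <- config$injected_e_target / max(f_window, 1e-9)
    # among pairs whose null expectation is near the target, prefer the one
    # with the most balanced margins: the injected excess then inflates the
    # pair's own row/column totals (and hence its estimated expectation) as
    # little as possible
    near <- which(abs(mu0 - target) <= 0.15 * target)
    if (!length(near)) near <- which.min(abs(mu0 - target))
    ij_all <- arrayInd(near, dim(mu0))
    balance <- abs(log(wd[ij_all[, 1]] / we[ij_all[, 2]]))
    ij <- ij_all[which.min(balance), , drop = TRUE]
    inj <- data.frame(drug = ij[1], event = ij[2],
                      true_rr = config$injected_rr)
  }
  if (!is.null(inj) && nrow(inj)) {
    di <- if (is.numeric(inj$drug)) as.integer(inj$drug)
          else match(inj$drug, drug_labels)
    ei <- if (is.numeric(inj$event)) as.integer(inj$event)
          else match(inj$event, event_labels)
    if (any(is.na(di)) || any(di < 1) || any(di > nd) ||
        any(is.na(ei)) || any(ei < 1) || any(ei > ne)) {
      stop("injected pair outside the configured grid")
    }
    rr[cbind(di, ei)] <- inj$true_rr
  }

  mu <- config$n_reports * outer(wd, we) * rr
  npair <- rpois(length(mu), as.vector(mu))
  M <- sum(npair)
  pair_idx <- rep.int(seq_along(npair), npair)
  di_case <- (pair_idx - 1L) %% nd + 1L
  ei_case <- (pair_idx - 1L) %/% nd + 1L
  ord <- sample.int(M)
  di_case <- di_case[ord]; ei_case <- ei_case[ord]

  cid_num <- 10000000 + seq_len(M)
  caseid <- as.character(cid_num)

  year <- sample(years, M, replace = TRUE)
  month <- sample.int(12, M, replace = TRUE)
  day <- sample.int(28, M, replace = TRUE)
  event_date <- as.Date(sprintf("%04d-%02d-%02d", year, month, day))
  lag <- rgeom(M, 1 / 30)
  fda_date <- event_date + lag
  ev_missing <- runif(M) < config$missing_date_rate
  fda_missing <- runif(M) < config$missing_date_rate
  event_dt <- ifelse(ev_missing, NA_character_, format(event_date, "%Y%m%d"))
  fda_dt <- ifelse(fda_missing, NA_character_, format(fda_date, "%Y%m%d"))

  sex <- sample(c("F", "M"), M, replace = TRUE, prob = c(0.52, 0.48))
  sex[runif(M) < config$missing_sex_rate] <- NA
  age_years <- round(pmin(95, pmax(5, rnorm(M, 58, 15))))
  unit <- sample(c("YR", "MON", "DY"), M, replace = TRUE,
                 prob = c(0.96, 0.03, 0.01))
  age_val <- ifelse(unit == "YR", age_years,
                    ifelse(unit == "MON", age_years * 12,
                           round(age_years * 365.25)))
  age_na <- runif(M) < config$missing_age_rate
  age_val[age_na] <- NA
  unit[age_na] <- NA
  country <- sample(c("US", "CA", "GB", "FR", "DE", "JP"), M,
                    replace = TRUE,
                    prob = c(0.6, 0.08, 0.1, 0.07, 0.07, 0.08))
  country[runif(M) < 0.05] <- NA

  # outcome codes, hospitalisation-heavy; 0-2 per case, no repeats
  oc_probs <- c(HO = 0.40, OT = 0.35, DE = 0.08, LT = 0.08, DS = 0.04,
                RI = 0.03, CA = 0.02)
  has1 <- runif(M) < 0.5
  has2 <- has1 & (runif(M) < 0.15)
  oc1 <- sample(names(oc_probs), M, replace = TRUE, prob = oc_probs)
  oc2 <- sample(names(oc_probs), M, replace = TRUE, prob = oc_probs)
  outc_case <- lapply(seq_len(M), function(i) {
    v <- c(if (has1[i]) oc1[i], if (has2[i]) oc2[i])
    unique(v)
  })

  # optional extra PS drug / extra PT
  extra_drug <- ifelse(runif(M) < config$multi_drug_rate,
                       sample.int(nd, M, replace = TRUE), NA_integer_)
  extra_drug[!is.na(extra_drug) & extra_drug == di_case] <- NA
  extra_pt <- ifelse(runif(M) < config$multi_pt_rate,
                     sample.int(ne, M, replace = TRUE), NA_integer_)
  extra_pt[!is.na(extra_pt) & extra_pt == ei_case] <- NA

  versioned <- runif(M) < config$version_rate
  duplicated_case <- runif(M) < config$duplicate_rate

  # final content of each case (what deduplication should retain): version 2
  # shifts the FDA receipt date by 30 days
  fda_date_v2 <- fda_date + 30
  final_fda_dt <- ifelse(versioned & !fda_missing,
                         format(fda_date_v2, "%Y%m%d"), fda_dt)
  final_version <- ifelse(versioned, 2L, 1L)
  final_year <- ifelse(!is.na(event_dt), faers_date_year(event_dt),
                       faers_date_year(final_fda_dt))
  in_window <- !is.na(final_year) &
    final_year >= config$window_years[1] &
    final_year <= config$window_years[2]

  # emissions: superseded version-1 rows, final rows, duplicate rows
  emit <- function(sel, version, fda, suffix) {
    if (!any(sel)) return(NULL)
    data.frame(idx = which(sel), caseversion = version[sel],
               fda_dt = fda[sel],
               primaryid = paste0(caseid[sel], suffix, version[sel]),
               stringsAsFactors = FALSE)
  }
  em_final <- emit(rep(TRUE, M), final_version, final_fda_dt, "")
  em_old <- emit(versioned, rep(1L, M), fda_dt, "")
  em_dup <- emit(duplicated_case, final_version, final_fda_dt, "9")
  emissions <- rbind(em_final, em_old, em_dup)

  i <- emissions$idx
  demo <- data.frame(
    primaryid = emissions$primaryid, caseid = caseid[i],
    caseversion = emissions$caseversion, event_dt = event_dt[i],
    fda_dt = emissions$fda_dt, sex = sex[i], age = age_val[i],
    age_cod = unit[i], occr_country = country[i],
    stringsAsFactors = FALSE)
  second_drug <- !is.na(extra_drug[i])
  drug <- data.frame(
    primaryid = c(emissions$primaryid, emissions$primaryid[second_drug]),
    drug_seq = c(rep(1L, length(i)), rep(2L, sum(second_drug))),
    role_cod = "PS",
    drugname = c(drug_labels[di_case[i]],
                 drug_labels[extra_drug[i][second_drug]]),
    stringsAsFactors = FALSE)
  second_pt <- !is.na(extra_pt[i])
  reac <- data.frame(
    primaryid = c(emissions$primaryid, emissions$primaryid[second_pt]),
    pt = c(event_labels[ei_case[i]],
           event_labels[extra_pt[i][second_pt]]),
    stringsAsFactors = FALSE)
  noc <- lengths(outc_case)[i]
  outc <- data.frame(
    primaryid = rep(emissions$primaryid, noc),
    outc_cod = unlist(outc_case[i], use.names = FALSE),
    stringsAsFactors = FALSE)

  # quarter assignment per emission: receipt date preferred
  qdate <- ifelse(!is.na(emissions$fda_dt), emissions$fda_dt, event_dt[i])
  qyear <- faers_date_year(qdate)
  qmonth <- suppressWarnings(as.integer(substr(qdate, 5, 6)))
  fallback <- is.na(qyear) | is.na(qmonth)
  if (any(fallback)) {
    qyear[fallback] <- sample(years, sum(fallback), replace = TRUE)
    qmonth[fallback] <- sample.int(12, sum(fallback), replace = TRUE)
  }
  qlab <- sprintf("%04dQ%d", qyear, .quarter_of_month(qmonth))

  labs <- sort(unique(qlab))
  drug_lab <- qlab[match(drug$primaryid, emissions$primaryid)]
  reac_lab <- qlab[match(reac$primaryid, emissions$primaryid)]
  outc_lab <- qlab[match(outc$primaryid, emissions$primaryid)]
  bundles <- lapply(labs, function(lb) {
    sel <- function(tab, lv) {
      out <- tab[lv == lb, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    quarter_bundle(sel(demo, qlab), sel(drug, drug_lab),
                   sel(reac, reac_lab), sel(outc, outc_lab),
                   character(0), lb)
  })

  pair_truth <- data.frame(
    drug = rep(drug_labels, times = ne),
    event = rep(event_labels, each = nd),
    true_rr = as.vector(rr),
    expected_count = as.vector(mu),
    expected_in_window = as.vector(mu) * f_window,
    n_cases = npair,
    stringsAsFactors = FALSE)
  nw <- tapply(in_window, pair_idx[ord], sum)
  pair_truth$n_in_window <- 0L
  pair_truth$n_in_window[as.integer(names(nw))] <- as.integer(nw)

  case_truth <- data.frame(
    caseid = caseid, drug = drug_labels[di_case],
    event = event_labels[ei_case], report_year = final_year,
    in_window = in_window, sex = sex, age_years = age_years,
    versioned = versioned, duplicated = duplicated_case,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    config = config,
    drug_weights = wd, event_weights = we,
    injected = inj,
    pair_truth = pair_truth,
    case_truth = case_truth,
    n_cases = M,
    n_versions = sum(versioned),
    n_duplicates = sum(duplicated_case),
    n_missing_year = sum(is.na(final_year)),
    n_out_of_window = sum(!is.na(final_year) & !in_window),
    n_in_window = sum(in_window)),
    class = "synthetic_truth")
  list(bundles = bundles, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic FAERS ground truth: %d cases (%d in window, %d versions, %d duplicates)\n",
              x$n_cases, x$n_in_window, x$n_versions, x$n_duplicates))
  ninj <- sum(x$pair_truth$true_rr != 1)
  cat(sprintf("  grid %d x %d, %d injected signal pair(s)\n",
              length(x$drug_weights), length(x$event_weights), ninj))
  invisible(x)
}

#' Ground-truth pair table
#'
#' One row per drug-by-event pair with the true relative risk and expected
#' count; joinable to pipeline outputs by the drug/event labels.
#'
#' @param truth a `synthetic_truth` (from [generate_database()]).
#' @return data.frame `drug`, `event`, `true_rr`, `expected_count`,
#'   `expected_in_window`, `n_cases`, `n_in_window`.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth$pair_truth
}
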