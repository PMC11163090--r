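# Signal triage: the all-four-indices decision rule with minimum report
# counts, plus the descriptive report summaries (sex, age, year, country,
# outcomes, seriousness).

#' Signal criteria (four-index rule)
#'
#' Defaults follow the study rule: ROR > 1 with at least 2 reports,
#' PRR > 2 with at least 3 reports, EBGM >= 2 and IC > 0 each with at least
#' 1 report; a pair is a signal only when all four indices meet their
#' criterion. `ror_rule` switches the ROR criterion from the point estimate
#' (the rule as literally stated) to the CI lower bound.
#'
#' @param ror_threshold exclusive ROR threshold.
#' @param prr_threshold exclusive PRR threshold.
#' @param ebgm_threshold inclusive EBGM threshold.
#' @param ic_threshold exclusive IC threshold.
#' @param min_n_ror,min_n_prr,min_n_bayes minimum report counts.
#' @param ror_rule `"point"` or `"ci_lower"`.
#' @return object of class `signal_criteria`.
#' @export
signal_criteria <- function(ror_threshold = 1, prr_threshold = 2,
                            ebgm_threshold = 2, ic_threshold = 0,
                            min_n_ror = 2, min_n_prr = 3, min_n_bayes = 1,
                            ror_rule = c("point", "ci_lower")) {
  stopifnot(ror_threshold > 0, prr_threshold > 0, ebgm_threshold > 0,
            min_n_ror >= 1, min_n_prr >= 1, min_n_bayes >= 1)
  structure(list(ror_threshold = ror_threshold,
                 prr_threshold = prr_threshold,
                 ebgm_threshold = ebgm_threshold,
                 ic_threshold = ic_threshold,
                 min_n_ror = min_n_ror, min_n_prr = min_n_prr,
                 min_n_bayes = min_n_bayes,
                 ror_rule = match.arg(ror_rule)),
            class = "signal_criteria")
}

#' Evaluate the four-index signal rule
#'
#' @param metrics a list (or one-row data.frame) holding `ror`, `prr`,
#'   `ebgm`, `ic` (and `ror_lo` when `ror_rule = "ci_lower"`).
#' @param n report count for the pair (cell `a`).
#' @param criteria a [signal_criteria()].
#' @return object of class `signal_decision`: `pass_ror`, `pass_prr`,
#'   `pass_ebgm`, `pass_ic`, `is_signal`.
#' @export
#' @examples
#' evaluate_signal(list(ror = 9.65, prr = 9.40, ebgm = 8.64, ic = 3.11),
#'                 n = 1624)
evaluate_signal <- function(metrics, n, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  metrics <- as.list(metrics)
  need <- c("ror", "prr", "ebgm", "ic")
  if (criteria$ror_rule == "ci_lower") need <- c(need, "ror_lo")
  for (nm in need) {
    if (is.null(metrics[[nm]]) || is.na(metrics[[nm]])) {
      stop("missing index: ", nm)
    }
  }
  ror_value <- if (criteria$ror_rule == "ci_lower") metrics$ror_lo else metrics$ror
  d <- list(
    pass_ror = ror_value > criteria$ror_threshold & n >= criteria$min_n_ror,
    pass_prr = metrics$prr > criteria$prr_threshold & n >= criteria$min_n_prr,
    pass_ebgm = metrics$ebgm >= criteria$ebgm_threshold & n >= criteria$min_n_bayes,
    pass_ic = metrics$ic > criteria$ic_threshold & n >= criteria$min_n_bayes)
  d$is_signal <- d$pass_ror & d$pass_prr & d$pass_ebgm & d$pass_ic
  structure(d, class = "signal_decision")
}

#' @export
print.signal_decision <- function(x, ...) {
  cat(sprintf("ROR %s | PRR %s | EBGM %s | IC %s => %s\n",
              ifelse(x$pass_ror, "pass", "fail"),
              ifelse(x$pass_prr, "pass", "fail"),
              ifelse(x$pass_ebgm, "pass", "fail"),
              ifelse(x$pass_ic, "pass", "fail"),
              ifelse(x$is_signal, "SIGNAL", "no signal")))
  invisible(x)
}

#' Percentage share of a class among all studied reports
#'
#' @param class_count reports for the class.
#' @param total all studied reports.
#' @return percentage, rounded to one decimal.
#' @export
#' @examples
#' class_share(1624, 2313)  # 70.2
class_share <- function(class_count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(class_count > total)) stop("class_count exceeds total")
  round(100 * class_count / total, 1)
}

# Serious outcome codes: death, disability, hospitalization,
# life-threatening, required intervention, congenital anomaly. "Other"
# (OT) is not counted as serious.
.serious_codes <- c("DE", "DS", "HO", "LT", "RI", "CA")

#' Descriptive summary of the cases for one exposure
#'
#' Tabulates sex (counts and percents over the sex-recorded denominator,
#' with the missing count reported separately), age bins, report years,
#' countries and outcome codes (one tally per case-code occurrence), plus
#' the count and percent of cases with at least one serious outcome.
#'
#' @param cohort a `faers_cohort`.
#' @param exposure optional class/drug restriction (cases only).
#' @param cases_only restrict to reports with the target event
#'   (default TRUE).
#' @return object of class `descriptive_summary`.
#' @export
summarize_descriptives <- function(cohort, exposure = NULL,
                                   cases_only = TRUE) {
  stopifnot(inherits(cohort, "faers_cohort"))
  x <- cohort
  if (!is.null(exposure)) x <- x[.exposed_rows(x, exposure), , drop = FALSE]
  if (cases_only) x <- x[x$event_flag, , drop = FALSE]
  n <- nrow(x)
  sex_rec <- x$sex[!is.na(x$sex)]
  by_sex <- table(factor(sex_rec, levels = c("F", "M")))
  sex_pct <- if (length(sex_rec)) round(100 * as.numeric(by_sex) / length(sex_rec), 1) else c(NA, NA)
  oc <- unlist(lapply(x$outcome_codes, .split_key), use.names = FALSE)
  by_outcome <- table(factor(oc, levels = .outcome_codes))
  serious <- vapply(x$outcome_codes,
                    function(k) any(.split_key(k) %in% .serious_codes),
                    logical(1), USE.NAMES = FALSE)
  structure(list(
    n_cases = n,
    by_sex = data.frame(sex = names(by_sex), count = as.integer(by_sex),
                        percent = sex_pct, stringsAsFactors = FALSE),
    sex_missing = n - length(sex_rec),
    by_age_bin = as.data.frame(table(factor(x$age_bin,
                                            levels = .age_bin_levels)),
                               stringsAsFactors = FALSE,
                               responseName = "count"),
    age_missing = sum(is.na(x$age_bin)),
    by_year = as.data.frame(table(year = x$report_year),
                            stringsAsFactors = FALSE,
                            responseName = "count"),
    by_country = as.data.frame(sort(table(country = x$country),
                                    decreasing = TRUE),
                               stringsAsFactors = FALSE,
                               responseName = "count"),
    by_outcome = data.frame(code = names(by_outcome),
                            count = as.integer(by_outcome),
                            stringsAsFactors = FALSE),
    serious_count = sum(serious),
    serious_percent = if (n) round(100 * sum(serious) / n, 1) else NA_real_),
    class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(sprintf("%d cases; sex recorded for %d (missing %d)\n",
              x$n_cases, sum(x$by_sex$count), x$sex_missing))
  for (i in seq_len(nrow(x$by_sex))) {
    cat(sprintf("  %s: %d (%.1f%%)\n", x$by_sex$sex[i], x$by_sex$count[i],
                x$by_sex$percent[i]))
  }
  cat(sprintf("serious outcomes in %d cases (%.1f%%)\n",
              x$serious_count, x$serious_percent))
  invisible(x)
}

#' Published class-level reference values
#'
#' Class-level pancreatitis disproportionality estimates reported by a
#' published FAERS 2019--2021 analysis of the three antidiabetic drug
#' classes, plus its within-class (reference drug exenatide) reporting odds
#' ratios, its sex table and its outcome table. These printed values serve
#' as worked-example inputs for the signal rule and the descriptive
#' arithmetic; reproducing them from raw data requires the real FAERS
#' quarters and the original dictionary/deduplication choices.
#'
#' @return list with data.frames `class_indices` (class, n, ror, ror_lo,
#'   ror_hi, prr, prr_lo, prr_hi, ebgm, ic), `within_class_ror` (drug, ror,
#'   ror_lo, ror_hi vs exenatide), `sex` (sex, count) with missing count,
#'   and `outcomes` (code, count).
#' @export
reference_values <- function() {
  list(
    class_indices = data.frame(
      class = c("GLP-1 RA", "DPP-4 inhibitor", "SGLT2 inhibitor"),
      n = c(1624L, 348L, 341L),
      ror = c(9.65, 13.20, 3.67),
      ror_lo = c(9.17, 11.84, 3.29),
      ror_hi = c(10.16, 14.70, 4.09),
      prr = c(9.40, 12.67, 3.63),
      prr_lo = c(8.92, 11.37, 3.26),
      prr_hi = c(9.90, 14.12, 4.05),
      ebgm = c(8.64, 12.25, 3.57),
      ic = c(3.11, 3.61, 1.84),
      stringsAsFactors = FALSE),
    within_class_ror = data.frame(
      drug = c("dulaglutide", "semaglutide", "liraglutide"),
      ror = c(2.71, 5.69, 6.83),
      ror_lo = c(2.63, 5.45, 6.60),
      ror_hi = c(2.79, 5.84, 7.07),
      reference = "exenatide",
      stringsAsFactors = FALSE),
    sex = list(counts = data.frame(sex = c("F", "M"),
                                   count = c(705L, 692L),
                                   stringsAsFactors = FALSE),
               missing = 226L),
    outcomes = data.frame(
      code = c("DE", "DS", "HO", "LT", "OT", "RI"),
      count = c(12L, 4L, 208L, 12L, 287L, 1L),
      stringsAsFactors = FALSE))
}
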