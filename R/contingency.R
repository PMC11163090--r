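# 2x2 contingency tables and the frequentist disproportionality indices
# (ROR, PRR) with 95% Wald confidence intervals on the log scale.

#' Construct a 2x2 disproportionality contingency table
#'
#' Cell `a` counts event reports for the studied exposure, `b` non-event
#' reports for the exposure, `c` event reports for all other exposures and
#' `d` non-event reports for all other exposures.
#'
#' @param a,b,c,d non-negative counts.
#' @param exposure_label,event_label optional labels.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, exposure_label = "",
                              event_label = "") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts")
  }
  structure(list(a = a, b = b, c = c, d = d,
                 exposure_label = exposure_label,
                 event_label = event_label),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table%s%s\n",
              if (nzchar(x$exposure_label)) paste0(" [", x$exposure_label, "]") else "",
              if (nzchar(x$event_label)) paste0(" vs ", x$event_label) else ""))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "other"),
                              c("event", "non-event")))
  print(m)
  invisible(x)
}

# Exposure membership: class name, or (generic) drug name, matched against
# a cohort row's class set / generic PS-drug set.
.exposed_rows <- function(cohort, exposure) {
  ex <- normalize_term(exposure)
  in_class <- vapply(strsplit(cohort$drug_classes, "|", fixed = TRUE),
                     function(k) any(normalize_term(k) == ex), logical(1),
                     USE.NAMES = FALSE)
  if (any(in_class)) return(in_class)
  vapply(strsplit(cohort$ps_generics, "|", fixed = TRUE),
         function(k) any(normalize_term(k) == ex), logical(1),
         USE.NAMES = FALSE)
}

#' Build the 2x2 table for one exposure against the full background
#'
#' The comparator is every cohort report whose primary-suspect set does not
#' include the studied exposure (the whole cleaned reporting window, not
#' only the studied classes).
#'
#' @param cohort a `faers_cohort` ([build_cohort()]).
#' @param exposure a drug-class name or (generic) drug name.
#' @param event event label for bookkeeping (defaults to the cohort's
#'   target preferred term).
#' @param class_map optional `drug_class_map`; an exposure found neither in
#'   the cohort nor in the map raises a lookup error, whereas a mapped
#'   exposure with zero reports yields a zero-margin table.
#' @return a [contingency_table()].
#' @export
build_contingency <- function(cohort, exposure,
                              event = paste(attr(cohort, "target_pt"),
                                            collapse = "|"),
                              class_map = NULL) {
  stopifnot(inherits(cohort, "faers_cohort"))
  exposed <- .exposed_rows(cohort, exposure)
  if (!any(exposed)) {
    ex <- normalize_term(exposure)
    in_map <- !is.null(class_map) &&
      (ex %in% normalize_term(class_map$class_name) ||
         ex %in% class_map$drug_norm || ex %in% class_map$synonym_norm)
    all_classes <- unique(unlist(strsplit(cohort$drug_classes, "|", fixed = TRUE)))
    all_drugs <- unique(unlist(strsplit(cohort$ps_generics, "|", fixed = TRUE)))
    in_cohort <- ex %in% normalize_term(c(all_classes, all_drugs))
    if (!in_map && !in_cohort) {
      stop(sprintf("exposure '%s' found neither in the cohort nor in the class map",
                   exposure))
    }
  }
  ev <- cohort$event_flag
  contingency_table(a = sum(exposed & ev), b = sum(exposed & !ev),
                    c = sum(!exposed & ev), d = sum(!exposed & !ev),
                    exposure_label = as.character(exposure),
                    event_label = event)
}

# Haldane-Anscombe continuity correction: +0.5 to every cell when any cell
# is zero. Returns list(cells, corrected).
.correct_cells <- function(tab) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (sum(cells) == 0) stop("all-zero contingency table: indices undefined")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a d)/(b c)`; the interval is
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, 0.5 is added to all four cells (point estimate and interval) and
#' `correction_applied` is set.
#'
#' @param table a [contingency_table()].
#' @return list of class `dispro_metrics` with `ror`, `ror_lo`, `ror_hi`,
#'   `n` (= a), `correction_applied`.
#' @export
#' @examples
#' ror(contingency_table(10, 90, 100, 9900))
ror <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cc <- .correct_cells(table)
  a <- cc$cells[1]; b <- cc$cells[2]; c <- cc$cells[3]; d <- cc$cells[4]
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(ror = est,
                 ror_lo = exp(log(est) - 1.96 * se),
                 ror_hi = exp(log(est) + 1.96 * se),
                 n = table$a,
                 correction_applied = cc$corrected),
            class = "dispro_metrics")
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the interval is
#' `exp(log PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Zero-cell
#' handling as in [ror()].
#'
#' @param table a [contingency_table()].
#' @return list of class `dispro_metrics` with `prr`, `prr_lo`, `prr_hi`,
#'   `n`, `correction_applied`.
#' @export
prr <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cc <- .correct_cells(table)
  a <- cc$cells[1]; b <- cc$cells[2]; c <- cc$cells[3]; d <- cc$cells[4]
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  structure(list(prr = est,
                 prr_lo = exp(log(est) - 1.96 * se),
                 prr_hi = exp(log(est) + 1.96 * se),
                 n = table$a,
                 correction_applied = cc$corrected),
            class = "dispro_metrics")
}

#' @export
print.dispro_metrics <- function(x, ...) {
  fmt <- function(v, lo, hi, nm)
    cat(sprintf("%s %.2f (95%% CI %.2f-%.2f)\n", nm, v, lo, hi))
  if (!is.null(x$ror)) fmt(x$ror, x$ror_lo, x$ror_hi, "ROR")
  if (!is.null(x$prr)) fmt(x$prr, x$prr_lo, x$prr_hi, "PRR")
  cat(sprintf("n = %d%s\n", x$n,
              if (isTRUE(x$correction_applied)) " (continuity correction applied)" else ""))
  invisible(x)
}

#' Within-class reporting odds ratio against a reference drug
#'
#' Restricts the cohort to reports exposed to either the studied drug or the
#' reference drug, and computes the ROR of the target event for the drug
#' versus the reference (`a`/`b` from the drug's reports, `c`/`d` from the
#' reference drug's reports).
#'
#' @param cohort a `faers_cohort`.
#' @param drug generic drug name under study.
#' @param reference generic name of the comparator (e.g. the class's
#'   reference drug).
#' @return a `dispro_metrics` list (ROR part), plus the underlying
#'   `contingency_table` in element `table`.
#' @export
pairwise_ror <- function(cohort, drug, reference) {
  stopifnot(inherits(cohort, "faers_cohort"))
  if (normalize_term(drug) == normalize_term(reference)) {
    stop("drug and reference must differ")
  }
  ed <- .exposed_rows(cohort, drug)
  er <- .exposed_rows(cohort, reference)
  if (!any(er)) stop(sprintf("reference drug '%s' absent from the cohort", reference))
  ev <- cohort$event_flag
  tab <- contingency_table(a = sum(ed & ev), b = sum(ed & !ev),
                           c = sum(er & ev), d = sum(er & !ev),
                           exposure_label = sprintf("%s vs %s", drug, reference),
                           event_label = paste(attr(cohort, "target_pt"),
                                               collapse = "|"))
  out <- ror(tab)
  out$table <- tab
  out
}
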