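# Vectorized disproportionality scan over a drug-by-event count grid:
# every pair gets its 2x2 cells from the grid margins, the four indices,
# and a signal decision.

#' Scan a drug-by-event grid for disproportionality signals
#'
#' For each pair, the 2x2 cells are derived from the grid margins
#' (`a = n`, `b` = drug total minus `a`, `c` = event total minus `a`,
#' `d` = remainder), ROR and PRR are computed with their 95% intervals
#' (0.5 added to all cells of a pair when any cell is zero), expectations
#' come from [expected_counts()], EBGM from the gamma-mixture prior (fitted
#' on the grid when not supplied) and IC from its closed form. The
#' four-index rule is then applied pair-wise.
#'
#' @param pairs a `pair_grid` / data.frame with `drug`, `event`, `n`.
#' @param prior optional fitted [gps_prior()]; fitted on `pairs` when NULL.
#' @param criteria a [signal_criteria()].
#' @param quantiles compute EB05/EB95 (numerical root-finding per pair)?
#' @return data.frame of class `signal_scan`: pair labels, cells, all
#'   indices with intervals, per-index pass flags and `is_signal`;
#'   attributes `prior` and `criteria`.
#' @export
signal_scan <- function(pairs, prior = NULL, criteria = signal_criteria(),
                        quantiles = FALSE) {
  stopifnot(is.data.frame(pairs),
            all(c("drug", "event", "n") %in% names(pairs)))
  pe <- expected_counts(pairs)
  N <- sum(pe$n)
  rowtot <- tapply(pe$n, pe$drug, sum)
  coltot <- tapply(pe$n, pe$event, sum)
  a <- as.numeric(pe$n)
  rt <- as.numeric(rowtot[pe$drug])
  ct <- as.numeric(coltot[pe$event])
  b <- rt - a
  cc <- ct - a
  d <- N - rt - ct + a
  corr <- a == 0 | b == 0 | cc == 0 | d == 0
  a2 <- a + 0.5 * corr; b2 <- b + 0.5 * corr
  c2 <- cc + 0.5 * corr; d2 <- d + 0.5 * corr
  ror_est <- (a2 * d2) / (b2 * c2)
  ror_se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  prr_est <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  prr_se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
  if (is.null(prior)) prior <- fit_gps_prior(pe)
  bm <- bayes_metrics(a, pe$e, prior = prior, quantiles = quantiles)
  out <- data.frame(
    drug = pe$drug, event = pe$event,
    a = a, b = b, c = cc, d = d, e = pe$e,
    ror = ror_est,
    ror_lo = exp(log(ror_est) - 1.96 * ror_se),
    ror_hi = exp(log(ror_est) + 1.96 * ror_se),
    prr = prr_est,
    prr_lo = exp(log(prr_est) - 1.96 * prr_se),
    prr_hi = exp(log(prr_est) + 1.96 * prr_se),
    correction_applied = corr,
    stringsAsFactors = FALSE)
  out <- cbind(out, bm)
  ror_val <- if (criteria$ror_rule == "ci_lower") out$ror_lo else out$ror
  out$pass_ror <- ror_val > criteria$ror_threshold & a >= criteria$min_n_ror
  out$pass_prr <- out$prr > criteria$prr_threshold & a >= criteria$min_n_prr
  out$pass_ebgm <- out$ebgm >= criteria$ebgm_threshold & a >= criteria$min_n_bayes
  out$pass_ic <- out$ic > criteria$ic_threshold & a >= criteria$min_n_bayes
  out$is_signal <- out$pass_ror & out$pass_prr & out$pass_ebgm & out$pass_ic
  structure(out, prior = prior, criteria = criteria,
            class = c("signal_scan", "data.frame"))
}

#' @export
print.signal_scan <- function(x, ...) {
  cat(sprintf("Disproportionality scan: %d drug-event pairs, %d signals\n",
              nrow(x), sum(x$is_signal)))
  invisible(x)
}

#' @export
summary.signal_scan <- function(object, top = 10, ...) {
  sig <- object[object$is_signal, , drop = FALSE]
  sig <- sig[order(-sig$ebgm), , drop = FALSE]
  cat(sprintf("%d of %d pairs meet all four criteria\n",
              nrow(sig), nrow(object)))
  cols <- c("drug", "event", "a", "e", "ror", "prr", "ebgm", "ic")
  print(utils::head(as.data.frame(sig)[cols], top), digits = 3)
  invisible(sig)
}

#' @export
plot.signal_scan <- function(x, ...) {
  n <- pmax(x$a, 0.5)
  plot(n, pmax(x$ebgm, 1e-3), log = "xy",
       xlab = "reports (n)", ylab = "EBGM",
       col = ifelse(x$is_signal, "red3", "grey50"),
       pch = ifelse(x$is_signal, 19, 1), ...)
  abline(h = attr(x, "criteria")$ebgm_threshold, lty = 2)
  legend("topleft", legend = c("signal", "no signal"),
         col = c("red3", "grey50"), pch = c(19, 1), bty = "n")
  invisible(x)
}
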