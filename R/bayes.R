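# Bayesian disproportionality: DuMouchel's two-component gamma-Poisson
# shrinker (EBGM with EB05/EB95) and the information component (IC) in its
# closed form with gamma credibility bounds.

#' Expected pair counts under row/column independence
#'
#' For a drug-by-event count grid, the expected count of pair (i, j) is
#' `row_i total * col_j total / grand total`. With stratification, the
#' expectation is computed within each stratum and summed over strata
#' (Mantel-Haenszel-type expectations).
#'
#' @param pairs data.frame with columns `drug`, `event`, `n`, and optionally
#'   the stratification columns named in `strata`.
#' @param strata character vector of column names to stratify by (default
#'   none).
#' @return `pairs` with an added column `e`; within each stratum the `e`
#'   values sum to that stratum's total count.
#' @export
expected_counts <- function(pairs, strata = character(0)) {
  stopifnot(is.data.frame(pairs),
            all(c("drug", "event", "n") %in% names(pairs)))
  if (sum(pairs$n) == 0) stop("zero grand total: expectations undefined")
  one <- function(p) {
    N <- sum(p$n)
    rd <- tapply(p$n, p$drug, sum)
    re <- tapply(p$n, p$event, sum)
    p$e <- as.numeric(rd[p$drug]) * as.numeric(re[p$event]) / N
    p
  }
  if (!length(strata)) return(one(pairs))
  stopifnot(all(strata %in% names(pairs)))
  skey <- do.call(paste, c(pairs[strata], sep = "\x01"))
  parts <- lapply(split(pairs, skey), one)
  strat <- do.call(rbind, parts)
  # sum stratum-wise expectations back to the (drug, event) level
  agg_e <- tapply(strat$e, paste(strat$drug, strat$event, sep = "\x01"), sum)
  agg_n <- tapply(strat$n, paste(strat$drug, strat$event, sep = "\x01"), sum)
  de <- strsplit(names(agg_e), "\x01", fixed = TRUE)
  out <- data.frame(drug = vapply(de, `[`, character(1), 1),
                    event = vapply(de, `[`, character(1), 2),
                    n = as.numeric(agg_n), e = as.numeric(agg_e),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' DuMouchel gamma-mixture prior
#'
#' Container for the five hyperparameters of the two-component gamma prior
#' on the report-rate ratio lambda: lambda ~ p Gamma(alpha1, beta1) +
#' (1-p) Gamma(alpha2, beta2), shape/rate parameterisation.
#'
#' @param alpha1,beta1,alpha2,beta2 positive shape/rate parameters.
#' @param p mixture weight in (0, 1).
#' @param loglik fitted marginal log-likelihood (NA before fitting).
#' @param converged logical.
#' @param n_pairs number of pairs the prior was fitted on.
#' @return object of class `gps_prior`.
#' @export
gps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                      p = 1 / 3, loglik = NA_real_, converged = NA,
                      n_pairs = NA_integer_) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, p > 0, p < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, p = p, loglik = loglik,
                 converged = converged, n_pairs = n_pairs),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat("Gamma-Poisson mixture prior (DuMouchel shrinker)\n")
  cat(sprintf("  component 1: Gamma(shape %.4g, rate %.4g), mean %.3g\n",
              x$alpha1, x$beta1, x$alpha1 / x$beta1))
  cat(sprintf("  component 2: Gamma(shape %.4g, rate %.4g), mean %.3g\n",
              x$alpha2, x$beta2, x$alpha2 / x$beta2))
  cat(sprintf("  mixture weight p = %.4g\n", x$p))
  if (!is.na(x$loglik)) {
    cat(sprintf("  marginal log-likelihood %.2f over %d pairs (%s)\n",
                x$loglik, x$n_pairs,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
coef.gps_prior <- function(object, ...) {
  c(alpha1 = object$alpha1, beta1 = object$beta1,
    alpha2 = object$alpha2, beta2 = object$beta2, p = object$p)
}

#' @export
logLik.gps_prior <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n_pairs, class = "logLik")
}

#' Fit the gamma-mixture hyperparameters by marginal maximum likelihood
#'
#' Maximizes the summed log marginal likelihood of the observed pair counts
#' (mixture of two negative binomials induced by the gamma priors) over the
#' five hyperparameters, by expectation-maximization: the E-step computes
#' each pair's posterior component membership, the M-step refits each
#' component's (shape, rate) by weighted negative-binomial likelihood on
#' the log scale and sets the mixture weight to the mean membership. The
#' observed-data log-likelihood is non-decreasing across accepted EM steps
#' and the procedure is fully deterministic (no random restarts). A mixture
#' weight at the (0, 1) boundary in `init` is clipped inwards.
#'
#' @param pairs data.frame with columns `n` and `e` (see
#'   [expected_counts()]); pairs with `e <= 0` are dropped.
#' @param init a [gps_prior()] used as starting point (DuMouchel's published
#'   defaults by default).
#' @param tol convergence tolerance: maximum absolute change of the
#'   hyperparameter vector (log scale for shapes/rates, logit for the
#'   weight) between successive EM iterations.
#' @param max_iter EM iteration cap.
#' @return a fitted `gps_prior`; `converged = FALSE` (with a warning, never
#'   silently) when the tolerance was not met within the cap.
#' @export
fit_gps_prior <- function(pairs, init = gps_prior(), tol = 1e-6,
                          max_iter = 500) {
  stopifnot(is.data.frame(pairs), all(c("n", "e") %in% names(pairs)))
  keep <- !is.na(pairs$n) & !is.na(pairs$e) & pairs$e > 0
  n <- as.numeric(pairs$n[keep])
  e <- as.numeric(pairs$e[keep])
  m <- length(n)
  if (sum(n > 0) < 2) stop("need at least 2 pairs with positive counts")
  # shapes/rates restricted to a wide but numerically safe range; a gamma
  # with shape exp(12) is already indistinguishable from a point mass
  clamp <- function(x) min(max(x, -12), 12)
  comp_ll <- function(lpar, w) {
    a <- exp(clamp(lpar[1]))
    b <- exp(clamp(lpar[2]))
    ll <- dnbinom(n, size = a, prob = b / (b + e), log = TRUE)
    ll[!is.finite(ll)] <- -1e10
    -sum(w * ll)
  }
  a1 <- init$alpha1; b1 <- init$beta1
  a2 <- init$alpha2; b2 <- init$beta2
  p <- min(max(init$p, 1e-8), 1 - 1e-8)
  par_vec <- function() c(log(a1), log(b1), log(a2), log(b2), qlogis(p))
  obs_ll <- function() {
    l1 <- log(p) + dnbinom(n, size = a1, prob = b1 / (b1 + e), log = TRUE)
    l2 <- log1p(-p) + dnbinom(n, size = a2, prob = b2 / (b2 + e), log = TRUE)
    mx <- pmax(l1, l2)
    list(ll = sum(mx + log(exp(l1 - mx) + exp(l2 - mx))),
         q1 = 1 / (1 + exp(l2 - l1)))
  }
  prev <- par_vec()
  converged <- FALSE
  cur <- obs_ll()
  for (iter in seq_len(max_iter)) {
    q1 <- cur$q1
    o1 <- optim(c(log(a1), log(b1)), comp_ll, w = q1,
                method = "Nelder-Mead", control = list(maxit = 200))
    o2 <- optim(c(log(a2), log(b2)), comp_ll, w = 1 - q1,
                method = "Nelder-Mead", control = list(maxit = 200))
    a1 <- exp(clamp(o1$par[1])); b1 <- exp(clamp(o1$par[2]))
    a2 <- exp(clamp(o2$par[1])); b2 <- exp(clamp(o2$par[2]))
    p <- min(max(mean(q1), 1e-8), 1 - 1e-8)
    cur <- obs_ll()
    now <- par_vec()
    delta <- max(abs(now - prev))
    prev <- now
    if (is.finite(delta) && delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("gamma-mixture EM did not meet tol = %g within %d iterations",
                    tol, max_iter))
  }
  gps_prior(alpha1 = a1, beta1 = b1, alpha2 = a2, beta2 = b2, p = p,
            loglik = cur$ll, converged = converged, n_pairs = m)
}

# Posterior mixture for one (n, e): updated weights Q and components
# Gamma(alpha_k + n, beta_k + e). Vectorized over n, e.
.gps_posterior <- function(n, e, prior) {
  l1 <- log(prior$p) +
    dnbinom(n, size = prior$alpha1,
            prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  l2 <- log1p(-prior$p) +
    dnbinom(n, size = prior$alpha2,
            prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  d <- l2 - l1
  # both marginals can underflow to -Inf for an extreme (n, e) under a
  # near-degenerate fitted prior; fall back to the prior weight there
  d[is.na(d)] <- log((1 - prior$p) / prior$p)
  q1 <- 1 / (1 + exp(d))
  list(q1 = q1,
       a1 = prior$alpha1 + n, b1 = prior$beta1 + e,
       a2 = prior$alpha2 + n, b2 = prior$beta2 + e)
}

# Quantile of the posterior 2-component gamma mixture, per element.
.gps_quantile <- function(post, probs, tol = 1e-8) {
  vapply(seq_along(post$q1), function(i) {
    q1 <- post$q1[i]
    cdf <- function(x) q1 * pgamma(x, post$a1[i], rate = post$b1[i]) +
      (1 - q1) * pgamma(x, post$a2[i], rate = post$b2[i])
    vapply(probs, function(pr) {
      q1c <- qgamma(pr, post$a1[i], rate = post$b1[i])
      q2c <- qgamma(pr, post$a2[i], rate = post$b2[i])
      lo <- min(q1c, q2c); hi <- max(q1c, q2c)
      if (hi - lo < tol) return((lo + hi) / 2)
      # widen slightly: qgamma/pgamma roundoff under very concentrated
      # components can leave cdf(lo) marginally above pr
      lo <- lo * 0.999
      hi <- hi * 1.001
      uniroot(function(x) cdf(x) - pr, lower = lo, upper = hi,
              extendInt = "upX", tol = tol)$root
    }, numeric(1))
  }, numeric(length(probs)))
}

#' Empirical Bayes geometric mean and posterior limits
#'
#' Given a fitted prior, the posterior of the rate ratio lambda for a pair
#' with observed count `n` and expectation `e` is the two-component gamma
#' mixture with components `Gamma(alpha_k + n, beta_k + e)` and updated
#' weights. `EBGM = 2^(E[log2 lambda | n, e])` (the posterior geometric
#' mean); `eb05`/`eb95` are the posterior 5th and 95th percentiles, solved
#' numerically.
#'
#' @param n observed count(s).
#' @param e expected count(s) under independence (> 0).
#' @param prior a `gps_prior`.
#' @param quantiles compute `eb05`/`eb95` (slower; numerical root-finding)?
#' @return data.frame with columns `ebgm` and, if requested, `eb05`,
#'   `eb95`.
#' @export
#' @examples
#' ebgm(5, 1, gps_prior())
ebgm <- function(n, e, prior = gps_prior(), quantiles = TRUE) {
  stopifnot(inherits(prior, "gps_prior"), all(e > 0))
  k <- max(length(n), length(e))
  n <- rep_len(as.numeric(n), k)
  e <- rep_len(as.numeric(e), k)
  post <- .gps_posterior(n, e, prior)
  elog <- post$q1 * (digamma(post$a1) - log(post$b1)) +
    (1 - post$q1) * (digamma(post$a2) - log(post$b2))
  out <- data.frame(ebgm = exp(elog))
  if (quantiles) {
    qs <- .gps_quantile(post, c(0.05, 0.95))
    if (is.null(dim(qs))) qs <- matrix(qs, nrow = 2)
    out$eb05 <- qs[1, ]
    out$eb95 <- qs[2, ]
  }
  out
}

#' Information component with 95% credibility bounds
#'
#' The shrunk observed-to-expected log ratio
#' `IC = log2((n + 0.5) / (e + 0.5))`; `IC025`/`IC975` are `log2` of the
#' 2.5th and 97.5th percentiles of `Gamma(shape = n + 0.5,
#' rate = e + 0.5)`.
#'
#' @param n observed count(s).
#' @param e expected count(s) (> 0).
#' @return data.frame with columns `ic`, `ic025`, `ic975`.
#' @export
#' @examples
#' ic(10, 1.0891)
ic <- function(n, e) {
  stopifnot(all(e > 0))
  k <- max(length(n), length(e))
  n <- rep_len(as.numeric(n), k)
  e <- rep_len(as.numeric(e), k)
  data.frame(
    ic = log2((n + 0.5) / (e + 0.5)),
    ic025 = log2(qgamma(0.025, shape = n + 0.5, rate = e + 0.5)),
    ic975 = log2(qgamma(0.975, shape = n + 0.5, rate = e + 0.5)))
}

#' All Bayesian indices for a set of pairs
#'
#' @param n,e observed and expected counts.
#' @param prior a `gps_prior`.
#' @param quantiles compute EB05/EB95?
#' @return data.frame with `ebgm` (, `eb05`, `eb95`), `ic`, `ic025`,
#'   `ic975`.
#' @export
bayes_metrics <- function(n, e, prior = gps_prior(), quantiles = TRUE) {
  cbind(ebgm(n, e, prior, quantiles = quantiles), ic(n, e))
}

#' Predicted shrinkage estimates from a fitted prior
#'
#' @param object a `gps_prior`.
#' @param n,e observed and expected counts for new pairs.
#' @param quantiles compute EB05/EB95?
#' @param ... unused.
#' @return as [bayes_metrics()].
#' @export
predict.gps_prior <- function(object, n, e, quantiles = FALSE, ...) {
  bayes_metrics(n, e, prior = object, quantiles = quantiles)
}

#' Serialize / read a fitted prior as a flat key-value text file
#'
#' @param prior a `gps_prior`.
#' @param path file path.
#' @return `write_gps_prior()` returns the path invisibly;
#'   `read_gps_prior()` returns a `gps_prior`.
#' @export
write_gps_prior <- function(prior, path) {
  stopifnot(inherits(prior, "gps_prior"))
  v <- c(alpha1 = prior$alpha1, beta1 = prior$beta1, alpha2 = prior$alpha2,
         beta2 = prior$beta2, p = prior$p, loglik = prior$loglik,
         converged = as.numeric(isTRUE(prior$converged)),
         n_pairs = as.numeric(prior$n_pairs))
  writeLines(sprintf("%s\t%.17g", names(v), v), path)
  invisible(path)
}

#' @rdname write_gps_prior
#' @export
read_gps_prior <- function(path) {
  kv <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("key", "value"),
                          stringsAsFactors = FALSE)
  v <- setNames(kv$value, kv$key)
  gps_prior(alpha1 = v[["alpha1"]], beta1 = v[["beta1"]],
            alpha2 = v[["alpha2"]], beta2 = v[["beta2"]], p = v[["p"]],
            loglik = v[["loglik"]], converged = v[["converged"]] == 1,
            n_pairs = as.integer(v[["n_pairs"]]))
}
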