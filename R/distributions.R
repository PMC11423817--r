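# Gaussian-mixture decomposition of velocity distributions with AIC model
# selection, and pairwise two-sample Kolmogorov-Smirnov comparisons.
#
# The 1-D mixture is fitted by EM with multiple restarts: means initialized
# at spread quantiles plus jitter, a pooled variance, and near-uniform
# weights. Component variances are clamped at a floor so single points
# cannot collapse a component. The AIC uses 3K - 1 free parameters
# (K means, K sds, K - 1 weights).

#' Fit a one-dimensional Gaussian mixture by EM
#'
#' @param values numeric sample (e.g. segment velocities in um/s); must be
#'   finite, with `length(values) >= 3 * K`.
#' @param K number of components (>= 1).
#' @param seed RNG seed controlling the restart initializations; a fixed
#'   seed gives a bit-identical fit.
#' @param restarts number of random initializations (best final
#'   log-likelihood wins).
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum EM iterations per restart.
#' @param var_floor lower clamp on component variances, in (um/s)^2.
#' @return An object of class `"gmm_fit"`: a list with `K`, `weights`
#'   (sum 1), `means`, `sds`, `log_likelihood`, `aic`
#'   (`2 * (3K - 1) - 2 * logL`), `n`, `converged`, `seed` and the
#'   per-iteration `logL_trace` of the winning restart (non-decreasing).
#' @examples
#' v <- c(rnorm(200, 0.5, 0.2), rnorm(200, 2.5, 0.2))
#' fit_gmm(v, K = 2, seed = 1)
#' @export
fit_gmm <- function(values, K, seed = 1L, restarts = 10L, tol = 1e-6,
                    max_iter = 500L, var_floor = 1e-4) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_config("'values' must be finite numeric")
  K <- as.integer(K)
  n <- length(values)
  if (K < 1L) stop_config("'K' must be >= 1")
  if (n < 3L * K)
    stop_config("insufficient data: n = %d < 3K = %d", n, 3L * K)

  if (K == 1L) {
    # closed-form MLE
    mu <- mean(values)
    v <- mean((values - mu)^2)
    v <- max(v, var_floor)
    logL <- sum(stats::dnorm(values, mu, sqrt(v), log = TRUE))
    return(new_gmm_fit(1L, 1, mu, sqrt(v), logL, n, TRUE, seed, logL))
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- gmm_init(values, K)
      fit <- gmm_em(values, K, init, tol, max_iter, var_floor)
      if (is.null(best) || fit$logL > best$logL) best <- fit
    }
    ord <- order(best$mu)
    new_gmm_fit(K, best$w[ord], best$mu[ord], sqrt(best$v[ord]),
                best$logL, n, best$converged, seed, best$trace)
  })
}

new_gmm_fit <- function(K, w, mu, sd, logL, n, converged, seed, trace) {
  structure(list(K = K, weights = as.numeric(w / sum(w)),
                 means = as.numeric(mu), sds = as.numeric(sd),
                 log_likelihood = logL,
                 aic = 2 * (3 * K - 1) - 2 * logL,
                 n = n, converged = converged, seed = seed,
                 logL_trace = as.numeric(trace)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture, K = %d (n = %d, logL = %.3f, AIC = %.3f%s)\n",
              x$K, x$n, x$log_likelihood, x$aic,
              if (x$converged) "" else ", NOT converged"))
  for (k in seq_len(x$K))
    cat(sprintf("  comp %d: weight %.3f, mean %.3f, sd %.3f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  invisible(x)
}

gmm_init <- function(x, K) {
  qs <- stats::quantile(x, probs = (2 * seq_len(K) - 1) / (2 * K),
                        names = FALSE, type = 7)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1e-3
  list(mu = qs + stats::rnorm(K, 0, 0.1 * s),
       v = rep(s^2, K),
       w = {
         w <- rep(1 / K, K) * exp(stats::runif(K, -0.05, 0.05))
         w / sum(w)
       })
}

gmm_em <- function(x, K, init, tol, max_iter, var_floor) {
  n <- length(x)
  mu <- init$mu; v <- pmax(init$v, var_floor); w <- init$w
  trace <- numeric(0)
  logL_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step in log space for numerical stability
    lp <- vapply(seq_len(K), function(k)
      log(w[k]) + stats::dnorm(x, mu[k], sqrt(v[k]), log = TRUE),
      numeric(n))
    m <- apply(lp, 1L, max)
    lse <- m + log(rowSums(exp(lp - m)))
    logL <- sum(lse)
    trace <- c(trace, logL)
    if (is.finite(logL_old) &&
        abs(logL - logL_old) <= tol * (abs(logL_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    logL_old <- logL
    resp <- exp(lp - lse)                       # n x K responsibilities
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
  }
  list(mu = mu, v = v, w = w, logL = logL, converged = converged,
       trace = trace)
}

#' Select the mixture order by AIC
#'
#' Fits mixtures with `K = 1, ..., K_max` components (skipping K with fewer
#' than `3K` observations) and returns the fit minimizing the AIC; ties
#' break toward the smaller K.
#'
#' @inheritParams fit_gmm
#' @param K_max largest component count to try (default 6).
#' @param ... passed on to [fit_gmm()] (`restarts`, `tol`, `max_iter`,
#'   `var_floor`).
#' @return A list with `best` (the selected [fit_gmm()] object) and `fits`
#'   (all attempted fits, named by K).
#' @export
select_gmm <- function(values, K_max = 6L, seed = 1L, ...) {
  K_max <- as.integer(K_max)
  if (K_max < 1L) stop_config("'K_max' must be >= 1")
  ks <- seq_len(K_max)
  ks <- ks[3L * ks <= length(values)]
  if (!length(ks))
    stop_config("insufficient data: n = %d supports no K <= %d",
                length(values), K_max)
  fits <- lapply(ks, function(k) fit_gmm(values, k, seed = seed + k, ...))
  names(fits) <- ks
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  list(best = fits[[which.min(aics)]], fits = fits)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning the sup-distance D
#' between the two empirical CDFs and the p-value. The asymptotic
#' Kolmogorov p-value is used by default (matching large-sample practice);
#' set `exact = TRUE` for the exact small-sample method.
#'
#' @param a,b numeric samples, each with at least one observation.
#' @param exact logical passed to [stats::ks.test()] (default `FALSE`,
#'   asymptotic).
#' @return A list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b)) stop_config("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Pairwise KS comparison of conditions
#'
#' Runs the two-sample KS test on every unordered pair of conditions and
#' adjusts the p-values for multiplicity.
#'
#' @param samples named list of numeric samples, one per condition (at
#'   least two).
#' @param direction optional label (`"anterograde"` / `"retrograde"`) copied
#'   into the result for bookkeeping.
#' @param adjust multiplicity adjustment: `"holm"` (default),
#'   `"bonferroni"` or `"none"`.
#' @param exact passed to [ks_two_sample()].
#' @return A data.frame sorted by (`condition_a`, `condition_b`) with
#'   columns `condition_a`, `condition_b`, `direction`, `D`, `p_raw`,
#'   `p_adjusted`, `n_a`, `n_b`.
#' @export
pairwise_compare <- function(samples, direction = NA_character_,
                             adjust = c("holm", "bonferroni", "none"),
                             exact = FALSE) {
  adjust <- match.arg(adjust)
  if (!is.list(samples) || is.null(names(samples)) || length(samples) < 2L)
    stop_config("'samples' must be a named list with >= 2 conditions")
  conds <- sort(names(samples))
  pairs <- utils::combn(conds, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ks <- ks_two_sample(samples[[a]], samples[[b]], exact = exact)
    data.frame(condition_a = a, condition_b = b, direction = direction,
               D = ks$D, p_raw = ks$p,
               n_a = length(samples[[a]]), n_b = length(samples[[b]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out <- out[, c("condition_a", "condition_b", "direction", "D",
                 "p_raw", "p_adjusted", "n_a", "n_b")]
  rownames(out) <- NULL
  out
}

#' Tabulate a Gaussian-mixture fit
#'
#' Flattens one or more [fit_gmm()] objects into a long data.frame (one row
#' per component) for CSV export.
#'
#' @param fits a named list of `gmm_fit` objects (names like
#'   `"condition|direction"`), or a single fit.
#' @return A data.frame with columns `name`, `K`, `component`, `weight`,
#'   `mean`, `sd`, `aic`, `log_likelihood`, `n`, `converged`.
#' @export
gmm_table <- function(fits) {
  if (inherits(fits, "gmm_fit")) fits <- list(fit = fits)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(name = nm, K = f$K, component = seq_len(f$K),
               weight = f$weights, mean = f$means, sd = f$sds,
               aic = f$aic, log_likelihood = f$log_likelihood,
               n = f$n, converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
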