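#' Likelihood-ratio statistic between two fits of the same data
#'
#' \code{2 * (lnL_alt - lnL_null)}. The two fits must have been computed on
#' identical data (checked by fingerprint); the statistic may be negative for
#' non-nested misfits and is reported as-is.
#'
#' @param fit_alt,fit_null \code{evo_fit} or \code{averaged_fit} objects.
#' @return the likelihood ratio statistic.
#' @export
lr_statistic <- function(fit_alt, fit_null) {
  fa <- fit_alt$data_fingerprint; fn <- fit_null$data_fingerprint
  if (!is.null(fa) && !is.null(fn) && !identical(fa, fn))
    stop("fits were not computed on the same data")
  2 * (fit_lnL(fit_alt) - fit_lnL(fit_null))
}

#' Phylogenetic Monte Carlo model-adequacy test
#'
#' Parametric bootstrap of the likelihood-ratio statistic comparing a best-fit
#' model against a null model (canonically single-rate Brownian motion). Data
#' are simulated under each fitted model in turn; to every simulated dataset
#' both models are refit and the likelihood ratio recorded, yielding two
#' bootstrap LR distributions and their percentile 95\% confidence intervals.
#' The observed LR is then located relative to both intervals: falling inside
#' the null interval means the data are indistinguishable from the null;
#' inside the best-fit interval, consistent with that model; outside both,
#' neither model adequately explains the data (commonly a sign the tree has
#' too few taxa for the comparison).
#'
#' @param tree a dated tree.
#' @param x named numeric tip data.
#' @param null_spec,alt_spec lists with \code{kind} and optional
#'   \code{painting} describing the two models.
#' @param n_iter bootstrap iterations per model (study protocol: 10,000;
#'   must be >= 100).
#' @param seed integer seed.
#' @param level confidence level of the percentile intervals.
#' @param control refit control; defaults to 3 optimiser restarts for speed.
#' @return an object of class \code{pmc_test}: \code{lr_obs}, \code{ci_null},
#'   \code{ci_alt}, \code{lr_null} and \code{lr_alt} vectors, dropped-iteration
#'   counts and the \code{verdict}.
#' @export
pmc_test <- function(tree, x, null_spec, alt_spec, n_iter = 200L, seed = NULL,
                     level = 0.95, control = evo_control(restarts = 3L)) {
  if (n_iter < 100L) stop("n_iter must be >= 100")
  cache_null <- tree_cache(tree, null_spec$painting)
  cache_alt <- tree_cache(tree, alt_spec$painting)
  fit_null <- fit_evo(tree, x, null_spec$kind, null_spec$painting,
                      control = control, cache = cache_null)
  fit_alt <- fit_evo(tree, x, alt_spec$kind, alt_spec$painting,
                     control = control, cache = cache_alt)
  lr_obs <- lr_statistic(fit_alt, fit_null)
  mom_null <- evo_moments(tree, null_spec$kind, fit_null$params, cache = cache_null)
  mom_alt <- evo_moments(tree, alt_spec$kind, fit_alt$params, cache = cache_alt)
  R_null <- chol(mom_null$cov); R_alt <- chol(mom_alt$cov)
  n <- length(x)
  lr_from <- function(R, mu) {
    z <- stats::rnorm(n)
    xs <- stats::setNames(as.vector(mu + crossprod(R, z)), names(mu))
    f0 <- fit_evo(tree, xs, null_spec$kind, control = control, cache = cache_null)
    f1 <- fit_evo(tree, xs, alt_spec$kind, control = control, cache = cache_alt)
    if (!f0$converged || !f1$converged) return(NA_real_)
    2 * (f1$lnL - f0$lnL)
  }
  res <- with_seed(seed, {
    lr_null <- vapply(seq_len(n_iter), function(i) lr_from(R_null, mom_null$mean), 0)
    lr_alt <- vapply(seq_len(n_iter), function(i) lr_from(R_alt, mom_alt$mean), 0)
    list(lr_null = lr_null, lr_alt = lr_alt)
  })
  dropped <- sum(is.na(res$lr_null)) + sum(is.na(res$lr_alt))
  if (dropped > 0.05 * 2 * n_iter)
    stop(sprintf("%d of %d refits failed to converge", dropped, 2L * n_iter))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci_null <- stats::quantile(res$lr_null, pr, na.rm = TRUE, names = FALSE)
  ci_alt <- stats::quantile(res$lr_alt, pr, na.rm = TRUE, names = FALSE)
  inside <- function(v, ci) v >= ci[1L] && v <= ci[2L]
  verdict <- if (inside(lr_obs, ci_null)) "consistent-with-null"
             else if (inside(lr_obs, ci_alt)) "consistent-with-best"
             else "outside-both"
  structure(list(lr_obs = lr_obs, ci_null = ci_null, ci_alt = ci_alt,
                 lr_null = res$lr_null, lr_alt = res$lr_alt,
                 n_iter = n_iter, dropped = dropped, level = level,
                 verdict = verdict,
                 fit_null = fit_null, fit_alt = fit_alt),
            class = "pmc_test")
}

#' @export
print.pmc_test <- function(x, ...) {
  cat(sprintf("Phylogenetic Monte Carlo adequacy test (%d iterations)\n", x$n_iter))
  cat(sprintf("observed LR = %.3f\n", x$lr_obs))
  cat(sprintf("%.0f%% CI under null:     (%.3f, %.3f)\n",
              100 * x$level, x$ci_null[1L], x$ci_null[2L]))
  cat(sprintf("%.0f%% CI under best fit: (%.3f, %.3f)\n",
              100 * x$level, x$ci_alt[1L], x$ci_alt[2L]))
  if (x$dropped > 0) cat(x$dropped, "refits dropped (non-convergence)\n")
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}
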