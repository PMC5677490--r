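#' Small-sample Akaike information criterion
#'
#' \code{AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)}. Requires \code{n > k + 1}.
#'
#' @param lnL log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (number of tips with data).
#' @return the AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (any(n <= k + 1)) stop("AICc undefined: need n > k + 1")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Delta-AICc, relative likelihoods and Akaike weights
#'
#' @param aicc_values numeric vector of AICc scores.
#' @return list with \code{delta} (\code{AICc - min}), \code{rel_lik}
#'   (\code{exp(-delta/2)}), and \code{weight} (normalised relative
#'   likelihoods, summing to 1).
#' @export
delta_and_weights <- function(aicc_values) {
  if (length(aicc_values) < 1L) stop("need at least one AICc value")
  delta <- aicc_values - min(aicc_values)
  rel <- exp(-delta / 2)
  list(delta = delta, rel_lik = rel, weight = rel / sum(rel))
}

#' Assemble a model-comparison table
#'
#' Builds the AICc comparison of a set of fitted models sharing the same data:
#' log-likelihood, relative likelihood, AICc, delta-AICc and Akaike weight per
#' model, preserving input order, with the phylogenetic half-life attached for
#' OU fits. The best model is the minimum-AICc row; ties break toward fewer
#' parameters.
#'
#' @param fits list of \code{evo_fit} and/or \code{averaged_fit} objects.
#' @param labels optional character vector of row labels.
#' @return a data.frame of class \code{comparison_table} with attribute
#'   \code{best} (the best row index) and column \code{best} flagging it.
#' @export
build_comparison_table <- function(fits, labels = NULL) {
  if (is.null(labels)) labels <- vapply(fits, function(f) f$kind, "")
  lnL <- vapply(fits, fit_lnL, 0)
  k <- vapply(fits, function(f) as.numeric(f$k), 0)
  n <- vapply(fits, function(f) as.numeric(f$n), 0)
  if (length(unique(n)) != 1L) stop("fits have differing sample sizes n")
  ic <- aicc(lnL, k, n)
  dw <- delta_and_weights(ic)
  hl <- vapply(fits, function(f) {
    a <- fit_alpha(f)
    if (is.null(a) || is.na(a) || a <= 0) NA_real_ else half_life(a)
  }, 0)
  best <- which(dw$delta == 0)
  if (length(best) > 1L) best <- best[which.min(k[best])]
  out <- data.frame(model = labels, lnL = lnL, rel_lik = dw$rel_lik,
                    AICc = ic, delta = dw$delta, weight = dw$weight,
                    k = k, half_life = hl,
                    best = seq_along(fits) == best)
  attr(out, "n") <- n[1L]
  attr(out, "best") <- best
  class(out) <- c("comparison_table", "data.frame")
  out
}

fit_lnL <- function(f) if (inherits(f, "averaged_fit")) f$mean_lnL else f$lnL

fit_alpha <- function(f) {
  if (inherits(f, "averaged_fit")) {
    a <- f$mean_params["alpha"]
    if (is.na(a)) NULL else unname(a)
  } else f$params$alpha
}

#' @export
print.comparison_table <- function(x, ...) {
  # presentation rounding mirrors the conventional reporting: AICc and delta
  # to 1 d.p., relative likelihood to 4 d.p., weight as percent to 1 d.p.
  df <- data.frame(model = x$model,
                   L = sprintf("%.1f", x$lnL),
                   Rel.L = sprintf("%.4f", x$rel_lik),
                   AICc = sprintf("%.1f", x$AICc),
                   dAICc = sprintf("%.1f", x$delta),
                   weight_pct = sprintf("%.1f", 100 * x$weight),
                   half_life = ifelse(is.na(x$half_life), "",
                                      sprintf("%.2f", x$half_life)))
  df$model[x$best] <- paste0("* ", df$model[x$best])
  print(df, row.names = FALSE)
  cat("n =", attr(x, "n"), "; * = best model (min AICc)\n")
  invisible(x)
}
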