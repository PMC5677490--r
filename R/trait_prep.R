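#' The fourteen forelimb measurements
#'
#' Names of the linear skeletal dimensions used throughout: lengths of the
#' scapula, humerus, radius, ulna and metacarpal III; anteroposterior (AP)
#' and mediolateral (ML) midshaft diameters of the humerus, radius and ulna;
#' the deltoid ridge length and epicondylar breadth of the humerus; and the
#' olecranon process length of the ulna. All in mm.
#'
#' @return character vector of length 14.
#' @export
forelimb_traits <- function() c(
  "scapula_length",
  "humerus_length", "humerus_ap_diameter", "humerus_ml_diameter",
  "humerus_deltoid_ridge_length", "humerus_epicondylar_breadth",
  "radius_length", "radius_ap_diameter", "radius_ml_diameter",
  "ulna_length", "ulna_ap_diameter", "ulna_ml_diameter",
  "ulna_olecranon_length",
  "metacarpal3_length"
)

#' Recognised locomotor habits
#' @return character vector of the four habit labels.
#' @export
locomotor_habits <- function() c("generalized", "scansorial", "fossorial", "natatorial")

#' Per-species trait means from a specimen table
#'
#' @param specimens data.frame with columns \code{specimen}, \code{species},
#'   and one positive numeric column per trait (any trait set; the standard
#'   one is \code{\link{forelimb_traits}()}). Missing cells are an error.
#' @return a species x trait matrix of arithmetic means on the raw mm scale,
#'   rownames = species.
#' @export
species_means <- function(specimens) {
  need <- c("specimen", "species")
  if (!all(need %in% names(specimens))) stop("specimen table needs columns: specimen, species")
  traits <- setdiff(names(specimens), need)
  if (length(traits) == 0L) stop("no trait columns found")
  vals <- as.matrix(specimens[, traits, drop = FALSE])
  if (anyNA(vals)) stop("missing trait values are not allowed")
  if (any(vals <= 0)) stop("all trait values must be positive (mm)")
  sp <- as.character(specimens$species)
  out <- rowsum(vals, sp) / as.vector(table(sp)[sort(unique(sp))])
  out[order(rownames(out)), , drop = FALSE]
}

#' Geometric mean of positive values
#' @param values positive numeric vector (typically the 14 traits of one species).
#' @return \code{exp(mean(log(values)))}.
#' @export
geometric_mean <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) stop("values must be positive and finite")
  exp(mean(log(values)))
}

#' Size-correct a trait table by log-log regression on the geometric mean
#'
#' For every trait, the natural log of the per-species mean is regressed by
#' OLS (with intercept) on the natural log of the per-species geometric mean
#' of all traits; the residuals are the size-corrected trait values used for
#' ordination. Each residual column sums to zero by construction.
#'
#' @param trait_table species x trait matrix of positive means (mm), as from
#'   \code{\link{species_means}}.
#' @return an object of class \code{size_residuals}: list with
#'   \code{residuals} (species x trait matrix), \code{slope} and
#'   \code{intercept} (per trait), and \code{log_gm} (per species).
#' @export
size_residuals <- function(trait_table) {
  tt <- as.matrix(trait_table)
  if (nrow(tt) < 3L) stop("need at least 3 species")
  if (any(tt <= 0)) stop("trait means must be positive")
  gm <- apply(tt, 1L, geometric_mean)
  lg <- log(gm)
  if (diff(range(lg)) < 1e-12) stop("geometric mean is constant across species; size regression degenerate")
  lt <- log(tt)
  X <- cbind(1, lg)
  # one normal-equations solve for all traits at once
  beta <- solve(crossprod(X), crossprod(X, lt))
  res <- lt - X %*% beta
  structure(list(residuals = res,
                 slope = beta[2L, ], intercept = beta[1L, ], log_gm = lg),
            class = "size_residuals")
}

#' @export
print.size_residuals <- function(x, ...) {
  cat("Size-corrected log residuals:", nrow(x$residuals), "species x",
      ncol(x$residuals), "traits\n")
  cat("allometric slopes (log trait ~ log geometric mean):\n")
  print(round(x$slope, 3))
  invisible(x)
}

#' Principal components of size-corrected residuals
#'
#' Eigen-decomposition of the covariance matrix of the residual columns
#' (columns are already dimensionless log deviations on a common scale, so
#' no rescaling is applied by default). Loadings are unit-norm; each
#' component's sign is flipped so its largest-magnitude loading is positive,
#' making output deterministic across linear-algebra backends. Significant
#' axes are those whose variance proportion strictly exceeds the broken-stick
#' expectation.
#'
#' @param rm a \code{size_residuals} object, or a species x trait matrix of
#'   residuals.
#' @param scale \code{"covariance"} (default) or \code{"correlation"}.
#' @return an object of class \code{trait_pca}: loadings, scores,
#'   \code{proportions}, \code{broken_stick} expectations,
#'   \code{significant} component indices, \code{center}.
#' @export
trait_pca <- function(rm, scale = c("covariance", "correlation")) {
  scale <- match.arg(scale)
  R <- if (inherits(rm, "size_residuals")) rm$residuals else as.matrix(rm)
  if (nrow(R) < 3L) stop("need at least 3 species")
  ctr <- colMeans(R)
  Rc <- sweep(R, 2L, ctr)
  if (scale == "correlation") {
    sds <- apply(Rc, 2L, stats::sd)
    if (any(sds == 0)) stop("zero-variance trait under correlation scaling")
    Rc <- sweep(Rc, 2L, sds, "/")
  }
  S <- stats::cov(Rc)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tot <- sum(ev)
  props <- if (tot > 0) ev / tot else rep(NA_real_, length(ev))
  L <- eg$vectors
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- Rc %*% L
  bs <- broken_stick(ncol(R))
  zerovar <- which(ev < 1e-14 * max(ev, 1e-300))
  out <- structure(list(loadings = L, scores = scores, proportions = props,
                        eigenvalues = ev, broken_stick = bs,
                        center = ctr, zero_variance = zerovar),
                   class = "trait_pca")
  out$significant <- significant_pcs(out)
  out
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA:", nrow(x$scores), "species,", ncol(x$loadings), "components\n")
  k <- min(4L, length(x$proportions))
  tab <- rbind(`% variance` = 100 * x$proportions[1:k],
               `broken stick %` = 100 * x$broken_stick[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 1))
  cat("significant components:",
      if (length(x$significant)) paste(x$significant, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Broken-stick expected variance proportions
#'
#' The null expectation for the proportion of variance of the k-th of p
#' principal components when total variance is split at random:
#' \eqn{E_k = (1/p) \sum_{i=k}^{p} 1/i}. For p = 14 the first two
#' expectations are 23.2\% and 16.1\%.
#'
#' @param p number of components (>= 1).
#' @return numeric vector of p proportions summing to 1.
#' @export
broken_stick <- function(p) {
  if (length(p) != 1L || p < 1 || p != round(p)) stop("p must be a positive integer")
  p <- as.integer(p)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' Indices of components exceeding the broken-stick expectation
#'
#' A component is significant when its observed variance proportion strictly
#' exceeds the broken-stick expectation for its rank. Non-contiguous
#' exceedance sets are reported as-is with a warning.
#'
#' @param pr a \code{trait_pca} object.
#' @return integer vector of significant component indices (possibly empty).
#' @export
significant_pcs <- function(pr) {
  idx <- which(pr$proportions > pr$broken_stick)
  if (length(idx) > 1L && any(diff(idx) != 1L) ||
      (length(idx) >= 1L && idx[1L] != 1L))
    warning("significant components are not a leading contiguous block: ",
            paste(idx, collapse = ", "))
  idx
}
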