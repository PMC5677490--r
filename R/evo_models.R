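#' Trait-diversification models on a dated, regime-painted tree
#'
#' Six Gaussian models of continuous-trait evolution are supported, named by
#' the convention of the comparative-methods literature:
#' \describe{
#'   \item{BM1}{single-rate Brownian motion (parameters: \code{sigma2}, \code{root_value}).}
#'   \item{BMS}{multi-rate Brownian motion, one \code{sigma2} per painted regime.}
#'   \item{OU1}{single-optimum Ornstein-Uhlenbeck (\code{alpha}, \code{sigma2}, \code{theta}).}
#'   \item{OUM}{multi-optimum OU, one \code{theta} per painted regime; the
#'     root lineage starts at the root regime's optimum.}
#'   \item{EB}{early burst: BM whose rate decays as \code{exp(eb_rate * t)},
#'     \code{eb_rate <= 0}.}
#'   \item{WN}{white noise: tip values iid Normal(\code{wn_mean}, \code{wn_var}),
#'     no phylogenetic structure.}
#' }
#' All models are Gaussian, so each is fully described by its tip expectation
#' vector and tip covariance matrix; see \code{\link{evo_moments}}.
#'
#' @name evo_models
NULL

model_kinds <- function() c("BM1", "BMS", "OU1", "OUM", "EB", "WN")

# parameter count per the AICc accounting used throughout:
# BM1 k=2 (sigma2, root); OU1 k=3 (alpha, sigma2, theta); EB k=3; WN k=2;
# OUM k=2+m (alpha, sigma2, m thetas; root fixed at root-regime theta);
# BMS k=1+m (m sigma2, root).
evo_k <- function(kind, n_regimes = 1L) {
  switch(kind,
         BM1 = 2L, WN = 2L, OU1 = 3L, EB = 3L,
         OUM = 2L + as.integer(n_regimes),
         BMS = 1L + as.integer(n_regimes),
         stop("unknown model kind: ", kind))
}

# geometry reused across likelihood evaluations: shared times, pairwise
# distances, per-regime shared times and painted root-to-tip paths
tree_cache <- function(tree, painting = NULL) {
  Tsh <- shared_time_matrix(tree)
  ti <- diag(Tsh)
  D <- outer(ti, ti, "+") - 2 * Tsh
  out <- list(n = ape::Ntip(tree), Tsh = Tsh, D = D,
              tip_depth = ti, height = max(ti), tips = tree$tip.label,
              ultrametric = (max(ti) - min(ti)) <= 1e-6 * max(ti))
  if (!is.null(painting)) {
    out$regimes <- painting_regimes(painting)
    out$Creg <- painting_shared_times(tree, painting)
    out$paths <- painting_paths(tree, painting)
    out$root_regime <- painting$root_regime
  }
  out
}

# Hansen exponential weight matrix: W[i, r] = weight of regime r's optimum in
# the expectation of tip i. With root_anchor = TRUE the root lineage is
# anchored at the root regime's optimum and rows sum to 1; with FALSE the
# residual weight exp(-alpha T) is left out, for use with a separately
# estimated root state.
hansen_weights <- function(cache, alpha, root_anchor = TRUE) {
  regs <- cache$regimes
  n <- cache$n
  W <- matrix(0, n, length(regs), dimnames = list(cache$tips, regs))
  for (i in seq_len(n)) {
    p <- cache$paths[[i]]
    Ti <- cache$tip_depth[i]
    w <- exp(-alpha * (Ti - p$t1)) - exp(-alpha * (Ti - p$t0))
    for (j in seq_len(nrow(p))) W[i, p$regime[j]] <- W[i, p$regime[j]] + w[j]
    if (root_anchor)
      W[i, cache$root_regime] <- W[i, cache$root_regime] + exp(-alpha * Ti)
  }
  W
}

# model covariance divided by the overall sigma2 scale (or the full
# covariance where no common scale exists), plus the mean structure
evo_structure <- function(kind, cache, alpha = NULL, eb_rate = NULL,
                          rate_weights = NULL) {
  switch(kind,
    BM1 = cache$Tsh,
    EB = {
      r <- eb_rate
      if (abs(r) < 1e-12) cache$Tsh else (exp(r * cache$Tsh) - 1) / r
    },
    OU1 = ,
    OUM = {
      if (!isTRUE(cache$ultrametric))
        stop("OU covariances use the root-conditioned form for ultrametric ",
             "trees; this tree is not ultrametric")
      exp(-alpha * cache$D) * (1 - exp(-2 * alpha * cache$Tsh)) / (2 * alpha)
    },
    BMS = {
      V <- matrix(0, cache$n, cache$n)
      for (r in names(cache$Creg)) V <- V + rate_weights[r] * cache$Creg[[r]]
      V
    },
    stop("no covariance structure for kind ", kind))
}

#' Tip moments of a trait-diversification model
#'
#' Returns the exact expectation vector and covariance matrix of the tip
#' values under the given model and parameters. OU covariances use the
#' root-conditioned form for ultrametric trees,
#' \eqn{V_{ij} = \sigma^2/(2\alpha)\, e^{-\alpha d_{ij}} (1 - e^{-2\alpha t_{ij}})},
#' with \eqn{d_{ij}} the patristic distance and \eqn{t_{ij}} the shared time;
#' OU expectations weight the optima along each root-to-tip lineage by the
#' Hansen exponential weights, the root lineage starting at the root regime's
#' optimum.
#'
#' @param tree a dated ultrametric tree.
#' @param kind one of \code{"BM1","BMS","OU1","OUM","EB","WN"}.
#' @param params named list: \code{sigma2} (scalar, or named per regime for
#'   BMS), \code{alpha}, \code{theta} (scalar for OU1, named per regime for
#'   OUM), \code{root_value}, \code{eb_rate}, \code{wn_mean}, \code{wn_var}
#'   as the kind requires.
#' @param painting a \code{regime_painting}; required for BMS and OUM.
#' @param cache optional precomputed \code{tree_cache} (internal reuse).
#' @return list with \code{mean} (named numeric) and \code{cov} (matrix).
#' @export
evo_moments <- function(tree, kind, params, painting = NULL, cache = NULL) {
  kind <- match.arg(kind, model_kinds())
  if (kind %in% c("BMS", "OUM") && is.null(painting) && is.null(cache$Creg))
    stop(kind, " requires a regime painting")
  if (is.null(cache)) cache <- tree_cache(tree, painting)
  n <- cache$n
  if (kind == "WN") {
    return(list(mean = stats::setNames(rep(params$wn_mean, n), cache$tips),
                cov = diag(params$wn_var, n)))
  }
  if (kind == "BM1") {
    V <- params$sigma2 * cache$Tsh
    mu <- rep(params$root_value, n)
  } else if (kind == "EB") {
    if (params$eb_rate > 0) stop("eb_rate must be <= 0")
    V <- params$sigma2 * evo_structure("EB", cache, eb_rate = params$eb_rate)
    mu <- rep(params$root_value, n)
  } else if (kind == "BMS") {
    s2 <- params$sigma2
    if (is.null(names(s2)) || !setequal(names(s2), cache$regimes))
      stop("BMS sigma2 must be named by regime")
    V <- evo_structure("BMS", cache, rate_weights = s2)
    mu <- rep(params$root_value, n)
  } else { # OU1 / OUM
    a <- params$alpha
    if (is.null(a) || a <= 0) stop("OU models need alpha > 0")
    V <- params$sigma2 * evo_structure("OU1", cache, alpha = a)
    if (kind == "OU1") {
      mu <- rep(params$theta, n)
    } else {
      th <- params$theta
      if (is.null(names(th)) || !setequal(names(th), cache$regimes))
        stop("OUM theta must be named by regime")
      if (is.null(params$root_value)) {
        W <- hansen_weights(cache, a)
        mu <- as.vector(W %*% th[colnames(W)])
      } else {
        # estimated-root convention: the root state is its own parameter
        W <- hansen_weights(cache, a, root_anchor = FALSE)
        mu <- as.vector(W %*% th[colnames(W)]) +
          exp(-a * cache$tip_depth) * params$root_value
      }
    }
  }
  list(mean = stats::setNames(as.vector(mu), cache$tips), cov = V)
}

#' Multivariate-normal log-likelihood of tip data under model moments
#'
#' @param x named numeric vector of tip values.
#' @param moments list with \code{mean} and \code{cov}, as from
#'   \code{\link{evo_moments}}.
#' @return the log density (a scalar).
#' @export
evo_loglik <- function(x, moments) {
  x <- if (!is.null(names(x)) && !is.null(names(moments$mean)))
    x[names(moments$mean)] else x
  mvn_loglik(as.numeric(x), as.numeric(moments$mean), moments$cov)
}

mvn_loglik <- function(x, mu, V) {
  R <- tryCatch(chol(V), error = function(e)
    stop("covariance not positive definite (condition estimate ",
         format(kappa(V), digits = 3), ")"))
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

# profile lnL for a fixed scale-free structure V0: GLS mean(s) via design W,
# MLE sigma2 = quadform/n. Returns lnL, coefficients, sigma2.
profile_gaussian <- function(x, V0, W) {
  n <- length(x)
  R <- chol(V0)
  xt <- backsolve(R, x, transpose = TRUE)
  Wt <- backsolve(R, W, transpose = TRUE)
  A <- crossprod(Wt)
  b <- crossprod(Wt, xt)
  # pseudo-inverse fallback: at large alpha the Hansen weight of a deep
  # regime can vanish at every tip, making the design rank-deficient
  beta <- tryCatch(solve(A, b), error = function(e) {
    sv <- svd(A)
    pos <- sv$d > 1e-12 * max(sv$d)
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  })
  resid <- xt - Wt %*% beta
  q <- sum(resid^2)
  s2 <- q / n
  lnL <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
  list(lnL = lnL, beta = as.vector(beta), sigma2 = s2)
}

#' Control settings for \code{\link{fit_evo}}
#'
#' @param alpha_bounds search interval for the OU attraction rate (1/My);
#'   default \code{c(1e-6, 50/height)}, set at fit time when \code{NULL}.
#'   The upper bound scales with tree height because alpha is only weakly
#'   identified beyond a few half-lives per tree depth.
#' @param eb_bounds search interval for the early-burst decay rate (<= 0);
#'   default \code{c(-11.5/height, 0)}.
#' @param restarts number of optimiser starts for the multi-rate BM search.
#' @param tol relative convergence tolerance of the 1-D profile searches.
#' @param ou_root root handling for multi-optimum OU: \code{"regime_theta"}
#'   (default) fixes the root lineage at the root regime's optimum;
#'   \code{"estimated"} adds the root state as a free parameter (k grows
#'   by one).
#' @return a list of control values.
#' @export
evo_control <- function(alpha_bounds = NULL, eb_bounds = NULL,
                        restarts = 4L, tol = 1e-8,
                        ou_root = c("regime_theta", "estimated")) {
  list(alpha_bounds = alpha_bounds, eb_bounds = eb_bounds,
       restarts = restarts, tol = tol, ou_root = match.arg(ou_root))
}

#' Maximum-likelihood fit of a trait-diversification model
#'
#' Fits one of the six models to tip data by maximum likelihood. Linear
#' parameters (optima / root value) and the overall rate scale are profiled
#' analytically by generalised least squares, so the numerical search runs
#' only over the parameters that enter the covariance nonlinearly: nothing
#' for BM1 and WN (closed form), a 1-D bounded search over \code{alpha}
#' (OU1/OUM) or \code{eb_rate} (EB), and an (m-1)-D multistart quasi-Newton
#' search over rate ratios for m-regime BMS.
#'
#' @param tree a dated ultrametric tree.
#' @param x named numeric vector of tip values (names = tip labels).
#' @param kind model kind; see \code{\link{evo_models}}.
#' @param painting a \code{regime_painting} (required for BMS/OUM).
#' @param control a list from \code{\link{evo_control}}.
#' @param cache optional precomputed \code{tree_cache}.
#' @return an object of class \code{evo_fit} with elements \code{kind},
#'   \code{params}, \code{lnL}, \code{k}, \code{n}, \code{converged},
#'   \code{trace}, and the data fingerprint used to guard comparisons.
#' @export
fit_evo <- function(tree, x, kind, painting = NULL, control = evo_control(),
                    cache = NULL) {
  kind <- match.arg(kind, model_kinds())
  if (is.null(cache)) cache <- tree_cache(tree, painting)
  x <- align_to_tips_cache(cache, x)
  n <- cache$n
  if (n < 2L) stop("need at least 2 tips (>= k + 2 recommended)")
  h <- cache$height
  ab <- control$alpha_bounds %||% c(1e-6, 50 / h)
  eb <- control$eb_bounds %||% c(-11.5 / h, 0)
  converged <- TRUE
  trace <- list()
  extra_k <- 0L  # estimated-root OUM adds one parameter

  if (kind == "WN") {
    m <- mean(x); v <- mean((x - m)^2)
    lnL <- sum(stats::dnorm(x, m, sqrt(v), log = TRUE))
    params <- list(wn_mean = m, wn_var = v)
  } else if (kind == "BM1") {
    pr <- profile_gaussian(x, cache$Tsh, matrix(1, n, 1))
    params <- list(sigma2 = pr$sigma2, root_value = pr$beta)
    lnL <- pr$lnL
  } else if (kind == "EB") {
    f <- function(r) profile_gaussian(x, evo_structure("EB", cache, eb_rate = r),
                                      matrix(1, n, 1))$lnL
    opt <- stats::optimize(f, interval = eb, maximum = TRUE, tol = control$tol)
    pr <- profile_gaussian(x, evo_structure("EB", cache, eb_rate = opt$maximum),
                           matrix(1, n, 1))
    params <- list(sigma2 = pr$sigma2, eb_rate = opt$maximum, root_value = pr$beta)
    lnL <- pr$lnL
    trace$eb_rate <- opt$maximum
  } else if (kind %in% c("OU1", "OUM")) {
    est_root <- kind == "OUM" && identical(control$ou_root, "estimated")
    W_of <- function(a) {
      if (kind == "OU1") return(matrix(1, n, 1))
      W <- hansen_weights(cache, a, root_anchor = !est_root)
      if (est_root) W <- cbind(W, ".root" = exp(-a * cache$tip_depth))
      W
    }
    f <- function(la) {
      a <- exp(la)
      profile_gaussian(x, evo_structure("OU1", cache, alpha = a), W_of(a))$lnL
    }
    opt <- stats::optimize(f, interval = log(ab), maximum = TRUE, tol = control$tol)
    a <- exp(opt$maximum)
    pr <- profile_gaussian(x, evo_structure("OU1", cache, alpha = a), W_of(a))
    if (kind == "OU1") {
      params <- list(alpha = a, sigma2 = pr$sigma2, theta = pr$beta)
    } else if (est_root) {
      m_r <- length(cache$regimes)
      params <- list(alpha = a, sigma2 = pr$sigma2,
                     theta = stats::setNames(pr$beta[seq_len(m_r)], cache$regimes),
                     root_value = pr$beta[m_r + 1L])
      extra_k <- 1L
    } else {
      th <- stats::setNames(pr$beta, cache$regimes)
      params <- list(alpha = a, sigma2 = pr$sigma2, theta = th)
    }
    lnL <- pr$lnL
    trace$alpha <- a
    trace$at_bound <- a <= ab[1] * 1.01 || a >= ab[2] * 0.99
  } else { # BMS
    regs <- cache$regimes
    m <- length(regs)
    if (m < 2L) stop("BMS requires a painting with >= 2 regimes")
    obj <- function(z) {
      w <- stats::setNames(c(1, exp(z)), regs)
      -profile_gaussian(x, evo_structure("BMS", cache, rate_weights = w),
                        matrix(1, n, 1))$lnL
    }
    starts <- c(list(rep(0, m - 1L)),
                lapply(seq_len(max(0L, control$restarts - 1L)),
                       function(i) stats::rnorm(m - 1L, 0, 1.5)))
    best <- NULL; vals <- numeric(0)
    for (s in starts) {
      o <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                                 lower = rep(-12, m - 1L), upper = rep(12, m - 1L)),
                    error = function(e) NULL)
      if (is.null(o)) next
      vals <- c(vals, -o$value)
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) {
      return(structure(list(kind = kind, params = NULL, lnL = -Inf, k = evo_k(kind, m),
                            n = n, converged = FALSE, trace = list(),
                            data_fingerprint = data_fingerprint(x), x = x),
                       class = "evo_fit"))
    }
    w <- stats::setNames(c(1, exp(best$par)), regs)
    pr <- profile_gaussian(x, evo_structure("BMS", cache, rate_weights = w),
                           matrix(1, n, 1))
    params <- list(sigma2 = pr$sigma2 * w, root_value = pr$beta)
    lnL <- pr$lnL
    converged <- best$convergence == 0 &&
      (length(vals) < 2L || max(vals) - sort(vals, decreasing = TRUE)[2L] < 1e-4 ||
         sum(abs(vals - max(vals)) < 1e-4) >= 2L)
    trace$restart_lnL <- vals
  }

  m_reg <- if (!is.null(cache$regimes)) length(cache$regimes) else 1L
  structure(list(kind = kind, params = params, lnL = lnL,
                 k = evo_k(kind, m_reg) + extra_k, n = n, converged = converged,
                 trace = trace, data_fingerprint = data_fingerprint(x),
                 x = x, cache = cache),
            class = "evo_fit")
}

align_to_tips_cache <- function(cache, x) {
  if (is.null(names(x))) {
    if (length(x) != cache$n) stop("data length does not match tip count")
    return(stats::setNames(as.numeric(x), cache$tips))
  }
  if (!setequal(names(x), cache$tips)) stop("data names do not match tree tips")
  x[cache$tips]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evo_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, n = %d%s\n", x$kind, x$lnL, x$k, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  p <- unlist(x$params)
  print(round(p, digits))
  if (!is.null(x$params$alpha) && x$params$alpha > 0)
    cat(sprintf("phylogenetic half-life: %.3f My\n", half_life(x$params$alpha)))
  invisible(x)
}

#' @export
logLik.evo_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
coef.evo_fit <- function(object, ...) unlist(object$params)

#' Simulate tip data under a fitted or specified model
#'
#' Draws exactly from the model's multivariate normal tip distribution via a
#' Cholesky factor of the covariance from \code{\link{evo_moments}}.
#'
#' @param tree a dated tree.
#' @param kind model kind.
#' @param params parameter list (see \code{\link{evo_moments}}).
#' @param painting regime painting for BMS/OUM.
#' @param seed optional integer seed (reproducible, stream-isolated).
#' @param cache,moments optional precomputed pieces for repeated simulation.
#' @return named numeric vector of tip values.
#' @export
simulate_evo <- function(tree, kind, params, painting = NULL, seed = NULL,
                         cache = NULL, moments = NULL) {
  if (is.null(moments)) moments <- evo_moments(tree, kind, params, painting, cache)
  R <- chol(moments$cov)
  with_seed(seed, {
    z <- stats::rnorm(length(moments$mean))
    stats::setNames(as.vector(moments$mean + crossprod(R, z)), names(moments$mean))
  })
}

#' @export
#' @importFrom stats simulate
simulate.evo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cache <- object$cache
  moments <- evo_moments(NULL, object$kind, object$params, cache = cache)
  out <- with_seed(seed, replicate(nsim, {
    z <- stats::rnorm(length(moments$mean))
    as.vector(moments$mean + crossprod(chol(moments$cov), z))
  }))
  out <- matrix(out, ncol = nsim,
                dimnames = list(names(moments$mean), NULL))
  if (nsim == 1) stats::setNames(out[, 1L], rownames(out)) else out
}

#' Phylogenetic half-life
#'
#' Time for the expected trait value to move halfway to the optimum under an
#' OU process: \eqn{t_{1/2} = \ln 2 / \alpha}. For Brownian motion
#' (\eqn{\alpha = 0}) the half-life is infinite; that case is rejected here
#' rather than returned.
#'
#' @param alpha OU attraction rate (1/My), > 0.
#' @return half-life in My.
#' @export
half_life <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0 (half-life is infinite for BM)")
  log(2) / alpha
}
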