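#' Fit an Mk model of discrete-habit evolution
#'
#' Maximum-likelihood continuous-time Markov (Mk) model for a discrete
#' character (here the locomotor habit) on a dated tree, computed by the
#' pruning algorithm with a uniform root-state prior. The default
#' equal-rates (ER) structure has a single exchange rate; all-rates-different
#' (ARD) estimates one rate per ordered state pair.
#'
#' @param tree a dated tree.
#' @param tip_states named character vector of states, names = tip labels.
#' @param structure \code{"ER"} (default) or \code{"ARD"}.
#' @param states the full state set; defaults to the states observed at the
#'   tips. States supplied here but absent from the tips are retained with a
#'   warning.
#' @return an object of class \code{mk_fit}: \code{states}, \code{Q},
#'   \code{rates}, \code{lnL}, \code{structure}.
#' @export
fit_mk <- function(tree, tip_states, structure = c("ER", "ARD"), states = NULL) {
  structure <- match.arg(structure)
  tip_states <- align_to_tips(tree, tip_states)
  obs <- sort(unique(as.character(tip_states)))
  if (is.null(states)) states <- obs
  states <- sort(unique(as.character(states)))
  if (!all(obs %in% states)) stop("tip states outside the declared state set")
  if (!all(states %in% obs))
    warning("state(s) absent from tips retained in the model: ",
            paste(setdiff(states, obs), collapse = ", "))
  k <- length(states)
  if (k == 1L) {
    Q <- matrix(0, 1, 1, dimnames = list(states, states))
    return(structure(list(states = states, Q = Q, rates = 0, lnL = 0,
                          structure = structure, tree = tree,
                          tip_states = tip_states), class = "mk_fit"))
  }
  if (structure == "ER") {
    f <- function(lq) mk_loglik(tree, tip_states, mk_Q_er(exp(lq), states))
    opt <- stats::optimize(f, interval = log(c(1e-10, 1e3)), maximum = TRUE,
                           tol = 1e-10)
    q <- exp(opt$maximum)
    Q <- mk_Q_er(q, states)
    lnL <- opt$objective
    rates <- q
  } else {
    np <- k * (k - 1L)
    obj <- function(lr) -mk_loglik(tree, tip_states, mk_Q_ard(exp(lr), states))
    best <- NULL
    for (s in list(rep(log(0.1), np), rep(log(0.5), np))) {
      o <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                                 lower = rep(log(1e-9), np),
                                 upper = rep(log(1e3), np)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("ARD optimisation failed")
    rates <- exp(best$par)
    Q <- mk_Q_ard(rates, states)
    lnL <- -best$value
  }
  structure(list(states = states, Q = Q, rates = rates, lnL = lnL,
                 structure = structure, tree = tree, tip_states = tip_states),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk (%s) fit over %d states: lnL = %.4f\n",
              x$structure, length(x$states), x$lnL))
  print(round(x$Q, 5))
  invisible(x)
}

mk_Q_er <- function(q, states) {
  k <- length(states)
  Q <- matrix(q, k, k, dimnames = list(states, states))
  diag(Q) <- -(k - 1L) * q
  Q
}

mk_Q_ard <- function(rates, states) {
  k <- length(states)
  Q <- matrix(0, k, k, dimnames = list(states, states))
  Q[row(Q) != col(Q)] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probability matrix; closed form for ER, matrix exponential else
mk_P <- function(Q, t) {
  k <- nrow(Q)
  off <- Q[row(Q) != col(Q)]
  if (max(off) - min(off) < 1e-14 * max(off, 1e-300)) {
    q <- off[1L]
    e <- exp(-k * q * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- (1 + (k - 1) * e) / k
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  as.matrix(Matrix::expm(Q * t))
}

# pruning-algorithm conditional likelihoods; returns per-node scaled partials
# and the total log-likelihood under a uniform root prior
mk_prune <- function(tree, tip_states, Q) {
  states <- rownames(Q)
  k <- length(states)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  L <- matrix(0, nn, k, dimnames = list(NULL, states))
  logscale <- 0
  for (i in seq_len(n)) L[i, match(tip_states[tree$tip.label[i]], states)] <- 1
  tr <- reorder(tree, "postorder")
  Pcache <- list()
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; c_ <- tr$edge[i, 2L]; t <- tr$edge.length[i]
    key <- format(t, digits = 15)
    P <- Pcache[[key]]
    if (is.null(P)) P <- Pcache[[key]] <- mk_P(Q, t)
    msg <- as.vector(P %*% L[c_, ])
    if (all(L[p, ] == 0)) L[p, ] <- msg else L[p, ] <- L[p, ] * msg
    m <- max(L[p, ])
    if (m > 0 && m < 1e-10) { L[p, ] <- L[p, ] / m; logscale <- logscale + log(m) }
  }
  root <- n + 1L
  lnL <- log(mean(L[root, ])) + logscale
  list(partials = L, lnL = lnL, logscale = logscale)
}

#' Mk log-likelihood for a given rate matrix
#' @param tree a dated tree.
#' @param tip_states named character vector over tips.
#' @param Q a valid generator matrix with state dimnames.
#' @return log-likelihood under a uniform root prior.
#' @export
mk_loglik <- function(tree, tip_states, Q) {
  tip_states <- align_to_tips(tree, tip_states)
  mk_prune(tree, tip_states, Q)$lnL
}

#' Sample stochastic character mappings
#'
#' Draws regime paintings from the posterior distribution of character
#' histories conditional on the observed tip states and the Mk rate matrix:
#' internal node states are sampled from the pruning partials (conditional on
#' the parent as the tree is descended), then the path along each edge is
#' drawn exactly by uniformization, conditioned on its endpoint states. Every
#' sampled painting agrees with the tip states and conserves segment sums.
#'
#' @param tree a dated tree.
#' @param tip_states named character vector over tips.
#' @param mk an \code{mk_fit} (or a list with elements \code{Q}).
#' @param n_samples number of mappings (the analysis default is 500).
#' @param seed optional integer seed.
#' @return list of \code{regime_painting} objects; each carries attributes
#'   \code{node_states} and \code{sample_index}.
#' @export
sample_mappings <- function(tree, tip_states, mk, n_samples = 500L, seed = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  Q <- mk$Q
  if (max(-diag(Q)) > 1e3) stop("pathological rate matrix (rate > 1e3/My)")
  tip_states <- align_to_tips(tree, tip_states)
  pr <- mk_prune(tree, tip_states, Q)
  states <- rownames(Q)
  k <- length(states)
  n <- ape::Ntip(tree)
  root <- n + 1L
  tr <- reorder(tree, "cladewise")
  mu <- max(-diag(Q))
  Rmat <- if (mu > 0) diag(k) + Q / mu else diag(k)
  Rpow <- list(diag(k), Rmat)  # R^0, R^1
  get_Rpow <- function(m) {
    while (length(Rpow) < m + 1L)
      Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% Rmat
    Rpow[[m + 1L]]
  }
  Pcache <- list()
  getP <- function(t) {
    key <- format(t, digits = 15)
    P <- Pcache[[key]]
    if (is.null(P)) P <- Pcache[[key]] <<- mk_P(Q, t)
    P
  }
  with_seed(seed, {
    lapply(seq_len(n_samples), function(si) {
      node_state <- integer(n + tree$Nnode)
      rp <- pr$partials[root, ]
      node_state[root] <- sample.int(k, 1L, prob = rp / sum(rp))
      segs <- vector("list", nrow(tree$edge))
      names(segs) <- as.character(tree$edge[, 2L])
      for (i in seq_len(nrow(tr$edge))) {
        p <- tr$edge[i, 1L]; c_ <- tr$edge[i, 2L]; t <- tr$edge.length[i]
        P <- getP(t)
        a <- node_state[p]
        w <- P[a, ] * pr$partials[c_, ]
        b <- sample.int(k, 1L, prob = w / sum(w))
        node_state[c_] <- b
        segs[[as.character(c_)]] <-
          sample_edge_path(a, b, t, mu, Q, P, get_Rpow, states)
      }
      painting <- regime_painting(tree, segs, states[node_state[root]])
      attr(painting, "node_states") <- states[node_state]
      attr(painting, "sample_index") <- si
      painting
    })
  })
}

# exact endpoint-conditioned path on one edge by uniformization
sample_edge_path <- function(a, b, t, mu, Q, P, get_Rpow, states) {
  if (mu == 0 || max(abs(Q)) == 0) {
    return(data.frame(regime = states[a], duration = t))
  }
  pab <- P[a, b]
  # sample the number of uniformized jumps
  u <- stats::runif(1) * pab
  cum <- 0; m <- -1L
  logpois <- -mu * t
  repeat {
    m <- m + 1L
    term <- exp(logpois + m * log(mu * t) - lgamma(m + 1)) * get_Rpow(m)[a, b]
    cum <- cum + term
    if (cum >= u || m >= 500L) break
  }
  if (m == 0L) return(data.frame(regime = states[a], duration = t))
  # jump times: order statistics of m uniforms on (0, t); state j holds on
  # [bounds[j], bounds[j+1])
  times <- sort(stats::runif(m, 0, t))
  bounds <- c(0, times, t)
  seq_states <- integer(m + 1L)
  seq_states[1L] <- a
  seq_states[m + 1L] <- b
  R1 <- get_Rpow(1)
  if (m > 1L) for (j in 2:m) {
    w <- R1[seq_states[j - 1L], ] * get_Rpow(m + 1L - j)[, b]
    seq_states[j] <- sample.int(length(states), 1L, prob = w / sum(w))
  }
  # collapse virtual (self) jumps into segments
  keep_states <- seq_states[1L]
  keep_starts <- 0
  for (j in 2:(m + 1L)) {
    if (seq_states[j] != keep_states[length(keep_states)]) {
      keep_states <- c(keep_states, seq_states[j])
      keep_starts <- c(keep_starts, bounds[j])
    }
  }
  dur <- diff(c(keep_starts, t))
  ok <- dur > 0
  data.frame(regime = states[keep_states[ok]], duration = dur[ok])
}

#' Average model fits over stochastic mappings
#'
#' Fits a multi-regime model (BMS or OUM) once per sampled mapping and
#' reports the arithmetic mean of every parameter and of the log-likelihood
#' across mappings, following the standard protocol of averaging over
#' character-history uncertainty. Non-converged per-mapping fits are excluded
#' from the means and counted.
#'
#' @param tree a dated tree.
#' @param mappings list of \code{regime_painting}s from
#'   \code{\link{sample_mappings}}.
#' @param x named numeric tip data.
#' @param kind \code{"BMS"} or \code{"OUM"}.
#' @param control optimiser control, see \code{\link{evo_control}}.
#' @return an object of class \code{averaged_fit}: per-mapping \code{fits},
#'   \code{mean_params}, \code{mean_lnL}, \code{n_mappings},
#'   \code{n_excluded}, plus \code{k} and \code{n} for model comparison.
#' @export
fit_over_mappings <- function(tree, mappings, x, kind = c("OUM", "BMS"),
                              control = evo_control()) {
  kind <- match.arg(kind)
  if (length(mappings) == 0L) stop("no mappings supplied")
  fits <- lapply(mappings, function(p)
    fit_evo(tree, x, kind, painting = p, control = control))
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("no per-mapping fit converged")
  used <- fits[ok]
  pnames <- names(unlist(used[[1L]]$params))
  pmat <- t(vapply(used, function(f) unlist(f$params)[pnames], numeric(length(pnames))))
  mean_params <- colMeans(pmat)
  structure(list(kind = kind, fits = fits,
                 mean_params = mean_params,
                 param_draws = pmat,
                 mean_lnL = mean(vapply(used, function(f) f$lnL, 0)),
                 n_mappings = length(mappings),
                 n_excluded = sum(!ok),
                 k = used[[1L]]$k, n = used[[1L]]$n,
                 data_fingerprint = used[[1L]]$data_fingerprint),
            class = "averaged_fit")
}

#' @export
print.averaged_fit <- function(x, ...) {
  cat(sprintf("%s averaged over %d mappings (%d excluded): mean lnL = %.4f\n",
              x$kind, x$n_mappings, x$n_excluded, x$mean_lnL))
  print(round(x$mean_params, 4))
  invisible(x)
}
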