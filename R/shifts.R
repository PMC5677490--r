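#' Configuration for the unconstrained-OU shift sampler
#'
#' Priors and tuning for \code{\link{run_shift_chain}}. The number of shifts
#' has a conditional Poisson prior (mean \code{lambda}, truncated at
#' \code{k_max}, at most one shift per branch, shifted branch sets uniform
#' given the count); shift positions are uniform along their branch; new
#' optima and the root optimum are Normal(data mean, \code{theta_k} x data
#' sd); \code{alpha} and the square root of \code{sigma2} have half-Cauchy
#' priors. These are weakly informative defaults in the spirit of common
#' unconstrained-OU practice, and every one is overridable.
#'
#' @param iterations chain length; the production default matches the study
#'   protocol of 1,500,000 iterations (use ~20,000 with thinning for quick
#'   exploratory runs).
#' @param burnin fraction of the chain discarded, in [0, 1).
#' @param thin keep every \code{thin}-th post-burn-in state.
#' @param lambda prior mean shift count.
#' @param k_max maximum shifts (default: half the tip count).
#' @param alpha_scale half-Cauchy scale for alpha (1/My).
#' @param sigma_scale half-Cauchy scale for sqrt(sigma2), in data-sd units.
#' @param theta_k prior sd of optima in data-sd units.
#' @param moves named probabilities of the move types (birth, death, slide,
#'   relocate, alpha, sigma2, theta); must sum to 1. The relocate move
#'   proposes moving an existing shift to a uniformly chosen unoccupied
#'   branch, which lets the chain hop between well-separated modes (e.g. a
#'   clade shift and its complementary shift) that birth/death alone crosses
#'   only slowly.
#' @param prop_alpha,prop_sigma log-random-walk sd for alpha / sqrt(sigma2).
#' @param prop_theta random-walk sd for optima, in data-sd units.
#' @param prop_slide random-walk sd for relative shift positions.
#' @param seed integer seed; identical (config, seed) gives identical chains.
#' @param prior_only if \code{TRUE} the likelihood is switched off, so the
#'   chain samples the prior (used to verify the sampler against the
#'   conditional-Poisson shift-count prior).
#' @return a list of class \code{shift_config}.
#' @export
shift_config <- function(iterations = 1500000L, burnin = 0.3, thin = 10L,
                         lambda = 1, k_max = NULL,
                         alpha_scale = 1, sigma_scale = 1, theta_k = 2,
                         moves = c(birth = 0.2, death = 0.2, slide = 0.05,
                                   relocate = 0.05, alpha = 0.15,
                                   sigma2 = 0.15, theta = 0.2),
                         prop_alpha = 0.5, prop_sigma = 0.5,
                         prop_theta = 0.5, prop_slide = 0.15,
                         seed = NULL, prior_only = FALSE) {
  if (iterations < 1000L) stop("chain too short to burn in: need >= 1000 iterations")
  if (burnin < 0 || burnin >= 1) stop("burnin fraction must be in [0, 1)")
  need <- c("birth", "death", "slide", "relocate", "alpha", "sigma2", "theta")
  if (!setequal(names(moves), need))
    stop("moves must name exactly: ", paste(need, collapse = ", "))
  if (abs(sum(moves) - 1) > 1e-9) stop("move probabilities must sum to 1")
  structure(list(iterations = as.integer(iterations), burnin = burnin,
                 thin = as.integer(thin), lambda = lambda, k_max = k_max,
                 alpha_scale = alpha_scale, sigma_scale = sigma_scale,
                 theta_k = theta_k, moves = moves,
                 prop_alpha = prop_alpha, prop_sigma = prop_sigma,
                 prop_theta = prop_theta, prop_slide = prop_slide,
                 seed = seed, prior_only = prior_only),
            class = "shift_config")
}

#' Reversible-jump MCMC over shifts in phenotypic optima
#'
#' Samples the posterior of an unconstrained single-alpha, single-rate OU
#' model in which the optimum theta may shift at most once per branch, at an
#' unknown position, to an unknown new value. Birth/death moves change the
#' number of shifts with the usual reversible-jump (Green) acceptance ratio;
#' new optima are proposed from their prior so the dimension-matching terms
#' cancel; slide moves shift positions within a branch; scalar moves update
#' alpha, sigma2 and the optima. The likelihood is the exact Gaussian tip
#' density of the induced regime painting, with the covariance factor reused
#' across moves that do not change alpha.
#'
#' @param tree a dated ultrametric tree.
#' @param x named numeric tip values.
#' @param config a \code{\link{shift_config}}.
#' @return an object of class \code{shift_chain}: thinned post-burn-in
#'   \code{samples} (each with shift set, alpha, sigma2, theta0, lnL,
#'   iteration), \code{acceptance} rates by move, the \code{config}, and the
#'   edge key (child node id per branch).
#' @export
run_shift_chain <- function(tree, x, config = shift_config()) {
  cache <- tree_cache(tree)
  x <- align_to_tips_cache(cache, x)
  n <- cache$n
  E <- nrow(tree$edge)
  sdx <- stats::sd(x)
  k_max <- config$k_max %||% floor(n / 2)
  d <- node_depths(tree)
  edge_t0 <- d[tree$edge[, 1L]]
  edge_len <- tree$edge.length
  tipT <- cache$tip_depth
  desc <- descendant_tips(tree)
  onpath <- matrix(FALSE, E, n)     # onpath[e, i]: edge e is on tip i's root path
  for (e in seq_len(E)) onpath[e, desc[[tree$edge[e, 2L]]]] <- TRUE

  m_theta <- mean(x); s_theta <- config$theta_k * sdx
  lp_theta <- function(th) stats::dnorm(th, m_theta, s_theta, log = TRUE)
  lp_alpha <- function(a) stats::dcauchy(a, 0, config$alpha_scale, log = TRUE)
  lp_sigma <- function(s2) {
    s <- sqrt(s2)
    stats::dcauchy(s, 0, config$sigma_scale * sdx, log = TRUE) - log(2 * s)
  }

  # expectation of every tip given the shift set (Hansen weighting; the root
  # lineage is anchored at the root optimum theta0)
  mean_fun <- function(alpha, theta0, sh) {
    mu <- numeric(n)
    ea_T <- exp(-alpha * tipT)
    if (nrow(sh) == 0L) return(rep(theta0, n))
    st <- edge_t0[sh$edge] + sh$pos * edge_len[sh$edge]
    for (i in seq_len(n)) {
      sel <- which(onpath[sh$edge, i])
      if (length(sel) == 0L) { mu[i] <- theta0; next }
      o <- sel[order(st[sel])]
      tb <- c(st[o], tipT[i])
      vals <- c(theta0, sh$theta[o])
      w_end <- exp(-alpha * (tipT[i] - tb))          # weights at interval ends
      w_start <- c(ea_T[i], w_end[-length(w_end)])
      # anchor at theta0 plus interval contributions; first interval merges
      # with the anchor
      mu[i] <- theta0 * ea_T[i] +
        sum(vals * (w_end - c(exp(-alpha * tipT[i]), w_end[-length(w_end)])))
    }
    mu
  }

  chol_of_alpha <- function(alpha) {
    V0 <- exp(-alpha * cache$D) * (1 - exp(-2 * alpha * cache$Tsh)) / (2 * alpha)
    R <- chol(V0)
    list(R = R, logdet = 2 * sum(log(diag(R))))
  }
  quad <- function(R, mu) { z <- backsolve(R, x - mu, transpose = TRUE); sum(z * z) }
  lnL_fun <- function(sig2, logdet, q) {
    if (config$prior_only) return(0)
    -0.5 * (n * log(2 * pi) + n * log(sig2) + logdet + q / sig2)
  }

  mv <- config$moves
  move_names <- names(mv)
  samples <- vector("list",
                    max(0L, floor((config$iterations - floor(config$burnin * config$iterations)) /
                                    config$thin)))
  with_seed(config$seed, {
    alpha <- log(2) / (cache$height / 2)
    sig2 <- max(stats::var(x), 1e-8) * 2 * alpha
    theta0 <- m_theta
    sh <- data.frame(edge = integer(0), pos = numeric(0), theta = numeric(0))
    ch <- chol_of_alpha(alpha)
    mu <- mean_fun(alpha, theta0, sh)
    q <- quad(ch$R, mu)
    lnL <- lnL_fun(sig2, ch$logdet, q)
    acc <- stats::setNames(numeric(length(mv)), move_names)
    tried <- acc
    burn <- floor(config$burnin * config$iterations)
    si <- 0L
    for (it in seq_len(config$iterations)) {
      mt <- sample.int(length(mv), 1L, prob = mv)
      mname <- move_names[mt]
      tried[mt] <- tried[mt] + 1
      k <- nrow(sh)
      if (mname == "birth") {
        if (k < k_max && k < E) {
          free <- setdiff(seq_len(E), sh$edge)
          e_new <- free[sample.int(length(free), 1L)]
          pos_new <- stats::runif(1)
          th_new <- stats::rnorm(1, m_theta, s_theta)
          sh2 <- rbind(sh, data.frame(edge = e_new, pos = pos_new, theta = th_new))
          mu2 <- mean_fun(alpha, theta0, sh2)
          q2 <- quad(ch$R, mu2)
          lnL2 <- lnL_fun(sig2, ch$logdet, q2)
          # prior-count x subset x proposal terms collapse to lambda/(k+1) x Pd/Pb;
          # the theta prior cancels against its prior proposal
          logA <- (lnL2 - lnL) + log(config$lambda) - log(k + 1) +
            log(mv[["death"]]) - log(mv[["birth"]])
          if (log(stats::runif(1)) < logA) {
            sh <- sh2; mu <- mu2; q <- q2; lnL <- lnL2; acc[mt] <- acc[mt] + 1
          }
        }
      } else if (mname == "death") {
        if (k > 0L) {
          drop <- sample.int(k, 1L)
          sh2 <- sh[-drop, , drop = FALSE]
          mu2 <- mean_fun(alpha, theta0, sh2)
          q2 <- quad(ch$R, mu2)
          lnL2 <- lnL_fun(sig2, ch$logdet, q2)
          logA <- (lnL2 - lnL) + log(k) - log(config$lambda) +
            log(mv[["birth"]]) - log(mv[["death"]])
          if (log(stats::runif(1)) < logA) {
            sh <- sh2; mu <- mu2; q <- q2; lnL <- lnL2; acc[mt] <- acc[mt] + 1
          }
        }
      } else if (mname == "slide") {
        if (k > 0L) {
          j <- sample.int(k, 1L)
          p2 <- sh$pos[j] + stats::rnorm(1, 0, config$prop_slide)
          # reflect into [0, 1)
          p2 <- p2 %% 2; if (p2 >= 1) p2 <- 2 - p2
          p2 <- min(p2, 1 - 1e-12)
          sh2 <- sh; sh2$pos[j] <- p2
          mu2 <- mean_fun(alpha, theta0, sh2)
          q2 <- quad(ch$R, mu2)
          lnL2 <- lnL_fun(sig2, ch$logdet, q2)
          if (log(stats::runif(1)) < lnL2 - lnL) {
            sh <- sh2; mu <- mu2; q <- q2; lnL <- lnL2; acc[mt] <- acc[mt] + 1
          }
        }
      } else if (mname == "relocate") {
        if (k > 0L) {
          j <- sample.int(k, 1L)
          free <- c(sh$edge[j], setdiff(seq_len(E), sh$edge))
          sh2 <- sh
          sh2$edge[j] <- free[sample.int(length(free), 1L)]
          sh2$pos[j] <- stats::runif(1)
          mu2 <- mean_fun(alpha, theta0, sh2)
          q2 <- quad(ch$R, mu2)
          lnL2 <- lnL_fun(sig2, ch$logdet, q2)
          # same shift count, uniform subsets and positions: symmetric proposal
          if (log(stats::runif(1)) < lnL2 - lnL) {
            sh <- sh2; mu <- mu2; q <- q2; lnL <- lnL2; acc[mt] <- acc[mt] + 1
          }
        }
      } else if (mname == "alpha") {
        a2 <- alpha * exp(stats::rnorm(1, 0, config$prop_alpha))
        ok <- tryCatch({ ch2 <- chol_of_alpha(a2); TRUE },
                       error = function(e) FALSE)
        if (ok) {
          mu2 <- mean_fun(a2, theta0, sh)
          q2 <- quad(ch2$R, mu2)
          lnL2 <- lnL_fun(sig2, ch2$logdet, q2)
          logA <- (lnL2 - lnL) + lp_alpha(a2) - lp_alpha(alpha) +
            log(a2) - log(alpha)   # log-RW Jacobian
          if (log(stats::runif(1)) < logA) {
            alpha <- a2; ch <- ch2; mu <- mu2; q <- q2; lnL <- lnL2
            acc[mt] <- acc[mt] + 1
          }
        }
      } else if (mname == "sigma2") {
        s2b <- sig2 * exp(stats::rnorm(1, 0, 2 * config$prop_sigma))
        lnL2 <- lnL_fun(s2b, ch$logdet, q)
        logA <- (lnL2 - lnL) + lp_sigma(s2b) - lp_sigma(sig2) +
          log(s2b) - log(sig2)
        if (log(stats::runif(1)) < logA) {
          sig2 <- s2b; lnL <- lnL2; acc[mt] <- acc[mt] + 1
        }
      } else { # theta: root optimum or one shift's optimum
        j <- sample.int(k + 1L, 1L)
        step <- stats::rnorm(1, 0, config$prop_theta * sdx)
        if (j == 1L) {
          t0b <- theta0 + step
          mu2 <- mean_fun(alpha, t0b, sh)
          pr <- lp_theta(t0b) - lp_theta(theta0)
        } else {
          sh2 <- sh; sh2$theta[j - 1L] <- sh$theta[j - 1L] + step
          mu2 <- mean_fun(alpha, theta0, sh2)
          pr <- lp_theta(sh2$theta[j - 1L]) - lp_theta(sh$theta[j - 1L])
        }
        q2 <- quad(ch$R, mu2)
        lnL2 <- lnL_fun(sig2, ch$logdet, q2)
        if (log(stats::runif(1)) < (lnL2 - lnL) + pr) {
          if (j == 1L) theta0 <- t0b else sh <- sh2
          mu <- mu2; q <- q2; lnL <- lnL2; acc[mt] <- acc[mt] + 1
        }
      }
      if (it > burn && (it - burn) %% config$thin == 0L) {
        si <- si + 1L
        samples[[si]] <- list(shifts = sh, alpha = alpha, sigma2 = sig2,
                              theta0 = theta0, lnL = lnL, iteration = it)
      }
    }
    structure(list(samples = samples[seq_len(si)],
                   acceptance = ifelse(tried > 0, acc / tried, NA),
                   config = config, n_edges = E,
                   edge_child = tree$edge[, 2L], x = x,
                   data_fingerprint = data_fingerprint(x)),
              class = "shift_chain")
  })
}

#' @export
print.shift_chain <- function(x, ...) {
  ks <- vapply(x$samples, function(s) nrow(s$shifts), 0L)
  cat(sprintf("rjMCMC shift chain: %d retained samples (%d iterations)\n",
              length(x$samples), x$config$iterations))
  cat("posterior shift-count distribution:\n"); print(table(ks) / length(ks))
  cat("acceptance rates:\n"); print(round(x$acceptance, 3))
  invisible(x)
}

#' Conditional-Poisson prior mass on the shift count
#' @param lambda prior mean.
#' @param k_max truncation point.
#' @return numeric vector of probabilities for counts 0..k_max.
#' @export
shift_count_prior <- function(lambda, k_max) {
  p <- stats::dpois(0:k_max, lambda)
  p / sum(p)
}

#' Per-branch posterior shift probabilities
#'
#' @param chain a \code{shift_chain}.
#' @param threshold posterior probability at or above which a branch's shift
#'   is deemed significant (the analysis convention is 0.20).
#' @return an object of class \code{shift_posterior}: per-branch
#'   \code{prob}, \code{mean_pos}, \code{mean_theta} (indexed by edge, with
#'   the child node id as key), \code{significant} edge indices, posterior
#'   mean \code{alpha} and \code{sigma2}, and the lnL effective sample size.
#' @export
shift_posterior <- function(chain, threshold = 0.20) {
  S <- length(chain$samples)
  if (S == 0L) stop("chain has no retained samples")
  E <- chain$n_edges
  cnt <- numeric(E); pos_sum <- numeric(E); th_sum <- numeric(E)
  for (s in chain$samples) {
    if (nrow(s$shifts) == 0L) next
    cnt[s$shifts$edge] <- cnt[s$shifts$edge] + 1
    pos_sum[s$shifts$edge] <- pos_sum[s$shifts$edge] + s$shifts$pos
    th_sum[s$shifts$edge] <- th_sum[s$shifts$edge] + s$shifts$theta
  }
  prob <- cnt / S
  lnls <- vapply(chain$samples, function(s) s$lnL, 0)
  structure(list(prob = prob,
                 mean_pos = ifelse(cnt > 0, pos_sum / cnt, NA),
                 mean_theta = ifelse(cnt > 0, th_sum / cnt, NA),
                 edge_child = chain$edge_child,
                 significant = which(prob >= threshold),
                 threshold = threshold,
                 alpha = mean(vapply(chain$samples, function(s) s$alpha, 0)),
                 sigma2 = mean(vapply(chain$samples, function(s) s$sigma2, 0)),
                 theta0 = mean(vapply(chain$samples, function(s) s$theta0, 0)),
                 ess_lnL = ess(lnls), n_samples = S),
            class = "shift_posterior")
}

# crude initial-sequence effective sample size
ess <- function(v) {
  S <- length(v)
  if (S < 10L || stats::sd(v) == 0) return(S)
  r <- stats::acf(v, plot = FALSE, lag.max = min(S - 1L, 200L))$acf[-1L]
  neg <- which(r < 0)
  if (length(neg)) r <- r[seq_len(neg[1L] - 1L)]
  S / (1 + 2 * sum(r))
}

#' @export
print.shift_posterior <- function(x, ...) {
  cat(sprintf("Shift posterior from %d samples: mean alpha = %.4f, sigma2 = %.4f\n",
              x$n_samples, x$alpha, x$sigma2))
  sig <- x$significant
  if (length(sig) == 0L) {
    cat("no branch reaches the", x$threshold, "posterior threshold\n")
  } else {
    cat("significant shifts (threshold", x$threshold, "):\n")
    print(data.frame(edge = sig, child_node = x$edge_child[sig],
                     prob = round(x$prob[sig], 3),
                     mean_pos = round(x$mean_pos[sig], 3),
                     mean_theta = round(x$mean_theta[sig], 3)))
  }
  invisible(x)
}

#' Convert significant shifts into a fixed regime painting
#'
#' Each branch whose posterior shift probability reaches the threshold gets
#' its own regime, beginning at the posterior mean position on that branch;
#' descendants inherit the new regime until a nested significant shift.
#' This is the conversion used to compare the unconstrained model against
#' the a-priori painted models on a common footing.
#'
#' @param tree the dated tree the chain was run on.
#' @param posterior a \code{shift_posterior}.
#' @param threshold optional override of the posterior's threshold.
#' @return a \code{regime_painting}; attribute \code{theta} holds the
#'   posterior-mean optima per regime (root regime "base").
#' @export
shift_painting <- function(tree, posterior, threshold = NULL) {
  thr <- threshold %||% posterior$threshold
  sig <- which(posterior$prob >= thr)
  # map posterior edges (keyed by child node) onto this tree's edge rows
  erow <- match(posterior$edge_child[sig], tree$edge[, 2L])
  if (anyNA(erow)) stop("posterior edges not found in tree")
  labels <- paste0("shift_", tree$edge[erow, 2L])
  root <- ape::Ntip(tree) + 1L
  node_regime <- rep("base", ape::Ntip(tree) + tree$Nnode)
  segs <- vector("list", nrow(tree$edge))
  names(segs) <- as.character(tree$edge[, 2L])
  tr_ord <- order(node_depths(tree)[tree$edge[, 2L]])  # rootward first
  theta <- c(base = posterior$theta0)
  for (i in tr_ord) {
    p <- tree$edge[i, 1L]; c_ <- tree$edge[i, 2L]; len <- tree$edge.length[i]
    j <- match(i, erow)
    if (!is.na(j)) {
      pos <- posterior$mean_pos[sig[j]]
      segs[[as.character(c_)]] <- data.frame(
        regime = c(node_regime[p], labels[j]),
        duration = c(pos * len, (1 - pos) * len))
      node_regime[c_] <- labels[j]
      theta[labels[j]] <- posterior$mean_theta[sig[j]]
    } else {
      segs[[as.character(c_)]] <- data.frame(regime = node_regime[p], duration = len)
      node_regime[c_] <- node_regime[p]
    }
  }
  painting <- regime_painting(tree, segs, "base")
  attr(painting, "theta") <- theta
  painting
}
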