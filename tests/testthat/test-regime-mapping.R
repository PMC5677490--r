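test_that("Mk pruning likelihood matches exhaustive enumeration on a 4-tip tree", {
  tr <- balanced4()
  states <- locomotor_habits()
  tips <- stats::setNames(c("fossorial", "generalized", "fossorial", "natatorial"),
                          tr$tip.label)
  for (q in c(0.05, 0.3, 1.1)) {
    Q <- ouregimes:::mk_Q_er(q, states)
    expect_equal(mk_loglik(tr, tips, Q), mk_brute(tr, tips, q, states),
                 tolerance = 1e-10)
  }
})

test_that("Mk rate MLE behaves: zero for constant tips, halves when lengths double", {
  tr <- make_tree(12, 16, seed = 31)
  const <- stats::setNames(rep("fossorial", 12), tr$tip.label)
  f0 <- suppressWarnings(fit_mk(tr, const, states = locomotor_habits()))
  expect_lte(f0$rates, 1e-6)

  set.seed(32)
  tips <- stats::setNames(sample(locomotor_habits(), 12, replace = TRUE),
                          tr$tip.label)
  f1 <- fit_mk(tr, tips)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  f2 <- fit_mk(tr2, tips)
  expect_equal(f2$rates, f1$rates / 2, tolerance = 1e-4)
})

test_that("Mk ML rate agrees with the ape::ace independent route", {
  skip_if_not_installed("ape")
  set.seed(33)
  tr <- make_tree(25, 16, seed = 33)
  sim <- simulate_habits(tr, 0.03, seed = 34)
  f <- fit_mk(tr, sim$tip_states)
  a <- ape::ace(sim$tip_states[tr$tip.label], tr, type = "discrete", model = "ER")
  expect_equal(unname(f$rates), unname(a$rates), tolerance = 1e-3)
})

test_that("sampled mappings conserve segments and pin tip states", {
  tr <- make_tree(15, 16, seed = 41)
  sim <- simulate_habits(tr, 0.03, seed = 42)
  mk <- fit_mk(tr, sim$tip_states)
  maps <- sample_mappings(tr, sim$tip_states, mk, n_samples = 30, seed = 43)
  expect_length(maps, 30)
  for (m in maps) {
    expect_silent(validate_painting(tr, m))
    tipreg <- tip_regimes(tr, m)
    expect_identical(unname(tipreg), unname(sim$tip_states[names(tipreg)]))
  }
  # determinism under seed
  maps2 <- sample_mappings(tr, sim$tip_states, mk, n_samples = 3, seed = 43)
  expect_identical(maps[[1]]$edge_segments, maps2[[1]]$edge_segments)
  # zero-rate model with uniform tips: the single-regime painting every time
  const <- stats::setNames(rep("fossorial", 15), tr$tip.label)
  mk0 <- list(Q = ouregimes:::mk_Q_er(1e-12, locomotor_habits()))
  m0 <- sample_mappings(tr, const, mk0, n_samples = 5, seed = 44)
  for (m in m0) {
    expect_identical(painting_regimes(m), "fossorial")
    expect_true(all(vapply(m$edge_segments, nrow, 0L) == 1))
  }
})

test_that("endpoint-conditioned path sampling matches a rejection-sampling oracle", {
  states <- locomotor_habits()
  Q <- ouregimes:::mk_Q_er(0.08, states)
  t_edge <- 6
  mu <- max(-diag(Q))
  Rmat <- diag(4) + Q / mu
  Rpow <- list(diag(4), Rmat)
  get_Rpow <- function(m) {
    while (length(Rpow) < m + 1) Rpow[[length(Rpow) + 1]] <<- Rpow[[length(Rpow)]] %*% Rmat
    Rpow[[m + 1]]
  }
  P <- ouregimes:::mk_P(Q, t_edge)
  n_changes <- function(segs) nrow(segs) - 1L
  for (ab in list(c(1L, 1L), c(1L, 2L))) {
    set.seed(51)
    ours <- replicate(2000, n_changes(
      ouregimes:::sample_edge_path(ab[1], ab[2], t_edge, mu, Q, P, get_Rpow, states)))
    # oracle: naive forward simulation, keep paths hitting the right endpoint
    set.seed(52)
    kept <- numeric(0)
    while (length(kept) < 2000) {
      s <- ab[1]; tt <- t_edge; ch <- 0L
      repeat {
        w <- rexp(1, -Q[s, s])
        if (w >= tt) break
        tt <- tt - w; ch <- ch + 1L
        s <- sample(setdiff(1:4, s), 1)
      }
      if (s == ab[2]) kept <- c(kept, ch)
    }
    se <- sqrt(var(ours) / 2000 + var(kept) / 2000)
    expect_lt(abs(mean(ours) - mean(kept)), 3 * se + 1e-12)
  }
})

test_that("mapping regime occupancy agrees with phytools::make.simmap", {
  skip_if_not_installed("phytools")
  tr <- make_tree(20, 16, seed = 61)
  sim <- simulate_habits(tr, 0.03, seed = 62)
  mk <- fit_mk(tr, sim$tip_states)
  maps <- sample_mappings(tr, sim$tip_states, mk, n_samples = 150, seed = 63)
  occ <- function(m) {
    segs <- do.call(rbind, m$edge_segments)
    tapply(segs$duration, segs$regime, sum)
  }
  states <- sort(unique(sim$tip_states))
  ours <- rowMeans(vapply(maps, function(m) occ(m)[states], numeric(length(states))),
                   na.rm = TRUE)
  ph <- suppressWarnings(phytools::make.simmap(
    tr, sim$tip_states[tr$tip.label], model = "ER", Q = mk$Q, nsim = 150,
    pi = "equal", message = FALSE))
  theirs <- colMeans(do.call(rbind, lapply(ph, function(s)
    colSums(s$mapped.edge)[states])))
  tot <- sum(tr$edge.length)
  expect_lt(max(abs(ours - theirs)) / tot, 0.05)
})

test_that("fits averaged over mappings match their definition and recover optima", {
  dat <- simulate_dataset(synth_scenario("A", seed = 71))
  tt <- species_means(dat$specimens)
  pca <- suppressWarnings(trait_pca(size_residuals(tt)))
  x <- stats::setNames(pca$scores[, 1], rownames(pca$scores))
  mk <- fit_mk(dat$tree, dat$habits)
  maps <- sample_mappings(dat$tree, dat$habits, mk, n_samples = 20, seed = 72)
  av <- fit_over_mappings(dat$tree, maps, x, "OUM")
  expect_equal(av$n_mappings, 20)
  # definition audit: means equal the column means of the stored draws
  ok <- vapply(av$fits, function(f) isTRUE(f$converged), TRUE)
  recomp <- colMeans(t(vapply(av$fits[ok], function(f)
    unlist(f$params)[names(av$mean_params)], numeric(length(av$mean_params)))))
  expect_equal(av$mean_params, recomp, tolerance = 1e-12)
  expect_equal(av$mean_lnL, mean(vapply(av$fits[ok], function(f) f$lnL, 0)),
               tolerance = 1e-12)
  # identical mappings collapse to the single fit
  av1 <- fit_over_mappings(dat$tree, maps[c(1, 1, 1)], x, "OUM")
  f1 <- fit_evo(dat$tree, x, "OUM", painting = maps[[1]])
  expect_equal(av1$mean_lnL, f1$lnL)
  expect_equal(av1$mean_params, unlist(f1$params)[names(av1$mean_params)])
  # the scansorial optimum separates clearly from the generalized one for
  # scenario-A data (PC1 sign is arbitrary, so compare magnitudes)
  expect_gt(abs(av$mean_params["theta.scansorial"] -
                  av$mean_params["theta.generalized"]), 0.15)
})

test_that("mapping-averaged parameters are Monte-Carlo consistent across batches", {
  dat <- simulate_dataset(synth_scenario("A", seed = 73))
  pca <- suppressWarnings(trait_pca(size_residuals(species_means(dat$specimens))))
  x <- stats::setNames(pca$scores[, 1], rownames(pca$scores))
  mk <- fit_mk(dat$tree, dat$habits)
  b1 <- fit_over_mappings(dat$tree,
                          sample_mappings(dat$tree, dat$habits, mk, 40, seed = 74),
                          x, "OUM")
  b2 <- fit_over_mappings(dat$tree,
                          sample_mappings(dat$tree, dat$habits, mk, 40, seed = 75),
                          x, "OUM")
  # between-batch differences bounded by the within-batch standard errors
  for (nm in c("theta.scansorial", "theta.generalized", "sigma2")) {
    se <- sqrt(stats::var(b1$param_draws[, nm]) / nrow(b1$param_draws) +
                 stats::var(b2$param_draws[, nm]) / nrow(b2$param_draws))
    expect_lt(abs(b1$mean_params[nm] - b2$mean_params[nm]), 4 * se + 1e-8)
  }
})
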