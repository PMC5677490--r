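# a small scenario-A dataset and its PC1 scores, shared across tests
shift_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      dat <- simulate_dataset(synth_scenario("A", seed = 81))
      pca <- suppressWarnings(trait_pca(size_residuals(species_means(dat$specimens))))
      memo <<- list(dat = dat,
                    x = stats::setNames(pca$scores[, 1], rownames(pca$scores)))
    }
    memo
  }
})

test_that("configuration is validated and chains are deterministic under seed", {
  expect_error(shift_config(iterations = 500), "too short")
  expect_error(shift_config(burnin = 1), "burnin")
  expect_error(shift_config(moves = c(birth = 1)), "moves must name")
  bad <- c(birth = 0.5, death = 0.2, slide = 0.05, relocate = 0.05,
           alpha = 0.15, sigma2 = 0.15, theta = 0.2)
  expect_error(shift_config(moves = bad), "sum to 1")

  fx <- shift_fixture()
  cfg <- shift_config(iterations = 2000, burnin = 0.5, thin = 5, seed = 7)
  c1 <- run_shift_chain(fx$dat$tree, fx$x, cfg)
  c2 <- run_shift_chain(fx$dat$tree, fx$x, cfg)
  expect_identical(c1$samples, c2$samples)
  expect_length(c1$samples, 200)
})

test_that("prior-only chains recover the conditional-Poisson shift-count prior", {
  fx <- shift_fixture()
  for (lam in c(0.5, 2)) {
    cfg <- shift_config(iterations = 30000, burnin = 0.2, thin = 20,
                        lambda = lam, seed = 90 + lam * 2, prior_only = TRUE)
    ch <- run_shift_chain(fx$dat$tree, fx$x, cfg)
    ks <- vapply(ch$samples, function(s) nrow(s$shifts), 0L)
    S <- length(ks)
    prior <- shift_count_prior(lam, floor(40 / 2))
    for (k in 0:3) {
      obs <- mean(ks == k)
      se <- sqrt(prior[k + 1] * (1 - prior[k + 1]) / S)
      # allowance for residual autocorrelation at thin = 20
      expect_lt(abs(obs - prior[k + 1]), 3 * se * 2.5 + 0.01)
    }
  }
})

test_that("posterior probabilities equal brute-force counting and obey thresholds", {
  fx <- shift_fixture()
  cfg <- shift_config(iterations = 5000, burnin = 0.4, thin = 5, seed = 11)
  ch <- run_shift_chain(fx$dat$tree, fx$x, cfg)
  post <- shift_posterior(ch, threshold = 0.20)
  # brute-force audit of every branch probability
  for (e in seq_len(ch$n_edges)) {
    cnt <- sum(vapply(ch$samples, function(s) e %in% s$shifts$edge, TRUE))
    expect_equal(post$prob[e], cnt / length(ch$samples))
  }
  expect_true(all(post$prob >= 0 & post$prob <= 1))
  expect_identical(post$significant, which(post$prob >= 0.20))
  # synthetic two-branch case: thresholding keeps only the strong branch
  fake <- ch
  fake$samples <- lapply(seq_len(100), function(i) {
    sh <- data.frame(edge = integer(0), pos = numeric(0), theta = numeric(0))
    if (i <= 73) sh <- rbind(sh, data.frame(edge = 5L, pos = 0.5, theta = 1))
    if (i <= 10) sh <- rbind(sh, data.frame(edge = 9L, pos = 0.2, theta = -1))
    list(shifts = sh, alpha = 0.3, sigma2 = 1, theta0 = 0, lnL = 0, iteration = i)
  })
  pf <- shift_posterior(fake, threshold = 0.20)
  expect_equal(pf$prob[5], 0.73)
  expect_equal(pf$prob[9], 0.10)
  expect_identical(pf$significant, 5L)
  # all samples carrying a shift on a branch gives probability 1
  fake$samples <- lapply(fake$samples, function(s) {
    s$shifts <- data.frame(edge = 3L, pos = 0.4, theta = 2); s })
  expect_equal(shift_posterior(fake)$prob[3], 1)
})

test_that("converting significant shifts yields a consistent painting", {
  fx <- shift_fixture()
  tr <- fx$dat$tree
  cfg <- shift_config(iterations = 5000, burnin = 0.4, thin = 5, seed = 12)
  post <- shift_posterior(run_shift_chain(tr, fx$x, cfg))
  # no significant branch: single-regime painting
  post0 <- post
  post0$prob[] <- 0
  p0 <- shift_painting(tr, post0)
  expect_identical(painting_regimes(p0), "base")
  # one significant shift at position 0.5 splits its branch in half
  post1 <- post0
  e <- which(tr$edge[, 2] > ape::Ntip(tr))[3]
  post1$prob[e] <- 0.9; post1$mean_pos[e] <- 0.5; post1$mean_theta[e] <- 1.5
  p1 <- shift_painting(tr, post1)
  segs <- p1$edge_segments[[as.character(tr$edge[e, 2])]]
  expect_equal(nrow(segs), 2)
  expect_equal(segs$duration, rep(tr$edge.length[e] / 2, 2))
  expect_silent(validate_painting(tr, p1))
  # nested significant shifts: three regimes, tipward regime wins below
  desc_edges <- which(tr$edge[, 1] == tr$edge[e, 2])
  e2 <- desc_edges[1]
  post2 <- post1
  post2$prob[e2] <- 0.8; post2$mean_pos[e2] <- 0.25; post2$mean_theta[e2] <- -2
  p2 <- shift_painting(tr, post2)
  expect_length(painting_regimes(p2), 3)
  expect_silent(validate_painting(tr, p2))
  child2 <- tr$edge[e2, 2]
  below <- ouregimes:::descendant_tips(tr)[[child2]]
  tipr <- tip_regimes(tr, p2)
  expect_true(all(tipr[tr$tip.label[below]] == paste0("shift_", child2)))
})

test_that("two singleton-tip shifts rank first and second in posterior probability", {
  ok <- vapply(1:5, function(r) {
    dat <- simulate_dataset(synth_scenario("B", seed = 8500 + r))
    res <- size_residuals(species_means(dat$specimens))
    x <- stats::setNames(as.vector(res$residuals %*% dat$truth$contrast_unit),
                         rownames(res$residuals))
    ch <- run_shift_chain(dat$tree, x,
                          shift_config(iterations = 60000, burnin = 0.3,
                                       thin = 20, seed = 8600 + r))
    post <- shift_posterior(ch)
    top2 <- post$edge_child[order(post$prob, decreasing = TRUE)[1:2]]
    setequal(top2, dat$truth$shift_edge_child)
  }, TRUE)
  expect_gte(mean(ok), 0.8)
})

test_that("the full PCA pipeline recovers the shifted clade in most replicates", {
  # end-to-end: specimens -> size correction -> PC1 -> rjMCMC. The estimated
  # PC1 rotation mixes the true contrast with phylogenetic pseudo-structure,
  # so recovery is expected in a clear majority (not the near-certainty seen
  # on the true-contrast projection).
  hits <- vapply(1:8, function(r) {
    dat <- simulate_dataset(synth_scenario("A", seed = 8000 + r))
    pca <- suppressWarnings(trait_pca(size_residuals(species_means(dat$specimens))))
    x <- stats::setNames(pca$scores[, 1], rownames(pca$scores))
    ch <- run_shift_chain(dat$tree, x,
                          shift_config(iterations = 20000, burnin = 0.3,
                                       thin = 10, seed = 8200 + r))
    post <- shift_posterior(ch)
    top <- which.max(post$prob)
    post$edge_child[top] == dat$truth$shift_edge_child && post$prob[top] >= 0.20
  }, TRUE)
  expect_gte(mean(hits), 0.5)
})

test_that("a null (no-shift) dataset concentrates posterior mass on zero shifts", {
  dat <- simulate_dataset(synth_scenario("NULL", seed = 83))
  tr <- dat$tree
  cache <- ouregimes:::tree_cache(tr)
  x <- simulate_evo(tr, "OU1", list(alpha = 0.26, sigma2 = 0.05, theta = 0),
                    seed = 84, cache = cache)
  cfg <- shift_config(iterations = 20000, burnin = 0.3, thin = 10,
                      lambda = 0.5, seed = 85)
  ch <- run_shift_chain(tr, x, cfg)
  ks <- vapply(ch$samples, function(s) nrow(s$shifts), 0L)
  mode_k <- as.integer(names(which.max(table(ks))))
  expect_identical(mode_k, 0L)
})
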