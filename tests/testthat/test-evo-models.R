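test_that("model moments match closed forms on small trees", {
  # BM1 on a cherry: no shared path -> identity covariance
  m <- evo_moments(cherry(), "BM1", list(sigma2 = 1, root_value = 0))
  expect_equal(unname(m$cov), diag(2))
  expect_equal(unname(m$mean), c(0, 0))

  # OU1 with alpha -> 0 reproduces BM1 covariance
  tr <- balanced4()
  mb <- evo_moments(tr, "BM1", list(sigma2 = 1.3, root_value = 0))
  mo <- evo_moments(tr, "OU1", list(alpha = 1e-10, sigma2 = 1.3, theta = 0))
  expect_equal(mo$cov, mb$cov, tolerance = 1e-6)

  # EB with rate 0 equals BM1 exactly
  me <- evo_moments(tr, "EB", list(sigma2 = 1.3, eb_rate = 0, root_value = 0))
  expect_lt(max(abs(me$cov - mb$cov)), 1e-12)

  # WN is iid
  mw <- evo_moments(tr, "WN", list(wn_mean = 2, wn_var = 0.5))
  expect_equal(unname(mw$cov), diag(0.5, 4))
  expect_equal(unname(mw$mean), rep(2, 4))
})

test_that("OUM tip expectations match numerical integration of the Hansen weights", {
  tr <- balanced4()
  p <- paint_from_node_states(tr, c("x", "x", "y", "y", "x", "x", "y"))
  alpha <- 0.7
  th <- c(x = -1, y = 2)
  m <- evo_moments(tr, "OUM", list(alpha = alpha, sigma2 = 1, theta = th),
                   painting = p)
  # quadrature oracle: E_i = theta_root e^{-aT} + int_0^T a theta(t) e^{-a(T-t)} dt
  paths <- ouregimes:::painting_paths(tr, p)
  for (i in 1:4) {
    Ti <- 2
    ex <- th[p$root_regime] * exp(-alpha * Ti)
    for (j in seq_len(nrow(paths[[i]]))) {
      seg <- paths[[i]][j, ]
      ex <- ex + th[seg$regime] *
        integrate(function(t) alpha * exp(-alpha * (Ti - t)), seg$t0, seg$t1,
                  rel.tol = 1e-12)$value
    }
    expect_equal(unname(m$mean[i]), unname(ex), tolerance = 1e-8)
  }
})

test_that("tree-model log-likelihoods match the dense brute-force density", {
  # all kinds, random parameters, trees of 4-6 tips, many draws
  set.seed(101)
  kinds <- c("BM1", "OU1", "OUM", "BMS", "EB", "WN")
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    tr <- make_tree(n, 16, seed = 1000 + rep)
    p <- paint_from_node_states(tr, sample(c("r1", "r2"), n + tr$Nnode, replace = TRUE))
    for (kind in kinds) {
      pars <- random_params(kind, painting_regimes(p))
      mom <- evo_moments(tr, kind, pars, painting = p)
      x <- stats::setNames(rnorm(n), tr$tip.label)
      expect_equal(evo_loglik(x, mom),
                   mvn_brute(unname(x), unname(mom$mean), mom$cov),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("log-likelihood is invariant to tip reordering and WN matches dnorm", {
  tr <- study_tree()
  x <- simulate_evo(tr, "BM1", list(sigma2 = 1, root_value = 0), seed = 5)
  mom <- evo_moments(tr, "BM1", list(sigma2 = 1, root_value = 0))
  perm <- sample(seq_along(x))
  expect_equal(evo_loglik(x[perm], mom), evo_loglik(x, mom))
  # single tip white noise standard normal at 0
  mom1 <- list(mean = c(A = 0), cov = matrix(1, 1, 1))
  expect_equal(evo_loglik(c(A = 0), mom1), -0.5 * log(2 * pi))
})

test_that("BM1 closed form on a cherry and WN reduce to textbook MLEs", {
  x <- c(A = 0, B = 2)
  f <- fit_evo(cherry(), x, "BM1")
  expect_equal(unname(f$params$root_value), 1)
  expect_equal(f$params$sigma2, 1)
  # hand formula: -0.5 (2 log(2 pi s2) + log|I| + q/s2), s2 = 1, q = 2
  expect_equal(f$lnL, -(log(2 * pi) + 1))
  expect_equal(f$k, 2L)

  tr <- study_tree()
  xx <- simulate_evo(tr, "OU1", list(alpha = 0.3, sigma2 = 1, theta = 0), seed = 2)
  fw <- fit_evo(tr, xx, "WN")
  expect_equal(fw$params$wn_mean, mean(xx))
  expect_equal(fw$params$wn_var, mean((xx - mean(xx))^2))
  expect_equal(fw$lnL, sum(dnorm(xx, mean(xx), sqrt(fw$params$wn_var), log = TRUE)))
})

test_that("ML fits match a brute-force full-parameter search on a small tree", {
  tr <- make_tree(6, 16, seed = 77)
  x <- simulate_evo(tr, "OU1", list(alpha = 0.2, sigma2 = 0.8, theta = 1), seed = 8)
  f <- fit_evo(tr, x, "OU1")
  # oracle: direct optimisation of the dense MVN density over (alpha, s2, theta)
  obj <- function(par) {
    mom <- evo_moments(tr, "OU1", list(alpha = exp(par[1]), sigma2 = exp(par[2]),
                                       theta = par[3]))
    -mvn_brute(unname(x), unname(mom$mean), mom$cov)
  }
  o <- optim(c(log(0.2), log(0.8), 1), obj, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-12))
  expect_gte(f$lnL + 1e-5, -o$value)  # profile ML at least as good
  expect_equal(f$lnL, -o$value, tolerance = 1e-4)
})

test_that("OU1 collapses to BM1 as alpha approaches zero on fixed data", {
  tr <- study_tree()
  x <- simulate_evo(tr, "BM1", list(sigma2 = 1, root_value = 0), seed = 9)
  lb <- fit_evo(tr, x, "BM1")$lnL
  mo <- evo_moments(tr, "OU1", list(alpha = 1e-8, sigma2 = 1, theta = 0))
  mb <- evo_moments(tr, "BM1", list(sigma2 = 1, root_value = 0))
  expect_equal(evo_loglik(x, mo), evo_loglik(x, mb), tolerance = 1e-4)
  # and the fitted OU1 cannot beat BM1 by more than numerical slack at the
  # boundary when data are truly Brownian-compatible (nested at alpha -> 0)
  lo <- fit_evo(tr, x, "OU1")$lnL
  expect_gte(lo, lb - 1e-4)
})

test_that("simulation is seeded, exact, and matches analytic moments", {
  tr <- cherry()
  pars <- list(sigma2 = 1, root_value = 0)
  s1 <- simulate_evo(tr, "BM1", pars, seed = 3)
  s2 <- simulate_evo(tr, "BM1", pars, seed = 3)
  expect_identical(s1, s2)
  # degenerate diffusion collapses to the root value
  s0 <- simulate_evo(tr, "BM1", list(sigma2 = 1e-12, root_value = 5), seed = 1)
  expect_equal(unname(s0), c(5, 5), tolerance = 1e-4)
  # moment check: 10,000 draws on a cherry within 3 SE of analytic
  set.seed(12)
  draws <- replicate(10000, simulate_evo(tr, "BM1", pars))
  expect_lt(abs(var(draws[1, ]) - 1), 3 * sqrt(2 / 9999))
  expect_lt(abs(cov(draws[1, ], draws[2, ])), 3 / sqrt(9999))
})

test_that("parameter recovery: sigma2 within 15% and theta within 0.1 over replicates", {
  tr <- study_tree()
  cache <- ouregimes:::tree_cache(tr)
  # BM1 and WN rate recovery
  set.seed(21)
  s2_bm <- replicate(200, {
    x <- simulate_evo(tr, "BM1", list(sigma2 = 1, root_value = 0), cache = cache)
    fit_evo(tr, x, "BM1", cache = cache)$params$sigma2
  })
  expect_lt(abs(mean(s2_bm) - 1), 0.15)
  set.seed(22)
  v_wn <- replicate(200, {
    x <- simulate_evo(tr, "WN", list(wn_mean = 0, wn_var = 1), cache = cache)
    fit_evo(tr, x, "WN", cache = cache)$params$wn_var
  })
  expect_lt(abs(mean(v_wn) - 1), 0.15)
  # OU1 theta recovery
  set.seed(23)
  th <- replicate(200, {
    x <- simulate_evo(tr, "OU1", list(alpha = 0.26, sigma2 = 1, theta = 0),
                      cache = cache)
    fit_evo(tr, x, "OU1", cache = cache)$params$theta
  })
  expect_lt(abs(mean(th)), 0.1)
})

test_that("estimated-root OU nests the fixed-root convention", {
  tr <- make_tree(12, 16, seed = 55)
  set.seed(56)
  p <- paint_from_node_states(tr, sample(c("g", "s"), 23, replace = TRUE))
  x <- simulate_evo(tr, "OUM",
                    list(alpha = 0.3, sigma2 = 0.5, theta = c(g = 0, s = 1)),
                    painting = p, seed = 57)
  f_fix <- fit_evo(tr, x, "OUM", painting = p)
  f_est <- fit_evo(tr, x, "OUM", painting = p,
                   control = evo_control(ou_root = "estimated"))
  expect_equal(f_est$k, f_fix$k + 1L)
  expect_gte(f_est$lnL, f_fix$lnL - 1e-6)
  # the estimated-root moments reproduce the fitted likelihood
  mom <- evo_moments(tr, "OUM", f_est$params, painting = p)
  expect_equal(evo_loglik(x, mom), f_est$lnL, tolerance = 1e-6)
})

test_that("half-life follows ln(2)/alpha", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.26), log(2) / 0.26)
  expect_equal(round(half_life(0.26), 3), 2.666)
  expect_equal(round(half_life(0.11), 3), 6.301)
  expect_error(half_life(0), "alpha")
})

test_that("OU moments refuse non-ultrametric trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  expect_error(evo_moments(tr, "OU1", list(alpha = 0.3, sigma2 = 1, theta = 0)),
               "ultrametric")
})
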