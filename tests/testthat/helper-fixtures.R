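# shared fixtures and independent oracles, all built in code

cherry <- function() read_dated_tree("(A:1,B:1);")

balanced4 <- function() read_dated_tree("((A:1,B:1):1,(C:1,D:1):1);")

# a fixed 40-tip, 16-My pure-birth tree used by the larger studies
study_tree <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- make_tree(40, 16, seed = 20260901)
    memo
  }
})

# dense brute-force multivariate-normal log density via explicit inverse;
# deliberately naive, independent of the package's Cholesky route
mvn_brute <- function(x, mu, V) {
  n <- length(x)
  r <- x - mu
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
            drop(t(r) %*% solve(V) %*% r))
}

# equal-rates Mk transition matrix written independently of the package
er_P <- function(q, k, t) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- (1 + (k - 1) * e) / k
  P
}

# brute-force Mk likelihood by enumerating all internal-node assignments
mk_brute <- function(tree, tip_states, q, states) {
  k <- length(states)
  n <- ape::Ntip(tree)
  nodes <- (n + 1):(n + tree$Nnode)
  tip_idx <- match(tip_states[tree$tip.label], states)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), length(nodes)))
  tot <- 0
  for (g in seq_len(nrow(grids))) {
    assign_ <- c(tip_idx, as.integer(grids[g, ]))
    pr <- 1 / k   # uniform root prior
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign_[tree$edge[e, 1]]; b <- assign_[tree$edge[e, 2]]
      pr <- pr * er_P(q, k, tree$edge.length[e])[a, b]
    }
    tot <- tot + pr
  }
  log(tot)
}

# random regime painting on a tree: assigns random node states, midpoint rule
random_painting <- function(tree, regimes = c("r1", "r2"), seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  nn <- ape::Ntip(tree) + tree$Nnode
  withr_seed(paint_from_node_states(tree, sample(regimes, nn, replace = TRUE)))
}

# random parameter draw for a given model kind (painting regimes if needed)
random_params <- function(kind, regimes = NULL) {
  switch(kind,
    BM1 = list(sigma2 = runif(1, 0.1, 3), root_value = rnorm(1)),
    OU1 = list(alpha = runif(1, 0.05, 1), sigma2 = runif(1, 0.1, 3),
               theta = rnorm(1)),
    OUM = list(alpha = runif(1, 0.05, 1), sigma2 = runif(1, 0.1, 3),
               theta = stats::setNames(rnorm(length(regimes)), regimes)),
    BMS = list(sigma2 = stats::setNames(runif(length(regimes), 0.1, 3), regimes),
               root_value = rnorm(1)),
    EB = list(sigma2 = runif(1, 0.1, 3), eb_rate = -runif(1, 0, 1),
              root_value = rnorm(1)),
    WN = list(wn_mean = rnorm(1), wn_var = runif(1, 0.1, 3)))
}
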