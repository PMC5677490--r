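#' Synthetic-study scenario definition
#'
#' Defines the generating conditions for a synthetic mustelid-like dataset:
#' a dated pure-birth tree (default 40 tips, 16 My tall, matching the scale
#' of the empirical system), 4-state equal-rates habit evolution, and 14
#' log-normal traits built as a shared Brownian allometric size factor plus
#' habit-structured OU deviations, sampled as 1-6 specimens per species with
#' log-normal measurement error.
#'
#' Scenarios: \code{"A"} places one shift in the deviation optima on the stem
#' branch of a mid-sized clade (5-10 tips) whose members are also assigned
#' the scansorial habit — a detectable clade-level regime shift;
#' \code{"B"} places shifts on two terminal branches (one optimum up, one
#' down), emulating two singleton specialists; \code{"NULL"} evolves
#' deviations under single-regime Brownian motion with no shift.
#'
#' Default effect size for the shifted optima is 2 stationary standard
#' deviations of the OU deviation process per trait — comfortably detectable
#' at 40 tips without being trivial.
#'
#' @param id \code{"A"}, \code{"B"} or \code{"NULL"}.
#' @param n_tips,height tree size and root age (My).
#' @param mk_rate per-pair habit transition rate (1/My).
#' @param alpha,stat_sd OU attraction rate and stationary sd of the trait
#'   deviations (\code{sigma2 = 2 * alpha * stat_sd^2}).
#' @param effect_sd scenario-A shift magnitude: the optimum moves by this
#'   many stationary sds per trait (clade tips have several half-lives to
#'   equilibrate, so the expressed displacement is close to this).
#' @param effect_sd_b scenario-B expressed displacement: each singleton tip's
#'   expected deviation is this many stationary sds at the tip, i.e. the raw
#'   optimum is inflated by \code{1/(1 - exp(-alpha t/2))} to undo the
#'   attenuation over the short post-shift time on a terminal branch. The
#'   default (4) emulates singletons at the extremes of the trait axis.
#' @param slopes,intercepts allometric log-log slopes and intercepts per
#'   trait; defaults are near-isometric slopes and intercepts at realistic
#'   mm magnitudes for mustelid forelimb elements.
#' @param size_sigma2 Brownian rate of the log size factor (1/My).
#' @param spec_range range of specimens per species.
#' @param cv within-species coefficient of variation of measurements.
#' @param seed master seed; all stages derive child seeds from it.
#' @return a list of class \code{synth_scenario}.
#' @export
synth_scenario <- function(id = c("A", "B", "NULL"),
                           n_tips = 40L, height = 16,
                           mk_rate = 0.02,
                           alpha = 0.26, stat_sd = 0.05, effect_sd = 2,
                           effect_sd_b = 4,
                           slopes = NULL, intercepts = NULL,
                           size_sigma2 = 0.02,
                           spec_range = c(1L, 6L), cv = 0.05,
                           seed = 1L) {
  id <- match.arg(id)
  traits <- forelimb_traits()
  if (is.null(slopes)) {
    slopes <- rep(1, 14) + c(-0.04, 0.06, -0.02, 0.0, 0.08, 0.02, 0.05,
                             -0.05, -0.03, 0.04, -0.02, 0.01, 0.06, 0.03)
  }
  if (is.null(intercepts)) {
    typical_mm <- c(40, 55, 5, 5.5, 25, 12, 45, 4, 4.5, 55, 5, 4, 12, 20)
    intercepts <- log(typical_mm)
  }
  names(slopes) <- names(intercepts) <- traits
  # loading pattern of the shifted optimum: gracile (+: bone lengths, deltoid
  # ridge, ulnar ML) vs robust (-: shaft diameters, olecranon, epicondyle).
  # The pattern is balanced (sums to zero) so the shift is a pure shape
  # contrast: it leaves the geometric mean untouched and cannot leak into the
  # allometric size regression.
  contrast_sign <- stats::setNames(
    c(1, 1, -1, -1, 1, -1, 1, -1, -1, 1, -1, 1, -1, 1), traits)
  structure(list(id = id, n_tips = as.integer(n_tips), height = height,
                 mk_rate = mk_rate, alpha = alpha, stat_sd = stat_sd,
                 ou_sigma2 = 2 * alpha * stat_sd^2,
                 bm_sigma2 = stat_sd^2 / height,
                 effect_sd = effect_sd, effect_sd_b = effect_sd_b,
                 contrast_sign = contrast_sign,
                 slopes = slopes, intercepts = intercepts,
                 size_sigma2 = size_sigma2,
                 spec_range = as.integer(spec_range), cv = cv,
                 seed = as.integer(seed)),
            class = "synth_scenario")
}

#' Simulate a dated pure-birth tree of fixed height
#'
#' Pure-birth (Yule) topology and node times, rescaled so the root age equals
#' \code{height}; tips are relabelled \code{sp01, sp02, ...}.
#'
#' @param n_tips number of extant tips (>= 3).
#' @param height root age in My.
#' @param seed integer seed.
#' @return a dated \code{phylo} tree.
#' @export
make_tree <- function(n_tips, height = 16, seed = NULL) {
  if (n_tips < 3L) stop("need n_tips >= 3")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length * (height / tree_height(tree))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  validate_dated_tree(tree)
  tree
}

#' Simulate 4-state locomotor-habit evolution
#'
#' Equal-rates Markov simulation of the four habits from a uniform root
#' state, root to tips. If all tips end in one state at the given rate the
#' simulation is redrawn (up to 20 times) so downstream regime models have
#' something to work with; a warning is issued if variation never appears.
#'
#' @param tree a dated tree.
#' @param rate per-pair transition rate (1/My), > 0.
#' @param seed integer seed.
#' @return list with \code{tip_states} (named by tip label) and
#'   \code{node_states} (all nodes; ground truth for validation only).
#' @export
simulate_habits <- function(tree, rate, seed = NULL) {
  if (rate <= 0) stop("rate must be > 0")
  states <- locomotor_habits()
  k <- length(states)
  with_seed(seed, {
    for (try in 1:20) {
      ns <- sim_mk_once(tree, rate, k)
      if (length(unique(ns[seq_len(ape::Ntip(tree))])) > 1L) break
    }
    if (length(unique(ns[seq_len(ape::Ntip(tree))])) == 1L)
      warning("all tips share one habit after 20 attempts; increase rate")
    tips <- stats::setNames(states[ns[seq_len(ape::Ntip(tree))]], tree$tip.label)
    list(tip_states = tips, node_states = states[ns])
  })
}

sim_mk_once <- function(tree, rate, k) {
  nn <- ape::Ntip(tree) + tree$Nnode
  ns <- integer(nn)
  root <- ape::Ntip(tree) + 1L
  ns[root] <- sample.int(k, 1L)
  tr <- reorder(tree, "cladewise")
  leave <- (k - 1L) * rate
  for (i in seq_len(nrow(tr$edge))) {
    s <- ns[tr$edge[i, 1L]]
    t_rem <- tr$edge.length[i]
    repeat {
      w <- stats::rexp(1, leave)
      if (w >= t_rem) break
      t_rem <- t_rem - w
      s <- sample(setdiff(seq_len(k), s), 1L)
    }
    ns[tr$edge[i, 2L]] <- s
  }
  ns
}

# deterministically pick the clade whose stem will carry the scenario-A
# shift: among internal edges subtending 5-10 tips, the count closest to 7
pick_shift_clade <- function(tree) {
  desc <- descendant_tips(tree)
  cnt <- vapply(tree$edge[, 2L], function(nd) length(desc[[nd]]), 0L)
  lo <- 5L; hi <- 10L
  cand <- which(cnt >= lo & cnt <= hi)
  while (length(cand) == 0L) { lo <- max(2L, lo - 1L); hi <- hi + 2L
    cand <- which(cnt >= lo & cnt <= hi) }
  cand[order(abs(cnt[cand] - 7L), tree$edge[cand, 2L])][1L]
}

# painting with one regime shift partway along the given edges
shift_painting_at <- function(tree, edges, pos = 0.5,
                              labels = paste0("shift_", tree$edge[edges, 2L])) {
  segs <- vector("list", nrow(tree$edge))
  names(segs) <- as.character(tree$edge[, 2L])
  node_regime <- rep("base", ape::Ntip(tree) + tree$Nnode)
  ord <- order(node_depths(tree)[tree$edge[, 2L]])
  for (i in ord) {
    p <- tree$edge[i, 1L]; c_ <- tree$edge[i, 2L]; len <- tree$edge.length[i]
    j <- match(i, edges)
    if (!is.na(j)) {
      segs[[as.character(c_)]] <- data.frame(
        regime = c(node_regime[p], labels[j]),
        duration = c(pos * len, (1 - pos) * len))
      node_regime[c_] <- labels[j]
    } else {
      segs[[as.character(c_)]] <- data.frame(regime = node_regime[p], duration = len)
      node_regime[c_] <- node_regime[p]
    }
  }
  regime_painting(tree, segs, "base")
}

#' Simulate a full specimen-level dataset with known ground truth
#'
#' Generates a dated tree, a habit history, latent species trait values and a
#' specimen table under the scenario's model: log trait = intercept + slope x
#' (Brownian log size factor) + OU/BM deviation, with the deviation optima
#' shifted according to the scenario. In scenario A the shifted clade's tips
#' are additionally assigned the scansorial habit, so the discrete map and
#' the continuous shift agree as they do in the empirical system.
#'
#' @param scenario a \code{\link{synth_scenario}}.
#' @return list of class \code{synth_data}: \code{specimens} (data.frame),
#'   \code{tree}, \code{habits} (named character), and \code{truth} — a
#'   record of every generating parameter, the latent log trait table, the
#'   deviations, the size factor and the shifted branches, sufficient to
#'   reconstruct the latent data exactly.
#' @export
simulate_dataset <- function(scenario) {
  sc <- scenario
  traits <- forelimb_traits()
  tree <- make_tree(sc$n_tips, sc$height, child_seed(sc$seed, 1L))
  hb <- simulate_habits(tree, sc$mk_rate, child_seed(sc$seed, 2L))
  n <- ape::Ntip(tree)
  cache <- tree_cache(tree)

  shift_edges <- integer(0)
  painting <- NULL
  if (sc$id == "A") {
    shift_edges <- pick_shift_clade(tree)
  } else if (sc$id == "B") {
    tip_edges <- which(tree$edge[, 2L] <= n)
    # restrict to terminal branches of at least median length: a shift on a
    # very short pendant edge has almost no time to be expressed
    elig <- tip_edges[tree$edge.length[tip_edges] >=
                        stats::median(tree$edge.length[tip_edges])]
    shift_edges <- with_seed(child_seed(sc$seed, 3L),
                             sort(sample(elig, 2L)))
  }
  if (length(shift_edges))
    painting <- shift_painting_at(tree, shift_edges, pos = 0.5)

  # shifted clade tips get the scansorial habit in scenario A
  habits <- hb$tip_states
  if (sc$id == "A") {
    clade_tips <- descendant_tips(tree)[[tree$edge[shift_edges, 2L]]]
    habits[tree$tip.label[clade_tips]] <- "scansorial"
    if (length(unique(habits)) == 1L) habits[1L] <- "generalized"
  }

  # latent size factor: BM on the tree
  s <- with_seed(child_seed(sc$seed, 4L), {
    R <- chol(sc$size_sigma2 * cache$Tsh)
    as.vector(crossprod(R, stats::rnorm(n)))
  })
  names(s) <- tree$tip.label

  # deviations: one independent draw per trait from the scenario model
  theta_shift <- sc$effect_sd * sc$stat_sd * sc$contrast_sign
  shift_labels <- paste0("shift_", tree$edge[shift_edges, 2L])
  shift_comp <- if (sc$id == "B")
    (sc$effect_sd_b / sc$effect_sd) /
      (1 - exp(-sc$alpha * tree$edge.length[shift_edges] / 2))
  else rep(1, length(shift_edges))
  dev <- with_seed(child_seed(sc$seed, 5L), {
    if (sc$id == "NULL") {
      R <- chol(sc$bm_sigma2 * cache$Tsh)
      vapply(seq_along(traits), function(j) as.vector(crossprod(R, stats::rnorm(n))),
             numeric(n))
    } else {
      pc <- tree_cache(tree, painting)
      V0 <- evo_structure("OU1", pc, alpha = sc$alpha)
      R <- chol(sc$ou_sigma2 * V0)
      W <- hansen_weights(pc, sc$alpha)
      # scenario B inflates the optimum to undo attenuation over the short
      # post-shift time, so the expressed tip displacement is effect_sd_b sds
      vapply(seq_along(traits), function(j) {
        th <- stats::setNames(numeric(length(pc$regimes)), pc$regimes)
        if (sc$id == "A") {
          th[shift_labels] <- theta_shift[j]
        } else {
          th[shift_labels[1L]] <- theta_shift[j] * shift_comp[1L]
          th[shift_labels[2L]] <- -theta_shift[j] * shift_comp[2L]
        }
        mu <- as.vector(W %*% th[colnames(W)])
        mu + as.vector(crossprod(R, stats::rnorm(n)))
      }, numeric(n))
    }
  })
  colnames(dev) <- traits; rownames(dev) <- tree$tip.label

  latent_log <- outer(s, sc$slopes) + matrix(sc$intercepts, n, 14, byrow = TRUE) + dev
  dimnames(latent_log) <- list(tree$tip.label, traits)

  specimens <- with_seed(child_seed(sc$seed, 6L), {
    n_spec <- sample(seq(sc$spec_range[1L], sc$spec_range[2L]), n, replace = TRUE)
    sdlog <- sqrt(log(1 + sc$cv^2))
    rows <- lapply(seq_len(n), function(i) {
      m <- n_spec[i]
      noise <- if (sdlog > 0) matrix(stats::rnorm(m * 14, 0, sdlog), m, 14) else
        matrix(0, m, 14)
      vals <- exp(matrix(latent_log[i, ], m, 14, byrow = TRUE) + noise)
      colnames(vals) <- traits
      data.frame(specimen = sprintf("%s_%02d", tree$tip.label[i], seq_len(m)),
                 species = tree$tip.label[i], vals, check.names = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(specimens) <- NULL

  truth <- list(scenario = sc, shift_edges = shift_edges,
                shift_edge_child = tree$edge[shift_edges, 2L],
                shift_tips = if (length(shift_edges) && sc$id == "A")
                  tree$tip.label[descendant_tips(tree)[[tree$edge[shift_edges, 2L]]]]
                else if (sc$id == "B") tree$tip.label[tree$edge[shift_edges, 2L]]
                else character(0),
                theta_shift = theta_shift, shift_scale = shift_comp,
                contrast_unit = sc$contrast_sign / sqrt(14),
                painting = painting,
                node_habits = hb$node_states, size_factor = s,
                deviations = dev, latent_log = latent_log)
  structure(list(specimens = specimens, tree = tree, habits = habits,
                 truth = truth),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("Synthetic dataset (scenario %s, seed %d): %d species, %d specimens\n",
              x$truth$scenario$id, x$truth$scenario$seed,
              ape::Ntip(x$tree), nrow(x$specimens)))
  if (length(x$truth$shift_edges))
    cat("true shifted branch(es): child node(s)",
        paste(x$truth$shift_edge_child, collapse = ", "), "\n")
  cat("habit counts:\n"); print(table(x$habits))
  invisible(x)
}
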