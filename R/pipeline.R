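#' Pipeline run configuration
#'
#' Collects input paths, the output directory, the master seed and per-stage
#' parameter blocks for the file-based pipeline drivers
#' (\code{\link{pipeline_simulate}}, \code{\link{pipeline_prep}},
#' \code{\link{pipeline_fit_all}}, \code{\link{pipeline_adequacy}}). The
#' master seed fans out to fixed per-stage child seeds, so every stage is
#' individually reproducible. \code{production = TRUE} switches to the full
#' study protocol (1,500,000-iteration shift chains, 10,000 adequacy
#' iterations, 500 mappings); the default settings are scaled for interactive
#' use.
#'
#' @param outdir output directory (created if missing).
#' @param specimens,tree,habits input file paths (CSV / Newick / CSV); if
#'   \code{NULL} they default to the files \code{pipeline_simulate} writes
#'   into \code{outdir}.
#' @param seed non-negative integer master seed.
#' @param scenario synthetic scenario id for \code{pipeline_simulate}.
#' @param n_mappings stochastic mappings for the averaged models.
#' @param shift_iterations,adequacy_iterations chain / bootstrap lengths.
#' @param production use the full study protocol lengths.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(outdir, specimens = NULL, tree = NULL, habits = NULL,
                       seed = 1L, scenario = "A",
                       n_mappings = 100L, shift_iterations = 20000L,
                       adequacy_iterations = 200L, production = FALSE) {
  if (seed < 0) stop("seed must be a non-negative integer")
  if (production) {
    n_mappings <- 500L; shift_iterations <- 1500000L; adequacy_iterations <- 10000L
  }
  structure(list(outdir = outdir,
                 specimens = specimens %||% file.path(outdir, "specimens.csv"),
                 tree = tree %||% file.path(outdir, "tree.nwk"),
                 habits = habits %||% file.path(outdir, "habits.csv"),
                 seed = as.integer(seed), scenario = scenario,
                 n_mappings = as.integer(n_mappings),
                 shift_iterations = as.integer(shift_iterations),
                 adequacy_iterations = as.integer(adequacy_iterations)),
            class = "run_config")
}

log_line <- function(config, stage, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " stage=", stage, " ",
                paste(..., sep = " "))
  cat(msg, "\n", file = file.path(config$outdir, "pipeline.log"), append = TRUE)
  invisible(msg)
}

#' Simulate a scenario dataset to disk
#'
#' Writes \code{specimens.csv}, \code{tree.nwk}, \code{habits.csv} and
#' \code{truth.json} into the configured output directory.
#'
#' @param config a \code{\link{run_config}}.
#' @return the \code{synth_data} object, invisibly.
#' @export
pipeline_simulate <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- synth_scenario(config$scenario, seed = child_seed(config$seed, 11L))
  dat <- simulate_dataset(sc)
  utils::write.csv(dat$specimens, config$specimens, row.names = FALSE)
  write_dated_tree(dat$tree, config$tree)
  utils::write.csv(data.frame(species = names(dat$habits), habit = dat$habits),
                   config$habits, row.names = FALSE)
  truth <- list(scenario = sc$id, seed = sc$seed, n_tips = sc$n_tips,
                height = sc$height, mk_rate = sc$mk_rate, alpha = sc$alpha,
                stat_sd = sc$stat_sd, ou_sigma2 = sc$ou_sigma2,
                effect_sd = sc$effect_sd,
                shift_edge_child = dat$truth$shift_edge_child,
                shift_tips = dat$truth$shift_tips)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             file.path(config$outdir, "truth.json"))
  log_line(config, "simulate", paste0("scenario=", sc$id),
           paste0("seed=", config$seed), paste0("n=", ape::Ntip(dat$tree)))
  invisible(dat)
}

#' Size correction and PCA stage
#'
#' Reads the specimen table, computes species means, size-corrected log
#' residuals and the covariance PCA with broken-stick selection, and writes
#' \code{means.csv}, \code{residuals.csv}, \code{loadings.csv},
#' \code{scores.csv} and \code{pca.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @return the \code{trait_pca} object, invisibly.
#' @export
pipeline_prep <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  specimens <- utils::read.csv(config$specimens, check.names = FALSE)
  tt <- species_means(specimens)
  rm_ <- size_residuals(tt)
  pca <- trait_pca(rm_)
  utils::write.csv(tt, file.path(config$outdir, "means.csv"))
  utils::write.csv(rm_$residuals, file.path(config$outdir, "residuals.csv"))
  utils::write.csv(pca$loadings, file.path(config$outdir, "loadings.csv"))
  utils::write.csv(pca$scores, file.path(config$outdir, "scores.csv"))
  writeLines(jsonlite::toJSON(list(
    proportions = pca$proportions, broken_stick = pca$broken_stick,
    significant = pca$significant), auto_unbox = FALSE, digits = NA),
    file.path(config$outdir, "pca.json"))
  log_line(config, "prep", paste0("n_species=", nrow(tt)),
           paste0("significant=", paste(pca$significant, collapse = "+")))
  invisible(pca)
}

#' Fit the full model suite to one PC axis
#'
#' Runs the seven-model comparison on the chosen PC score column:
#' the unconstrained shift model (rjMCMC, converted to a fixed painting),
#' single-rate BM, multirate BM and multi-optima OU (both averaged over
#' stochastic habit mappings), single-optimum OU, early burst and white
#' noise. Writes \code{comparison_pc<k>.csv}, a JSON version, and a run
#' bundle \code{fit_context_pc<k>.rds} for the adequacy stage.
#'
#' @param config a \code{\link{run_config}}.
#' @param pc PC axis index.
#' @return the \code{comparison_table}, invisibly.
#' @export
pipeline_fit_all <- function(config, pc = 1L) {
  scores <- utils::read.csv(file.path(config$outdir, "scores.csv"), row.names = 1L)
  tree <- read_dated_tree(file = config$tree)
  hab <- utils::read.csv(config$habits)
  habits <- stats::setNames(as.character(hab$habit), hab$species)
  x <- stats::setNames(scores[, pc], rownames(scores))

  fit_bm1 <- fit_evo(tree, x, "BM1")
  fit_ou1 <- fit_evo(tree, x, "OU1")
  fit_eb <- fit_evo(tree, x, "EB")
  fit_wn <- fit_evo(tree, x, "WN")

  mk <- fit_mk(tree, habits)
  maps <- sample_mappings(tree, habits, mk, config$n_mappings,
                          seed = child_seed(config$seed, 21L))
  fit_oum <- fit_over_mappings(tree, maps, x, "OUM")
  fit_bms <- fit_over_mappings(tree, maps, x, "BMS")

  cfg <- shift_config(iterations = config$shift_iterations,
                      seed = child_seed(config$seed, 31L))
  chain <- run_shift_chain(tree, x, cfg)
  post <- shift_posterior(chain)
  utils::write.csv(data.frame(edge = seq_along(post$prob),
                              child_node = post$edge_child,
                              prob = post$prob, mean_pos = post$mean_pos,
                              mean_theta = post$mean_theta),
                   file.path(config$outdir, sprintf("shifts_pc%d.csv", pc)),
                   row.names = FALSE)
  conv <- shift_painting(tree, post)
  fit_unc <- fit_evo(tree, x, if (length(painting_regimes(conv)) > 1L) "OUM" else "OU1",
                     painting = if (length(painting_regimes(conv)) > 1L) conv else NULL)

  tab <- build_comparison_table(
    list(fit_unc, fit_bm1, fit_bms, fit_ou1, fit_oum, fit_eb, fit_wn),
    labels = c(sprintf("Unconstrained OU (%d)", length(painting_regimes(conv))),
               "Single-rate BM", "Multirate BM", "Single-optimum OU",
               "Multi-optima OU", "Early burst", "White noise"))
  utils::write.csv(as.data.frame(tab), file.path(config$outdir,
                                                 sprintf("comparison_pc%d.csv", pc)),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(as.data.frame(tab), digits = NA, auto_unbox = TRUE),
             file.path(config$outdir, sprintf("comparison_pc%d.json", pc)))
  saveRDS(list(tree = tree, x = x, posterior = post, painting = conv,
               fits = list(unconstrained = fit_unc, bm1 = fit_bm1),
               table = tab),
          file.path(config$outdir, sprintf("fit_context_pc%d.rds", pc)))
  log_line(config, "fit_all", paste0("pc=", pc),
           paste0("best=", tab$model[attr(tab, "best")]))
  invisible(tab)
}

#' Adequacy stage: best model vs the Brownian null
#'
#' Loads the fit context written by \code{\link{pipeline_fit_all}} and runs
#' the phylogenetic Monte Carlo likelihood-ratio test of the converted
#' unconstrained model against single-rate BM, writing
#' \code{adequacy_pc<k>.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @param pc PC axis index.
#' @return the \code{pmc_test} object, invisibly.
#' @export
pipeline_adequacy <- function(config, pc = 1L) {
  ctx_path <- file.path(config$outdir, sprintf("fit_context_pc%d.rds", pc))
  if (!file.exists(ctx_path)) stop("run pipeline_fit_all first: missing ", ctx_path)
  ctx <- readRDS(ctx_path)
  multi <- length(painting_regimes(ctx$painting)) > 1L
  res <- pmc_test(ctx$tree, ctx$x,
                  null_spec = list(kind = "BM1"),
                  alt_spec = if (multi) list(kind = "OUM", painting = ctx$painting)
                             else list(kind = "OU1"),
                  n_iter = config$adequacy_iterations,
                  seed = child_seed(config$seed, 41L))
  writeLines(jsonlite::toJSON(list(
    lr_obs = res$lr_obs, ci_null = res$ci_null, ci_alt = res$ci_alt,
    verdict = res$verdict, n_iter = res$n_iter, dropped = res$dropped),
    auto_unbox = TRUE, digits = NA),
    file.path(config$outdir, sprintf("adequacy_pc%d.json", pc)))
  log_line(config, "adequacy", paste0("pc=", pc), paste0("verdict=", res$verdict))
  invisible(res)
}
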