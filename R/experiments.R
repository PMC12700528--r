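#' @title Scripted parameter-recovery experiments
#' @description End-to-end in-silico recovery studies: a synthetic connectome
#' and ground-truth parameter set generate one observation; a prior-predictive
#' simulation batch trains a conditional flow; the posterior for the
#' observation is sampled and scored with shrinkage/z-score diagnostics.
#' Presets reproduce the published recovery studies at desk scale (20
#' regions, thousands of simulations) with the published ground truths and
#' priors.
#' @name experiments
NULL

#' Build a recovery experiment configuration
#'
#' @param model_id registered model name.
#' @param theta_true named list/vector of ground-truth parameters (must lie
#'   inside the prior box).
#' @param prior a [prior_spec()].
#' @param recipe a [feature_recipe()].
#' @param simulator `function(theta_row, sc, seed)` (see
#'   [run_simulation_batch()]).
#' @param n_sim simulation budget.
#' @param family flow family, `"maf"` or `"nsf"`.
#' @param n_regions,density,connectome_seed synthetic connectome settings.
#' @param seed master seed (observation, batch, training, and sampling seeds
#'   derive from it).
#' @param n_draws posterior draws for diagnostics.
#' @param train_args extra arguments for [train_posterior_estimator()].
#' @return a `recovery_config`.
#' @export
recovery_config <- function(model_id, theta_true, prior, recipe, simulator,
                            n_sim, family = "maf", n_regions = 20,
                            density = 0.35, connectome_seed = 42, seed = 1,
                            n_draws = 10000, train_args = list()) {
  theta_true <- unlist(theta_true)
  if (!all(prior$name %in% names(theta_true)))
    stop("theta_true must name every prior parameter")
  theta_true <- theta_true[prior$name]
  if (any(theta_true < prior$lower | theta_true > prior$upper))
    stop("ground truth lies outside the prior box: ",
         paste(prior$name[theta_true < prior$lower | theta_true > prior$upper],
               collapse = ", "))
  structure(list(model_id = model_id, theta_true = theta_true, prior = prior,
                 recipe = recipe, simulator = simulator, n_sim = n_sim,
                 family = family, n_regions = n_regions, density = density,
                 connectome_seed = connectome_seed, seed = seed,
                 n_draws = n_draws, train_args = train_args),
            class = "recovery_config")
}

#' Run a recovery experiment end to end
#'
#' @param config a [recovery_config()].
#' @param sc optional pre-built normalized connectome (else synthesized from
#'   the config).
#' @param progress print batch progress.
#' @param out_dir optional directory; when given, the dataset (NPZ), the
#'   estimator (RDS), the report (JSON), and a manifest of every seed are
#'   written there.
#' @return a `recovery_result`: observation features, dataset, estimator,
#'   posterior samples, diagnostics report, and the manifest.
#' @export
run_recovery <- function(config, sc = NULL, progress = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "recovery_config"))
  if (is.null(sc)) {
    sc <- normalize_connectome(generate_synthetic_connectome(
      config$n_regions, config$density, config$connectome_seed))
  }
  seed_obs <- derive_seed(config$seed, 1)
  seed_batch <- derive_seed(config$seed, 2)
  seed_train <- derive_seed(config$seed, 3)
  seed_draw <- derive_seed(config$seed, 4)

  obs_sim <- config$simulator(config$theta_true, sc, seed_obs)
  x_obs <- apply_recipe(config$recipe, obs_sim)

  dataset <- run_simulation_batch(sc, config$prior, config$n_sim,
                                  config$simulator, config$recipe,
                                  seed = seed_batch, progress = progress)
  est <- do.call(train_posterior_estimator,
                 c(list(data = dataset, family = config$family,
                        seed = seed_train), config$train_args))
  samples <- sample_posterior(est, x_obs, n_draws = config$n_draws,
                              seed = seed_draw)
  report <- diagnostics_report(samples, config$theta_true)
  manifest <- list(model_id = config$model_id, seed = config$seed,
                   seed_obs = seed_obs, seed_batch = seed_batch,
                   seed_train = seed_train, seed_draw = seed_draw,
                   connectome_seed = config$connectome_seed,
                   n_regions = config$n_regions, density = config$density,
                   n_sim = config$n_sim, family = config$family,
                   recipe_id = config$recipe$id,
                   theta_true = as.list(config$theta_true),
                   n_failed = dataset$n_failed)
  result <- structure(list(config = config, sc = sc, x_obs = x_obs,
                           dataset = dataset, estimator = est,
                           samples = samples, report = report,
                           manifest = manifest),
                      class = "recovery_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_npz(file.path(out_dir, "dataset.npz"),
              theta = dataset$theta, features = dataset$features)
    saveRDS(est, file.path(out_dir, "estimator.rds"))
    write_report_json(report, file.path(out_dir, "report.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %s (%s flow, %d sims)\n",
              x$config$model_id, x$config$family, x$config$n_sim))
  print(tidy(x$report))
  invisible(x)
}

#' Classify regions by epileptogenicity from posterior-mean excitability
#'
#' Nearest-centroid assignment of each region's posterior-mean excitability
#' to the epileptogenic-zone (EZ), propagation-zone (PZ), or healthy class.
#'
#' @param posterior_means numeric vector of per-region posterior-mean
#'   excitability.
#' @param centroids named 3-vector of class centroids, strictly ordered
#'   (EZ > PZ > healthy on the excitability scale).
#' @return character vector of labels `"EZ"`, `"PZ"`, `"healthy"`.
#' @export
classify_epileptogenicity <- function(posterior_means,
                                      centroids = c(EZ = -1.6, PZ = -2.2,
                                                    healthy = -3.65)) {
  if (length(centroids) != 3 || is.null(names(centroids)))
    stop("centroids must be a named 3-vector")
  d <- diff(centroids)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("centroids must be strictly ordered")
  labels <- names(centroids)
  idx <- vapply(posterior_means, function(m) which.min(abs(m - centroids)),
                integer(1))
  labels[idx]
}

# ---------------------------------------------------------------------------
# Presets: the published in-silico studies at desk scale.
# ---------------------------------------------------------------------------

#' Recovery experiment presets
#'
#' Returns a ready-to-run [recovery_config()] for one of the published
#' in-silico studies, scaled to 20 synthetic regions and a few thousand
#' simulations. Ground truths and priors are the published values:
#' \describe{
#' \item{stuart_landau}{theta = (G = 350, V = 6 m/s), priors U(0,400) and
#'   U(1,30); per-region spectral summaries of 4 s of fast activity.}
#' \item{jansen_rit}{theta = (C = 135, G = 1.5), priors U(100,650), U(0,5);
#'   per-region spectral summaries.}
#' \item{epileptor}{theta = (G = 1, eta_1..eta_N) with 2 planted EZ and 3 PZ
#'   regions; priors U(0,2) and U(-5,-1); per-region seizure total power and
#'   onset features.}
#' \item{montbrio}{theta = (G = 0.56, eta = -4.6) homogeneous; priors U(0,1),
#'   U(-6,-3.5); FC/FCD and moment features of BOLD through the
#'   Balloon-Windkessel model.}
#' \item{wilson_cowan}{theta = (g_e, P) homogeneous, priors U(0,3) each;
#'   per-region spectral summaries of excitatory activity.}
#' \item{wong_wang}{theta = (G, w, I), priors U(1,10), U(0,1), U(0,0.5);
#'   FC and moment features of BOLD.}
#' }
#'
#' @param model one of the preset names above.
#' @param n_sim simulation budget override (defaults follow the published
#'   or scaled-down budgets).
#' @param seed master seed.
#' @param n_regions region count (default 20).
#' @param ez_regions,pz_regions region indices for the epileptor preset;
#'   by default the two strongest hub regions of the synthetic connectome
#'   become the epileptogenic zone and their three most strongly connected
#'   neighbours the propagation zone (recruitment needs white-matter routes
#'   from the seizing focus).
#' @param connectome_seed seed of the synthetic connectome (shared with
#'   [run_recovery()]).
#' @return a `recovery_config`.
#' @export
recovery_preset <- function(model = c("stuart_landau", "jansen_rit",
                                      "epileptor", "montbrio",
                                      "wilson_cowan", "wong_wang"),
                            n_sim = NULL, seed = 1, n_regions = 20,
                            ez_regions = NULL, pz_regions = NULL,
                            connectome_seed = 42) {
  model <- match.arg(model)
  n <- n_regions
  switch(model,
    stuart_landau = {
      recipe <- feature_recipe(
        list(fn = "psd_summary", fs = 1000, log_power = TRUE,
             bands = list(c(0, 5), c(5, 10), c(10, 15), c(15, 20), c(20, 25),
                          c(25, 30), c(30, 35), c(35, 40), c(40, 45),
                          c(45, 50), c(50, 60), c(60, 80)),
             seg_len = 1000),
        id = "sl_psd")
      sim <- function(theta, sc, seed) {
        p <- stuart_landau_params(n_regions(sc), G = theta[["G"]],
                                  velocity = theta[["V"]])
        simulate_stuart_landau(sc, p, duration = 12, dt = 1e-4, seed = seed,
                               record_every = 10L)
      }
      recovery_config("stuart_landau",
                      theta_true = c(G = 350, V = 6),
                      prior = prior_spec(c("G", "V"), c(0, 1), c(400, 30)),
                      recipe = recipe, simulator = sim,
                      n_sim = n_sim %||% 2000, n_regions = n, seed = seed)
    },
    jansen_rit = {
      recipe <- feature_recipe(
        list(fn = "psd_summary", fs = 2000,
             bands = list(c(2, 6), c(6, 9), c(9, 12), c(12, 16), c(16, 25),
                          c(25, 45)),
             seg_len = 2700),
        id = "jr_psd")
      sim <- function(theta, sc, seed) {
        p <- jansen_rit_params(n_regions(sc), C = theta[["C"]], G = theta[["G"]])
        simulate_jansen_rit(sc, p, duration = 3, dt = 1e-4, seed = seed,
                            record_every = 5L)
      }
      recovery_config("jansen_rit",
                      theta_true = c(C = 135, G = 1.5),
                      prior = prior_spec(c("C", "G"), c(100, 0), c(650, 5)),
                      recipe = recipe, simulator = sim,
                      n_sim = n_sim %||% 2000, n_regions = n, seed = seed)
    },
    epileptor = {
      if (is.null(ez_regions) || is.null(pz_regions)) {
        W <- generate_synthetic_connectome(n, 0.35, connectome_seed)$weights
        if (is.null(ez_regions))
          ez_regions <- order(rowSums(W), decreasing = TRUE)[1:2]
        if (is.null(pz_regions)) {
          to_ez <- rowSums(W[, ez_regions, drop = FALSE])
          to_ez[ez_regions] <- -1
          pz_regions <- order(to_ez, decreasing = TRUE)[1:3]
        }
      }
      eta_true <- rep(-3.65, n)
      eta_true[ez_regions] <- -1.6
      eta_true[pz_regions] <- -2.2
      names_eta <- paste0("eta_", seq_len(n))
      recipe <- feature_recipe(list(fn = "seizure_features", k = 3),
                               transient = 0, id = "vep_power_onset")
      sim <- function(theta, sc, seed) {
        nn <- n_regions(sc)
        p <- epileptor_params(nn, eta = theta[paste0("eta_", seq_len(nn))],
                              G = theta[["G"]], tau = 90)
        init <- rbind(rep(-1.9, nn), rep(6.5, nn))
        res <- simulate_epileptor2d(sc, p, duration = 300, dt = 0.05,
                                    seed = seed, record_every = 2L,
                                    init = init)
        # small additive observation noise on the recorded traces
        res$states <- res$states + with_seed(derive_seed(seed, 999),
          matrix(stats::rnorm(length(res$states), 0, 0.05),
                 nrow(res$states)))
        res
      }
      recovery_config("epileptor2d",
                      theta_true = c(G = 1, stats::setNames(eta_true, names_eta)),
                      prior = prior_spec(c("G", names_eta),
                                         c(0, rep(-5, n)), c(2, rep(-1, n))),
                      recipe = recipe, simulator = sim,
                      n_sim = n_sim %||% 3000, n_regions = n, seed = seed)
    },
    montbrio = {
      recipe <- feature_recipe(
        list(fn = "stat_moments"),
        list(fn = "fcd_fc", window = 16, stride = 4, n_components = 2),
        id = "mpr_bold_fc_fcd")
      sim <- function(theta, sc, seed) {
        p <- montbrio_params(n_regions(sc), G = theta[["G"]],
                             eta = theta[["eta"]])
        act <- simulate_montbrio(sc, p, duration = 20000, dt = 0.1,
                                 seed = seed, record_every = 10L)
        bold_forward(act, balloon_params(TR = 0.5), decimate = 2L)
      }
      recovery_config("montbrio",
                      theta_true = c(G = 0.56, eta = -4.6),
                      prior = prior_spec(c("G", "eta"), c(0, -6), c(1, -3.5)),
                      recipe = recipe, simulator = sim,
                      n_sim = n_sim %||% 2000, n_regions = n, seed = seed)
    },
    wilson_cowan = {
      recipe <- feature_recipe(
        list(fn = "psd_summary", fs = 4,
             bands = list(c(0.02, 0.06), c(0.06, 0.12), c(0.12, 0.3))),
        list(fn = "stat_moments"),
        id = "wc_psd_moments")
      sim <- function(theta, sc, seed) {
        p <- wilson_cowan_params(n_regions(sc), P = theta[["P"]],
                                 g_e = theta[["g_e"]])
        simulate_wilson_cowan(sc, p, duration = 1000, dt = 0.05, seed = seed,
                              record_every = 5L)
      }
      recovery_config("wilson_cowan",
                      theta_true = c(g_e = 1.2, P = 1.5),
                      prior = prior_spec(c("g_e", "P"), c(0, 0), c(3, 3)),
                      recipe = recipe, simulator = sim,
                      n_sim = n_sim %||% 1000, n_regions = n, seed = seed)
    },
    wong_wang = {
      recipe <- feature_recipe(
        list(fn = "stat_moments"),
        list(fn = "fcd_fc", window = 16, stride = 4, n_components = 2),
        id = "ww_bold_fc_fcd")
      sim <- function(theta, sc, seed) {
        p <- wong_wang_params(n_regions(sc), G = theta[["G"]],
                              w = theta[["w"]], I = theta[["I"]])
        act <- simulate_wong_wang(sc, p, duration = 30000, dt = 1, seed = seed)
        bold_forward(act, balloon_params(TR = 0.5), decimate = 2L)
      }
      recovery_config("wong_wang",
                      theta_true = c(G = 6.28, w = 0.6, I = 0.3),
                      prior = prior_spec(c("G", "w", "I"), c(1, 0, 0),
                                         c(10, 1, 0.5)),
                      recipe = recipe, simulator = sim,
                      n_sim = n_sim %||% 1000, n_regions = n, seed = seed)
    }
  )
}
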