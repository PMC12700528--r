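test_that("epileptogenicity classification is nearest-centroid", {
  cents <- c(EZ = -1.6, PZ = -2.2, healthy = -3.65)
  expect_equal(classify_epileptogenicity(cents, cents),
               c("EZ", "PZ", "healthy"))
  expect_equal(classify_epileptogenicity(rep(-3.65, 5), cents),
               rep("healthy", 5))
  means <- c(-1.55, -3.6, -2.3, -1.7, -2.15, rep(-3.5, 15))
  labels <- classify_epileptogenicity(means, cents)
  expect_equal(sum(labels == "EZ"), 2)
  expect_equal(sum(labels == "PZ"), 2)
  expect_equal(sum(labels == "healthy"), 16)
  expect_error(classify_epileptogenicity(1, c(a = -1, b = -1, c = -2)),
               "ordered")
  expect_error(classify_epileptogenicity(1, c(-1, -2, -3)), "named")
})

toy_recovery_config <- function(n_sim, seed = 1) {
  prior <- prior_spec("mu", -1, 1)
  recipe <- feature_recipe(list(fn = "stat_moments"), transient = 0)
  sim_fn <- function(theta, sc, seed) {
    structure(list(states = matrix(brainsbi:::with_seed(seed,
      stats::rnorm(80, theta[["mu"]], 0.5)), 1), time = 1:80, dt = 1,
      model = "toy", seed = seed, params_digest = "x", time_unit = "s"),
      class = "simulation_result")
  }
  recovery_config("toy", c(mu = 0.3), prior, recipe, sim_fn,
                  n_sim = n_sim, n_regions = 1, seed = seed, n_draws = 1500,
                  train_args = list(max_epochs = 60))
}

test_that("a full recovery run is reproducible from its seeds", {
  cfg <- toy_recovery_config(150)
  r1 <- run_recovery(cfg, sc = single_node_sc())
  r2 <- run_recovery(cfg, sc = single_node_sc())
  expect_identical(as.matrix(r1$samples$draws), as.matrix(r2$samples$draws))
  expect_identical(r1$report$z, r2$report$z)
  expect_equal(r1$manifest$seed_obs, r2$manifest$seed_obs)
  # posterior actually concentrates near the truth on this easy problem
  expect_lt(abs(mean(r1$samples$draws$mu) - 0.3), 0.2)
  expect_gt(unname(r1$report$shrinkage["mu"]), 0.5)
})

test_that("recovery artifacts are written alongside a manifest", {
  out <- withr::local_tempdir()
  cfg <- toy_recovery_config(150)
  run_recovery(cfg, sc = single_node_sc(), out_dir = out)
  expect_true(file.exists(file.path(out, "dataset.npz")))
  expect_true(file.exists(file.path(out, "estimator.rds")))
  expect_true(file.exists(file.path(out, "report.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$model_id, "toy")
  expect_equal(man$n_sim, 150)
  expect_true(!is.null(man$seed_batch))
})

test_that("shrinkage degrades monotonically as the budget shrinks", {
  med_shrink <- function(n_sim) {
    vals <- vapply(1:5, function(s) {
      r <- run_recovery(toy_recovery_config(n_sim, seed = s),
                        sc = single_node_sc())
      unname(r$report$shrinkage["mu"])
    }, numeric(1))
    stats::median(vals)
  }
  s100 <- med_shrink(100)
  s500 <- med_shrink(500)
  s2000 <- med_shrink(2000)
  expect_lte(s100, s500 + 0.02)
  expect_lte(s500, s2000 + 0.02)
})

test_that("presets assemble valid configurations", {
  for (m in c("stuart_landau", "jansen_rit", "epileptor", "montbrio",
              "wilson_cowan", "wong_wang")) {
    cfg <- recovery_preset(m, n_sim = 500)
    expect_s3_class(cfg, "recovery_config")
    expect_true(all(cfg$theta_true >= cfg$prior$lower &
                      cfg$theta_true <= cfg$prior$upper), label = m)
  }
  ep <- recovery_preset("epileptor")
  expect_equal(sum(ep$theta_true == -1.6), 2)
  expect_equal(sum(ep$theta_true == -2.2), 3)
  expect_equal(sum(ep$theta_true == -3.65), 15)
})
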