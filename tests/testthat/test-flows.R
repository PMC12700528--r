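# Correctness of the conditional normalizing flows: exact gradients, exact
# invertibility, and posterior quality on the linear-Gaussian toy problem
# where the truth is known in closed form.

ns <- asNamespace("brainsbi")

test_that("flow gradients match finite differences (MAF and NSF)", {
  set.seed(1)
  d <- 3; m <- 4; n <- 12
  x <- matrix(stats::rnorm(n * d), n, d)
  y <- matrix(stats::rnorm(n * m), n, m)
  for (family in c("maf", "nsf")) {
    fl <- ns$new_flow(family, d, m, n_transforms = 2, hidden = 8, seed = 5)
    # move off the ReLU kinks that zero-initialized biases sit on
    for (li in seq_along(fl$layers)) {
      for (pn in names(fl$layers[[li]]$params)) {
        p <- fl$layers[[li]]$params[[pn]]
        fl$layers[[li]]$params[[pn]] <- p + 0.01 * stats::rnorm(length(p))
      }
    }
    lg <- ns$flow_loss_grads(fl, x, y, training = TRUE)
    worst <- 0
    for (li in seq_along(fl$layers)) {
      ps <- fl$layers[[li]]$params
      if (length(ps) == 0) next
      for (pn in names(ps)) {
        p <- ps[[pn]]
        for (ix in sample(length(p), min(5, length(p)))) {
          eps <- 1e-5
          f2 <- fl
          f2$layers[[li]]$params[[pn]][ix] <- p[ix] + eps
          lp <- ns$flow_loss_grads(f2, x, y, training = TRUE)$loss
          f2$layers[[li]]$params[[pn]][ix] <- p[ix] - eps
          lm <- ns$flow_loss_grads(f2, x, y, training = TRUE)$loss
          num <- (lp - lm) / (2 * eps)
          an <- lg$grads[[li]][[pn]][ix]
          worst <- max(worst, abs(num - an) / max(1e-6, abs(num) + abs(an)))
        }
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("sampling inverts the density transform exactly", {
  for (family in c("maf", "nsf")) {
    fl <- ns$new_flow(family, 2, 3, seed = 9)
    y <- matrix(stats::rnorm(3), 1, 3)
    x <- ns$flow_sample(fl, y, 5, seed = 3)
    fw <- ns$flow_forward(fl, x, y[rep(1, 5), , drop = FALSE],
                          training = FALSE)
    z0 <- ns$with_seed(3, matrix(stats::rnorm(10), 5, 2))
    expect_lt(max(abs(fw$z - z0)), 1e-10)
  }
})

test_that("trained MAF matches the conjugate posterior of the toy problem", {
  est <- toy_estimator()
  # analytic posterior (away from the box edge): N(x_obs, 0.5^2 I); compare
  # by the Gaussian 2-Wasserstein distance at 10% of the posterior scale
  for (x_obs in list(c(0.7, -1.2), c(-1.5, 0.3))) {
    s <- sample_posterior(est, x_obs, 3000, seed = 5)
    draws <- as.matrix(s$draws)
    mu <- colMeans(draws)
    S1 <- stats::cov(draws)
    S2 <- diag(0.25, 2)
    sq2 <- diag(0.5, 2)
    cross <- sq2 %*% S1 %*% sq2
    ec <- eigen(cross, symmetric = TRUE)
    cross_half_tr <- sum(sqrt(pmax(ec$values, 0)))
    w2 <- sqrt(sum((mu - x_obs)^2) +
                 sum(diag(S1)) + sum(diag(S2)) - 2 * cross_half_tr)
    expect_lt(w2, 0.1 * sqrt(sum(diag(S2)) * 2))
  }
})

test_that("NSF training also recovers the toy posterior", {
  # the spline flow wants a larger step size than the MAF; bounds stay
  # looser than the conjugate-match test above
  est <- memoise_fixture("toy_nsf", function() {
    train_posterior_estimator(toy_dataset(1500), family = "nsf", seed = 4,
                              lr = 2e-3, patience = 40)
  })
  s <- sample_posterior(est, c(0.5, -0.5), 2000, seed = 6)
  td <- tidy(s)
  expect_lt(max(abs(td$mean - c(0.5, -0.5))), 0.2)
  expect_lt(max(abs(td$sd - 0.5)), 0.2)
})

test_that("shuffled parameter-feature pairs destroy information", {
  data <- toy_dataset(1500)
  shuffled <- data
  shuffled$theta <- data$theta[ns$with_seed(9, sample(nrow(data$theta))), ]
  est <- train_posterior_estimator(shuffled, family = "maf", seed = 2,
                                   max_epochs = 60)
  s <- sample_posterior(est, c(0, 0), 3000, seed = 3)
  shr <- posterior_shrinkage(s)
  # a smooth flow slightly sharpens the flat box; far from the informative
  # case (shrinkage ~0.97 when the pairing is intact)
  expect_lt(max(shr), 0.5)
  expect_lt(max(abs(colMeans(as.matrix(s$draws)))), 0.5)
})

test_that("amortization: one estimator serves many observations and is deterministic", {
  est <- toy_estimator()
  s1 <- sample_posterior(est, c(1, 1), 500, seed = 11)
  s2 <- sample_posterior(est, c(-2, 0.5), 500, seed = 11)
  expect_gt(abs(mean(s1$draws$t1) - mean(s2$draws$t1)), 1)
  s1b <- sample_posterior(est, c(1, 1), 500, seed = 11)
  expect_identical(as.matrix(s1$draws), as.matrix(s1b$draws))
  expect_equal(nrow(sample_posterior(est, c(1, 1), 0, seed = 1)$draws), 0)
})

test_that("posterior mass concentrates near the generating parameters", {
  est <- toy_estimator()
  data <- toy_dataset()
  prior_mean <- matrix(c(0, 0), 1)
  hits <- 0
  idx <- ns$with_seed(13, sample(nrow(data$theta), 50))
  for (i in idx) {
    lp_true <- posterior_log_prob(est, data$theta[i, , drop = FALSE],
                                  data$features[i, ])
    lp_prior_mean <- posterior_log_prob(est, prior_mean, data$features[i, ])
    dist <- sqrt(sum((data$theta[i, ] - c(0, 0))^2))
    if (lp_true > lp_prior_mean || dist < 0.75) hits <- hits + 1
  }
  expect_gte(hits, 45) # >= 90% of held-in pairs
})

test_that("feature standardization round-trips through sampling", {
  est <- toy_estimator()
  st <- est$theta_std
  Z <- matrix(stats::rnorm(20), 10, 2)
  back <- ns$std_apply(ns$std_invert(Z, st), st)
  expect_equal(back, Z, tolerance = 1e-12)
})

test_that("simulation-based calibration ranks are uniform on the toy problem", {
  est <- toy_estimator()
  prior <- toy_prior()
  n_obs <- 120
  L <- 19
  theta_star <- as.matrix(sample_prior(prior, n_obs, seed = 31))
  noise <- ns$with_seed(32, matrix(stats::rnorm(n_obs * 2, 0, 0.5), n_obs, 2))
  x_star <- theta_star + noise
  ranks <- matrix(NA_integer_, n_obs, 2)
  for (i in seq_len(n_obs)) {
    s <- sample_posterior(est, x_star[i, ], L, seed = 100 + i)
    draws <- as.matrix(s$draws)
    ranks[i, ] <- colSums(draws < rep(theta_star[i, ], each = L))
  }
  for (j in 1:2) {
    tab <- tabulate(ranks[, j] + 1L, nbins = L + 1L)
    p <- stats::chisq.test(tab)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("dataset filtering drops failed simulations without reordering", {
  prior <- prior_spec("a", 0, 1)
  recipe <- feature_recipe(list(fn = "stat_moments"), transient = 0)
  sim_fn <- function(theta, sc, seed) {
    if (theta[["a"]] > 0.7) stop("diverged")
    structure(list(states = matrix(stats::rnorm(50, theta[["a"]]), 1),
                   time = 1:50, dt = 1, model = "toy", seed = seed,
                   params_digest = "x", time_unit = "s"),
              class = "simulation_result")
  }
  suppressMessages(
    ds <- run_simulation_batch(single_node_sc(), prior, 40, sim_fn, recipe,
                               seed = 5))
  expect_true(all(ds$theta[, "a"] <= 0.7))
  expect_equal(ds$n_failed, sum(as.matrix(sample_prior(prior, 40, 5)) > 0.7))
  # surviving rows keep their original order
  kept <- as.matrix(sample_prior(prior, 40, 5))
  expect_equal(ds$theta[, "a"], kept[kept[, 1] <= 0.7, 1])
  # an all-failing simulator aborts
  bad <- function(theta, sc, seed) stop("nope")
  expect_error(suppressMessages(
    run_simulation_batch(single_node_sc(), prior, 10, bad, recipe, seed = 1)),
    "half")
})
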