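test_that("posterior z-score matches its closed forms", {
  draws <- cbind(a = c(1, 3), b = c(2, 2.5))
  expect_equal(unname(posterior_zscore(draws, c(a = 2, b = 2.25))["a"]), 0)
  big <- cbind(theta = brainsbi:::with_seed(1, stats::rnorm(1e5, 5, 1)))
  z <- posterior_zscore(big, c(theta = 3))
  expect_equal(unname(z), 2, tolerance = 3 * sqrt(2 / 1e5) + 0.01)
  expect_error(posterior_zscore(cbind(a = c(2, 2, 2)), c(a = 1)), "degenerate")
})

test_that("posterior shrinkage matches its closed forms", {
  prior <- prior_spec("p", 0, 1) # prior sd = 1/sqrt(12)
  sd_prior <- 1 / sqrt(12)
  draws_prior <- cbind(p = brainsbi:::with_seed(2, stats::runif(2e4)))
  s0 <- posterior_shrinkage(draws_prior, prior)
  expect_equal(unname(s0), 0, tolerance = 0.03)
  half <- cbind(p = brainsbi:::with_seed(3, stats::rnorm(2e4, 0.5, sd_prior / 2)))
  expect_equal(unname(posterior_shrinkage(half, prior)), 0.75, tolerance = 0.01)
  point <- cbind(p = rep(0.5, 100))
  expect_equal(unname(posterior_shrinkage(point, prior)), 1)
})

test_that("shrinkage is invariant under a consistent affine reparameterization", {
  prior <- prior_spec("p", -2, 4)
  draws <- cbind(p = brainsbi:::with_seed(4, stats::rnorm(5000, 1, 0.4)))
  s1 <- posterior_shrinkage(draws, prior)
  a <- 3.7; b <- -1.1
  prior2 <- prior_spec("p", a * -2 + b, a * 4 + b)
  s2 <- posterior_shrinkage(cbind(p = a * draws[, 1] + b), prior2)
  expect_equal(s1, s2)
})

test_that("posterior correlation recovers planted dependence", {
  x <- brainsbi:::with_seed(5, stats::rnorm(1e5))
  y <- brainsbi:::with_seed(6, stats::rnorm(1e5))
  cc <- posterior_correlation(cbind(a = x, b = y))
  expect_lt(abs(cc["a", "b"]), 0.02)
  cc2 <- posterior_correlation(cbind(a = x, b = x, c = -x + 0))
  expect_equal(cc2["a", "b"], 1)
  expect_equal(cc2["a", "c"], -1)
  expect_error(posterior_correlation(cbind(a = x[1:10], b = rep(1, 10))),
               "degenerate")
})

test_that("z and shrinkage are permutation-equivariant in parameter order", {
  draws <- cbind(a = stats::rnorm(500, 1, 0.2), b = stats::rnorm(500, -2, 0.5))
  prior <- prior_spec(c("a", "b"), c(-5, -5), c(5, 5))
  z <- posterior_zscore(draws, c(a = 1, b = -2))
  z_perm <- posterior_zscore(draws[, c("b", "a")], c(b = -2, a = 1))
  expect_equal(z_perm[c("a", "b")], z)
  s <- posterior_shrinkage(draws, prior)
  s_perm <- posterior_shrinkage(draws[, c("b", "a")], prior[c(2, 1), ])
  expect_equal(s_perm[c("a", "b")], s)
})

test_that("sensitivity matrix is PSD with an exact eigendecomposition", {
  # anisotropic Gaussian fixture: the steep axis dominates the spectrum
  ld <- function(th) -0.5 * (th[, 1]^2 / 0.1^2 + th[, 2]^2 / 1^2)
  draws <- brainsbi:::with_seed(7,
    cbind(stats::rnorm(4000, 0, 0.1), stats::rnorm(4000, 0, 1)))
  se <- sensitivity_eigs(ld, draws = draws)
  expect_true(all(se$values >= 0))
  recon <- se$vectors %*% diag(se$values) %*% t(se$vectors)
  expect_lt(norm(recon - se$M, "F") / norm(se$M, "F"), 1e-8)
  expect_gt(se$values[1] / se$values[2], 10)
  expect_gt(abs(se$vectors[1, 1]), 0.99) # steep direction is the first axis
})

test_that("isotropic and flat-direction sensitivity fixtures behave", {
  iso <- function(th) -0.5 * rowSums(th^2)
  draws <- brainsbi:::with_seed(8, matrix(stats::rnorm(2e4), ncol = 2))
  se <- sensitivity_eigs(iso, draws = draws)
  expect_lt(se$values[1] / se$values[2], 1.2)
  flat <- function(th) -0.5 * th[, 1]^2 # density flat in the second coordinate
  draws2 <- brainsbi:::with_seed(9,
    cbind(stats::rnorm(5000), stats::runif(5000, -1, 1)))
  se2 <- sensitivity_eigs(flat, draws = draws2)
  expect_lt(se2$values[2] / se2$values[1], 0.05)
  # scalar case: single eigenvalue equals the mean squared density gradient
  g1 <- function(th) -0.5 * th[, 1]^2 / 0.3^2
  d1 <- cbind(brainsbi:::with_seed(10, stats::rnorm(5000, 0, 0.3)))
  se1 <- sensitivity_eigs(g1, draws = d1)
  p <- exp(g1(d1) - max(g1(d1))); p <- p / mean(p)
  expect_equal(se1$values[1], mean((p * (-d1[, 1] / 0.3^2))^2),
               tolerance = 1e-6)
})

test_that("diagnostics report assembles and serializes", {
  draws <- cbind(a = stats::rnorm(300, 1, 0.1), b = stats::rnorm(300, 0, 0.4))
  samples <- structure(list(draws = tibble::as_tibble(draws),
                            acceptance = 1,
                            prior = prior_spec(c("a", "b"), c(-3, -3), c(3, 3)),
                            x_obs = numeric(0)),
                       class = "posterior_samples")
  rep <- diagnostics_report(samples, c(a = 1, b = 0))
  td <- tidy(rep)
  expect_named(td, c("parameter", "zscore", "shrinkage"))
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$z$a, unname(rep$z["a"]), tolerance = 1e-12)
})
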