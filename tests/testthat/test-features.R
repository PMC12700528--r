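test_that("FC matrix reproduces exact correlation cases", {
  t <- seq(0, 1, length.out = 200)
  x <- sin(2 * pi * 5 * t)
  states <- rbind(x, x, -x)
  fc <- fc_matrix(states)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(unname(diag(fc)), rep(1, 3))
  expect_error(fc_matrix(rbind(x, rep(2, 200))), "region")
})

test_that("independent white-noise rows decorrelate at large T", {
  states <- brainsbi:::with_seed(5, matrix(stats::rnorm(4 * 10000), 4))
  fc <- fc_matrix(states)
  expect_lt(max(abs(fc[upper.tri(fc)])), 0.05)
})

test_that("FCD of a stationary signal is uniformly high", {
  t <- seq(0, 20, by = 0.01)
  states <- rbind(sin(2 * pi * t), cos(2 * pi * t),
                  sin(2 * pi * t + 1), 0.5 * cos(2 * pi * t + 2))
  fcd <- fcd_matrix(states, window = 300, stride = 100)
  expect_gt(min(fcd), 0.9)
  expect_equal(diag(unclass(fcd)), rep(1, nrow(fcd)))
  expect_true(all(abs(fcd) <= 1 + 1e-12))
})

test_that("a mid-series coupling flip produces FCD block structure", {
  set.seed(9)
  n_t <- 2000
  base <- stats::rnorm(n_t)
  noise <- matrix(stats::rnorm(3 * n_t, 0, 0.3), 3)
  sgn <- rep(c(1, -1), each = n_t / 2)
  states <- rbind(base + noise[1, ], sgn * base + noise[2, ],
                  base + noise[3, ])
  fcd <- fcd_matrix(states, window = 200, stride = 100)
  w_times <- seq(1, n_t - 200 + 1, by = 100) + 100
  block <- w_times <= n_t / 2
  within <- c(fcd[block, block][upper.tri(fcd[block, block])],
              fcd[!block, !block][upper.tri(fcd[!block, !block])])
  between <- as.numeric(fcd[block, !block])
  expect_gt(mean(within), mean(between))
})

test_that("FCD degenerate and error cases follow the contract", {
  states <- matrix(stats::rnorm(3 * 50), 3)
  expect_equal(unclass(fcd_matrix(states, window = 50, stride = 10))[1, 1], 1)
  expect_error(fcd_matrix(states, window = 5, stride = 2), "at least 10")
  expect_error(fcd_matrix(states, window = 60, stride = 10), "shorter")
})

test_that("PSD summary finds tones, honours Parseval, and ranks band power", {
  fs <- 1000
  t <- seq(1 / fs, 4, by = 1 / fs)
  x40 <- matrix(sin(2 * pi * 40 * t), 1)
  ps <- psd_summary(x40, fs = fs)
  expect_equal(unname(ps["r1_psd_peak_freq"]), 40, tolerance = 0.51)
  noise <- brainsbi:::with_seed(2, matrix(stats::rnorm(20000), 1))
  pn <- psd_summary(noise, fs = fs)
  expect_equal(unname(pn["r1_psd_total_power"]), stats::var(noise[1, ]),
               tolerance = 0.05)
  two <- matrix(2 * sin(2 * pi * 10 * t) + sin(2 * pi * 40 * t), 1)
  pt <- psd_summary(two, fs = fs, bands = list(c(5, 15), c(35, 45)))
  expect_equal(unname(pt["r1_psd_peak_freq"]), 10, tolerance = 0.51)
  expect_equal(unname(pt["r1_psd_band_35_45"] / pt["r1_psd_band_5_15"]), 0.25,
               tolerance = 0.02)
  expect_error(psd_summary(matrix(0, 2, 100), fs = fs), "all-zero")
})

test_that("statistical moments match closed forms and affine algebra", {
  x <- brainsbi:::with_seed(3, matrix(stats::rnorm(1e5), 1))
  m <- stat_moments(x)
  expect_equal(unname(m["r1_mean"]), 0, tolerance = 3 / sqrt(1e5))
  expect_equal(unname(m["r1_var"]), 1, tolerance = 3 * sqrt(2 / 1e5))
  const <- stat_moments(matrix(2, 1, 100))
  expect_equal(as.numeric(const), c(2, 0, 0, 0))
  expect_equal(attr(const, "degenerate"), 1L)
  y <- 2 * x + 1
  my <- stat_moments(y)
  expect_equal(unname(my["r1_mean"]), unname(2 * m["r1_mean"] + 1))
  expect_equal(unname(my["r1_skew"]), unname(m["r1_skew"]), tolerance = 1e-10)
})

test_that("seizure features localize onsets and scale quadratically", {
  n_t <- 1000
  dt <- 0.1
  flat <- matrix(stats::rnorm(n_t, 0, 0.01), 1)
  sf <- seizure_features(flat, dt = dt)
  expect_equal(unname(sf["r1_onset"]), n_t * dt + dt) # sentinel
  burst <- rep(0, n_t)
  burst[301:600] <- sin(2 * pi * (1:300) / 10) * 5
  sig <- matrix(burst + stats::rnorm(n_t, 0, 0.01), 1)
  sb <- seizure_features(sig, dt = dt)
  expect_gte(unname(sb["r1_onset"]), 30)
  expect_lte(unname(sb["r1_onset"]), 30 + 0.05 * n_t * dt)
  s2 <- seizure_features(2 * sig, dt = dt)
  expect_equal(unname(s2["r1_total_power"] / sb["r1_total_power"]), 4,
               tolerance = 0.01)
})

test_that("FC/FCD summaries expose moments and planted structure", {
  fc_id <- diag(4)
  fcd_one <- structure(matrix(1, 3, 3), class = c("fcd_matrix", "matrix", "array"))
  fs <- fcd_fc_summary(fc_id, fcd_one, n_components = 1)
  expect_equal(unname(fs["fc_mean"]), 0)
  expect_equal(unname(fs["fcd_mean"]), 1)
  expect_equal(unname(fs["fcd_var"]), 0)
  # planted two-community FC: first eigenvector separates the communities
  fc_comm <- rbind(c(1, .8, -.6, -.6), c(.8, 1, -.6, -.6),
                   c(-.6, -.6, 1, .8), c(-.6, -.6, .8, 1))
  fs2 <- fcd_fc_summary(fc_comm, fcd_one, n_components = 2)
  pc1 <- attr(fs2, "fc_pc1")
  expect_equal(sign(pc1[1]), sign(pc1[2]))
  expect_equal(sign(pc1[3]), sign(pc1[4]))
  expect_true(sign(pc1[1]) != sign(pc1[3]))
  expect_error(fcd_fc_summary(fc_id, fcd_one, n_components = 5), "rank")
})

test_that("recipes concatenate deterministically with declared arity", {
  sc <- small_sc(4, 0.9, 2)
  p <- stuart_landau_params(4, G = 0, sigma = 1e-4)
  sim <- simulate_stuart_landau(sc, p, duration = 1, dt = 1e-3, seed = 2)
  rec <- feature_recipe(
    list(fn = "psd_summary", fs = 1000, bands = list(c(10, 30), c(30, 60))),
    list(fn = "stat_moments"))
  fv <- apply_recipe(rec, sim)
  expect_length(fv, 4 * (5 + 2) + 4 * 4)
  fv2 <- apply_recipe(rec, sim)
  expect_identical(fv, fv2)
  empty <- apply_recipe(feature_recipe(), sim)
  expect_length(empty, 0)
  expect_error(feature_recipe(list(fn = "nope")), "unknown extractor")
})

test_that("per-region feature blocks are permutation-equivariant", {
  set.seed(6)
  states <- matrix(stats::rnorm(4 * 2000), 4)
  perm <- c(2, 4, 1, 3)
  m1 <- matrix(stat_moments(states), nrow = 4, byrow = TRUE)
  m2 <- matrix(stat_moments(states[perm, ]), nrow = 4, byrow = TRUE)
  expect_equal(m2, m1[perm, ])
  p1 <- matrix(psd_summary(states, fs = 100), nrow = 4, byrow = TRUE)
  p2 <- matrix(psd_summary(states[perm, ], fs = 100), nrow = 4, byrow = TRUE)
  expect_equal(p2, p1[perm, ])
})
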