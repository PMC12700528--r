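# Shared fixtures: tiny connectomes, a single-node shell, the linear-Gaussian
# toy problem, and a memoised store so expensive end-to-end experiments are
# computed once per test run.

.cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

single_node_sc <- function() {
  sc <- connectome(matrix(0, 1, 1), distances = matrix(0, 1, 1))
  sc$normalized <- TRUE
  sc
}

two_node_sc <- function(w = 1, d_mm = 60) {
  sc <- connectome(matrix(c(0, w, w, 0), 2, 2),
                   distances = matrix(c(0, d_mm, d_mm, 0), 2, 2))
  normalize_connectome(sc)
}

small_sc <- function(n = 10, density = 0.4, seed = 7) {
  memoise_fixture(sprintf("sc_%d_%s_%d", n, density, seed), function() {
    normalize_connectome(generate_synthetic_connectome(n, density, seed))
  })
}

# linear-Gaussian toy: theta ~ U(-3,3)^2, x = theta + N(0, noise_sd^2);
# the posterior given x is (up to box truncation) N(x, noise_sd^2) per axis
toy_prior <- function() prior_spec(c("t1", "t2"), c(-3, -3), c(3, 3))

toy_dataset <- function(n_sim = 2000, noise_sd = 0.5, seed = 11) {
  prior <- toy_prior()
  theta <- as.matrix(sample_prior(prior, n_sim, seed = seed))
  noise <- brainsbi:::with_seed(seed + 1,
    matrix(stats::rnorm(n_sim * 2, 0, noise_sd), n_sim, 2))
  X <- theta + noise
  colnames(X) <- c("x1", "x2")
  structure(list(theta = theta, features = X, prior = prior,
                 recipe_id = "toy", seeds = seq_len(n_sim), n_failed = 0L),
            class = "training_dataset")
}

toy_estimator <- function() {
  memoise_fixture("toy_maf", function() {
    train_posterior_estimator(toy_dataset(), family = "maf", seed = 3)
  })
}

# uncoupled Jansen-Rit parameter shortcut used by several spectral tests
jr_single <- function(C = 135, sigma = 2) jansen_rit_params(1, C = C, G = 0,
                                                           sigma = sigma)
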