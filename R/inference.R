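#' Uniform box prior specification
#'
#' @param names parameter labels.
#' @param lower,upper numeric bound vectors (elementwise `lower < upper`).
#' @return a `prior_spec` tibble with columns `name`, `lower`, `upper`.
#' @export
prior_spec <- function(names, lower, upper) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper))
  if (any(!(lower < upper))) stop("prior needs lower < upper elementwise")
  structure(tibble::tibble(name = as.character(names),
                           lower = as.numeric(lower),
                           upper = as.numeric(upper)),
            class = c("prior_spec", "tbl_df", "tbl", "data.frame"))
}

prior_sd <- function(prior) (prior$upper - prior$lower) / sqrt(12)

#' Draw i.i.d. samples from a box prior
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return an `n` x `d` tibble with one column per parameter.
#' @export
sample_prior <- function(prior, n, seed = 1) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  d <- nrow(prior)
  draws <- with_seed(seed, matrix(stats::runif(n * d), n, d))
  draws <- sweep(sweep(draws, 2, prior$upper - prior$lower, "*"),
                 2, prior$lower, "+")
  colnames(draws) <- prior$name
  tibble::as_tibble(draws)
}

#' Run a batch of simulations and assemble a training dataset
#'
#' Draws `n_sim` parameter vectors from the prior, simulates each with a
#' per-simulation seed derived from the master seed, extracts features with
#' the recipe, and row-aligns `(theta, x)` pairs. Simulations whose features
#' are non-finite (or that diverge) are dropped with a logged count; more
#' than 50% failures aborts.
#'
#' @param sc a normalized `connectome` passed to the simulator.
#' @param prior a [prior_spec()].
#' @param n_sim number of simulations.
#' @param simulator `function(theta_row, sc, seed)` returning a
#'   `simulation_result` (or `bold_result`); `theta_row` is a named numeric
#'   vector.
#' @param recipe a [feature_recipe()].
#' @param seed master seed; per-simulation seeds derive from it.
#' @param theta optional pre-drawn parameter tibble/matrix (overrides prior
#'   draws; used to resume or to inject ground-truth rows).
#' @param progress print a progress line every 200 simulations.
#' @return a `training_dataset`: list with `theta` (matrix), `features`
#'   (matrix), `prior`, `recipe_id`, `seeds`, `n_failed`.
#' @export
run_simulation_batch <- function(sc, prior, n_sim, simulator, recipe,
                                 seed = 1, theta = NULL, progress = FALSE) {
  stopifnot(inherits(prior, "prior_spec"))
  if (is.null(theta)) theta <- sample_prior(prior, n_sim, seed)
  theta <- as.matrix(theta)
  n_sim <- nrow(theta)
  seeds <- vapply(seq_len(n_sim), function(i) derive_seed(seed, i), integer(1))
  feats <- NULL
  ok <- logical(n_sim)
  rows <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    fv <- tryCatch({
      sim <- simulator(theta[i, ], sc, seeds[i])
      apply_recipe(recipe, sim)
    }, error = function(e) NULL)
    if (!is.null(fv) && all(is.finite(fv))) {
      rows[[i]] <- as.numeric(fv)
      if (is.null(feats)) feats <- names(fv)
      ok[i] <- TRUE
    }
    if (progress && i %% 200 == 0)
      message(sprintf("simulated %d / %d", i, n_sim))
  }
  n_failed <- sum(!ok)
  if (n_failed > 0)
    message(sprintf("dropped %d / %d simulations with failed/non-finite features",
                    n_failed, n_sim))
  if (n_failed > n_sim / 2)
    stop("more than half of the simulations failed; dataset rejected")
  features <- do.call(rbind, rows[ok])
  colnames(features) <- feats
  structure(list(theta = theta[ok, , drop = FALSE], features = features,
                 prior = prior, recipe_id = recipe$id, seeds = seeds[ok],
                 n_failed = n_failed),
            class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf("<training_dataset> %d simulations, %d parameters, %d features\n",
              nrow(x$theta), ncol(x$theta), ncol(x$features)))
  invisible(x)
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  list(mean = mu, sd = sd, keep = keep)
}

std_apply <- function(X, st) {
  X <- X[, st$keep, drop = FALSE]
  sweep(sweep(X, 2, st$mean[st$keep]), 2, st$sd[st$keep], "/")
}

std_invert <- function(Z, st) {
  sweep(sweep(Z, 2, st$sd[st$keep], "*"), 2, st$mean[st$keep], "+")
}

#' Train a conditional neural density estimator on a simulation dataset
#'
#' Minimizes the negative conditional log-density of the parameters given
#' the features (amortized, single round) over a masked autoregressive flow
#' (`"maf"`: 5 transforms, 2 blocks of 50 tanh units, batch normalization)
#' or a neural spline flow (`"nsf"`: 5 transforms, residual ReLU conditioner
#' blocks of 50 units, 10 spline bins). Features and parameters are z-scored
#' internally (zero-variance features dropped with a logged list);
#' validation early stopping controls overfitting.
#'
#' @param data a `training_dataset` from [run_simulation_batch()].
#' @param family `"maf"` or `"nsf"`.
#' @param n_transforms,hidden,n_bins architecture knobs.
#' @param batch_size,lr,max_epochs,patience,val_frac training knobs.
#' @param min_sims floor on usable simulations.
#' @param seed training seed (initialization, shuffling, split).
#' @return a `posterior_estimator`.
#' @export
train_posterior_estimator <- function(data, family = c("maf", "nsf"),
                                      n_transforms = 5, hidden = 50,
                                      n_bins = 10, batch_size = 256,
                                      lr = 5e-4, max_epochs = 500,
                                      patience = 20, val_frac = 0.1,
                                      min_sims = 100, seed = 1) {
  family <- match.arg(family)
  stopifnot(inherits(data, "training_dataset"))
  if (nrow(data$theta) < min_sims)
    stop("need at least ", min_sims, " usable simulations, got ", nrow(data$theta))
  th_st <- standardizer(data$theta)
  ft_st <- standardizer(data$features)
  if (any(!ft_st$keep))
    message("dropping zero-variance feature(s): ",
            paste(colnames(data$features)[!ft_st$keep], collapse = ", "))
  if (any(!th_st$keep)) stop("a parameter column has zero variance")
  Zt <- std_apply(data$theta, th_st)
  Zf <- std_apply(data$features, ft_st)
  flow <- new_flow(family, d = ncol(Zt), m = ncol(Zf),
                   n_transforms = n_transforms, hidden = hidden,
                   n_bins = n_bins, seed = derive_seed(seed, 7))
  fit <- train_flow(flow, Zt, Zf, batch_size = batch_size, lr = lr,
                    max_epochs = max_epochs, patience = patience,
                    val_frac = val_frac, seed = seed)
  structure(list(
    flow = fit$flow, family = family,
    theta_names = colnames(data$theta), feature_names = colnames(data$features),
    theta_std = th_st, feature_std = ft_st,
    prior = data$prior, recipe_id = data$recipe_id,
    val_loss = fit$val_loss, history = fit$history,
    epochs_run = fit$epochs_run
  ), class = "posterior_estimator")
}

#' @export
print.posterior_estimator <- function(x, ...) {
  cat(sprintf(
    "<posterior_estimator> %s flow: %d parameters | %d features; val loss %.3f (%d epochs)\n",
    toupper(x$family), length(x$theta_names), sum(x$feature_std$keep),
    x$val_loss, x$epochs_run))
  invisible(x)
}

est_condition <- function(est, x_obs) {
  x <- as.numeric(x_obs)
  if (length(x) != length(est$feature_names))
    stop("observed features have length ", length(x), ", estimator expects ",
         length(est$feature_names))
  matrix(std_apply(matrix(x, 1), est$feature_std), nrow = 1)
}

#' Conditional posterior log-density
#'
#' @param est a `posterior_estimator`.
#' @param theta matrix/tibble of parameter values (natural units).
#' @param x_obs observed feature vector.
#' @return log-density values (natural-units density).
#' @export
posterior_log_prob <- function(est, theta, x_obs) {
  theta <- as.matrix(theta)
  y <- est_condition(est, x_obs)
  Zt <- std_apply(theta, est$theta_std)
  y_rep <- y[rep(1, nrow(Zt)), , drop = FALSE]
  flow_log_prob(est$flow, Zt, y_rep) -
    sum(log(est$theta_std$sd[est$theta_std$keep]))
}

#' Sample the amortized posterior for an observation
#'
#' Draws are filtered to the prior box by rejection (probability mass that
#' leaks outside the prior support is discarded and reported as the
#' acceptance fraction); sampling continues until `n_draws` are retained.
#'
#' @param est a `posterior_estimator`.
#' @param x_obs observed feature vector (same recipe as training).
#' @param n_draws number of retained draws.
#' @param seed integer seed.
#' @return a `posterior_samples` object: `draws` tibble (n_draws x d),
#'   `acceptance`, `x_obs`, `prior`.
#' @export
sample_posterior <- function(est, x_obs, n_draws = 1000, seed = 1) {
  stopifnot(inherits(est, "posterior_estimator"))
  y <- est_condition(est, x_obs)
  d <- length(est$theta_names)
  if (n_draws == 0) {
    draws <- matrix(numeric(0), 0, d, dimnames = list(NULL, est$theta_names))
    return(structure(list(draws = tibble::as_tibble(draws), acceptance = NA_real_,
                          x_obs = as.numeric(x_obs), prior = est$prior),
                     class = "posterior_samples"))
  }
  kept <- NULL
  proposed <- 0
  round_i <- 0
  while (is.null(kept) || nrow(kept) < n_draws) {
    round_i <- round_i + 1
    n_try <- max(1000, 2 * (n_draws - if (is.null(kept)) 0 else nrow(kept)))
    Z <- flow_sample(est$flow, y, n_try, seed = derive_seed(seed, round_i))
    th <- std_invert(Z, est$theta_std)
    proposed <- proposed + n_try
    inside <- rep(TRUE, nrow(th))
    for (j in seq_len(d))
      inside <- inside & th[, j] >= est$prior$lower[j] & th[, j] <= est$prior$upper[j]
    kept <- rbind(kept, th[inside, , drop = FALSE])
    if (proposed >= 100 * n_draws && nrow(kept) < 0.01 * proposed)
      stop("posterior leakage: acceptance under prior support fell below 1%")
  }
  acceptance <- nrow(kept) / proposed
  kept <- kept[seq_len(n_draws), , drop = FALSE]
  colnames(kept) <- est$theta_names
  structure(list(draws = tibble::as_tibble(kept), acceptance = acceptance,
                 x_obs = as.numeric(x_obs), prior = est$prior),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws x %d parameters (acceptance %.2f)\n",
              nrow(x$draws), ncol(x$draws),
              if (is.na(x$acceptance)) NA else x$acceptance))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior draws into per-parameter summaries
#'
#' @param x a `posterior_samples` object.
#' @param ... unused.
#' @return tibble with one row per parameter: mean, sd, and central 95%
#'   interval of the draws.
#' @method tidy posterior_samples
#' @export
tidy.posterior_samples <- function(x, ...) {
  draws <- as.matrix(x$draws)
  tibble::tibble(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, stats::quantile, 0.025),
    q97.5 = apply(draws, 2, stats::quantile, 0.975)
  )
}

#' One-row training summary of a posterior estimator
#'
#' @param x a `posterior_estimator`.
#' @param ... unused.
#' @return tibble with family, dimensions, epochs, validation loss.
#' @method glance posterior_estimator
#' @export
glance.posterior_estimator <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_parameters = length(x$theta_names),
    n_features = sum(x$feature_std$keep),
    epochs = x$epochs_run,
    val_loss = x$val_loss
  )
}
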