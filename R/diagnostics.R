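#' Posterior z-scores
#'
#' `z = |posterior mean - truth| / posterior SD`, per parameter; values near
#' zero indicate the posterior is centered on the true value.
#'
#' @param samples a `posterior_samples` object (or a draws matrix).
#' @param theta_true named (or ordered) true parameter vector.
#' @return named numeric vector of z-scores (>= 0).
#' @export
posterior_zscore <- function(samples, theta_true) {
  draws <- if (inherits(samples, "posterior_samples")) as.matrix(samples$draws)
           else as.matrix(samples)
  if (nrow(draws) < 2) stop("z-score needs at least 2 draws")
  sds <- apply(draws, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate posterior: zero SD in parameter(s) ",
                          paste(colnames(draws)[sds == 0], collapse = ", "))
  if (!is.null(names(theta_true)) && !is.null(colnames(draws)))
    theta_true <- theta_true[colnames(draws)]
  abs(colMeans(draws) - as.numeric(theta_true)) / sds
}

#' Posterior shrinkage
#'
#' `s = 1 - posterior variance / prior variance`, per parameter; for the
#' uniform box prior the variance is `(upper - lower)^2 / 12`. Values near
#' one indicate the data strongly constrain the parameter; ideal inference
#' pairs shrinkage near one with z-scores near zero.
#'
#' @param samples a `posterior_samples` object (or a draws matrix).
#' @param prior a [prior_spec()]; defaults to the one stored in `samples`.
#' @return named numeric vector of shrinkages (<= 1).
#' @export
posterior_shrinkage <- function(samples, prior = NULL) {
  if (inherits(samples, "posterior_samples")) {
    if (is.null(prior)) prior <- samples$prior
    draws <- as.matrix(samples$draws)
  } else draws <- as.matrix(samples)
  if (is.null(prior)) stop("a prior_spec is required")
  v_post <- apply(draws, 2, stats::var)
  v_prior <- prior_sd(prior)^2
  stats::setNames(1 - v_post / v_prior, colnames(draws))
}

#' Posterior correlation matrix
#'
#' Pearson correlation between posterior draws of different parameters,
#' revealing degeneracies (e.g. coupling-velocity trade-offs).
#'
#' @param samples a `posterior_samples` object (or a draws matrix).
#' @return d x d symmetric correlation matrix with unit diagonal.
#' @export
posterior_correlation <- function(samples) {
  draws <- if (inherits(samples, "posterior_samples")) as.matrix(samples$draws)
           else as.matrix(samples)
  if (nrow(draws) < 3) stop("correlation needs at least 3 draws")
  sds <- apply(draws, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate posterior: constant parameter column(s) ",
                          paste(colnames(draws)[sds == 0], collapse = ", "))
  cc <- stats::cor(draws)
  diag(cc) <- 1
  cc
}

#' Active-subspace sensitivity eigendecomposition
#'
#' Estimates `M = E[ grad p(theta|x) grad p(theta|x)^T ]` over posterior
#' draws by Monte Carlo, using `grad p = p * grad log p` with density values
#' normalized by their posterior-sample mean (the matrix is scale-sensitive;
#' normalization stabilizes it). Gradients of the flow log-density are
#' central finite differences with step `1e-4` of the prior width. Large
#' eigenvalues mark directions in parameter space along which the posterior
#' is most sensitive.
#'
#' @param est a `posterior_estimator`, or a function `log_prob(theta_matrix)`
#'   for analytic fixtures.
#' @param x_obs observed feature vector (ignored when `est` is a function).
#' @param n_mc number of Monte-Carlo posterior draws (>= 100).
#' @param seed integer seed.
#' @param draws optional matrix of posterior draws (required when `est` is a
#'   function).
#' @param fd_step finite-difference step, per parameter (defaults to
#'   `1e-4 * prior width` for estimators, `1e-4` otherwise).
#' @return list with `values` (descending eigenvalues, >= 0), `vectors`
#'   (matching eigenvectors in columns), and `M`.
#' @export
sensitivity_eigs <- function(est, x_obs = NULL, n_mc = 1000, seed = 1,
                             draws = NULL, fd_step = NULL) {
  if (n_mc < 100 && is.null(draws)) stop("n_mc must be at least 100")
  if (inherits(est, "posterior_estimator")) {
    if (is.null(draws))
      draws <- as.matrix(sample_posterior(est, x_obs, n_mc, seed)$draws)
    log_prob <- function(th) posterior_log_prob(est, th, x_obs)
    if (is.null(fd_step))
      fd_step <- 1e-4 * (est$prior$upper - est$prior$lower)
  } else {
    if (!is.function(est)) stop("est must be a posterior_estimator or a log-density function")
    if (is.null(draws)) stop("draws are required with a log-density function")
    draws <- as.matrix(draws)
    log_prob <- est
    if (is.null(fd_step)) fd_step <- rep(1e-4, ncol(draws))
  }
  d <- ncol(draws)
  if (length(fd_step) == 1) fd_step <- rep(fd_step, d)
  n <- nrow(draws)
  lp0 <- log_prob(draws)
  grad_lp <- matrix(0, n, d)
  for (j in seq_len(d)) {
    up <- draws; up[, j] <- up[, j] + fd_step[j]
    dn <- draws; dn[, j] <- dn[, j] - fd_step[j]
    grad_lp[, j] <- (log_prob(up) - log_prob(dn)) / (2 * fd_step[j])
  }
  p <- exp(lp0 - max(lp0))
  p <- p / mean(p) # normalize density scale over the posterior sample
  gp <- grad_lp * p # grad p = p * grad log p (up to the common scale)
  M <- crossprod(gp) / n
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors, M = M)
}

#' Full posterior diagnostics report
#'
#' @param samples a `posterior_samples` object.
#' @param theta_true true parameter vector.
#' @param est optional `posterior_estimator` for the sensitivity analysis.
#' @param x_obs observed features (needed with `est`).
#' @param n_mc Monte-Carlo size for the sensitivity matrix.
#' @param seed integer seed.
#' @return a `diagnostics_report`: z, shrinkage, posterior correlation, and
#'   (optionally) sensitivity eigenvalues/eigenvectors.
#' @export
diagnostics_report <- function(samples, theta_true, est = NULL, x_obs = NULL,
                               n_mc = 1000, seed = 1) {
  z <- posterior_zscore(samples, theta_true)
  s <- posterior_shrinkage(samples)
  corr <- posterior_correlation(samples)
  sens <- if (!is.null(est)) sensitivity_eigs(est, x_obs, n_mc, seed) else NULL
  structure(list(z = z, shrinkage = s, corr = corr,
                 sens_eigvals = sens$values, sens_eigvecs = sens$vectors,
                 theta_true = theta_true),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  print(tidy.diagnostics_report(x))
  invisible(x)
}

#' Tidy a diagnostics report
#'
#' @param x a `diagnostics_report`.
#' @param ... unused.
#' @return tibble with parameter, z-score, and shrinkage columns.
#' @method tidy diagnostics_report
#' @export
tidy.diagnostics_report <- function(x, ...) {
  tibble::tibble(parameter = names(x$z), zscore = as.numeric(x$z),
                 shrinkage = as.numeric(x$shrinkage[names(x$z)]))
}

#' Write a diagnostics report to JSON
#'
#' @param report a `diagnostics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(z = as.list(report$z), shrinkage = as.list(report$shrinkage),
              correlation = report$corr)
  if (!is.null(report$sens_eigvals)) obj$sensitivity_eigenvalues <- report$sens_eigvals
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
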