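#' @title Summary-statistic extraction
#' @description Converts simulated regional time series into the fixed-length
#' feature vectors used to condition the posterior density estimators:
#' functional connectivity (FC), its sliding-window dynamics (FCD), Welch
#' power-spectral summaries, statistical moments, and seizure-envelope
#' features. All extractors are deterministic and permutation-equivariant
#' across regions.
#' @name features
NULL

states_matrix <- function(x) {
  if (inherits(x, "simulation_result")) x$states else as.matrix(x)
}

#' Functional connectivity matrix
#'
#' Pearson correlation between regional time series.
#'
#' @param states regions x time matrix (or a `simulation_result`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
fc_matrix <- function(states) {
  x <- states_matrix(states)
  if (ncol(x) < 3) stop("FC needs at least 3 time samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("constant signal in region(s) ", paste(which(sds == 0), collapse = ", "),
         "; correlation undefined")
  fc <- stats::cor(t(x))
  diag(fc) <- 1
  fc
}

#' Functional connectivity dynamics matrix
#'
#' FC is computed in sliding windows; entry (i, j) of the FCD matrix is the
#' Pearson correlation between the vectorized upper triangles of the FCs of
#' windows i and j, capturing transitions between connectivity patterns.
#'
#' @param states regions x time matrix (or a `simulation_result`).
#' @param window window length in samples (>= 10).
#' @param stride window step in samples.
#' @return a `fcd_matrix` object: windows x windows correlation matrix with
#'   attributes `window` and `stride`.
#' @export
fcd_matrix <- function(states, window, stride) {
  x <- states_matrix(states)
  n_t <- ncol(x)
  if (window < 10) stop("FCD window must be at least 10 samples")
  if (window > n_t) stop("time series shorter than one FCD window")
  if (n_t < window + stride && window != n_t)
    stop("time series too short: need at least window + stride samples")
  starts <- seq.int(1L, n_t - window + 1L, by = stride)
  ut <- upper.tri(matrix(0, nrow(x), nrow(x)))
  fcs <- vapply(starts, function(s) {
    fc_matrix(x[, s:(s + window - 1L), drop = FALSE])[ut]
  }, numeric(sum(ut)))
  fcd <- if (length(starts) == 1) matrix(1, 1, 1) else stats::cor(fcs)
  diag(fcd) <- 1
  structure(fcd, window = as.integer(window), stride = as.integer(stride),
            class = c("fcd_matrix", "matrix", "array"))
}

# Welch estimate: segment-averaged Hann-tapered periodogram, 50% overlap.
welch_psd <- function(x, fs, seg_len = NULL) {
  x <- as.matrix(x)
  n_t <- ncol(x)
  if (is.null(seg_len)) seg_len <- min(n_t, round(2 * fs))
  seg_len <- min(seg_len, n_t)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq.int(1L, n_t - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  norm <- sum(w^2) * fs
  n_f <- floor(seg_len / 2) + 1L
  psd <- matrix(0, nrow(x), n_f)
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- stats::mvfft(t(seg * rep(w, each = nrow(x))))
    p <- (Mod(ft[seq_len(n_f), , drop = FALSE])^2) / norm
    if (seg_len %% 2 == 0) {
      p[2:(n_f - 1L), ] <- 2 * p[2:(n_f - 1L), ]
    } else {
      p[2:n_f, ] <- 2 * p[2:n_f, ]
    }
    psd <- psd + t(p)
  }
  list(freq = (seq_len(n_f) - 1) * fs / seg_len, psd = psd / length(starts))
}

#' Power-spectral-density summary features
#'
#' Per region: peak frequency, peak power, total power (area under the PSD),
#' spectral centroid, spectral bandwidth, and band powers. The estimator is a
#' segment-averaged Hann-tapered periodogram (segment length two seconds of
#' samples or the full series if shorter, 50% overlap).
#'
#' @param states regions x time matrix (or a `simulation_result`).
#' @param fs sampling frequency (Hz).
#' @param bands list of `c(lo, hi)` frequency bands (Hz); may be empty.
#' @param seg_len optional segment length in samples.
#' @param log_power log10-transform the power-type entries (peak, total, and
#'   band powers); spectral powers span orders of magnitude and conditioning
#'   on their logs keeps the feature scales comparable.
#' @return named feature vector of length `n_regions * (5 + length(bands))`.
#' @export
psd_summary <- function(states, fs, bands = list(), seg_len = NULL,
                        log_power = FALSE) {
  x <- states_matrix(states)
  if (all(x == 0)) stop("all-zero signal: PSD summary undefined")
  est <- welch_psd(x, fs, seg_len)
  f <- est$freq
  df <- f[2] - f[1]
  out <- lapply(seq_len(nrow(x)), function(k) {
    p <- est$psd[k, ]
    total <- sum(p) * df
    i_max <- which.max(p)
    centroid <- if (total > 0) sum(f * p) / sum(p) else 0
    bw <- if (total > 0) sqrt(sum((f - centroid)^2 * p) / sum(p)) else 0
    v <- c(peak_freq = f[i_max], peak_power = p[i_max], total_power = total,
           centroid = centroid, bandwidth = bw)
    for (b in seq_along(bands)) {
      sel <- f >= bands[[b]][1] & f < bands[[b]][2]
      v[paste0("band_", bands[[b]][1], "_", bands[[b]][2])] <- sum(p[sel]) * df
    }
    if (log_power) {
      pow <- c(2, 3, seq_len(length(bands)) + 5)
      v[pow] <- log10(pmax(v[pow], 1e-300))
    }
    v
  })
  vec <- unlist(out)
  names(vec) <- paste0("r", rep(seq_len(nrow(x)), each = length(out[[1]])),
                       "_psd_", names(vec))
  assert_finite_features(vec, "psd_summary")
}

#' Statistical moments per region
#'
#' Mean, variance, skewness, and excess kurtosis of each regional series.
#' Constant signals report zero variance and zero higher moments (with a
#' `degenerate` attribute flagging the regions).
#'
#' @param states regions x time matrix (or a `simulation_result`).
#' @return named feature vector of length `n_regions * 4`.
#' @export
stat_moments <- function(states) {
  x <- states_matrix(states)
  if (ncol(x) < 4) stop("moments need at least 4 samples")
  m <- rowMeans(x)
  xc <- x - m
  v <- rowMeans(xc^2)
  degenerate <- v == 0
  sk <- ifelse(degenerate, 0, rowMeans(xc^3) / v^1.5)
  ku <- ifelse(degenerate, 0, rowMeans(xc^4) / v^2 - 3)
  vec <- as.numeric(rbind(m, v, sk, ku))
  names(vec) <- paste0("r", rep(seq_len(nrow(x)), each = 4),
                       "_", c("mean", "var", "skew", "kurt"))
  out <- assert_finite_features(vec, "stat_moments")
  attr(out, "degenerate") <- which(degenerate)
  out
}

# causal (trailing) moving average with an expanding head, so envelope and
# trend estimates never anticipate upcoming samples
moving_average <- function(x, win) {
  win <- max(1L, as.integer(win))
  if (win == 1L) return(x)
  f <- as.numeric(stats::filter(x, rep(1 / win, win), sides = 1))
  head_idx <- seq_len(min(win - 1L, length(x)))
  f[head_idx] <- cumsum(x[head_idx]) / head_idx
  f
}

#' Seizure-envelope features: total power and onset per region
#'
#' The envelope is the absolute value of the signal after removing a slow
#' causal moving-average trend, smoothed by a trailing moving average
#' spanning 1% of the series. Onset is the first time the envelope exceeds
#' `baseline mean + k * baseline SD` (baseline = first 10% of samples) for a
#' sustained run of at least one smoothing window, scanning after the
#' baseline period; a region that never crosses reports the sentinel
#' `max(time) + dt` ("beyond the recording"). Total power is the area under
#' the squared envelope.
#'
#' @param states regions x time matrix (or a `simulation_result`).
#' @param dt sample spacing (taken from a `simulation_result` if given).
#' @param k onset threshold in baseline SDs.
#' @return named feature vector of length `n_regions * 2`
#'   (`total_power`, `onset`).
#' @export
seizure_features <- function(states, dt = NULL, k = 3) {
  x <- states_matrix(states)
  if (inherits(states, "simulation_result") && is.null(dt))
    dt <- diff(states$time[1:2])
  if (is.null(dt)) stop("dt is required for seizure features")
  n_t <- ncol(x)
  base_n <- max(4L, floor(0.1 * n_t))
  smooth_win <- max(1L, floor(0.01 * n_t))
  trend_win <- max(5L, floor(0.05 * n_t))
  sentinel <- n_t * dt + dt
  out <- vapply(seq_len(nrow(x)), function(r) {
    sig <- x[r, ]
    env <- moving_average(abs(sig - moving_average(sig, trend_win)), smooth_win)
    base <- env[seq_len(base_n)]
    thr <- mean(base) + k * stats::sd(base)
    # detection starts after the baseline window the threshold was fit on,
    # and a crossing must be sustained for one smoothing window so isolated
    # noise excursions do not register as seizure onsets
    above <- env[(base_n + 1L):n_t] > thr
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    hit <- which(runs$values & runs$lengths >= smooth_win)
    onset <- if (length(hit) > 0) {
      (ends[hit[1]] - runs$lengths[hit[1]] + 1L + base_n) * dt
    } else sentinel
    c(total_power = sum(env^2) * dt, onset = onset)
  }, numeric(2))
  vec <- as.numeric(out)
  names(vec) <- paste0("r", rep(seq_len(nrow(x)), each = 2),
                       "_", c("total_power", "onset"))
  assert_finite_features(vec, "seizure_features")
}

#' Low-dimensional FC/FCD summary
#'
#' Moments (mean, variance, skewness, excess kurtosis) of the off-diagonal
#' FC and FCD entries plus the leading eigenvalues of each matrix, which
#' summarize their dominant structure in a rotation- and sign-invariant way.
#' The sign-normalized leading eigenvectors are attached as attributes
#' `fc_pc1` / `fcd_pc1` for inspection.
#'
#' @param fc an FC matrix from [fc_matrix()].
#' @param fcd an FCD matrix from [fcd_matrix()].
#' @param n_components number of leading eigenvalues per matrix.
#' @return named feature vector of fixed length `8 + 2 * n_components`.
#' @export
fcd_fc_summary <- function(fc, fcd, n_components = 2) {
  if (n_components > min(nrow(fc), nrow(fcd)))
    stop("n_components exceeds matrix rank")
  off_moments <- function(m, tag) {
    v <- m[upper.tri(m)]
    if (length(v) == 0) v <- 0
    mu <- mean(v); va <- mean((v - mu)^2)
    sk <- if (va > 0) mean((v - mu)^3) / va^1.5 else 0
    ku <- if (va > 0) mean((v - mu)^4) / va^2 - 3 else 0
    stats::setNames(c(mu, va, sk, ku),
                    paste0(tag, c("_mean", "_var", "_skew", "_kurt")))
  }
  pc <- function(m, tag) {
    e <- eigen(m, symmetric = TRUE)
    vec <- e$vectors[, 1]
    if (vec[which.max(abs(vec))] < 0) vec <- -vec
    list(vals = stats::setNames(e$values[seq_len(n_components)],
                                paste0(tag, "_eig", seq_len(n_components))),
         pc1 = vec)
  }
  fc_pc <- pc(fc, "fc")
  fcd_pc <- pc(unclass(fcd), "fcd")
  out <- c(off_moments(fc, "fc"), off_moments(unclass(fcd), "fcd"),
           if (n_components > 0) c(fc_pc$vals, fcd_pc$vals))
  out <- assert_finite_features(out, "fcd_fc_summary")
  attr(out, "fc_pc1") <- fc_pc$pc1
  attr(out, "fcd_pc1") <- fcd_pc$pc1
  out
}

assert_finite_features <- function(vec, stage) {
  if (any(!is.finite(vec)))
    stop("non-finite feature value(s) from ", stage, ": ",
         paste(utils::head(names(vec)[!is.finite(vec)], 5), collapse = ", "))
  vec
}

#' Build a feature-extraction recipe
#'
#' A recipe is an ordered list of extractor steps applied to a simulation
#' after transient removal; identical recipes produce identically named,
#' identically ordered feature vectors, so datasets built from the same
#' recipe are guaranteed column-compatible.
#'
#' @param ... named steps; each is a list with `fn` (one of `"psd_summary"`,
#'   `"stat_moments"`, `"seizure_features"`, `"fcd_fc"`) and optional
#'   arguments for it (`fs`, `bands`, `seg_len`, `window`, `stride`,
#'   `n_components`, `k`).
#' @param transient fraction of initial samples discarded before extraction.
#' @param id recipe identifier recorded with every feature vector.
#' @return a `feature_recipe` object.
#' @export
feature_recipe <- function(..., transient = 0.1, id = NULL) {
  steps <- list(...)
  known <- c("psd_summary", "stat_moments", "seizure_features", "fcd_fc")
  for (s in steps) {
    if (is.null(s$fn) || !s$fn %in% known)
      stop("unknown extractor; use one of: ", paste(known, collapse = ", "))
  }
  if (is.null(id)) {
    id <- hex32(.cpp_crc32(serialize(list(steps, transient), NULL)))
  }
  structure(list(steps = steps, transient = transient, id = id),
            class = "feature_recipe")
}

#' Apply a feature recipe to a simulation
#'
#' @param recipe a [feature_recipe()].
#' @param sim a `simulation_result` or `bold_result`.
#' @return named feature vector with attribute `recipe_id`; an empty recipe
#'   yields a zero-length vector.
#' @export
apply_recipe <- function(recipe, sim) {
  stopifnot(inherits(recipe, "feature_recipe"))
  if (length(recipe$steps) == 0)
    return(structure(numeric(0), recipe_id = recipe$id))
  sim <- remove_transient(sim, recipe$transient)
  dt_rec <- if (ncol(sim$states) > 1) diff(sim$time[1:2]) else sim$dt
  pieces <- lapply(recipe$steps, function(s) {
    switch(s$fn,
      psd_summary = {
        fs <- s$fs %||% (1 / dt_rec)
        psd_summary(sim$states, fs = fs, bands = s$bands %||% list(),
                    seg_len = s$seg_len, log_power = isTRUE(s$log_power))
      },
      stat_moments = stat_moments(sim$states),
      seizure_features = seizure_features(sim$states, dt = dt_rec,
                                          k = s$k %||% 3),
      fcd_fc = {
        fc <- fc_matrix(sim$states)
        fcd <- fcd_matrix(sim$states, window = s$window, stride = s$stride)
        fcd_fc_summary(fc, fcd, n_components = s$n_components %||% 2)
      }
    )
  })
  vec <- unlist(lapply(pieces, function(p) { attributes(p) <- list(names = names(p)); p }))
  structure(assert_finite_features(vec, "apply_recipe"), recipe_id = recipe$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
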