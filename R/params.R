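#' @title Neural mass model parameter sets
#' @description Constructors for the parameter sets of the six network models.
#' Defaults are the nominal values of the published parameter tables for each
#' model; per-region parameters accept a scalar (recycled) or a length-`n`
#' vector. Each constructor validates positivity/shape invariants.
#' @name model-params
NULL

recycle_n <- function(x, n, what) {
  if (length(x) == 1) x <- rep(as.numeric(x), n)
  if (length(x) != n) stop(what, " must have length 1 or ", n)
  if (any(!is.finite(x))) stop(what, " must be finite")
  as.numeric(x)
}

#' Wilson-Cowan parameters
#'
#' Coupled excitatory/inhibitory firing-rate populations per region with
#' sigmoidal transfer (optionally shifted so that S(0) = 0) and long-range
#' excitatory/inhibitory coupling. Time is in the units of `tau_e`.
#'
#' @param n number of regions.
#' @param P,Q external inputs per region (scalar or length `n`).
#' @param g_e,g_i global excitatory/inhibitory coupling strengths.
#' @param sigma additive noise SD.
#' @param shifted_sigmoid logical; use the shifted sigmoid with S(0) = 0.
#' @param c_ee,c_ei,c_ie,c_ii synaptic strengths.
#' @param tau_e,tau_i population time constants (> 0).
#' @param a_e,a_i,b_e,b_i,c_e,c_i sigmoid slope, threshold, maximum.
#' @param theta_e,theta_i firing thresholds.
#' @param r_e,r_i refractoriness.
#' @param k_e,k_i output scalings.
#' @param alpha_e,alpha_i input gains.
#' @return a `wilson_cowan_params` object.
#' @export
wilson_cowan_params <- function(n, P = 0, Q = 0, g_e = 0, g_i = 0,
                                sigma = 0.005, shifted_sigmoid = TRUE,
                                c_ee = 16, c_ei = 12, c_ie = 15, c_ii = 3,
                                tau_e = 8, tau_i = 8,
                                a_e = 1.3, a_i = 2, b_e = 4, b_i = 3.7,
                                c_e = 1, c_i = 1, theta_e = 0, theta_i = 0,
                                r_e = 1, r_i = 1, k_e = 0.994, k_i = 0.999,
                                alpha_e = 1, alpha_i = 1) {
  stopifnot(tau_e > 0, tau_i > 0, sigma >= 0)
  structure(list(
    c_ee = c_ee, c_ei = c_ei, c_ie = c_ie, c_ii = c_ii,
    tau_e = tau_e, tau_i = tau_i, a_e = a_e, a_i = a_i, b_e = b_e, b_i = b_i,
    c_e = c_e, c_i = c_i, theta_e = theta_e, theta_i = theta_i,
    r_e = r_e, r_i = r_i, k_e = k_e, k_i = k_i,
    alpha_e = alpha_e, alpha_i = alpha_i,
    P = recycle_n(P, n, "P"), Q = recycle_n(Q, n, "Q"),
    g_e = g_e, g_i = g_i, sigma = sigma,
    shifted_sigmoid = isTRUE(shifted_sigmoid), n = as.integer(n)
  ), class = c("wilson_cowan_params", "model_params"))
}

#' Wilson-Cowan sigmoidal transfer function
#'
#' The plain logistic `c / (1 + exp(-a (x - b)))` or, when shifted, the form
#' subtracting its own value at zero so that `S(0) = 0`.
#'
#' @param x input (vectorized).
#' @param side `"e"` or `"i"`, selecting the population's constants.
#' @param params a `wilson_cowan_params` object.
#' @return numeric vector of firing rates.
#' @export
sigmoid_wc <- function(x, side = c("e", "i"), params) {
  side <- match.arg(side)
  a <- params[[paste0("a_", side)]]
  b <- params[[paste0("b_", side)]]
  cc <- params[[paste0("c_", side)]]
  s <- cc / (1 + exp(-a * (x - b)))
  if (params$shifted_sigmoid) s <- s - cc / (1 + exp(a * b))
  s
}

#' Jansen-Rit parameters
#'
#' Three-population (pyramidal, excitatory and inhibitory interneuron) model
#' per region; the synapse counts C1..C4 are derived from the per-region base
#' count `C` as (1, 0.8, 0.25, 0.25) x C. Time in seconds, potentials in mV.
#'
#' @param n number of regions.
#' @param C per-region base synapse count (scalar or length `n`, > 0).
#' @param G global coupling.
#' @param P mean external input (s^-1).
#' @param sigma SD of the Gaussian fluctuations of the external drive.
#' @param A,B excitatory/inhibitory PSP amplitudes (mV).
#' @param a,b PSP rate constants (s^-1, > 0).
#' @param v_max maximum firing rate (Hz, > 0).
#' @param v0 potential at half-maximum firing (mV).
#' @param r sigmoid slope (mV^-1).
#' @return a `jansen_rit_params` object.
#' @export
jansen_rit_params <- function(n, C = 135, G = 1.5, P = 120, sigma = 2,
                              A = 3.25, B = 22, a = 100, b = 50,
                              v_max = 5, v0 = 6, r = 0.56) {
  stopifnot(a > 0, b > 0, v_max > 0, sigma >= 0)
  C <- recycle_n(C, n, "C")
  if (any(C <= 0)) stop("C must be positive")
  structure(list(
    A = A, B = B, a = a, b = b, C = C, v_max = v_max, v0 = v0, r = r,
    G = G, P = P, sigma = sigma, n = as.integer(n)
  ), class = c("jansen_rit_params", "model_params"))
}

#' Stuart-Landau parameters
#'
#' Coupled hopf-normal-form oscillators with per-pair conduction delays
#' `T_jk = d_jk / velocity`. Time in seconds; `a < 0` gives damped
#' noise-driven oscillations at the natural frequency.
#'
#' @param n number of regions.
#' @param a bifurcation parameter.
#' @param freq_hz natural frequency per region (Hz); `omega = 2 pi freq_hz`.
#' @param G global coupling.
#' @param velocity average conduction velocity (m/s, > 0).
#' @param sigma complex-noise SD (per real/imaginary component).
#' @return a `stuart_landau_params` object.
#' @export
stuart_landau_params <- function(n, a = -5, freq_hz = 40, G = 350,
                                 velocity = 6, sigma = 1e-4) {
  stopifnot(sigma >= 0, velocity > 0)
  freq_hz <- recycle_n(freq_hz, n, "freq_hz")
  structure(list(
    a = a, omega = 2 * pi * freq_hz, G = G, velocity = velocity,
    sigma = sigma, n = as.integer(n)
  ), class = c("stuart_landau_params", "model_params"))
}

#' 2D Epileptor parameters
#'
#' Fast-slow reduction of the Epileptor for seizure-spread modeling; the
#' per-region excitability map `eta` determines which regions can seize
#' (the epileptogenic zone) and the slow time constant `tau` sets the
#' seizure-envelope time scale.
#'
#' @param n number of regions.
#' @param eta spatial map of epileptogenicity (scalar or length `n`).
#' @param G global coupling.
#' @param I input current.
#' @param tau slow time constant (> 0).
#' @return an `epileptor_params` object.
#' @export
epileptor_params <- function(n, eta = -3.65, G = 1, I = 3.1, tau = 90) {
  stopifnot(tau > 0)
  structure(list(
    I = I, tau = tau, eta = recycle_n(eta, n, "eta"), G = G, n = as.integer(n)
  ), class = c("epileptor_params", "model_params"))
}

#' Montbrio mean-field parameters
#'
#' Exact mean-field of quadratic integrate-and-fire populations in terms of
#' firing rate r and mean membrane potential v; bistable at the nominal
#' values. Time in milliseconds; noise (SD `sigma`) enters the v equation.
#'
#' @param n number of regions.
#' @param eta excitability per region (scalar or length `n`).
#' @param G global coupling.
#' @param J synaptic weight (ms^-1).
#' @param Delta half-width of the excitability distribution (ms^-1, > 0).
#' @param tau characteristic time constant (ms, > 0).
#' @param sigma noise SD.
#' @param I_stim stimulation current (scalar; 0 disables).
#' @return a `montbrio_params` object.
#' @export
montbrio_params <- function(n, eta = -4.6, G = 0.56, J = 14.5, Delta = 0.7,
                            tau = 1, sigma = 0.037, I_stim = 0) {
  stopifnot(Delta > 0, tau > 0, sigma >= 0)
  structure(list(
    tau = tau, J = J, Delta = Delta, eta = recycle_n(eta, n, "eta"),
    G = G, I_stim = I_stim, sigma = sigma, n = as.integer(n)
  ), class = c("montbrio_params", "model_params"))
}

#' Reduced Wong-Wang parameters
#'
#' Single-population mean-field of synaptic gating S per region with the
#' transfer function `H(x) = (a x - b) / (1 - exp(-d (a x - b)))` (Hz).
#' Time in milliseconds; `w`, `I` and `sigma` may vary per region (e.g. from
#' [pdmf_expand()]).
#'
#' @param n number of regions.
#' @param w recurrent strength per region.
#' @param I external input per region (nA).
#' @param sigma noise amplitude per region.
#' @param G global coupling.
#' @param a,b,d transfer-function constants (n/C, Hz, s).
#' @param gamma kinetic parameter (per ms).
#' @param tau_s synaptic time constant (ms, > 0).
#' @param J synaptic coupling (nA).
#' @return a `wong_wang_params` object.
#' @export
wong_wang_params <- function(n, w = 0.6, I = 0.3, sigma = 0.005, G = 6.28,
                             a = 270, b = 108, d = 0.154, gamma = 0.641 / 1000,
                             tau_s = 100, J = 0.2609) {
  stopifnot(tau_s > 0, d > 0)
  structure(list(
    a = a, b = b, d = d, gamma = gamma, tau_s = tau_s, J = J,
    w = recycle_n(w, n, "w"), I = recycle_n(I, n, "I"),
    sigma = recycle_n(sigma, n, "sigma"), G = G, n = as.integer(n)
  ), class = c("wong_wang_params", "model_params"))
}

#' Wong-Wang transfer function
#'
#' Evaluates `H(x) = (a x - b) / (1 - exp(-d (a x - b)))` with a guarded
#' series branch at the removable singularity `a x = b`, where
#' `H = 1/d` exactly.
#'
#' @param x total input current (vectorized).
#' @param a,b,d transfer constants.
#' @return firing rate (Hz).
#' @export
wong_wang_transfer <- function(x, a = 270, b = 108, d = 0.154) {
  .cpp_ww_transfer(as.numeric(x), a, b, d)
}

#' Expand pDMF coefficients into regional parameter maps
#'
#' The parameterized dynamic mean-field (pDMF) approach expresses the
#' per-region recurrent strength `w_i`, input `I_i`, and noise `sigma_i` of
#' the Wong-Wang model as linear combinations of two anatomical maps (the
#' T1w/T2w myelin map and the first principal FC gradient):
#' `w_i = a_w Mye_i + b_w Grad_i + c_w`, and likewise for I and sigma. For
#' `N` regions this replaces `3 N` regional parameters by 9 coefficients.
#' Values are reported as-is; range handling is the simulator's contract.
#'
#' @param coeffs numeric vector of the 9 coefficients, named or in the order
#'   `a_w, b_w, c_w, a_I, b_I, c_I, a_sigma, b_sigma, c_sigma`.
#' @param mye regional myelin map (length `N`, finite).
#' @param grad regional FC-gradient map (length `N`, finite).
#' @return a tibble with columns `region`, `w`, `I`, `sigma`.
#' @export
pdmf_expand <- function(coeffs, mye, grad) {
  nm <- c("a_w", "b_w", "c_w", "a_I", "b_I", "c_I",
          "a_sigma", "b_sigma", "c_sigma")
  if (length(coeffs) != 9) stop("pDMF needs exactly 9 coefficients")
  if (!is.null(names(coeffs))) {
    if (!all(nm %in% names(coeffs))) stop("coefficient names must be ", paste(nm, collapse = ", "))
    coeffs <- coeffs[nm]
  }
  if (length(mye) != length(grad)) stop("mye and grad maps must have equal length")
  if (any(!is.finite(mye)) || any(!is.finite(grad)))
    stop("anatomical maps must be finite")
  cf <- as.numeric(coeffs)
  tibble::tibble(
    region = seq_along(mye),
    w = cf[1] * mye + cf[2] * grad + cf[3],
    I = cf[4] * mye + cf[5] * grad + cf[6],
    sigma = cf[7] * mye + cf[8] * grad + cf[9]
  )
}

#' Generate smooth synthetic anatomical maps in [0, 1]
#'
#' Stand-ins for the group-level T1w/T2w myelin map and the first principal
#' FC gradient used by the pDMF parameterization: values are smooth functions
#' of synthetic region centroids, rescaled to the unit interval.
#'
#' @param n number of regions.
#' @param seed integer seed.
#' @return a tibble with columns `region`, `mye`, `grad` (synthetic).
#' @export
generate_synthetic_maps <- function(n, seed = 1) {
  with_seed(seed, {
    xyz <- matrix(stats::runif(n * 3), n, 3)
    mye <- xyz[, 1] + 0.4 * sin(2 * pi * xyz[, 2]) + 0.15 * stats::rnorm(n)
    grad <- xyz[, 3] + 0.4 * cos(2 * pi * xyz[, 1]) + 0.15 * stats::rnorm(n)
  })
  unit <- function(v) (v - min(v)) / (max(v) - min(v))
  tibble::tibble(region = seq_len(n), mye = unit(mye), grad = unit(grad))
}
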