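#' Balloon-Windkessel hemodynamic parameters
#'
#' Neurovascular coupling constants mapping neural activity to BOLD. Two
#' distinct epsilons appear in the model and are kept as separate fields to
#' prevent conflation: `epsilon_eff`, the efficacy with which neural activity
#' raises the vasodilatory signal, and `epsilon_ratio`, the resting ratio of
#' intra- to extravascular signal entering the readout constants.
#'
#' @param tau_s vasodilatory signal decay time constant (s).
#' @param tau_f flow-dependent elimination time constant (s).
#' @param alpha Grubb's vessel stiffness exponent, in (0, 1).
#' @param tau_0 hemodynamic transit time (s).
#' @param epsilon_eff neuronal efficacy.
#' @param r_0 slope of the intravascular relaxation rate (Hz).
#' @param vartheta_0 frequency offset at the surface of fully deoxygenated
#'   vessels (1.5 T).
#' @param epsilon_ratio intra/extravascular signal ratio at rest.
#' @param V_0 resting blood volume fraction.
#' @param E_0 resting oxygen extraction fraction, in (0, 1).
#' @param TE echo time (s).
#' @param TR output sampling interval (s).
#' @return a `balloon_params` object.
#' @export
balloon_params <- function(tau_s = 1.5, tau_f = 4.5, alpha = 0.2, tau_0 = 1.0,
                           epsilon_eff = 0.1, r_0 = 25, vartheta_0 = 40.3,
                           epsilon_ratio = 1.43, V_0 = 0.02, E_0 = 0.8,
                           TE = 0.04, TR = 2) {
  stopifnot(tau_s > 0, tau_f > 0, tau_0 > 0, TR > 0, TE > 0,
            alpha > 0, alpha < 1, E_0 > 0, E_0 < 1)
  structure(list(
    tau_s = tau_s, tau_f = tau_f, alpha = alpha, tau_0 = tau_0,
    epsilon_eff = epsilon_eff, r_0 = r_0, vartheta_0 = vartheta_0,
    epsilon_ratio = epsilon_ratio, V_0 = V_0, E_0 = E_0, TE = TE, TR = TR
  ), class = "balloon_params")
}

#' BOLD readout constants k1, k2, k3
#'
#' `k1 = 4.3 vartheta_0 E_0 TE`, `k2 = epsilon_ratio r_0 E_0 TE`,
#' `k3 = 1 - epsilon_ratio`.
#'
#' @param params a [balloon_params()] object.
#' @return named numeric vector `c(k1, k2, k3)`.
#' @export
balloon_constants <- function(params) {
  c(k1 = 4.3 * params$vartheta_0 * params$E_0 * params$TE,
    k2 = params$epsilon_ratio * params$r_0 * params$E_0 * params$TE,
    k3 = 1 - params$epsilon_ratio)
}

#' Map neural activity to BOLD through the Balloon-Windkessel model
#'
#' Integrates the vasodilatory signal s, inflow f, venous volume v, and
#' deoxyhemoglobin q per region from the rest state (s = 0, f = v = q = 1),
#' driven by the simulation's observable, and emits the BOLD signal
#' `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))` sampled every TR.
#' The hemodynamic states are integrated at `decimate` times the neural step
#' on block-averaged drive (the system's fastest time constant is about a
#' second, so a millisecond-scale step loses nothing).
#'
#' @param activity a `simulation_result`; its `time_unit` ("s" or "ms")
#'   fixes the unit conversion.
#' @param params a [balloon_params()] object.
#' @param gain multiplies the (optionally centered) neural drive.
#' @param center subtract the per-region mean of the drive before scaling.
#' @param decimate integer; hemodynamic integration step in neural samples.
#' @return a `bold_result` with fields `bold` (regions x TR samples) and
#'   `time` (s).
#' @export
bold_forward <- function(activity, params, gain = 1, center = FALSE,
                         decimate = 1L) {
  stopifnot(inherits(activity, "simulation_result"),
            inherits(params, "balloon_params"))
  dt_s <- switch(activity$time_unit,
    "s" = activity$dt, "ms" = activity$dt / 1000,
    stop("BOLD mapping needs activity in seconds or milliseconds, not '",
         activity$time_unit, "' units"))
  dt_rec <- dt_s * if (ncol(activity$states) > 1)
    round(diff(activity$time[1:2]) / activity$dt) else 1
  if (params$TR < dt_rec * decimate)
    stop("TR must be at least the hemodynamic integration step")
  x <- activity$states
  if (center) x <- x - rowMeans(x)
  x <- gain * x
  if (any(!is.finite(x))) stop("neural activity contains non-finite values")
  par <- c(unclass(params), as.list(balloon_constants(params)))
  res <- .cpp_bold_forward(x, dt_rec, par, params$TR, as.integer(decimate))
  structure(list(bold = res$bold, states = res$bold, time = res$time,
                 TR = params$TR, dt = params$TR, time_unit = "s",
                 model = paste0(activity$model, "+bold"),
                 seed = activity$seed),
            class = c("bold_result", "simulation_result"))
}
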