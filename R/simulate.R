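#' @title Network simulation front-ends
#' @description Each `simulate_*()` integrates one connectome-coupled neural
#' mass model with a shared stochastic Heun contract: per-node noise streams
#' derived from `(seed, node id)` so that a zero-coupling network run is
#' bit-identical to isolated single-node runs, deterministic output given
#' `(params, sc, seed, dt, duration)`, and divergence errors naming the step.
#' @name simulate
NULL

new_simulation_result <- function(states, time, dt, model, seed, params,
                                  time_unit) {
  structure(list(
    states = states, time = time, dt = dt, model = model, seed = seed,
    params_digest = params_digest(params), time_unit = time_unit
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s: %d regions x %d samples, dt = %g %s\n",
              x$model, nrow(x$states), ncol(x$states), x$dt, x$time_unit))
  invisible(x)
}

params_digest <- function(params) {
  hex32(.cpp_crc32(serialize(unclass(params), NULL)))
}

# hex rendering of an unsigned 32-bit value carried in a double
hex32 <- function(x) {
  sprintf("%04x%04x", as.integer(x %/% 65536), as.integer(x %% 65536))
}

# Per-node initial-condition perturbations, reproducible from (seed, node id)
# so isolated runs see the same initial state as network runs.
node_noise <- function(seed, node_ids, k_draws) {
  matrix(vapply(node_ids, function(id) {
    with_seed(derive_seed(seed, id + 1), stats::rnorm(k_draws))
  }, numeric(k_draws)), nrow = k_draws)
}

check_sim_args <- function(sc, duration, dt, record_every) {
  stopifnot(inherits(sc, "connectome"))
  if (!sc$normalized)
    stop("connectome must be normalized (see normalize_connectome())")
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  if (duration / dt < record_every) stop("duration too short for record_every")
}

#' Simulate the Wilson-Cowan network model
#'
#' @param sc a normalized `connectome`.
#' @param params a [wilson_cowan_params()] object.
#' @param duration total time (units of the population time constants).
#' @param dt integration step; default 0.05 gives >= 20 steps per fastest
#'   time constant at the nominal parameters.
#' @param seed integer seed for the per-node noise streams.
#' @param record_every thin the output to every k-th step.
#' @param node_ids node identities for the noise streams (default `0:(n-1)`);
#'   pass a single id to make an isolated run reproduce one network node.
#' @param init optional 2 x n matrix of initial `(E, I)`; default baseline
#'   0.1 with small seeded perturbations.
#' @param record_i also return the inhibitory rates (rows `n+1 .. 2n`).
#' @return a `simulation_result` whose `states` are the excitatory rates E
#'   (regions x time).
#' @export
simulate_wilson_cowan <- function(sc, params, duration = 400, dt = 0.05,
                                  seed = 1, record_every = 1L,
                                  node_ids = NULL, init = NULL,
                                  record_i = FALSE) {
  check_sim_args(sc, duration, dt, record_every)
  n <- n_regions(sc)
  stopifnot(params$n == n)
  if (is.null(node_ids)) node_ids <- seq_len(n) - 1L
  if (is.null(init)) {
    pert <- node_noise(seed, node_ids, 2)
    init <- rbind(0.1 + 0.01 * pert[1, ], 0.1 + 0.01 * pert[2, ])
  }
  res <- .cpp_sim_wilson_cowan(sc$weights, unclass(params), duration, dt,
                               as.numeric(seed), as.integer(record_every),
                               as.integer(node_ids), init[1, ], init[2, ],
                               isTRUE(record_i))
  new_simulation_result(res$states, res$time, dt, "wilson_cowan", seed, params,
                        "tau-units")
}

#' Simulate the Jansen-Rit network model
#'
#' The observable is the pyramidal membrane potential `y1 - y2` (mV). The
#' external drive is `P` plus Gaussian fluctuations with SD `sigma`, entering
#' the excitatory-interneuron PSP equation.
#'
#' @inheritParams simulate_wilson_cowan
#' @param params a [jansen_rit_params()] object.
#' @param duration total time (s).
#' @param dt integration step (s).
#' @param init optional 6 x n matrix of initial states.
#' @return a `simulation_result` (regions x time, mV).
#' @export
simulate_jansen_rit <- function(sc, params, duration = 4, dt = 1e-4,
                                seed = 1, record_every = 1L,
                                node_ids = NULL, init = NULL) {
  check_sim_args(sc, duration, dt, record_every)
  n <- n_regions(sc)
  stopifnot(params$n == n)
  if (is.null(node_ids)) node_ids <- seq_len(n) - 1L
  if (is.null(init)) {
    # start each region at its uncoupled equilibrium: the model coexists with
    # a large slow spike-wave cycle whose basin would otherwise capture the
    # initial transient
    pert <- node_noise(seed, node_ids, 3)
    init <- matrix(0, 6, n)
    init[1:3, ] <- jr_equilibrium(params) + 0.01 * pert
  }
  res <- .cpp_sim_jansen_rit(sc$weights, unclass(params), duration, dt,
                             as.numeric(seed), as.integer(record_every),
                             as.integer(node_ids), init)
  new_simulation_result(res$states, res$time, dt, "jansen_rit", seed, params, "s")
}

#' Simulate the delay-coupled Stuart-Landau network model
#'
#' Inter-regional coupling uses per-pair discrete delays
#' `T_jk = d_jk / velocity` rounded to the nearest integration step; the
#' history buffer is initialized by holding the initial state constant. The
#' observable is `Re(Z)`.
#'
#' @inheritParams simulate_wilson_cowan
#' @param params a [stuart_landau_params()] object.
#' @param duration total time (s).
#' @param dt integration step (s); must not exceed the smallest positive
#'   delay among connected region pairs.
#' @param init optional 2 x n matrix of initial `(Re Z, Im Z)`.
#' @return a `simulation_result` (regions x time).
#' @export
simulate_stuart_landau <- function(sc, params, duration = 4, dt = 1e-4,
                                   seed = 1, record_every = 1L,
                                   node_ids = NULL, init = NULL) {
  check_sim_args(sc, duration, dt, record_every)
  n <- n_regions(sc)
  stopifnot(params$n == n)
  if (params$G != 0 && is.null(sc$distances))
    stop("Stuart-Landau coupling needs a connectome with distances")
  if (!is.null(sc$distances)) {
    delays <- delay_matrix(sc, params$velocity)
    connected <- sc$weights > 0
    if (params$G != 0 && any(connected)) {
      min_pos <- min(delays[connected & delays > 0])
      if (dt > min_pos)
        stop(sprintf(
          "dt = %g s cannot resolve the smallest conduction delay %g s; reduce dt",
          dt, min_pos))
    }
    delay_steps <- matrix(as.integer(round(delays / dt)), n, n)
  } else {
    delay_steps <- matrix(0L, n, n)
  }
  if (is.null(node_ids)) node_ids <- seq_len(n) - 1L
  if (is.null(init)) {
    pert <- node_noise(seed, node_ids, 2)
    init <- 0.05 * pert
  }
  res <- .cpp_sim_stuart_landau(sc$weights, delay_steps, unclass(params),
                                duration, dt, as.numeric(seed),
                                as.integer(record_every),
                                as.integer(node_ids), init[1, ], init[2, ])
  new_simulation_result(res$states, res$time, dt, "stuart_landau", seed,
                        params, "s")
}

#' Simulate the 2D Epileptor network model
#'
#' Deterministic fast-slow dynamics; the coupling enters the slow equation as
#' printed in the model definition, `-G sum_j SC_ij (x_j - x_i)` inside the
#' `1/tau` bracket. The observable is the fast variable `x`.
#'
#' @inheritParams simulate_wilson_cowan
#' @param params an [epileptor_params()] object.
#' @param duration total time (same unit as `tau`).
#' @param dt integration step.
#' @param init optional 2 x n matrix of initial `(x, z)`; default places each
#'   region near the healthy branch at `x = -2` with small seeded
#'   perturbations.
#' @return a `simulation_result` (regions x time).
#' @export
simulate_epileptor2d <- function(sc, params, duration = 100, dt = 0.05,
                                 seed = 1, record_every = 1L,
                                 node_ids = NULL, init = NULL) {
  check_sim_args(sc, duration, dt, record_every)
  n <- n_regions(sc)
  stopifnot(params$n == n)
  if (is.null(node_ids)) node_ids <- seq_len(n) - 1L
  if (is.null(init)) {
    pert <- node_noise(seed, node_ids, 2)
    x0 <- -2 + 0.02 * pert[1, ]
    z0 <- 4 * (x0 - params$eta) + 0.02 * pert[2, ]
    init <- rbind(x0, z0)
  }
  res <- .cpp_sim_epileptor2d(sc$weights, unclass(params), duration, dt,
                              as.integer(record_every), init[1, ], init[2, ])
  new_simulation_result(res$states, res$time, dt, "epileptor2d", seed, params,
                        "tau-units")
}

#' Simulate the Montbrio mean-field network model
#'
#' Noise enters the membrane-potential equation only; the firing rate stays
#' positive (the `Delta / (pi tau)` term repels r = 0), and a step that would
#' cross zero is retried once with two half-steps before erroring.
#'
#' @inheritParams simulate_wilson_cowan
#' @param params a [montbrio_params()] object.
#' @param duration total time (ms).
#' @param dt integration step (ms).
#' @param record_v also return the membrane potentials (rows `n+1 .. 2n`).
#' @param init optional 2 x n matrix of initial `(r, v)`.
#' @return a `simulation_result` whose `states` are the firing rates r
#'   (and v if requested).
#' @export
simulate_montbrio <- function(sc, params, duration = 2000, dt = 0.01,
                              seed = 1, record_every = 1L, node_ids = NULL,
                              record_v = FALSE, init = NULL) {
  check_sim_args(sc, duration, dt, record_every)
  n <- n_regions(sc)
  stopifnot(params$n == n)
  if (is.null(node_ids)) node_ids <- seq_len(n) - 1L
  if (is.null(init)) {
    pert <- node_noise(seed, node_ids, 2)
    init <- rbind(0.05 + 0.01 * abs(pert[1, ]), -2 + 0.1 * pert[2, ])
  }
  if (any(init[1, ] <= 0)) stop("initial firing rates must be positive")
  res <- .cpp_sim_montbrio(sc$weights, unclass(params), duration, dt,
                           as.numeric(seed), as.integer(record_every),
                           as.integer(node_ids), init[1, ], init[2, ],
                           isTRUE(record_v))
  new_simulation_result(res$states, res$time, dt, "montbrio", seed, params, "ms")
}

#' Simulate the reduced Wong-Wang network model
#'
#' The gating variable is clipped to [0, 1] after each step; the transfer
#' function uses a guarded branch at its removable singularity.
#'
#' @inheritParams simulate_wilson_cowan
#' @param params a [wong_wang_params()] object.
#' @param duration total time (ms).
#' @param dt integration step (ms).
#' @param init optional length-n vector of initial gating values.
#' @return a `simulation_result` whose `states` are the gating variables S.
#' @export
simulate_wong_wang <- function(sc, params, duration = 60000, dt = 1,
                               seed = 1, record_every = 1L, node_ids = NULL,
                               init = NULL) {
  check_sim_args(sc, duration, dt, record_every)
  n <- n_regions(sc)
  stopifnot(params$n == n)
  if (is.null(node_ids)) node_ids <- seq_len(n) - 1L
  if (is.null(init)) {
    pert <- node_noise(seed, node_ids, 1)
    init <- pmin(pmax(0.1 + 0.01 * pert[1, ], 0), 1)
  }
  res <- .cpp_sim_wong_wang(sc$weights, unclass(params), duration, dt,
                            as.numeric(seed), as.integer(record_every),
                            as.integer(node_ids), init)
  new_simulation_result(res$states, res$time, dt, "wong_wang", seed, params, "ms")
}

#' Drop the initial transient of a simulation
#'
#' @param sim a `simulation_result` (or `bold_result`).
#' @param fraction fraction of the samples discarded from the start.
#' @return the object with the transient removed.
#' @export
remove_transient <- function(sim, fraction = 0.1) {
  stopifnot(fraction >= 0, fraction < 1)
  keep <- seq.int(floor(ncol(sim$states) * fraction) + 1L, ncol(sim$states))
  sim$states <- sim$states[, keep, drop = FALSE]
  sim$time <- sim$time[keep]
  sim
}

# Uncoupled fixed point of each region's local dynamics (damped fixed-point
# iteration on the pyramidal potential); rows are (y0, y1, y2).
jr_equilibrium <- function(params) {
  S <- function(v) params$v_max / (1 + exp(params$r * (params$v0 - v)))
  Aa <- params$A / params$a
  Bb <- params$B / params$b
  y0 <- rep(0.05, params$n)
  for (i in 1:3000) {
    y1 <- Aa * (params$P + 0.8 * params$C * S(params$C * y0))
    y2 <- Bb * 0.25 * params$C * S(0.25 * params$C * y0)
    y0 <- 0.95 * y0 + 0.05 * Aa * S(y1 - y2)
  }
  rbind(y0, y1, y2)
}

model_registry <- function() {
  list(
    wilson_cowan = simulate_wilson_cowan,
    jansen_rit = simulate_jansen_rit,
    stuart_landau = simulate_stuart_landau,
    epileptor2d = simulate_epileptor2d,
    montbrio = simulate_montbrio,
    wong_wang = simulate_wong_wang
  )
}

#' Simulate a registered model by name
#'
#' @param model_id one of `"wilson_cowan"`, `"jansen_rit"`,
#'   `"stuart_landau"`, `"epileptor2d"`, `"montbrio"`, `"wong_wang"`.
#' @param sc a normalized `connectome`.
#' @param params the matching parameter object.
#' @param ... passed to the model's `simulate_*()` function.
#' @return a `simulation_result`.
#' @export
simulate_model <- function(model_id, sc, params, ...) {
  reg <- model_registry()
  if (!model_id %in% names(reg))
    stop("unknown model '", model_id, "'; registered: ",
         paste(names(reg), collapse = ", "))
  reg[[model_id]](sc, params, ...)
}
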