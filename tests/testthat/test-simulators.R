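# Unit and oracle tests for the six network simulators. Root-finding oracles
# (pracma::fsolve / uniroot) provide independent references for fixed points.

test_that("Wilson-Cowan sigmoid matches its closed-form anchors", {
  p_shift <- wilson_cowan_params(1, shifted_sigmoid = TRUE)
  expect_equal(sigmoid_wc(0, "e", p_shift), 0)
  p_plain <- wilson_cowan_params(1, shifted_sigmoid = FALSE)
  expect_equal(sigmoid_wc(1e6, "e", p_plain), 1) # saturates at c_e = 1
  expect_equal(sigmoid_wc(4, "e", p_plain), 0.5) # logistic at threshold b_e
})

test_that("Wilson-Cowan origin is a fixed point with the shifted sigmoid", {
  sc <- small_sc(5, 0.6, 1)
  p <- wilson_cowan_params(5, P = 0, Q = 0, g_e = 0, g_i = 0, sigma = 0)
  sim <- simulate_wilson_cowan(sc, p, duration = 50, dt = 0.05, seed = 1,
                               init = matrix(0, 2, 5))
  expect_identical(max(abs(sim$states)), 0)
})

test_that("driven Wilson-Cowan node converges to the root-solved equilibrium", {
  # a mid-range drive (P ~ 1.2-2) puts the node on a slow limit cycle, so the
  # fixed-point oracle is exercised at drives on the convergent branches
  skip_if_not_installed("pracma")
  for (P in c(0.5, 2.5)) {
    p <- wilson_cowan_params(1, P = P, sigma = 0)
    rhs <- function(s) {
      E <- s[1]; I <- s[2]
      xe <- p$alpha_e * (p$c_ee * E - p$c_ei * I + P)
      xi <- p$alpha_i * (p$c_ie * E - p$c_ii * I)
      c(-E + (p$k_e - p$r_e * E) * sigmoid_wc(xe, "e", p),
        -I + (p$k_i - p$r_i * I) * sigmoid_wc(xi, "i", p))
    }
    sim <- simulate_wilson_cowan(single_node_sc(), p, duration = 3000,
                                 dt = 0.05, seed = 1, record_i = TRUE)
    end <- sim$states[, ncol(sim$states)]
    root <- pracma::fsolve(rhs, end)$x
    expect_lt(max(abs(rhs(root))), 1e-10)
    expect_equal(end, root, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("Jansen-Rit sigmoid is half-max at v0 and regions decouple at G=0", {
  p <- jansen_rit_params(2)
  S <- function(v) p$v_max / (1 + exp(p$r * (p$v0 - v)))
  expect_equal(S(p$v0), 2.5)
  sc <- two_node_sc()
  pj <- jansen_rit_params(2, G = 0, sigma = 2)
  net <- simulate_jansen_rit(sc, pj, duration = 1, dt = 1e-4, seed = 4)
  iso1 <- simulate_jansen_rit(single_node_sc(), jansen_rit_params(1, G = 0, sigma = 2),
                              duration = 1, dt = 1e-4, seed = 4, node_ids = 0L)
  iso2 <- simulate_jansen_rit(single_node_sc(), jansen_rit_params(1, G = 0, sigma = 2),
                              duration = 1, dt = 1e-4, seed = 4, node_ids = 1L)
  expect_identical(net$states[1, ], iso1$states[1, ])
  expect_identical(net$states[2, ], iso2$states[1, ])
})

test_that("stochastic Jansen-Rit node shows a dominant alpha-band peak", {
  sim <- simulate_jansen_rit(single_node_sc(), jr_single(), duration = 8,
                             dt = 1e-4, seed = 2, record_every = 5L)
  sim <- remove_transient(sim, 0.2)
  ps <- psd_summary(sim$states, fs = 2000, seg_len = 4000)
  peak <- unname(ps["r1_psd_peak_freq"])
  expect_gte(peak, 8)
  expect_lte(peak, 13)
  # independent long-run reference: a second seed and longer horizon agrees
  ref <- simulate_jansen_rit(single_node_sc(), jr_single(), duration = 16,
                             dt = 1e-4, seed = 9, record_every = 5L)
  ref <- remove_transient(ref, 0.2)
  pr <- psd_summary(ref$states, fs = 2000, seg_len = 4000)
  expect_lt(abs(unname(pr["r1_psd_peak_freq"]) - peak), 2)
})

test_that("Stuart-Landau origin is fixed and decay matches the linear rate", {
  p <- stuart_landau_params(1, G = 0, sigma = 0)
  sim <- simulate_stuart_landau(single_node_sc(), p, duration = 1, dt = 1e-4,
                                seed = 1, init = matrix(0, 2, 1))
  expect_identical(max(abs(sim$states)), 0)
  # amplitude envelope of the damped oscillator decays as exp(a t), a = -5
  sim2 <- simulate_stuart_landau(single_node_sc(), p, duration = 0.6,
                                 dt = 1e-4, seed = 1,
                                 init = rbind(0.1, 0))
  env <- abs(sim2$states[1, ]) # |Re Z| peaks trace the envelope
  pk <- which(diff(sign(diff(env))) == -2) + 1
  fit <- stats::lm(log(env[pk]) ~ sim2$time[pk])
  expect_equal(unname(stats::coef(fit)[2]), -5, tolerance = 0.05)
})

test_that("noise-driven Stuart-Landau node peaks at its natural frequency", {
  p <- stuart_landau_params(1, G = 0, sigma = 1e-4)
  sim <- simulate_stuart_landau(single_node_sc(), p, duration = 4, dt = 1e-4,
                                seed = 3)
  sim <- remove_transient(sim, 0.1)
  ps <- psd_summary(sim$states, fs = 1e4, seg_len = 18000)
  df <- 1e4 / 18000
  expect_lte(abs(unname(ps["r1_psd_peak_freq"]) - 40), df + 1e-9)
})

test_that("Stuart-Landau stationary variance follows the OU closed form", {
  # linearized at the stable focus: Var[Re Z] = sigma^2 / (2 |a|)
  for (sg in c(1e-4, 2e-4)) {
    p <- stuart_landau_params(1, G = 0, sigma = sg)
    sim <- simulate_stuart_landau(single_node_sc(), p, duration = 100,
                                  dt = 1e-4, seed = 6, record_every = 10L)
    sim <- remove_transient(sim, 0.05)
    expect_equal(stats::var(sim$states[1, ]), sg^2 / 10, tolerance = 0.1)
  }
})

test_that("delay configuration errors when dt cannot resolve a delay", {
  sc <- two_node_sc(d_mm = 0.3) # 0.3 mm at 6 m/s -> 5e-5 s delay
  p <- stuart_landau_params(2, G = 10, velocity = 6)
  expect_error(simulate_stuart_landau(sc, p, duration = 0.1, dt = 1e-3),
               "delay")
})

test_that("healthy Epileptor node settles at the root-solved equilibrium", {
  skip_if_not_installed("pracma")
  p <- epileptor_params(1, eta = -3.65, G = 0)
  rhs <- function(s) {
    x <- s[1]; z <- s[2]
    c(1 - x^3 - 2 * x^2 - z + p$I, (4 * (x - (-3.65)) - z) / p$tau)
  }
  root <- pracma::fsolve(rhs, c(-2, 6))$x
  sim <- simulate_epileptor2d(single_node_sc(), p, duration = 4000, dt = 0.05,
                              seed = 1)
  expect_equal(sim$states[1, ncol(sim$states)], root[1], tolerance = 1e-5)
  # no seizure oscillation late in the run
  late <- sim$states[1, seq(0.9 * ncol(sim$states), ncol(sim$states))]
  expect_lt(max(late) - min(late), 1e-6)
})

test_that("identical Epileptor regions stay identical when uncoupled", {
  sc <- small_sc(6, 0.5, 2)
  p <- epileptor_params(6, eta = -2.0, G = 0)
  init <- rbind(rep(-1.9, 6), rep(5, 6))
  sim <- simulate_epileptor2d(sc, p, duration = 100, dt = 0.05, seed = 1,
                              init = init)
  for (k in 2:6) expect_identical(sim$states[k, ], sim$states[1, ])
})

test_that("Montbrio keeps r positive and has the two root-solved attractors", {
  p <- montbrio_params(1, G = 0)
  sim <- simulate_montbrio(single_node_sc(), p, duration = 10000, dt = 0.01,
                           seed = 5, init = rbind(0.01, -2))
  expect_gt(min(sim$states), 0)
  # deterministic bistability: v = -Delta/(2 pi tau r) on the r-nullcline
  f <- function(r) {
    v <- -p$Delta / (2 * pi * p$tau * r)
    v^2 - (pi * p$tau * r)^2 + p$J * p$tau * r + p$eta[1]
  }
  roots <- sort(c(stats::uniroot(f, c(1e-4, 0.1))$root,
                  stats::uniroot(f, c(0.1, 1))$root,
                  stats::uniroot(f, c(1, 5))$root))
  jac_stable <- vapply(roots, function(r) {
    v <- -p$Delta / (2 * pi * p$tau * r)
    J11 <- 2 * v / p$tau; J12 <- 2 * r / p$tau
    J21 <- (-2 * pi^2 * p$tau^2 * r + p$J * p$tau) / p$tau; J22 <- 2 * v / p$tau
    all(Re(eigen(matrix(c(J11, J21, J12, J22), 2), only.values = TRUE)$values) < 0)
  }, logical(1))
  expect_equal(jac_stable, c(TRUE, FALSE, TRUE)) # down-state, saddle, up-state
  # deterministic runs started in either basin land on the matching root
  p0 <- montbrio_params(1, G = 0, sigma = 0)
  lo <- simulate_montbrio(single_node_sc(), p0, duration = 200, dt = 0.01,
                          seed = 1, init = rbind(0.02, -3))
  hi <- simulate_montbrio(single_node_sc(), p0, duration = 200, dt = 0.01,
                          seed = 1, init = rbind(roots[3] * 1.05, -0.05))
  expect_equal(lo$states[1, ncol(lo$states)], roots[1], tolerance = 1e-3)
  expect_equal(hi$states[1, ncol(hi$states)], roots[3], tolerance = 1e-3)
})

test_that("identical uncoupled Montbrio regions evolve identically", {
  sc <- small_sc(4, 0.9, 3)
  p <- montbrio_params(4, G = 0, sigma = 0)
  init <- rbind(rep(0.05, 4), rep(-2, 4))
  sim <- simulate_montbrio(sc, p, duration = 100, dt = 0.01, seed = 2,
                           init = init)
  for (k in 2:4) expect_identical(sim$states[k, ], sim$states[1, ])
})

test_that("Wong-Wang transfer function handles its removable singularity", {
  expect_equal(wong_wang_transfer(108 / 270), 1 / 0.154) # L'Hopital limit
  # high-precision reference at x = 0.5 via extended-precision arithmetic
  u <- 270 * 0.5 - 108
  ref <- u / (1 - exp(-0.154 * u)) # |du| large: direct evaluation is exact here
  expect_equal(wong_wang_transfer(0.5), ref, tolerance = 1e-12)
  # series branch is continuous across the switch
  eps <- 1e-7
  x0 <- 108 / 270
  expect_lt(abs(wong_wang_transfer(x0 + eps) - wong_wang_transfer(x0 - eps)),
            1e-4)
})

test_that("undriven Wong-Wang gating relaxes to the root-solved equilibrium", {
  p <- wong_wang_params(1, w = 0, I = 0, sigma = 0, G = 0)
  f <- function(S) -S / p$tau_s + (1 - S) * p$gamma * wong_wang_transfer(0)
  root <- stats::uniroot(f, c(0, 0.5))$root
  sim <- simulate_wong_wang(single_node_sc(), p, duration = 2000, dt = 1,
                            seed = 1, init = 0)
  expect_equal(sim$states[1, ncol(sim$states)], root, tolerance = 1e-6)
  expect_true(all(sim$states >= 0 & sim$states <= 1))
})

test_that("pDMF expansion applies the linear maps and broadcasts intercepts", {
  maps <- generate_synthetic_maps(88, seed = 1)
  cf <- c(a_w = 0, b_w = 0, c_w = 0.6, a_I = 0.01, b_I = 0.02, c_I = 0.3,
          a_sigma = 0, b_sigma = 0, c_sigma = 0.005)
  out <- pdmf_expand(cf, maps$mye, maps$grad)
  expect_equal(nrow(out), 88)
  expect_equal(out$w, rep(0.6, 88))
  expect_equal(out$I, 0.01 * maps$mye + 0.02 * maps$grad + 0.3)
  # 3 regional parameter maps x 88 regions expressed through 9 coefficients
  expect_equal(3 * nrow(out), 264)
  expect_length(cf, 9)
  zero <- pdmf_expand(cf, rep(0, 4), rep(0, 4))
  expect_equal(zero$sigma, rep(0.005, 4))
  expect_error(pdmf_expand(cf[1:5], maps$mye, maps$grad), "9 coefficients")
  expect_error(pdmf_expand(cf, maps$mye, maps$grad[1:3]), "equal length")
})

test_that("every model factorizes over regions at zero coupling", {
  sc <- two_node_sc()
  cases <- list(
    list(id = "wilson_cowan", par1 = wilson_cowan_params(1, P = 1, sigma = 0.005),
         par2 = wilson_cowan_params(2, P = 1, sigma = 0.005),
         args = list(duration = 20, dt = 0.05)),
    list(id = "stuart_landau", par1 = stuart_landau_params(1, G = 0),
         par2 = stuart_landau_params(2, G = 0),
         args = list(duration = 0.5, dt = 1e-4)),
    list(id = "montbrio", par1 = montbrio_params(1, G = 0),
         par2 = montbrio_params(2, G = 0),
         args = list(duration = 50, dt = 0.01)),
    list(id = "wong_wang", par1 = wong_wang_params(1, G = 0),
         par2 = wong_wang_params(2, G = 0),
         args = list(duration = 500, dt = 1))
  )
  for (cs in cases) {
    net <- do.call(simulate_model,
                   c(list(cs$id, sc, cs$par2, seed = 11), cs$args))
    iso2 <- do.call(simulate_model,
                    c(list(cs$id, single_node_sc(), cs$par1, seed = 11,
                           node_ids = 1L), cs$args))
    expect_identical(net$states[2, ], iso2$states[1, ], label = cs$id)
  }
})

test_that("simulations are bit-identical under a repeated seed", {
  sc <- small_sc(5, 0.6, 4)
  p <- montbrio_params(5)
  a <- simulate_montbrio(sc, p, duration = 100, dt = 0.01, seed = 21)
  b <- simulate_montbrio(sc, p, duration = 100, dt = 0.01, seed = 21)
  expect_identical(a$states, b$states)
  c2 <- simulate_montbrio(sc, p, duration = 100, dt = 0.01, seed = 22)
  expect_false(identical(a$states, c2$states))
})

test_that("deterministic Heun converges at second order", {
  sc <- single_node_sc()
  end_state <- function(dt) {
    p <- stuart_landau_params(1, G = 0, sigma = 0)
    s <- simulate_stuart_landau(sc, p, duration = 0.2, dt = dt, seed = 1,
                                init = rbind(0.5, 0.2))
    s$states[1, ncol(s$states)]
  }
  ref <- end_state(1e-5)
  e1 <- abs(end_state(8e-4) - ref)
  e2 <- abs(end_state(4e-4) - ref)
  order <- log2(e1 / e2)
  expect_gte(order, 1.7)
})

test_that("divergent integrations raise an error naming the step", {
  sc <- single_node_sc()
  p <- wilson_cowan_params(1, sigma = 0)
  expect_error(simulate_wilson_cowan(sc, p, duration = 10, dt = 0.05,
                                     init = rbind(1e308, 0)),
               "diverged")
})
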