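test_that("medium response implements the generalised Stokes relation", {
  # Newtonian: no medium stiffness, constant drag 6 pi eta a
  mr <- medium_response(newtonian_params(0.3), a = 1, omega = c(1, 10, 100))
  expect_equal(mr$kappa_m, rep(0, 3), tolerance = 1e-9)
  expect_equal(mr$xi_m, rep(6 * pi * 0.3, 3), tolerance = 1e-9)
  # Maxwell at omega tau = 1
  mr2 <- medium_response(burgers_params(0, 0, 1, 1), a = 1, omega = 1)
  expect_equal(mr2$kappa_m, 6 * pi * 0.5)
  expect_equal(mr2$xi_m, 6 * pi * 0.5)
  # cross-module identity with complex_moduli
  p <- burgers_params(0.1, 0.005, 0.2, 0.045)
  mr3 <- medium_response(p, a = 1, omega = 2 * pi)
  m <- complex_moduli(p, 2 * pi)
  expect_equal(mr3$kappa_m, 6 * pi * m$g_prime)
  expect_equal(mr3$xi_m, 6 * pi * m$g_dprime / (2 * pi))
  # flagged analytic zero-frequency limit
  mr0 <- medium_response(p, a = 1, omega = 0)
  expect_equal(mr0$xi_m, 6 * pi * 0.3)
  expect_true(attr(mr0, "zero_frequency_limit"))
})

test_that("the passive spectrum reduces to the Lorentzian for a Newtonian medium", {
  cfg <- sim_config(310, 1000, 10, seed = 1)
  eta <- 0.3
  wc <- 310 / (6 * pi * eta * 1)
  w <- 10^seq(-1, 3, length.out = 50)
  P <- passive_psd(newtonian_params(eta), cfg, w)
  P0 <- 2 * kbt_room() / (310 * wc)
  expect_equal(P, P0 / ((w / wc)^2 + 1), tolerance = 1e-9)
  expect_true(all(P > 0))
  # high-frequency asymptote of the Burgers spectrum: drag against the
  # saturated medium-plus-trap stiffness
  p <- burgers_params(0.1, 0.005, 0.2, 0.045)
  whi <- 1e5 / p$tau0
  mr <- medium_response(p, 1, whi)
  km_inf <- 6 * pi * (p$eta0 / p$tau0 + p$eta1 / p$tau1)
  asym <- 2 * kbt_room() * mr$xi_m / (310 + km_inf)^2
  expect_equal(passive_psd(p, cfg, whi), asym, tolerance = 5e-3)
})

test_that("passive traces satisfy equipartition and are seed-deterministic", {
  p <- burgers_params(0.1, 0.005, 0.2, 0.045)
  cfg <- sim_config(310, 1000, 100, seed = 42)
  tr <- simulate_passive_trace(p, cfg)
  target <- kbt_room() / 310
  # variance-estimator spread for this correlated trace is ~1.5%;
  # 5% covers three standard errors
  expect_lt(abs(var(tr$values) - target) / target, 0.05)
  expect_equal(mean(tr$values), 0, tolerance = 1e-3 * sqrt(target))
  tr2 <- simulate_passive_trace(p, cfg)
  expect_identical(tr$values, tr2$values)
})

test_that("synthesised spectra match the target density bin by bin", {
  # Newtonian medium, floor disabled: the periodogram should agree with
  # the Lorentzian at every bin within 5 standard errors over 50 seeds
  eta <- 0.3
  cfgs <- lapply(1:50, function(s) sim_config(310, 1000, 4.096, seed = s))
  acc <- NULL
  for (cfg in cfgs) {
    tr <- simulate_passive_trace(newtonian_params(eta), cfg,
                                 equipartition_floor = FALSE)
    ps <- periodogram(tr)
    acc <- if (is.null(acc)) ps$density else acc + ps$density
    omega <- ps$omega
  }
  mean_dens <- acc / 50
  target <- passive_psd(newtonian_params(eta),
                        sim_config(310, 1000, 4.096, seed = 1), omega)
  se <- target / sqrt(50) # periodogram bins are ~exponential
  expect_true(all(abs(mean_dens - target) < 5 * se))
})

test_that("spectral synthesis converges to the target total power", {
  p <- burgers_params(0.1, 0.01, 0.43, 0.125)
  err_at <- function(dur) {
    cfg0 <- sim_config(310, 1000, dur, seed = 1)
    target <- integrate(function(w) passive_psd(p, cfg0, w),
                        1e-9, pi * 1000, rel.tol = 1e-9)$value / pi
    errs <- sapply(1:6, function(s) {
      cfg <- sim_config(310, 1000, dur, seed = s)
      tr <- simulate_passive_trace(p, cfg, equipartition_floor = FALSE)
      abs(var(tr$values) - target) / target
    })
    mean(errs)
  }
  errs <- sapply(c(4, 16, 64), err_at)
  expect_lt(errs[3], errs[1]) # longer traces estimate the power better
  expect_lt(errs[3], 0.05)
})

test_that("driven traces solve the trap-medium force balance exactly", {
  # Newtonian closed form at kappa_t = 310, eta = 0.3, omega = 2 pi
  cfg <- sim_config(310, 1000, 10, seed = 3)
  dr <- simulate_driven_trace(newtonian_params(0.3), cfg, omega = 2 * pi,
                              thermal_noise = FALSE)
  expect_equal(dr$force$meta$F_t0, 35.29947578396646, tolerance = 1e-9)
  expect_equal(dr$force$meta$Delta, 1.45667952755798, tolerance = 1e-9)
  xi <- 6 * pi * 0.3
  expect_equal(dr$force$meta$Delta,
               pi / 2 - atan(2 * pi * xi / 310), tolerance = 1e-12)
  # nearly elastic medium: in-phase springs in series
  k <- 50 # target medium stiffness, pN/um
  pel <- burgers_params(0, 0, k / (6 * pi) * 1e6, 1e6)
  drel <- simulate_driven_trace(pel, cfg, omega = 2 * pi,
                                thermal_noise = FALSE)
  expect_equal(drel$force$meta$F_t0, 310 * k / (310 + k), tolerance = 1e-3)
  expect_equal(drel$force$meta$Delta, 0, tolerance = 1e-3)
  # the noise-free branch makes no stochastic calls
  set.seed(99); ref <- rnorm(1)
  set.seed(99)
  invisible(simulate_driven_trace(newtonian_params(0.3), cfg, omega = 2 * pi,
                                  thermal_noise = FALSE))
  expect_identical(rnorm(1), ref)
})

test_that("noise-free driven traces invert to the generating moduli", {
  for (cond in condensate_presets()) {
    for (w in 2 * pi * c(0.5, 2, 40)) {
      cfg <- sim_config(cond$kappa_t, 1000, 10, seed = 5)
      dr <- simulate_driven_trace(cond$params, cfg, omega = w,
                                  thermal_noise = FALSE)
      of <- oscillation_fit(fit_cosine(dr$trap, w), fit_cosine(dr$force, w),
                            kappa_t = cond$kappa_t)
      g <- moduli_from_oscillation(of, a = 1)
      m <- complex_moduli(cond$params, w)
      expect_equal(g[["g_prime"]], m$g_prime, tolerance = 1e-9)
      expect_equal(g[["g_dprime"]], m$g_dprime, tolerance = 1e-9)
    }
  }
})

test_that("stretch simulation composes the tension geometry correctly", {
  cfg <- sim_config(600, 1000, 1, seed = 8)
  # frozen hand evaluation of chi0 for gamma = 57.1, R = 5, a = 1
  sim <- simulate_stretch_experiment(57.1, 5, 1, 600, 600, 0.05, cfg)
  expect_equal(sim$force1$meta$chi0, 86.81480426765241, tolerance = 1e-12)
  # rigid traps: slope difference 2 v chi0
  simr <- simulate_stretch_experiment(57.1, 5, 1, 1e12, 1e12, 0.05, cfg)
  t <- trace_times(simr$force2)
  f2 <- coef(lm(simr$force2$values ~ t))[2]
  f1 <- coef(lm(simr$force1$values ~ t))[2]
  expect_equal(unname(f2 - f1), 2 * 0.05 * simr$force1$meta$chi0,
               tolerance = 1e-9)
  expect_error(simulate_stretch_experiment(57.1, 2.9, 1, 600, 600, 0.05, cfg),
               "theta0")
})

test_that("rupture ramps peak at 2 pi a f gamma", {
  cfg <- sim_config(1600, 1000, 20, seed = 4)
  # the discrete grid samples the peak to within one time step
  tr <- simulate_rupture_trace(1 / (2 * pi), a = 1, f = 1, v = 0.1, cfg = cfg)
  expect_equal(max(tr$values), 1, tolerance = 1e-6)
  tr2 <- simulate_rupture_trace(57.1, a = 1, f = 1.1, v = 0.1, cfg = cfg)
  expect_equal(max(tr2$values), 394.6468691439498, tolerance = 1e-6)
  expect_equal(tr2$meta$F_rup, 2 * pi * 1.1 * 57.1)
  # the trace collapses after rupture
  expect_lt(min(tr2$values[which.max(tr2$values):length(tr2$values)]), 1)
})

test_that("fusion datasets realise the tau proportional to R law", {
  d <- simulate_fusion_dataset(10.1, radii = 3, noise_sd = 0, seed = 1)
  expect_equal(d$tau_fu, 30.3)
  d2 <- simulate_fusion_dataset(6.7, radii = 3, noise_sd = 0, seed = 1)
  expect_equal(d2$tau_fu, 20.1)
  expect_error(simulate_fusion_dataset(10, radii = c(0.5, 3), seed = 1),
               "range")
  # noisy fit recovers the slope within 3 standard errors
  radii <- seq(0.8, 4, length.out = 17)
  d3 <- simulate_fusion_dataset(10.1, radii, noise_sd = 2, seed = 77)
  f <- fit_fusion_speed(d3)
  expect_lt(abs(f$inverse_speed - 10.1), 3 * f$se)
  expect_true(all(d3$tau_fu > 0))
  # seeded determinism
  d4 <- simulate_fusion_dataset(10.1, radii, noise_sd = 2, seed = 77)
  expect_identical(d3$tau_fu, d4$tau_fu)
})
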