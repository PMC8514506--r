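test_that("the periodogram carries the variance convention of the analysis", {
  # pure sinusoid: spectral mass A^2/2 concentrated at the drive bin
  dt <- 1e-3; n <- 4096; A <- 0.7
  w0 <- 2 * pi * 205 / (n * dt) # exactly on a frequency bin
  tr <- time_trace(A * cos(w0 * dt * (0:(n - 1))), dt = dt,
                   channel = "bead_position_um")
  ps <- periodogram(tr)
  dw <- diff(ps$omega[1:2])
  i0 <- which.min(abs(ps$omega - w0))
  mass <- sum(ps$density[(i0 - 1):(i0 + 1)]) * dw / pi
  expect_equal(mass, A^2 / 2, tolerance = 1e-6)
  # white noise integrates to its variance (50 seeds, well within 5 SE)
  tot <- sapply(1:50, function(s) {
    set.seed(s)
    wn <- time_trace(rnorm(n, 0, 2), dt = dt, channel = "bead_position_um")
    psn <- periodogram(wn)
    sum(psn$density) * diff(psn$omega[1:2]) / pi
  })
  se <- 4 * sqrt(2 / n) / sqrt(50)
  expect_lt(abs(mean(tot) - 4), 5 * se)
  # constant trace: zero density
  cst <- time_trace(rep(1.5, 64), dt = dt, channel = "bead_position_um")
  expect_true(all(periodogram(cst)$density < 1e-25))
  expect_error(periodogram(cst, n_segments = 64), "too short")
})

test_that("exact spectra round-trip through the Lorentzian fits", {
  w <- 10^seq(1, 5.2, length.out = 400)
  wc <- 2 * pi * 3273
  ps <- power_spectrum(w, 1 / ((w / wc)^2 + 1))
  fit <- fit_lorentzian(ps, log_bin = FALSE, dynamic_range = Inf)
  expect_equal(fit$p0, 1, tolerance = 1e-8)
  expect_equal(fit$omega_eff, wc, tolerance = 1e-8)
  expect_identical(fit$alpha, 2)
  # stretched form with alpha = 1.6
  we <- 2 * pi * 8
  w2 <- 10^seq(-1, 3, length.out = 400)
  ps2 <- power_spectrum(w2, 1 / ((w2 / we)^1.6 + 1))
  fit2 <- fit_stretched_lorentzian(ps2, log_bin = FALSE, dynamic_range = Inf)
  expect_equal(fit2$p0, 1, tolerance = 1e-8)
  expect_equal(fit2$omega_eff, we, tolerance = 1e-8)
  expect_equal(fit2$alpha, 1.6, tolerance = 1e-8)
  # nested-model consistency at alpha = 2
  ps3 <- power_spectrum(w2, 3 / ((w2 / we)^2 + 1))
  fit3 <- fit_stretched_lorentzian(ps3, log_bin = FALSE, dynamic_range = Inf)
  expect_equal(fit3$alpha, 2, tolerance = 1e-6)
})

test_that("corner frequency of water-like traces estimates the Stokes drag corner", {
  eta <- eta_water()
  wc_true <- 307 / (6 * pi * eta)
  est <- sapply(1:8, function(s) {
    cfg <- sim_config(307, 131072, 2, seed = s)
    tr <- simulate_passive_trace(newtonian_params(eta), cfg)
    fit_lorentzian(periodogram(tr, n_segments = 8), dynamic_range = 20)$omega_eff
  })
  se <- sd(est) / sqrt(8)
  expect_lt(abs(mean(est) - wc_true), 3 * se + 0.02 * wc_true)
  # a viscoelastic spectrum prefers the stretched model
  p <- burgers_params(0.1, 0.005, 0.2, 0.045)
  cfgv <- sim_config(310, 1000, 60, seed = 2)
  psv <- periodogram(simulate_passive_trace(p, cfgv), n_segments = 8)
  expect_gt(fit_lorentzian(psv)$residual,
            fit_stretched_lorentzian(psv)$residual)
})

test_that("droplet-like spectra put the effective corner below 10 Hz", {
  p <- burgers_params(0.1, 0.005, 0.2, 0.045) # eta ~ 0.3 Pa s
  cfg <- sim_config(310, 1000, 120, seed = 6)
  ps <- periodogram(simulate_passive_trace(p, cfg), n_segments = 12)
  fit <- fit_stretched_lorentzian(ps)
  expect_lt(fit$omega_eff / (2 * pi), 10)
  expect_gt(fit$alpha, 1)
  expect_lte(fit$alpha, 3)
})

test_that("stiffness from the corner frequency is linear in drag", {
  expect_equal(stiffness_from_corner(1, 1, 1 / (6 * pi)), 1)
  expect_equal(stiffness_from_corner(2 * pi * 3273, 1, 8.9e-4), 345.0,
               tolerance = 1e-4)
  expect_equal(stiffness_from_corner(10, 2, 0.3),
               2 * stiffness_from_corner(10, 1, 0.3))
})

test_that("the stretched-Lorentzian integral identity holds numerically", {
  # alpha sin(pi/alpha) kBT / (omega_eff P0) = kBT / ((1/pi) int P)
  for (alpha in c(1.2, 1.6, 2, 2.5)) {
    p0 <- 2.3; we <- 40
    num <- integrate(function(w) p0 / ((w / we)^alpha + 1), 0, Inf,
                     rel.tol = 1e-10)$value / pi
    lhs <- alpha * sin(pi / alpha) * kbt_room() / (we * p0)
    expect_equal(lhs, kbt_room() / num, tolerance = 1e-6)
  }
})

test_that("at alpha = 2 the first identity reduces to the Lorentzian form", {
  fit <- structure(list(p0 = 5e-5, omega_eff = 120, alpha = 2,
                        residual = 0, model = "lorentzian",
                        low_confidence = FALSE),
                   class = "spectrum_fit")
  drive <- make_volt_drive(omega = 2, X_t0 = 1, F_V0 = 0.4, Delta = 1.2)
  cal <- active_passive_calibrate(power_spectrum(1:10, rep(1e-5, 10), "V"),
                                  fit, drive)
  expect_equal(cal$kappa_t * cal$epsilon^2,
               2 * kbt_room() / (fit$omega_eff * fit$p0), tolerance = 1e-12)
})

test_that("active-passive calibration recovers stiffness and conversion in water", {
  eta <- eta_water(); kt <- 307; eps <- 0.1
  cfgc <- sim_config(kt, 131072, 8, seed = 1)
  ps <- periodogram(trace_to_volts(simulate_passive_trace(newtonian_params(eta),
                                                          cfgc), eps),
                    n_segments = 16)
  sf <- fit_lorentzian(ps, dynamic_range = 20)
  cfgd <- sim_config(kt, 8192, 60, seed = 501)
  drv <- simulate_driven_trace(newtonian_params(eta), cfgd, omega = 2 * pi,
                               amplitude = 1)
  of <- oscillation_fit(fit_cosine(drv$trap, 2 * pi),
                        fit_cosine(trace_to_volts(drv$force, eps,
                                                  kappa_t = kt), 2 * pi),
                        kappa_t = NA, force_in_volts = TRUE)
  cal <- active_passive_calibrate(ps, sf, of)
  expect_lt(abs(cal$kappa_t - kt) / kt, 0.20)
  expect_lt(abs(cal$epsilon - eps) / eps, 0.10)
  expect_identical(cal$method, "active_passive")
})

test_that("water-like stiffness estimates disperse within the measured spread", {
  # replicate spread of the stiffness estimator is comparable to the
  # experimental bead-to-bead spread (~11%)
  eta <- eta_water(); kt <- 307; eps <- 0.1
  est <- sapply(1:8, function(s) {
    cfgc <- sim_config(kt, 131072, 4, seed = s)
    ps <- periodogram(trace_to_volts(simulate_passive_trace(
      newtonian_params(eta), cfgc), eps), n_segments = 8)
    sf <- fit_lorentzian(ps, dynamic_range = 20)
    cfgd <- sim_config(kt, 8192, 30, seed = s + 500)
    drv <- simulate_driven_trace(newtonian_params(eta), cfgd,
                                 omega = 2 * pi, amplitude = 1)
    of <- oscillation_fit(fit_cosine(drv$trap, 2 * pi),
                          fit_cosine(trace_to_volts(drv$force, eps,
                                                    kappa_t = kt), 2 * pi),
                          kappa_t = NA, force_in_volts = TRUE)
    active_passive_calibrate(ps, sf, of)$kappa_t
  })
  expect_lt(sd(est) / mean(est), 0.11)
  expect_lt(abs(mean(est) - kt) / kt, 0.10)
})

test_that("calibration round-trips inside a droplet-like medium", {
  # Estimator dispersion measured over 24 seeds at these settings is
  # ~12% (kappa_t) and ~6% (epsilon); tolerances cover ~2.5 spreads.
  p <- burgers_params(0.1, 0.005, 0.2, 0.045)
  kt <- 310; eps <- 0.1
  cfgc <- sim_config(kt, 1000, 120, seed = 3)
  ps <- periodogram(trace_to_volts(simulate_passive_trace(p, cfgc), eps),
                    n_segments = 12)
  sf <- fit_stretched_lorentzian(ps)
  cfgd <- sim_config(kt, 1000, 60, seed = 503)
  drv <- simulate_driven_trace(p, cfgd, omega = 2 * pi * 0.2, amplitude = 1)
  of <- oscillation_fit(fit_cosine(drv$trap, 2 * pi * 0.2),
                        fit_cosine(trace_to_volts(drv$force, eps,
                                                  kappa_t = kt),
                                   2 * pi * 0.2),
                        kappa_t = NA, force_in_volts = TRUE)
  cal <- active_passive_calibrate(ps, sf, of)
  expect_lt(abs(cal$kappa_t - kt) / kt, 0.30)
  expect_lt(abs(cal$epsilon - eps) / eps, 0.15)
})

test_that("rescaling the volt channels rescales epsilon and not the stiffness", {
  fit <- structure(list(p0 = 5e-5, omega_eff = 120, alpha = 1.6,
                        residual = 0, model = "stretched",
                        low_confidence = FALSE),
                   class = "spectrum_fit")
  drive <- make_volt_drive(omega = 2, X_t0 = 1, F_V0 = 0.4, Delta = 1.2)
  cal <- active_passive_calibrate(power_spectrum(1:10, rep(1e-5, 10), "V"),
                                  fit, drive)
  # multiply volt readings by c: densities scale by c^2, F_V0 by c
  c0 <- 3
  fit2 <- fit; fit2$p0 <- fit$p0 * c0^2
  drive2 <- make_volt_drive(omega = 2, X_t0 = 1, F_V0 = 0.4 * c0, Delta = 1.2)
  cal2 <- active_passive_calibrate(power_spectrum(1:10, rep(1e-5, 10), "V"),
                                   fit2, drive2)
  expect_equal(cal2$epsilon, cal$epsilon / c0, tolerance = 1e-12)
  expect_equal(cal2$kappa_t, cal$kappa_t, tolerance = 1e-12)
})

test_that("unphysical calibration inputs are rejected", {
  fit <- structure(list(p0 = 5e-5, omega_eff = 120, alpha = 3.5,
                        residual = 0, model = "stretched",
                        low_confidence = FALSE),
                   class = "spectrum_fit")
  drive <- make_volt_drive(omega = 2, X_t0 = 1, F_V0 = 0.4, Delta = 1.2)
  ps <- power_spectrum(1:10, rep(1e-5, 10), "V")
  expect_error(active_passive_calibrate(ps, fit, drive), "alpha")
  fit$alpha <- 2
  drive_bad <- make_volt_drive(omega = 2, X_t0 = 1, F_V0 = 0.4, Delta = -0.5)
  expect_error(active_passive_calibrate(ps, fit, drive_bad), "sin\\(Delta\\)")
})
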