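#' Simulation configuration
#'
#' Collects the physical and sampling parameters shared by the trace
#' generators.  Inertia is neglected throughout: for a 1-um bead in
#' media of >= 0.3 Pa s the inertial corner lies far above the
#' experimental band, so the bead dynamics are overdamped.
#'
#' @param trap_stiffness trap stiffness `kappa_t` (pN/um, > 0).
#' @param sampling_rate sampling rate (Hz, > 0).
#' @param duration trace duration (s, > 0).
#' @param seed integer seed; mandatory for every stochastic generator.
#' @param kBT thermal energy (pN um); default room temperature.
#' @param bead_radius bead radius `a` (um); the experiments use 2-um
#'   diameter polystyrene beads, so the default is 1.
#' @param volt_per_um optional inverse detector conversion for
#'   fabricating volt-channel output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(trap_stiffness, sampling_rate, duration, seed,
                       kBT = kbt_room(), bead_radius = 1,
                       volt_per_um = NULL) {
  stopifnot(trap_stiffness > 0, sampling_rate > 0, duration > 0,
            kBT > 0, bead_radius > 0)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory")
  structure(list(trap_stiffness = trap_stiffness,
                 sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed), kBT = kBT,
                 bead_radius = bead_radius, volt_per_um = volt_per_um),
            class = "sim_config")
}

#' Medium response of a bead in a viscoelastic fluid
#'
#' The generalised Stokes relation maps the complex shear modulus to the
#' spring constant and friction coefficient felt by a bead of radius
#' `a`: `6 pi a G*(omega) = kappa_m + i omega xi_m`, so
#' `kappa_m = 6 pi a G'(omega)` and `xi_m = 6 pi a G''(omega)/omega`.
#' At `omega = 0` the analytic limit `(0, 6 pi a (eta0 + eta1))` is
#' returned, flagged with attribute `zero_frequency_limit`.
#'
#' @param params a [burgers_params].
#' @param a bead radius (um).
#' @param omega angular frequency (rad/s, >= 0); vectorised.
#' @return a data frame with columns `omega`, `kappa_m` (pN/um) and
#'   `xi_m` (pN s/um).
#' @export
medium_response <- function(params, a, omega) {
  stopifnot(inherits(params, "burgers_params"), a > 0)
  if (any(omega < 0)) stop("omega must be >= 0")
  m <- complex_moduli(params, omega)
  kappa_m <- stokes_factor(a) * m$g_prime
  xi_m <- ifelse(omega > 0, stokes_factor(a) * m$g_dprime / omega,
                 stokes_factor(a) * (params$eta0 + params$eta1))
  out <- data.frame(omega = omega, kappa_m = kappa_m, xi_m = xi_m)
  if (any(omega == 0)) attr(out, "zero_frequency_limit") <- TRUE
  out
}

#' Power spectral density of passive bead-position fluctuations
#'
#' One-sided spectral density of the thermal position fluctuations of a
#' trapped bead in a Burgers medium (overdamped; the inertial term is
#' dropped):
#' \deqn{P_x(\omega) = \frac{2 k_B T\, \xi_m(\omega)}
#'   {|\kappa_t + \kappa_m(\omega) + i\omega\,\xi_m(\omega)|^2}}
#' with the normalisation convention that the sample variance equals
#' `(1/pi) * integral of P_x over omega > 0`.  For a Newtonian medium
#' this reduces to the Lorentzian of a Brownian harmonic oscillator with
#' corner `omega_c = kappa_t / (6 pi eta a)`.
#'
#' @param params a [burgers_params].
#' @param cfg a [sim_config] (supplies `kappa_t`, `a`, `kBT`).
#' @param omega angular frequency (rad/s, > 0); vectorised.
#' @return spectral density in um^2 s, same length as `omega`.
#' @export
passive_psd <- function(params, cfg, omega) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(omega <= 0)) stop("omega must be > 0")
  mr <- medium_response(params, cfg$bead_radius, omega)
  denom <- (cfg$trap_stiffness + mr$kappa_m)^2 + (omega * mr$xi_m)^2
  2 * cfg$kBT * mr$xi_m / denom
}

#' Simulate a passive (thermal) bead-position trace
#'
#' Generates a stationary zero-mean Gaussian trace whose one-sided power
#' spectral density equals [passive_psd()], by frequency-domain
#' synthesis: independent complex Gaussian Fourier coefficients with
#' variance proportional to the target density, Hermitian symmetry, and
#' an inverse FFT.  This realises the target spectrum exactly (no
#' time-stepping discretisation bias) and is bit-reproducible for a
#' given seed.
#'
#' By equipartition, the equilibrium position variance of a bead in any
#' fluid is exactly `kBT / kappa_t`: the medium exerts no static
#' restoring force.  The overdamped in-band spectrum alone carries less
#' than this when the medium has instantaneous elasticity
#' (`kappa_m(Inf) > 0`), because the balance of the variance resides in
#' fast vibrational motion far above the sampled band (at the inertial
#' resonance, hundreds of kHz for a micron bead).  In sampled real data
#' that unresolved fast power appears as a flat floor; with
#' `equipartition_floor = TRUE` (default) the generator adds a white
#' component carrying exactly the missing variance, so the sample
#' variance of the trace is `kBT / kappa_t` in expectation.  Set it to
#' `FALSE` to obtain a trace whose spectrum is the bare in-band target.
#'
#' @inheritParams passive_psd
#' @param equipartition_floor add the white component that restores the
#'   exact equilibrium variance (see Details).
#' @return a [time_trace] (`bead_position_um`) with provenance in
#'   `meta`.
#' @export
simulate_passive_trace <- function(params, cfg, equipartition_floor = TRUE) {
  stopifnot(inherits(params, "burgers_params"), inherits(cfg, "sim_config"))
  n <- round(cfg$duration * cfg$sampling_rate)
  if (n < 1024) stop("duration * sampling_rate must be >= 1024 samples")
  dt <- 1 / cfg$sampling_rate
  psd <- function(w) passive_psd(params, cfg, w)
  if (equipartition_floor) {
    w_nyq <- pi / dt
    in_band <- stats::integrate(psd, 0 + 1e-12, w_nyq,
                                rel.tol = 1e-10)$value / pi
    deficit <- max(0, cfg$kBT / cfg$trap_stiffness - in_band)
    floor_density <- deficit * pi / w_nyq # flat one-sided density
    psd <- function(w) passive_psd(params, cfg, w) + floor_density
  }
  x <- synth_gaussian_trace(psd, n, dt, cfg$seed)
  time_trace(x, dt = dt, channel = "bead_position_um",
             meta = list(seed = cfg$seed, generator = "passive",
                         params = unclass(params),
                         trap_stiffness = cfg$trap_stiffness,
                         kBT = cfg$kBT, bead_radius = cfg$bead_radius))
}

## Spectral synthesis of a stationary Gaussian process.
## psd_fn(omega) is the one-sided density with variance = (1/pi) int P domega,
## numerically equal to the two-sided density in ordinary frequency,
## S(f) = P(2 pi f).  DC is set to zero (the process is zero-mean).
synth_gaussian_trace <- function(psd_fn, n, dt, seed) {
  set.seed(seed)
  m <- n %/% 2
  f <- (1:m) / (n * dt)
  S <- psd_fn(2 * pi * f)
  amp <- sqrt(S * n / dt)
  X <- complex(length.out = n)
  even <- n %% 2 == 0
  k_half <- if (even) m - 1 else m
  z <- complex(real = stats::rnorm(k_half), imaginary = stats::rnorm(k_half)) /
    sqrt(2)
  X[2:(k_half + 1)] <- amp[1:k_half] * z
  if (even) X[m + 1] <- amp[m] * stats::rnorm(1) # Nyquist bin is real
  X[n:(n - k_half + 1)] <- Conj(X[2:(k_half + 1)])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Simulate a driven oscillation trace pair
#'
#' Produces the steady-state trap-position and trapping-force traces of
#' a bead driven sinusoidally in a Burgers medium.  The force phasor is
#' the exact solution of the overdamped balance between trap and medium:
#' with `Gm* = 6 pi a G*(omega)` the complex force amplitude is
#' `kappa_t Gm* X_t0 / (kappa_t + Gm*)`, so the force amplitude `F_t0`
#' and phase lead `Delta` over the trap position are reproduced exactly.
#' When `thermal_noise` is set, the force trace additionally carries
#' `kappa_t` times a passive thermal position trace (the thermal force
#' seen by the detector has the same spectral origin as the passive
#' fluctuations); the noise-free branch makes no stochastic calls.
#'
#' @inheritParams passive_psd
#' @param omega drive angular frequency (rad/s); the experimental band
#'   is 0.5-40 Hz.
#' @param amplitude trap oscillation amplitude `X_t0` (um).
#' @param phase trap phase at t = 0 (rad).
#' @param thermal_noise add thermal force noise to the force trace.
#' @return list with elements `trap` (`trap_position_um`), `force`
#'   (`force_pn`); ground truth (`X_t0`, `F_t0`, `Delta`) is recorded in
#'   each trace's `meta`.
#' @export
simulate_driven_trace <- function(params, cfg, omega, amplitude = 1,
                                  phase = 0, thermal_noise = TRUE) {
  stopifnot(inherits(params, "burgers_params"), inherits(cfg, "sim_config"),
            omega > 0, amplitude > 0)
  dt <- 1 / cfg$sampling_rate
  n <- round(cfg$duration * cfg$sampling_rate)
  t <- dt * (0:(n - 1))
  m <- complex_moduli(params, omega)
  Gm <- stokes_factor(cfg$bead_radius) * complex(real = m$g_prime,
                                                 imaginary = m$g_dprime)
  kt <- cfg$trap_stiffness
  Z <- kt * Gm / (kt + Gm) # force phasor per unit trap amplitude
  F_t0 <- Mod(Z) * amplitude
  Delta <- Arg(Z)
  gt <- list(X_t0 = amplitude, F_t0 = F_t0, Delta = Delta, omega = omega,
             phase = phase, seed = cfg$seed, params = unclass(params),
             trap_stiffness = kt)
  trap <- time_trace(amplitude * cos(omega * t + phase), dt = dt,
                     channel = "trap_position_um", meta = gt)
  fvals <- F_t0 * cos(omega * t + phase + Delta)
  if (thermal_noise) {
    ## same spectral origin as the passive fluctuations (incl. the
    ## equipartition floor), scaled to force by kappa_t
    noise <- simulate_passive_trace(params, cfg)$values
    fvals <- fvals + kt * noise
  }
  force <- time_trace(fvals, dt = dt, channel = "force_pn",
                      meta = c(gt, list(thermal_noise = thermal_noise)))
  list(trap = trap, force = force)
}

#' Simulate a two-trap droplet-stretching experiment
#'
#' A droplet suspended between two trapped beads is stretched by pulling
#' trap 1 at constant speed `v`.  The droplet's static spring constant
#' follows from the interfacial tension and the pole geometry,
#' `chi0 = (pi/2) alpha(theta0) gamma` with
#' `1/alpha(theta0) = -0.5 log(theta0) + 0.34` and
#' `theta0 = a/(R - a)`; the measured system spring constant composes
#' the droplet and the two traps as three springs in series.  Force
#' traces are linear ramps with slopes `-v chi_sys0` (trap 1) and
#' `+v chi_sys0` (trap 2), plus optional additive Gaussian noise.
#'
#' @param gamma interfacial tension (pN/um).
#' @param R unstretched droplet radius (um), with `R > 2a`.
#' @param a bead radius (um).
#' @param kappa_t1,kappa_t2 trap stiffnesses (pN/um).
#' @param v pulling speed (um/s, > 0).
#' @param cfg a [sim_config] (sampling rate and seed; the trace duration
#'   is `pull_distance / v`).
#' @param noise_sd additive force-noise standard deviation (pN).
#' @param pull_distance total trap-1 travel (um); the experiments pull
#'   close to 0.5 um.
#' @return list with `trap1` (position ramp), `force1`, `force2`
#'   ([time_trace]s) and ground truth (`gamma`, `chi0`, `chi_sys0`) in
#'   `meta`.
#' @export
simulate_stretch_experiment <- function(gamma, R, a, kappa_t1, kappa_t2, v,
                                        cfg, noise_sd = 0,
                                        pull_distance = 0.5) {
  stopifnot(gamma > 0, R > 2 * a, v != 0, kappa_t1 > 0, kappa_t2 > 0,
            inherits(cfg, "sim_config"))
  theta0 <- a / (R - a)
  if (theta0 > 0.5)
    stop("theta0 = a/(R-a) exceeds 0.5, outside the geometry-factor domain")
  alpha <- 1 / (-0.5 * log(theta0) + 0.34)
  chi0 <- pi / 2 * alpha * gamma
  chi_sys0 <- 1 / (1 / chi0 + 1 / kappa_t1 + 1 / kappa_t2)
  duration <- pull_distance / abs(v)
  dt <- 1 / cfg$sampling_rate
  t <- seq(0, duration, by = dt)
  gt <- list(gamma = gamma, chi0 = chi0, chi_sys0 = chi_sys0, theta0 = theta0,
             R = R, a = a, kappa_t1 = kappa_t1, kappa_t2 = kappa_t2, v = v,
             noise_sd = noise_sd, seed = cfg$seed)
  set.seed(cfg$seed)
  n1 <- if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  n2 <- if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  list(
    trap1 = time_trace(-v * t, dt = dt, channel = "trap_position_um",
                       meta = gt),
    force1 = time_trace(-v * chi_sys0 * t + n1, dt = dt,
                        channel = "force_pn", meta = gt),
    force2 = time_trace(v * chi_sys0 * t + n2, dt = dt,
                        channel = "force_pn", meta = gt)
  )
}

#' Simulate a surface-rupture force ramp
#'
#' A trapped bead pulled from inside a droplet stretches the interface
#' until the surface ruptures; the force rises to a peak
#' `F_rup = 2 pi a f gamma` and then collapses to ~0.  The peak location
#' within the trace is randomised by the seed.
#'
#' @param gamma interfacial tension (pN/um).
#' @param a bead radius (um).
#' @param f dimensionless rupture scaling constant (calibrated value
#'   1.1).
#' @param v pulling speed (um/s); sets the ramp rate bookkeeping only.
#' @param cfg a [sim_config].
#' @param noise_sd additive force-noise SD (pN).
#' @return a [time_trace] (`force_pn`) with ground truth in `meta`.
#' @export
simulate_rupture_trace <- function(gamma, a, f = 1.1, v = 0.1, cfg,
                                   noise_sd = 0) {
  stopifnot(gamma > 0, a > 0, f > 0, v > 0, inherits(cfg, "sim_config"))
  F_rup <- 2 * pi * a * f * gamma
  dt <- 1 / cfg$sampling_rate
  n <- round(cfg$duration * cfg$sampling_rate)
  t <- dt * (0:(n - 1))
  set.seed(cfg$seed)
  t_peak <- cfg$duration * stats::runif(1, 0.6, 0.85)
  t_drop <- min(0.05, cfg$duration / 20) # fast post-rupture collapse
  vals <- ifelse(t <= t_peak, F_rup * t / t_peak,
                 F_rup * pmax(0, 1 - (t - t_peak) / t_drop))
  if (noise_sd > 0) vals <- vals + stats::rnorm(n, 0, noise_sd)
  time_trace(vals, dt = dt, channel = "force_pn",
             meta = list(gamma = gamma, a = a, f = f, F_rup = F_rup,
                         t_peak = t_peak, v = v, noise_sd = noise_sd,
                         seed = cfg$seed))
}

#' Simulate a fusion-time-versus-radius dataset
#'
#' Fusion times proportional to droplet radius,
#' `tau_fu = inverse_speed * R`, plus Gaussian noise truncated to stay
#' positive, emulating the measured proportionality between fusion time
#' and radius.
#'
#' @param inverse_speed inverse fusion speed (ms/um, > 0).
#' @param radii droplet radii (um), within the measured range 0.8-8 um.
#' @param noise_sd Gaussian noise SD on the fusion times (ms).
#' @param seed integer seed.
#' @return a [fusion_dataset].
#' @export
simulate_fusion_dataset <- function(inverse_speed, radii, noise_sd = 0,
                                    seed) {
  stopifnot(inverse_speed > 0)
  if (any(radii < 0.8 | radii > 8))
    stop("radii must lie within the measured range 0.8-8 um")
  if (missing(seed) && noise_sd > 0) stop("a seed is mandatory")
  tau <- inverse_speed * radii
  if (noise_sd > 0) {
    set.seed(seed)
    tau <- tau + stats::rnorm(length(radii), 0, noise_sd)
    while (any(tau <= 0)) { # truncate to positive fusion times
      bad <- tau <= 0
      tau[bad] <- inverse_speed * radii[bad] +
        stats::rnorm(sum(bad), 0, noise_sd)
    }
  }
  fusion_dataset(R = radii, tau_fu = tau,
                 provenance = list(inverse_speed = inverse_speed,
                                   noise_sd = noise_sd,
                                   seed = if (missing(seed)) NULL else seed))
}
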