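#' Construct a power spectrum
#'
#' Builds a `power_spectrum` object from frequencies and one-sided
#' densities, e.g. for feeding an analytically known spectrum to the
#' fitting routines.  [periodogram()] produces the same structure from
#' a time trace.
#'
#' @param omega angular frequencies (rad/s), increasing and positive.
#' @param density one-sided spectral densities (unit^2 s), >= 0.
#' @param unit `"um"`, `"V"` or `"pN"`.
#' @param n_averages number of averaged segments the densities
#'   represent.
#' @return an object of class `power_spectrum`.
#' @export
power_spectrum <- function(omega, density, unit = "um", n_averages = 1) {
  stopifnot(all(omega > 0), !is.unsorted(omega), all(density >= 0))
  structure(data.frame(omega = omega, density = density),
            unit = unit, n_averages = n_averages,
            class = c("power_spectrum", "data.frame"))
}

#' Welch-averaged periodogram of a time trace
#'
#' Splits the trace into `n_segments` non-overlapping segments, removes
#' each segment's mean, and averages the per-segment periodograms.  The
#' one-sided density is normalised so that the sample variance equals
#' `(1/pi) * integral of P over omega` — the same convention as
#' [passive_psd()], so spectra and theory can be compared bin by bin.
#'
#' @param trace a [time_trace].
#' @param n_segments number of segments to average (>= 1).
#' @return an object of class `power_spectrum`: a data frame with
#'   columns `omega` (rad/s) and `density` (unit^2 s), plus attributes
#'   `unit` and `n_averages`.
#' @export
periodogram <- function(trace, n_segments = 1) {
  stopifnot(inherits(trace, "time_trace"), n_segments >= 1)
  n <- length(trace$values)
  m <- n %/% n_segments
  if (m < 2) stop("trace too short for the requested number of segments")
  dt <- trace$dt
  half <- m %/% 2
  acc <- numeric(half)
  for (s in seq_len(n_segments)) {
    seg <- trace$values[((s - 1) * m + 1):(s * m)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg)
    acc <- acc + (dt / m) * Mod(X[2:(half + 1)])^2
  }
  dens <- acc / n_segments
  omega <- 2 * pi * (1:half) / (m * dt)
  unit <- if (grepl("_v$", trace$channel)) "V" else
    if (trace$channel == "force_pn") "pN" else "um"
  structure(data.frame(omega = omega, density = dens),
            unit = unit, n_averages = n_segments,
            class = c("power_spectrum", "data.frame"))
}

## Average the spectrum into log-spaced frequency bins (arithmetic mean
## density, geometric mean frequency).  Periodogram noise is
## multiplicative, so averaging before the log-space fit both smooths it
## and equalises the weight per frequency decade.
log_bin_spectrum <- function(ps, bins_per_decade = 12) {
  lw <- log10(ps$omega)
  edges <- seq(min(lw), max(lw) + 1e-12,
               length.out = max(2, ceiling(diff(range(lw)) * bins_per_decade)))
  idx <- findInterval(lw, edges, rightmost.closed = TRUE)
  keep <- tapply(ps$density, idx, mean)
  wgeo <- tapply(lw, idx, mean)
  data.frame(omega = 10^as.numeric(wgeo), density = as.numeric(keep))
}

fit_spectrum_internal <- function(ps, alpha_fixed = NULL, log_bin = TRUE,
                                  dynamic_range = 50) {
  stopifnot(inherits(ps, "power_spectrum"))
  d <- if (log_bin) log_bin_spectrum(ps) else ps[, c("omega", "density")]
  d <- d[d$density > 0, ]
  ## the (stretched) Lorentzian describes the spectrum around its
  ## corner; bins deep below the peak (detector floor, unresolved fast
  ## power) are excluded from the fit
  if (is.finite(dynamic_range))
    d <- d[d$density >= max(d$density) / dynamic_range, , drop = FALSE]
  if (nrow(d) < 8) stop("need at least 8 positive frequency bins")
  ld <- log(d$density)
  p0_start <- max(d$density)
  below <- d$omega[d$density < p0_start / 2]
  we_start <- if (length(below)) below[1] else stats::median(d$omega)

  if (is.null(alpha_fixed)) {
    par0 <- c(lp0 = log(p0_start), lwe = log(we_start), alpha = 2)
    lower <- c(-Inf, -Inf, 1 + 1e-8)
    upper <- c(Inf, Inf, 3)
  } else {
    par0 <- c(lp0 = log(p0_start), lwe = log(we_start))
    lower <- c(-Inf, -Inf)
    upper <- c(Inf, Inf)
  }
  fn <- function(p) {
    a <- if (is.null(alpha_fixed)) p[3] else alpha_fixed
    log(exp(p[1]) / ((d$omega / exp(p[2]))^a + 1)) - ld
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  p0 <- exp(fit$par[[1]])
  omega_eff <- exp(fit$par[[2]])
  alpha <- if (is.null(alpha_fixed)) fit$par[[3]] else alpha_fixed
  low_conf <- omega_eff < min(ps$omega) || omega_eff > max(ps$omega)
  structure(list(p0 = p0, omega_eff = omega_eff, alpha = alpha,
                 residual = fit$deviance,
                 model = if (is.null(alpha_fixed)) "stretched" else "lorentzian",
                 low_confidence = low_conf, n_bins = nrow(d)),
            class = "spectrum_fit")
}

#' Fit a Lorentzian to a power spectrum
#'
#' Least squares of `P(0) / ((omega/omega_c)^2 + 1)` against the
#' log-density (optionally after log-binning), the power spectrum of a
#' Brownian harmonic oscillator.  The stretch exponent is fixed at 2.
#' A corner frequency outside the sampled band flags the fit as low
#' confidence.
#'
#' @param ps a `power_spectrum` from [periodogram()] (>= 8 bins).
#' @param log_bin average into log-spaced bins before fitting (default);
#'   disable for exact noise-free spectra.
#' @param dynamic_range only bins within this factor of the spectral
#'   peak enter the fit (the corner model is local; deep-tail bins are
#'   floor-dominated).  Use `Inf` to fit every bin.
#' @return an object of class `spectrum_fit` with fields `p0`,
#'   `omega_eff` (the corner, rad/s), `alpha` (= 2), `residual`,
#'   `model`, `low_confidence`.
#' @export
fit_lorentzian <- function(ps, log_bin = TRUE, dynamic_range = 50) {
  fit_spectrum_internal(ps, alpha_fixed = 2, log_bin = log_bin,
                        dynamic_range = dynamic_range)
}

#' Fit a stretched Lorentzian to a power spectrum
#'
#' Fits `P(0) / ((omega/omega_eff)^alpha + 1)` with `alpha` free in
#' (1, 3].  Inside viscoelastic droplets the passive spectrum is not
#' Lorentzian; this flexible form captures its shape well enough for the
#' calibration identities, which only require the fitted `(P(0),
#' omega_eff, alpha)`.
#'
#' @inheritParams fit_lorentzian
#' @return a `spectrum_fit` with `alpha` estimated.
#' @export
fit_stretched_lorentzian <- function(ps, log_bin = TRUE,
                                     dynamic_range = 50) {
  fit_spectrum_internal(ps, alpha_fixed = NULL, log_bin = log_bin,
                        dynamic_range = dynamic_range)
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("%s spectrum fit: P(0) = %.4g, omega_eff = %.4g rad/s (%.3g Hz), alpha = %.4g\n",
              x$model, x$p0, x$omega_eff, x$omega_eff / (2 * pi), x$alpha))
  if (x$low_confidence)
    cat("  low confidence: corner outside the sampled band\n")
  invisible(x)
}

#' Trap stiffness from the corner frequency
#'
#' In a Newtonian calibration medium the corner of the Lorentzian
#' position spectrum is `omega_c = kappa_t / xi_m0` with the Stokes drag
#' `xi_m0 = 6 pi eta a`, so `kappa_t = omega_c * 6 pi eta a`.
#'
#' @param omega_c corner angular frequency (rad/s).
#' @param a bead radius (um).
#' @param eta_medium medium viscosity (Pa s), e.g. [eta_water()].
#' @return trap stiffness (pN/um).
#' @export
#' @examples
#' stiffness_from_corner(2 * pi * 3273, a = 1, eta_medium = eta_water())
stiffness_from_corner <- function(omega_c, a, eta_medium) {
  stopifnot(omega_c > 0, a > 0, eta_medium > 0)
  omega_c * stokes_factor(a) * eta_medium
}

#' Trap calibration record
#'
#' @param kappa_t trap stiffness (pN/um, > 0).
#' @param epsilon volt-to-um conversion (um/V, > 0); 1 when traces are
#'   already in physical units.
#' @param method `"corner"` or `"active_passive"`.
#' @param kBT thermal energy used (pN um).
#' @param provenance free-form record of the inputs.
#' @return an object of class `trap_calibration`.
#' @export
trap_calibration <- function(kappa_t, epsilon = 1,
                             method = c("corner", "active_passive"),
                             kBT = kbt_room(), provenance = list()) {
  stopifnot(kappa_t > 0, epsilon > 0)
  structure(list(kappa_t = kappa_t, epsilon = epsilon,
                 method = match.arg(method), kBT = kBT,
                 provenance = provenance),
            class = "trap_calibration")
}

#' @export
print.trap_calibration <- function(x, ...) {
  cat(sprintf("trap calibration (%s): kappa_t = %.4g pN/um, epsilon = %.4g um/V\n",
              x$method, x$kappa_t, x$epsilon))
  invisible(x)
}

#' Active-passive trap calibration
#'
#' Determines both the volt-to-um conversion `epsilon` and the trap
#' stiffness `kappa_t` from (i) the passive volt-unit power spectrum of
#' the trapped bead, summarised by a stretched-Lorentzian fit, and (ii)
#' one low-frequency sinusoidal drive, summarised by the cosine fits of
#' the trap-position (um) and force (volt) traces.  The two identities
#' are
#' \deqn{\epsilon = \frac{(\alpha/2)\sin(\pi/\alpha)\,
#'   (\omega/\omega_{eff}) / ((\omega/\omega_{eff})^\alpha + 1)\,
#'   X_{t0}}{F_{V0} \sin\Delta}}
#' \deqn{\kappa_t = \frac{\alpha \sin(\pi/\alpha)\, k_B T}
#'   {\omega_{eff}\, P_V(0)\, \epsilon^2}.}
#' At `alpha = 2` the second identity reduces to the classic Lorentzian
#' relation `kappa_t epsilon^2 = 2 kBT / (omega_c P_V(0))`.
#'
#' @param ps_v passive `power_spectrum` in V^2 s (used for provenance
#'   and band checks).
#' @param fit the `spectrum_fit` of `ps_v` (stretched Lorentzian).
#' @param drive an [oscillation_fit] of the drive, with trap amplitude
#'   `X_t0` in um and force amplitude `F_V0` in volts.
#' @param kBT thermal energy (pN um).
#' @return a [trap_calibration] with `method = "active_passive"`.
#' @export
active_passive_calibrate <- function(ps_v, fit, drive, kBT = kbt_room()) {
  stopifnot(inherits(fit, "spectrum_fit"), inherits(drive, "oscillation_fit"))
  alpha <- fit$alpha
  if (alpha <= 1 || alpha > 3) stop("alpha outside (1, 3]")
  if (sin(drive$Delta) <= 0)
    stop("sin(Delta) <= 0: unphysical phase (no viscous dissipation)")
  F_V0 <- if (!is.null(drive$F_V0)) drive$F_V0 else drive$F_t0
  w <- drive$omega
  wr <- w / fit$omega_eff
  epsilon <- (alpha / 2) * sin(pi / alpha) * wr / (wr^alpha + 1) *
    drive$X_t0 / (F_V0 * sin(drive$Delta))
  kappa_t <- alpha * sin(pi / alpha) * kBT /
    (fit$omega_eff * fit$p0 * epsilon^2)
  trap_calibration(kappa_t = kappa_t, epsilon = epsilon,
                   method = "active_passive", kBT = kBT,
                   provenance = list(alpha = alpha,
                                     omega_eff = fit$omega_eff,
                                     p_v0 = fit$p0,
                                     drive_omega = w,
                                     X_t0 = drive$X_t0, F_V0 = F_V0,
                                     Delta = drive$Delta,
                                     n_averages = attr(ps_v, "n_averages")))
}
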