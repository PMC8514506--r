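#' Fit a cosine wave at a known drive frequency
#'
#' Linear least squares of a trace on the basis
#' `{cos(omega t), sin(omega t), 1}`.  The drive frequency is set by the
#' instrument and treated as known exactly, which keeps the fit linear.
#' The trace must span at least two full periods.
#'
#' @param trace a [time_trace].
#' @param omega drive angular frequency (rad/s).
#' @return a list with `amplitude` (> 0), `phase` (rad, in (-pi, pi]),
#'   `offset`, `omega`, and `degenerate` (flag for zero amplitude).
#' @export
fit_cosine <- function(trace, omega) {
  stopifnot(inherits(trace, "time_trace"), omega > 0)
  t <- trace_times(trace)
  if ((t[length(t)] - t[1]) < 2 * (2 * pi / omega))
    stop("trace must span at least 2 full periods of the drive")
  X <- cbind(cos(omega * t), sin(omega * t), 1)
  cf <- qr.coef(qr(X), trace$values)
  a <- cf[1]; b <- cf[2]
  amplitude <- sqrt(a^2 + b^2)
  ## A cos(wt + phi) = A cos(phi) cos(wt) - A sin(phi) sin(wt)
  phase <- atan2(-b, a)
  list(amplitude = amplitude, phase = phase, offset = cf[3], omega = omega,
       degenerate = amplitude < .Machine$double.eps^0.5 *
         max(abs(trace$values), 1e-300))
}

#' Phase difference between force and trap cosine fits
#'
#' `Delta = (force phase) - (trap phase)`, wrapped to (-pi, pi].  A
#' physically dissipative medium requires `sin(Delta) > 0`; fits with
#' `Delta` outside (0, pi) are returned with attribute
#' `quality_flag = TRUE` rather than an error, so upstream noise can be
#' inspected.
#'
#' @param trap_fit,force_fit cosine fits from [fit_cosine()] at the same
#'   frequency.
#' @return phase difference in rad.
#' @export
phase_difference <- function(trap_fit, force_fit) {
  if (!isTRUE(all.equal(trap_fit$omega, force_fit$omega)))
    stop("trap and force fits are at different frequencies")
  d <- force_fit$phase - trap_fit$phase
  d <- ((d + pi) %% (2 * pi)) - pi # wrap to (-pi, pi]
  if (d == -pi) d <- pi
  if (d <= 0 || d >= pi) attr(d, "quality_flag") <- TRUE
  d
}

#' Oscillation fit of a driven trace pair
#'
#' Combines the trap and force cosine fits at one drive frequency into
#' the quantities needed for moduli extraction and calibration: the trap
#' amplitude `X_t0`, force amplitude `F_t0`, phase lead `Delta`, the
#' dimensionless ratio `Upsilon = F_t0 / (kappa_t X_t0)`, and the
#' derived bead response `(X0, delta)` from the phasor identity
#' `X0 e^{-i delta} = X_t0 - (F_t0/kappa_t) e^{i Delta}`.
#'
#' @param trap_fit cosine fit of the trap-position trace (um).
#' @param force_fit cosine fit of the force trace (pN, or volts for
#'   calibration use — see `force_in_volts`).
#' @param kappa_t trap stiffness (pN/um); may be `NA` when the force
#'   trace is in volts and only the calibration identities are needed.
#' @param force_in_volts the force-trace amplitude is in volts; it is
#'   stored as `F_V0` and `Upsilon`/`X0` are left `NA`.
#' @return an object of class `oscillation_fit`.
#' @export
oscillation_fit <- function(trap_fit, force_fit, kappa_t = NA,
                            force_in_volts = FALSE) {
  Delta <- phase_difference(trap_fit, force_fit)
  out <- list(omega = trap_fit$omega,
              X_t0 = trap_fit$amplitude, phi = trap_fit$phase,
              B1 = trap_fit$offset, B2 = force_fit$offset,
              Delta = as.numeric(Delta),
              quality_flag = isTRUE(attr(Delta, "quality_flag")))
  if (force_in_volts) {
    out$F_V0 <- force_fit$amplitude
    out$F_t0 <- NA_real_
    out$Upsilon <- NA_real_
    out$X0 <- NA_real_
    out$delta <- NA_real_
  } else {
    out$F_t0 <- force_fit$amplitude
    out$Upsilon <- force_fit$amplitude / (kappa_t * trap_fit$amplitude)
    z <- out$X_t0 - (out$F_t0 / kappa_t) * exp(1i * out$Delta)
    out$X0 <- Mod(z)
    out$delta <- -Arg(z)
  }
  out$kappa_t <- kappa_t
  structure(out, class = "oscillation_fit")
}

#' @export
print.oscillation_fit <- function(x, ...) {
  cat(sprintf("oscillation fit at %.4g Hz: X_t0 = %.4g um, %s = %.4g, Delta = %.4g rad\n",
              x$omega / (2 * pi), x$X_t0,
              if (!is.null(x$F_V0)) "F_V0 (V)" else "F_t0 (pN)",
              if (!is.null(x$F_V0)) x$F_V0 else x$F_t0, x$Delta))
  invisible(x)
}

#' Elastic and viscous moduli from one oscillation fit
#'
#' The complex modulus follows from the measured amplitudes and phase
#' via
#' \deqn{G'(\omega) = \frac{F_{t0}}{6\pi a X_{t0}}
#'   \frac{\cos\Delta - \Upsilon}{(\cos\Delta-\Upsilon)^2+\sin^2\Delta}}
#' \deqn{G''(\omega) = \frac{F_{t0}}{6\pi a X_{t0}}
#'   \frac{\sin\Delta}{(\cos\Delta-\Upsilon)^2+\sin^2\Delta}}
#' with `Upsilon = F_t0/(kappa_t X_t0)`.  `G''` is positive whenever
#' `sin(Delta) > 0`; `G'` may come out negative in noisy data, in which
#' case the result carries attribute `flag_g_prime = TRUE` (it is never
#' silently clipped).
#'
#' @param fit an [oscillation_fit] with force in pN.
#' @param kappa_t trap stiffness (pN/um); defaults to the one stored in
#'   `fit`.
#' @param a bead radius (um).
#' @return named numeric vector `c(g_prime, g_dprime)` in Pa.
#' @export
moduli_from_oscillation <- function(fit, kappa_t = fit$kappa_t, a = 1) {
  stopifnot(inherits(fit, "oscillation_fit"))
  if (is.na(fit$F_t0)) stop("oscillation fit has no force amplitude in pN")
  Upsilon <- fit$F_t0 / (kappa_t * fit$X_t0)
  if (Upsilon >= 1)
    stop("Upsilon >= 1: force amplitude exceeds trap capability (inconsistent calibration)")
  if (sin(fit$Delta) <= 0) stop("sin(Delta) <= 0: no viscous dissipation")
  pref <- fit$F_t0 / (stokes_factor(a) * fit$X_t0)
  den <- (cos(fit$Delta) - Upsilon)^2 + sin(fit$Delta)^2
  gp <- pref * (cos(fit$Delta) - Upsilon) / den
  gpp <- pref * sin(fit$Delta) / den
  out <- c(g_prime = gp, g_dprime = gpp)
  if (gp < 0) attr(out, "flag_g_prime") <- TRUE
  out
}

#' Extract a moduli table from driven trace pairs
#'
#' Convenience wrapper for one droplet: runs [fit_cosine()] on the trap
#' and force traces at each drive frequency and converts each pair to
#' moduli with [moduli_from_oscillation()].
#'
#' @param trace_pairs list of `list(trap =, force =)` [time_trace] pairs
#'   whose `meta$omega` records the drive frequency (as produced by
#'   [simulate_driven_trace()]).
#' @param kappa_t trap stiffness (pN/um).
#' @param a bead radius (um).
#' @return data frame with `omega`, `g_prime`, `g_dprime` (one row per
#'   frequency, sorted by `omega`).
#' @export
extract_moduli <- function(trace_pairs, kappa_t, a = 1) {
  rows <- lapply(trace_pairs, function(pr) {
    w <- pr$trap$meta$omega
    tf <- fit_cosine(pr$trap, w)
    ff <- fit_cosine(pr$force, w)
    g <- moduli_from_oscillation(oscillation_fit(tf, ff, kappa_t), a = a)
    data.frame(omega = w, g_prime = g[["g_prime"]],
               g_dprime = g[["g_dprime"]])
  })
  out <- do.call(rbind, rows)
  out[order(out$omega), , drop = FALSE]
}

#' Aggregate replicate moduli measurements
#'
#' Means and standard errors of the mean of `G'` and `G''` per
#' frequency, over replicate droplets measured on a shared frequency
#' grid.
#'
#' @param replicates list (length >= 2) of data frames with columns
#'   `omega`, `g_prime`, `g_dprime` on identical frequency grids.
#' @return a [moduli_dataset] with SEM columns and `n_replicates` set.
#' @export
aggregate_replicates <- function(replicates) {
  if (length(replicates) < 2) stop("need at least 2 replicates")
  grid <- replicates[[1]]$omega
  for (r in replicates[-1]) {
    if (length(r$omega) != length(grid) ||
        !isTRUE(all.equal(r$omega, grid)))
      stop("replicates measured on mismatched frequency grids")
  }
  n <- length(replicates)
  gp <- sapply(replicates, `[[`, "g_prime")
  gpp <- sapply(replicates, `[[`, "g_dprime")
  if (is.null(dim(gp))) { gp <- matrix(gp, nrow = 1); gpp <- matrix(gpp, nrow = 1) }
  sem <- function(m) apply(m, 1, stats::sd) / sqrt(n)
  moduli_dataset(omega = grid,
                 g_prime = rowMeans(gp), g_dprime = rowMeans(gpp),
                 sem_g_prime = sem(gp), sem_g_dprime = sem(gpp),
                 n_replicates = n)
}
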