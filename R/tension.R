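#' Two-trap stretching experiment record
#'
#' Bundles the force traces and geometry of a droplet-stretching
#' measurement: a droplet suspended between two trapped beads at its
#' poles, trap 2 fixed, trap 1 pulled at constant speed `v`.  The bead
#' must sit strictly inside each pole (`R > 2a`) and the polar angle
#' `theta0 = a/(R - a)` must not exceed 0.5, the validity domain of the
#' geometry factor.
#'
#' @param force1,force2 trap-1 and trap-2 force traces ([time_trace],
#'   pN).
#' @param kappa_t1,kappa_t2 trap stiffnesses (pN/um).
#' @param v pulling speed (um/s); negative for a retraction run.
#' @param R unstretched droplet radius (um).
#' @param a bead radius (um).
#' @param smoothing_window moving-average window (s) applied to the
#'   force traces before the slope fits; 64 ms by default.
#' @return an object of class `stretch_experiment`.
#' @export
stretch_experiment <- function(force1, force2, kappa_t1, kappa_t2, v, R, a,
                               smoothing_window = 0.064) {
  stopifnot(inherits(force1, "time_trace"), inherits(force2, "time_trace"),
            kappa_t1 > 0, kappa_t2 > 0, v != 0, a > 0)
  if (R <= 2 * a) stop("droplet must satisfy R > 2a")
  theta0 <- a / (R - a)
  if (theta0 > 0.5) stop("theta0 = a/(R-a) must not exceed 0.5")
  structure(list(force1 = force1, force2 = force2,
                 kappa_t1 = kappa_t1, kappa_t2 = kappa_t2, v = v,
                 R = R, a = a, theta0 = theta0,
                 smoothing_window = smoothing_window),
            class = "stretch_experiment")
}

## centred moving average; shrinks to the available window at the edges
moving_average <- function(x, window_s, dt) {
  k <- max(1L, round(window_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  if (k <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' System spring constant from a stretching experiment
#'
#' Smooths the two force traces by a moving average over the configured
#' window, fits each against time by ordinary least squares (slopes `f1`
#' and `f2`), and returns the static spring constant of the
#' droplet-plus-traps system,
#' `chi_sys0 = ((f2 - f1)/2) / v`.
#'
#' @param exp a [stretch_experiment].
#' @return `chi_sys0` (pN/um), with the fitted slopes and their
#'   residual standard errors in attribute `diagnostics`.
#' @export
stretch_spring_constant <- function(exp) {
  stopifnot(inherits(exp, "stretch_experiment"))
  slope_of <- function(tr) {
    y <- moving_average(tr$values, exp$smoothing_window, tr$dt)
    t <- trace_times(tr)
    ## half-window edges carry truncated averages; exclude them so a
    ## linear ramp stays exactly linear after smoothing
    k <- max(1L, round(exp$smoothing_window / tr$dt))
    h <- k %/% 2L
    idx <- if (length(y) > 2L * (h + 1L)) (h + 1L):(length(y) - h)
           else seq_along(y)
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    list(slope = fit$coefficients[2],
         rse = sqrt(mean(fit$residuals^2)))
  }
  s1 <- slope_of(exp$force1)
  s2 <- slope_of(exp$force2)
  f1 <- unname(s1$slope); f2 <- unname(s2$slope)
  ## signed v handles retraction runs: slopes flip with the pull
  ## direction and the spring constant comes out the same
  chi <- ((f2 - f1) / 2) / exp$v
  if (chi <= 0)
    stop("force slopes inconsistent with a restoring tension (f2 <= f1)")
  attr(chi, "diagnostics") <- list(f1 = f1, f2 = f2,
                                   rse1 = s1$rse, rse2 = s2$rse)
  chi
}

#' Droplet spring constant from the system spring constant
#'
#' The suspended droplet and the two traps form three springs in
#' series: `1/chi0 = 1/chi_sys0 - 1/kappa_t1 - 1/kappa_t2`.
#'
#' @param chi_sys0 system spring constant (pN/um).
#' @param kappa_t1,kappa_t2 trap stiffnesses (pN/um).
#' @return droplet spring constant `chi0` (pN/um).
#' @export
droplet_spring_constant <- function(chi_sys0, kappa_t1, kappa_t2) {
  stopifnot(chi_sys0 > 0, kappa_t1 > 0, kappa_t2 > 0)
  inv <- 1 / chi_sys0 - 1 / kappa_t1 - 1 / kappa_t2
  if (inv <= 0)
    stop("system softer than the traps alone (1/chi_sys0 <= 1/kt1 + 1/kt2): inconsistent input")
  1 / inv
}

#' Interfacial tension from the droplet spring constant
#'
#' Inverts the proportionality `chi0 = (pi/2) alpha(theta0) gamma`
#' with the geometry factor `1/alpha(theta0) = -0.5 log(theta0) + 0.34`,
#' `theta0 = a/(R-a)`, giving
#' `gamma = (1/pi) (log(R/a - 1) + 0.68) chi0`.  Valid for `theta0` up
#' to 0.5.
#'
#' @param chi0 droplet spring constant (pN/um).
#' @param R unstretched droplet radius (um).
#' @param a bead radius (um).
#' @return interfacial tension `gamma` (pN/um).
#' @export
tension_from_spring <- function(chi0, R, a) {
  stopifnot(chi0 > 0, a > 0, R > a)
  theta0 <- a / (R - a)
  if (theta0 > 0.5) stop("theta0 = a/(R-a) must not exceed 0.5")
  bracket <- log(R / a - 1) + 0.68
  if (bracket <= 0) stop("geometry outside validity (log(R/a - 1) + 0.68 <= 0)")
  bracket / pi * chi0
}

#' Full stretching analysis
#'
#' Chains [stretch_spring_constant()], [droplet_spring_constant()] and
#' [tension_from_spring()] for one experiment.
#'
#' @param exp a [stretch_experiment].
#' @return an object of class `tension_result` with `chi_sys0`, `chi0`,
#'   `gamma`, `method = "stretch"` and slope diagnostics.
#' @export
analyze_stretch <- function(exp) {
  chi_sys0 <- stretch_spring_constant(exp)
  diag <- attr(chi_sys0, "diagnostics")
  chi_sys0 <- as.numeric(chi_sys0)
  chi0 <- droplet_spring_constant(chi_sys0, exp$kappa_t1, exp$kappa_t2)
  gamma <- tension_from_spring(chi0, exp$R, exp$a)
  structure(list(chi_sys0 = chi_sys0, chi0 = chi0, gamma = gamma,
                 method = "stretch", diagnostics = diag),
            class = "tension_result")
}

#' Interfacial tension from a surface-rupture force trace
#'
#' The bead acts as a micro-tensiometer, like a Wilhelmy plate or a du
#' Nouy ring: the maximum (smoothed) trapping force before the surface
#' ruptures balances the tension force around the bead equator,
#' `F_rup = 2 pi a f gamma`, with the dimensionless constant `f`
#' absorbing the adhesive pull-back (calibrated value 1.1).  The trace
#' must show a rupture signature — a maximum followed by a drop of at
#' least `drop_frac` of the peak.  If the peak reaches `force_limit`
#' (the trapping power of the instrument), only a lower bound on
#' `gamma` can be placed and the result is flagged.
#'
#' @param force_trace a [time_trace] (pN).
#' @param a bead radius (um).
#' @param f rupture scaling constant (default 1.1).
#' @param smoothing_window moving-average window (s).
#' @param drop_frac minimum post-peak fractional drop that qualifies as
#'   rupture.
#' @param force_limit optional maximum trappable force (pN).
#' @return a `tension_result` with `method = "rupture"`, `F_rup`, and
#'   `lower_bound` flag.
#' @export
tension_from_rupture <- function(force_trace, a, f = 1.1,
                                 smoothing_window = 0.064, drop_frac = 0.5,
                                 force_limit = NULL) {
  stopifnot(inherits(force_trace, "time_trace"), a > 0, f > 0)
  y <- moving_average(force_trace$values, smoothing_window, force_trace$dt)
  ipk <- which.max(y)
  F_rup <- y[ipk]
  if (ipk == length(y) || min(y[ipk:length(y)]) > (1 - drop_frac) * F_rup)
    stop("no rupture signature: force does not drop after its maximum")
  lower_bound <- !is.null(force_limit) && F_rup >= force_limit
  gamma <- F_rup / (2 * pi * a * f)
  structure(list(chi_sys0 = NA_real_, chi0 = NA_real_, gamma = gamma,
                 F_rup = F_rup, f = f, method = "rupture",
                 lower_bound = lower_bound),
            class = "tension_result")
}

#' @export
print.tension_result <- function(x, ...) {
  cat(sprintf("interfacial tension (%s): gamma %s %.4g pN/um\n",
              x$method, if (isTRUE(x$lower_bound)) ">=" else "=", x$gamma))
  if (x$method == "stretch")
    cat(sprintf("  chi_sys0 = %.4g, chi0 = %.4g pN/um\n", x$chi_sys0, x$chi0))
  invisible(x)
}
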