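#' Burgers model parameters
#'
#' Constructs the parameter set of the Burgers model of linear
#' viscoelasticity: two Maxwell elements in parallel, with shear
#' relaxation modulus
#' \deqn{G(t) = (\eta_0/\tau_0) e^{-t/\tau_0} + (\eta_1/\tau_1) e^{-t/\tau_1}.}
#' The fast component (`eta0`, `tau0`) is typically attributed to
#' conformational dynamics of individual macromolecules, the slow
#' component (`eta1`, `tau1`) to reconfiguration of the transient
#' macromolecular network.  `tau0 = 0` is legal and denotes a Newtonian
#' fast component, whose contribution to the relaxation modulus is a
#' delta function `eta0 * delta(t)`.
#'
#' Components are stored in canonical order `tau0 <= tau1`; they are
#' swapped on construction if supplied the other way round.
#'
#' @param eta0 viscosity of the fast component (Pa s, >= 0).
#' @param tau0 relaxation time of the fast component (s, >= 0; 0 means
#'   Newtonian).
#' @param eta1 viscosity of the slow component (Pa s, >= 0).
#' @param tau1 relaxation time of the slow component (s, > 0).
#' @return an object of class `burgers_params`.
#' @export
#' @examples
#' p <- burgers_params(eta0 = 0.1, tau0 = 0.005, eta1 = 0.2, tau1 = 0.045)
#' zero_shear_viscosity(p)
burgers_params <- function(eta0, tau0, eta1, tau1) {
  vals <- c(eta0 = eta0, tau0 = tau0, eta1 = eta1, tau1 = tau1)
  if (any(!is.finite(vals))) stop("Burgers parameters must be finite")
  if (eta0 < 0 || eta1 < 0) stop("viscosities must be non-negative")
  if (tau0 < 0) stop("tau0 must be >= 0")
  if (tau0 > tau1) { # canonical ordering: fast component first
    tmp <- c(eta0, tau0); eta0 <- eta1; tau0 <- tau1
    eta1 <- tmp[1]; tau1 <- tmp[2]
  }
  if (tau1 <= 0) stop("tau1 must be > 0")
  structure(list(eta0 = eta0, tau0 = tau0, eta1 = eta1, tau1 = tau1),
            class = "burgers_params")
}

#' @export
print.burgers_params <- function(x, ...) {
  cat("Burgers model parameters (two Maxwell elements in parallel)\n")
  cat(sprintf("  fast: eta0 = %g Pa s, tau0 = %g ms%s\n",
              x$eta0, 1e3 * x$tau0,
              if (x$tau0 == 0) " (Newtonian)" else ""))
  cat(sprintf("  slow: eta1 = %g Pa s, tau1 = %g ms\n", x$eta1, 1e3 * x$tau1))
  cat(sprintf("  zero-shear viscosity eta0 + eta1 = %g Pa s\n",
              x$eta0 + x$eta1))
  invisible(x)
}

#' Shear relaxation modulus of the Burgers model
#'
#' Evaluates \eqn{G(t) = (\eta_0/\tau_0) e^{-t/\tau_0} +
#' (\eta_1/\tau_1) e^{-t/\tau_1}} at times `t > 0`.  When `tau0 = 0` the
#' fast component is a Dirac delta, which has no pointwise value; only
#' the slow exponential is returned and the result carries the attribute
#' `newtonian_component = TRUE`.
#'
#' @param params a [burgers_params] object.
#' @param t time(s) in seconds, strictly positive.
#' @return relaxation modulus in Pa, same length as `t`.
#' @export
relaxation_modulus <- function(params, t) {
  stopifnot(inherits(params, "burgers_params"))
  if (any(t <= 0)) stop("relaxation modulus is defined pointwise only for t > 0")
  g <- params$eta1 / params$tau1 * exp(-t / params$tau1)
  if (params$tau0 > 0) {
    g <- g + params$eta0 / params$tau0 * exp(-t / params$tau0)
  } else {
    attr(g, "newtonian_component") <- TRUE
  }
  g
}

#' Complex shear moduli of the Burgers model
#'
#' Elastic (storage) and viscous (loss) moduli at angular frequency
#' `omega`:
#' \deqn{G'(\omega) = \frac{\omega^2\tau_0\eta_0}{1+(\omega\tau_0)^2}
#'                  + \frac{\omega^2\tau_1\eta_1}{1+(\omega\tau_1)^2}}
#' \deqn{G''(\omega) = \frac{\omega\eta_0}{1+(\omega\tau_0)^2}
#'                   + \frac{\omega\eta_1}{1+(\omega\tau_1)^2}}
#' With `tau0 = 0` the fast component contributes nothing to `G'` and
#' `omega * eta0` to `G''` (Newtonian limit); the formulas reduce to
#' this algebraically.
#'
#' @inheritParams relaxation_modulus
#' @param omega angular frequency (rad/s, >= 0); vectorised.
#' @return a data frame with columns `omega`, `g_prime`, `g_dprime` (Pa).
#' @export
complex_moduli <- function(params, omega) {
  stopifnot(inherits(params, "burgers_params"))
  if (any(omega < 0)) stop("omega must be >= 0")
  x0 <- omega * params$tau0
  x1 <- omega * params$tau1
  gp <- omega^2 * params$tau0 * params$eta0 / (1 + x0^2) +
        omega^2 * params$tau1 * params$eta1 / (1 + x1^2)
  gpp <- omega * params$eta0 / (1 + x0^2) +
         omega * params$eta1 / (1 + x1^2)
  data.frame(omega = omega, g_prime = gp, g_dprime = gpp)
}

#' Zero-shear viscosity
#'
#' The viscosity governing dynamics much slower than all relaxation
#' times, `eta = eta0 + eta1`; equal to the limit of `G''(omega)/omega`
#' as `omega -> 0`.
#'
#' @inheritParams relaxation_modulus
#' @return viscosity in Pa s.
#' @export
zero_shear_viscosity <- function(params) {
  stopifnot(inherits(params, "burgers_params"))
  params$eta0 + params$eta1
}

#' Crossover angular frequency
#'
#' The smallest `omega > 0` at which the elastic and viscous moduli are
#' equal, `G'(omega_x) = G''(omega_x)`.  Its inverse is commonly read as
#' the network reconfiguration time, although for the Burgers model
#' `1/omega_x` tracks `tau1` only when `eta0/eta1` is small.  Found by
#' sign-change bracketing on a logarithmic grid over
#' `[1e-6/tau1, 1e6/max(tau0, 1e-6 tau1)]` followed by bisection to
#' 1e-12 relative precision.  Tangency without a sign change is treated
#' as no crossover.
#'
#' @inheritParams relaxation_modulus
#' @return crossover frequency in rad/s, or `NULL` when the moduli never
#'   cross (e.g. a dominant Newtonian component).
#' @export
#' @examples
#' crossover_frequency(burgers_params(0, 0.1, 1, 0.1)) # Maxwell: 1/tau1
crossover_frequency <- function(params) {
  stopifnot(inherits(params, "burgers_params"))
  f <- function(w) {
    m <- complex_moduli(params, w)
    m$g_prime - m$g_dprime
  }
  lo <- 1e-6 / params$tau1
  hi <- 1e6 / max(params$tau0, params$tau1 * 1e-6)
  grid <- exp(seq(log(lo), log(hi), length.out = 4096L))
  fv <- f(grid)
  s <- sign(fv)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) == 0) {
    zero <- which(fv == 0 & grid > lo)
    if (length(zero)) return(grid[zero[1]]) # exact grid hit
    return(NULL)
  }
  i <- idx[1]
  r <- stats::uniroot(function(lw) f(exp(lw)),
                      lower = log(grid[i]), upper = log(grid[i + 1]),
                      tol = 1e-14)
  exp(r$root)
}
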