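#' Fit the Burgers model to a complex-moduli dataset
#'
#' The central estimator of the package.  Minimises the weighted joint
#' sum of squares over the elastic and viscous moduli,
#' \deqn{\sum_i w'_i (G'(\omega_i) - \hat G'_i)^2 +
#'       \sum_i w''_i (G''(\omega_i) - \hat G''_i)^2,}
#' over the four Burgers parameters.  Optimisation is carried out in
#' log-parameter space (two-timescale fits are multimodal and strictly
#' positive), with eight deterministic multi-starts spanning relaxation
#' times `1/omega_max`, `1/omega_mid`, `1/omega_min` and a
#' Newtonian-fast-component start with `tau0` at its lower bound.  A
#' fitted `tau0` that lands on the bound is reported as exactly 0
#' (Newtonian fast component).
#'
#' Weights are `1/SEM^2` when standard errors are present, otherwise
#' `1/value^2` (constant relative error); for non-positive `g_prime`
#' rows the relative-weight scale falls back to the same row's
#' `g_dprime`.
#'
#' @param data a [moduli_dataset] with at least 4 frequency rows.
#' @param weights `"sem"` to use `1/SEM^2` when SEMs are available
#'   (falling back to relative weights when they are not), or
#'   `"relative"` to force `1/value^2` weights.
#' @param drop_flagged drop rows flagged for non-positive `g_prime`
#'   before fitting (default `FALSE`: flagged rows are kept, favouring
#'   transparency over silent cleaning).
#' @return an object of class `burgers_fit` with elements `params`
#'   ([burgers_params]), `stderr`, `eta` (zero-shear viscosity,
#'   `eta0 + eta1`), `omega_x` (crossover frequency or `NULL`),
#'   `residual` (weighted sum of squares), `converged`, `data`,
#'   `fitted`, and `n_starts`.
#' @seealso [predict.burgers_fit()], [plot.burgers_fit()],
#'   [write_fit_json()]
#' @export
#' @examples
#' p <- burgers_params(0.1, 0.01, 0.43, 0.125)
#' w <- 2 * pi * c(0.5, 1, 2, 5, 10, 20, 40)
#' m <- complex_moduli(p, w)
#' d <- moduli_dataset(w, m$g_prime, m$g_dprime)
#' fit <- fit_burgers(d)
#' coef(fit)
fit_burgers <- function(data, weights = c("sem", "relative"),
                        drop_flagged = FALSE) {
  stopifnot(inherits(data, "moduli_dataset"))
  weights <- match.arg(weights)
  if (drop_flagged) data <- data[!data$flag_g_prime, , drop = FALSE]
  n <- nrow(data)
  if (n < 4) stop("need at least 4 frequency rows to fit 4 parameters")
  if (any(data$g_dprime <= 0)) stop("g_dprime must be positive everywhere")

  omega <- data$omega
  use_sem <- weights == "sem" &&
    all(is.finite(data$sem_g_prime)) && all(is.finite(data$sem_g_dprime)) &&
    all(data$sem_g_prime > 0) && all(data$sem_g_dprime > 0)
  if (use_sem) {
    wp <- 1 / data$sem_g_prime^2
    wpp <- 1 / data$sem_g_dprime^2
  } else {
    scale_p <- ifelse(data$g_prime > 0, data$g_prime, data$g_dprime)
    wp <- 1 / scale_p^2
    wpp <- 1 / data$g_dprime^2
  }
  sw <- sqrt(c(wp, wpp))
  obs <- c(data$g_prime, data$g_dprime)

  tau_floor <- 1e-8 / max(omega)
  resid_fn <- function(theta) {
    p <- exp(theta)
    x0 <- omega * p[2]; x1 <- omega * p[4]
    gp <- omega^2 * p[2] * p[1] / (1 + x0^2) + omega^2 * p[4] * p[3] / (1 + x1^2)
    gpp <- omega * p[1] / (1 + x0^2) + omega * p[3] / (1 + x1^2)
    (c(gp, gpp) - obs) * sw
  }

  ## deterministic multi-starts over characteristic times of the band
  t_hi <- 1 / max(omega); t_mid <- 1 / exp(mean(log(range(omega)))); t_lo <- 1 / min(omega)
  eta_tot <- data$g_dprime[1] / omega[1] # low-frequency estimate of eta0+eta1
  starts <- expand.grid(tau0 = c(tau_floor, t_hi, t_mid, t_lo),
                        tau1 = c(t_mid, t_lo))
  lower <- c(-Inf, log(tau_floor), -Inf, log(tau_floor))
  upper <- c(Inf, log(1e4 * t_lo), Inf, log(1e4 * t_lo))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- log(c(0.3 * eta_tot, starts$tau0[i], 0.7 * eta_tot, starts$tau1[i]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimisation starts failed")

  p <- exp(best$par)
  ## canonical ordering tau0 <= tau1
  if (p[2] > p[4]) p <- p[c(3, 4, 1, 2)]
  ## standard errors from the Jacobian at the optimum (delta method back
  ## to the natural scale); unavailable when the Hessian is singular
  se_nat <- rep(NA_real_, 4)
  se_log <- tryCatch({
    dof <- max(length(obs) - 4, 1)
    covm <- solve(best$hessian) * best$deviance / dof
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, 4))
  if (!anyNA(se_log)) {
    se_nat <- se_log * exp(best$par)
    if (exp(best$par[2]) > exp(best$par[4])) se_nat <- se_nat[c(3, 4, 1, 2)]
  }

  tau0_at_floor <- p[2] <= 2 * tau_floor
  params <- burgers_params(eta0 = p[1],
                           tau0 = if (tau0_at_floor) 0 else p[2],
                           eta1 = p[3], tau1 = p[4])
  if (tau0_at_floor) se_nat[2] <- NA_real_
  names(se_nat) <- c("eta0", "tau0", "eta1", "tau1")

  converged <- best$info %in% 1:4
  fitted <- complex_moduli(params, omega)
  structure(list(
    params = params,
    stderr = se_nat,
    eta = params$eta0 + params$eta1,
    omega_x = crossover_frequency(params),
    residual = best$deviance,
    converged = converged,
    weights = if (use_sem) "sem" else "relative",
    data = data,
    fitted = fitted,
    n_starts = nrow(starts)
  ), class = "burgers_fit")
}

#' @export
print.burgers_fit <- function(x, ...) {
  cat("Burgers model fit", if (!x$converged) "(NOT converged)", "\n")
  print(x$params)
  if (!is.null(x$omega_x))
    cat(sprintf("  crossover omega_x = %.4g rad/s (1/omega_x = %.4g ms)\n",
                x$omega_x, 1e3 / x$omega_x))
  else
    cat("  no crossover frequency (G' never reaches G'')\n")
  cat(sprintf("  weighted residual sum of squares: %.4g (%s weights)\n",
              x$residual, x$weights))
  invisible(x)
}

#' @export
summary.burgers_fit <- function(object, ...) {
  est <- coef(object)
  tab <- cbind(Estimate = est, `Std. Error` = object$stderr)
  structure(list(coefficients = tab, eta = object$eta,
                 omega_x = object$omega_x, residual = object$residual,
                 converged = object$converged,
                 n = nrow(object$data)),
            class = "summary.burgers_fit")
}

#' @export
print.summary.burgers_fit <- function(x, ...) {
  cat("Burgers model fit:", x$n, "frequencies\n")
  stats::printCoefmat(x$coefficients, ...)
  cat(sprintf("zero-shear viscosity eta = %.4g Pa s\n", x$eta))
  if (!is.null(x$omega_x))
    cat(sprintf("crossover omega_x = %.4g rad/s\n", x$omega_x))
  if (!x$converged) cat("warning: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
coef.burgers_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
vcov.burgers_fit <- function(object, ...) {
  se <- object$stderr
  v <- diag(se^2, nrow = 4, ncol = 4)
  dimnames(v) <- list(names(se), names(se))
  v
}

#' Predict moduli from a fitted Burgers model
#'
#' @param object a `burgers_fit`.
#' @param omega angular frequencies (rad/s); defaults to the fitted
#'   frequencies.
#' @param ... unused.
#' @return data frame with `omega`, `g_prime`, `g_dprime`.
#' @export
predict.burgers_fit <- function(object, omega = NULL, ...) {
  if (is.null(omega)) omega <- object$data$omega
  complex_moduli(object$params, omega)
}

#' @export
residuals.burgers_fit <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  r <- data.frame(
    omega = object$data$omega,
    g_prime = object$data$g_prime - object$fitted$g_prime,
    g_dprime = object$data$g_dprime - object$fitted$g_dprime)
  if (type == "weighted") {
    ## reconstruct the weights used in the fit
    d <- object$data
    if (object$weights == "sem") {
      r$g_prime <- r$g_prime / d$sem_g_prime
      r$g_dprime <- r$g_dprime / d$sem_g_dprime
    } else {
      scale_p <- ifelse(d$g_prime > 0, d$g_prime, d$g_dprime)
      r$g_prime <- r$g_prime / scale_p
      r$g_dprime <- r$g_dprime / d$g_dprime
    }
  }
  r
}

#' Plot a fitted Burgers model over its data
#'
#' Log-log plot of the elastic (filled) and viscous (open) moduli with
#' the fitted curves, in the conventional style of frequency-sweep
#' rheology figures.
#'
#' @param x a `burgers_fit`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.burgers_fit <- function(x, ...) {
  d <- x$data
  wgrid <- exp(seq(log(min(d$omega)), log(max(d$omega)), length.out = 200))
  curves <- complex_moduli(x$params, wgrid)
  ylim <- range(c(d$g_prime[d$g_prime > 0], d$g_dprime,
                  curves$g_prime[curves$g_prime > 0], curves$g_dprime))
  graphics::plot(d$omega, d$g_dprime, log = "xy", pch = 1, col = "blue",
                 xlab = expression(omega ~ "(rad/s)"),
                 ylab = "modulus (Pa)", ylim = ylim, ...)
  graphics::points(d$omega, d$g_prime, pch = 16, col = "red")
  graphics::lines(wgrid, curves$g_prime, col = "red")
  graphics::lines(wgrid, curves$g_dprime, col = "blue")
  graphics::legend("topleft", legend = c("G'", "G''"), col = c("red", "blue"),
                   pch = c(16, 1), lty = 1, bty = "n")
  invisible(x)
}

#' Write a Burgers fit report as JSON
#'
#' Emits the fitted parameters, their standard errors, the zero-shear
#' viscosity, the crossover frequency (null when absent), the weighted
#' residual and the convergence flag.
#'
#' @param fit a `burgers_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "burgers_fit"))
  rec <- list(
    params = unclass(fit$params),
    stderrs = as.list(fit$stderr),
    eta = fit$eta,
    omega_x_rad_s = if (is.null(fit$omega_x)) NULL else fit$omega_x,
    residual = fit$residual,
    converged = fit$converged
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
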