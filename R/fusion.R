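#' Fusion-time dataset
#'
#' Pairs of droplet radius and fusion time for one condensate type.
#'
#' @param R droplet radii (um, > 0).
#' @param tau_fu fusion times (ms, > 0).
#' @param provenance free-form record.
#' @return a data frame of class `fusion_dataset`.
#' @export
fusion_dataset <- function(R, tau_fu, provenance = list()) {
  stopifnot(length(R) == length(tau_fu))
  if (any(R <= 0) || any(tau_fu <= 0))
    stop("radii and fusion times must be positive")
  d <- data.frame(R = R, tau_fu = tau_fu)
  attr(d, "provenance") <- provenance
  class(d) <- c("fusion_dataset", "data.frame")
  d
}

#' Inverse fusion speed from a fusion dataset
#'
#' Fusion time is proportional to droplet radius; the inverse fusion
#' speed is the slope `s` of the least-squares proportional fit
#' `tau_fu = s R` (through the origin, reflecting the measured
#' proportionality).  An intercept can be allowed for diagnostics but is
#' off by default.
#'
#' @param data a [fusion_dataset].
#' @param intercept fit an intercept as well (default `FALSE`).
#' @return list with `inverse_speed` (ms/um), `se` (standard error of
#'   the slope), `n`, and the underlying `lm` fit.
#' @export
fit_fusion_speed <- function(data, intercept = FALSE) {
  stopifnot(inherits(data, "fusion_dataset"))
  if (nrow(data) < 1) stop("empty dataset")
  fit <- if (intercept) stats::lm(tau_fu ~ R, data = data)
         else stats::lm(tau_fu ~ 0 + R, data = data)
  cf <- suppressWarnings(summary(fit))$coefficients # exact fits are fine
  slope_row <- if (intercept) "R" else "R"
  list(inverse_speed = unname(cf[slope_row, "Estimate"]),
       se = unname(cf[slope_row, "Std. Error"]),
       n = nrow(data), fit = fit)
}

#' Viscocapillary time of a Newtonian droplet
#'
#' `tau_vc = eta R / gamma`, the fusion timescale of a purely viscous
#' droplet of radius `R`, reported in ms.  In the pN/um/Pa s unit system
#' `eta R / gamma` is already in seconds, so only the ms conversion
#' appears.
#'
#' @param eta zero-shear viscosity (Pa s).
#' @param gamma interfacial tension (pN/um).
#' @param R droplet radius (um).
#' @return viscocapillary time (ms).
#' @export
viscocapillary_time <- function(eta, gamma, R) {
  stopifnot(eta > 0, gamma > 0, R > 0)
  1000 * eta * R / gamma
}

#' Newtonian fusion-time prediction
#'
#' The viscocapillary model predicts the fusion time of two equal-sized
#' Newtonian droplets as `tau_fu_N = 1.97 eta R / gamma = 1.97 tau_vc`.
#'
#' @inheritParams viscocapillary_time
#' @return predicted fusion time (ms).
#' @export
#' @examples
#' predict_newtonian_fusion_time(eta = 3.75, gamma = 73.4, R = 3) # ~302 ms
predict_newtonian_fusion_time <- function(eta, gamma, R) {
  1.97 * viscocapillary_time(eta, gamma, R)
}

#' Derived fusion metrics for one condensate
#'
#' Computes every derived quantity of the headline comparison between
#' measured and viscocapillary-predicted fusion dynamics, at a reference
#' radius `R_ref`:
#' * `tau_vc` and `tau_fu_N = 1.97 tau_vc` (viscocapillary prediction);
#' * `tau_fu = inverse_speed * R_ref` (measured fusion time);
#' * `tau_fu_star = sqrt(tau_fu * tau_fu_N)`, the geometric-mean
#'   timescale whose inverse measures the shear rate during fusion;
#' * `ratio_tau1_star = tau1 / tau_fu_star` (shear relaxation relative
#'   to deformation rate);
#' * `eta_eff_ratio = tau_fu / tau_fu_N`, the effective-viscosity ratio;
#' * `pct_diff = 200 |tau_fu - tau_fu_N| / (tau_fu + tau_fu_N)`;
#' * `relative_viscosity = eta / eta_w`;
#' * `regime`: shear `"thickening"` when `eta_eff_ratio > 1 + tol`,
#'   `"thinning"` when `< 1 - tol`, else `"newtonian"`.
#'
#' @param name condensate label.
#' @param eta zero-shear viscosity (Pa s).
#' @param gamma interfacial tension (pN/um).
#' @param tau1 shear relaxation time (ms).
#' @param inverse_speed inverse fusion speed (ms/um).
#' @param inverse_speed_se optional standard error of `inverse_speed`.
#' @param R_ref reference radius (um); 3 um by default.
#' @param eta_w reference water viscosity (Pa s).
#' @param tol half-width of the Newtonian band on `eta_eff_ratio`.
#' @return an object of class `condensate_summary`.
#' @export
derived_metrics <- function(name, eta, gamma, tau1, inverse_speed,
                            inverse_speed_se = NA_real_, R_ref = 3,
                            eta_w = eta_water(), tol = 0.05) {
  stopifnot(eta > 0, gamma > 0, tau1 > 0, inverse_speed > 0, R_ref > 0)
  tau_vc <- viscocapillary_time(eta, gamma, R_ref)
  tau_fu_N <- 1.97 * tau_vc
  tau_fu <- inverse_speed * R_ref
  tau_fu_star <- sqrt(tau_fu * tau_fu_N)
  eta_eff_ratio <- tau_fu / tau_fu_N
  regime <- if (eta_eff_ratio > 1 + tol) "thickening"
            else if (eta_eff_ratio < 1 - tol) "thinning"
            else "newtonian"
  structure(list(
    name = name, eta = eta, gamma = gamma, tau1 = tau1,
    inverse_speed = inverse_speed, inverse_speed_se = inverse_speed_se,
    R_ref = R_ref,
    tau_vc = tau_vc, tau_fu = tau_fu, tau_fu_N = tau_fu_N,
    tau_fu_star = tau_fu_star,
    ratio_tau1_star = tau1 / tau_fu_star,
    eta_eff_ratio = eta_eff_ratio,
    pct_diff = 200 * abs(tau_fu - tau_fu_N) / (tau_fu + tau_fu_N),
    relative_viscosity = eta / eta_w,
    regime = regime
  ), class = "condensate_summary")
}

#' @export
print.condensate_summary <- function(x, ...) {
  cat(sprintf("%s: eta = %g Pa s, gamma = %g pN/um, tau1 = %g ms\n",
              x$name, x$eta, x$gamma, x$tau1))
  cat(sprintf("  tau_fu = %.3g ms, tau_fu_N = %.3g ms (R = %g um) -> %s (eta_eff/eta = %.3g)\n",
              x$tau_fu, x$tau_fu_N, x$R_ref, x$regime, x$eta_eff_ratio))
  invisible(x)
}

#' Material-property summary table for several condensates
#'
#' Collects the measured and derived quantities of a set of condensates
#' into one table following the conventions of the headline comparison:
#' `tau_fu_star` to 2-3 significant figures, ratios and percent
#' deviation to 2 significant figures.
#'
#' @param summaries list of [derived_metrics()] results (>= 1).
#' @return a data frame of class `condensate_table` (one row per
#'   condensate).
#' @export
table1_report <- function(summaries) {
  if (length(summaries) < 1) stop("need at least one condensate summary")
  if (inherits(summaries, "condensate_summary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "condensate_summary"))
    data.frame(
      name = s$name,
      eta_pa_s = s$eta,
      gamma_pn_um = s$gamma,
      tau1_ms = s$tau1,
      tau_fu_star_ms = signif(s$tau_fu_star, 3),
      ratio_tau1_star = signif(s$ratio_tau1_star, 2),
      tau_fu_ms = signif(s$tau_fu, 3),
      tau_fu_N_ms = signif(s$tau_fu_N, 3),
      pct_diff = signif(s$pct_diff, 2),
      eta_eff_ratio = signif(s$eta_eff_ratio, 3),
      relative_viscosity = signif(s$relative_viscosity, 2),
      regime = s$regime)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condensate_table", "data.frame")
  out
}

#' Write a condensate summary table as JSON
#'
#' @param table a `condensate_table` from [table1_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_json <- function(table, path) {
  stopifnot(inherits(table, "condensate_table"))
  jsonlite::write_json(as.data.frame(table), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
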