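#' Built-in condensate parameter fixtures
#'
#' Ground-truth parameter sets for the four condensate types used
#' throughout the package's synthetic experiments: the Burgers
#' parameters of the interior medium, the interfacial tension, the
#' inverse fusion speed, and the trap stiffness used when probing that
#' condensate.  The zero-shear viscosities (0.30, 0.53, 3.75, 10.1
#' Pa s), slow relaxation times (45, 125, 72, 396 ms), tensions (57.1,
#' 67.0, 73.4, 106 pN/um) and inverse fusion speeds are the measured
#' values for pK:H, P:H, S:P and S:L droplets; the split of the total
#' viscosity between the fast and slow components, which is not fully
#' determined by those measurements, is fixed so that S:P has a
#' Newtonian fast component (`tau0 = 0`), S:L is the only type with
#' `eta0/eta1 > 1`, and the fast relaxation time is 5-35 times shorter
#' than the slow one.
#'
#' @return a named list, one element per condensate, each with fields
#'   `name`, `params` ([burgers_params]), `gamma` (pN/um),
#'   `inverse_fusion_speed` (ms/um), `tau1_ms`, and `kappa_t` (pN/um).
#' @export
#' @examples
#' condensate_presets()[["P:H"]]$params
condensate_presets <- function() {
  mk <- function(name, eta0, tau0, eta1, tau1, gamma, s, kappa_t) {
    list(name = name,
         params = burgers_params(eta0, tau0, eta1, tau1),
         gamma = gamma, inverse_fusion_speed = s,
         tau1_ms = 1000 * tau1, kappa_t = kappa_t)
  }
  list(
    "pK:H" = mk("pK:H", 0.10, 0.005, 0.20, 0.045, 57.1, 10.1, 310),
    "P:H"  = mk("P:H", 0.10, 0.010, 0.43, 0.125, 67.0, 39.3 / 3, 310),
    "S:P"  = mk("S:P", 0.55, 0, 3.20, 0.072, 73.4, 384 / 3, 310),
    "S:L"  = mk("S:L", 5.892, 0.040, 4.208, 0.396, 106, 1774 / 3, 1850)
  )
}
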