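# Shared fixtures for the test suite.  All synthetic inputs are built
# in code; no data files.

std_freq_grid <- function() 2 * pi * c(0.5, 1, 2, 5, 10, 20, 40)

# exact (noise-free) moduli dataset from known parameters
exact_dataset <- function(params, omega = std_freq_grid()) {
  m <- complex_moduli(params, omega)
  moduli_dataset(omega, m$g_prime, m$g_dprime)
}

# a Newtonian medium expressed in Burgers form (tau0 = 0, negligible
# slow component)
newtonian_params <- function(eta) burgers_params(eta, 0, 1e-12, 1e-9)

# one-sided Fourier transform of the relaxation modulus by adaptive
# quadrature: G*(w) = i w int_0^inf G(t) exp(-i w t) dt.  Independent of
# complex_moduli().
moduli_by_quadrature <- function(params, omega) {
  g <- function(t) {
    params$eta0 / params$tau0 * exp(-t / params$tau0) +
      params$eta1 / params$tau1 * exp(-t / params$tau1)
  }
  C <- stats::integrate(function(t) g(t) * cos(omega * t), 0, Inf,
                        rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 2000L)$value
  S <- stats::integrate(function(t) g(t) * sin(omega * t), 0, Inf,
                        rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 2000L)$value
  c(g_prime = omega * S, g_dprime = omega * C)
}

# fabricate an oscillation fit with the force amplitude in volts
make_volt_drive <- function(omega, X_t0, F_V0, Delta) {
  trap_fit <- list(amplitude = X_t0, phase = 0.1, offset = 0,
                   omega = omega, degenerate = FALSE)
  force_fit <- list(amplitude = F_V0, phase = 0.1 + Delta, offset = 0,
                    omega = omega, degenerate = FALSE)
  oscillation_fit(trap_fit, force_fit, kappa_t = NA, force_in_volts = TRUE)
}

# printed measured inputs for the four condensate types
printed_table_inputs <- function() {
  data.frame(
    name = c("pK:H", "P:H", "S:P", "S:L"),
    eta = c(0.30, 0.53, 3.75, 10.1),          # Pa s
    gamma = c(57.1, 67.0, 73.4, 106),          # pN/um
    tau1 = c(45, 125, 72, 396),                # ms
    tau_fu = c(30.3, 39.3, 384, 1774)          # ms at R = 3 um
  )
}
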