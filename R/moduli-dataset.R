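#' Complex-moduli dataset
#'
#' A table of elastic and viscous moduli versus angular frequency, the
#' interface between moduli extraction from driven-bead traces and
#' Burgers-model fitting.  Frequencies must be strictly increasing and
#' positive; `g_dprime` must be positive at every frequency (a fluid
#' always dissipates).  `g_prime` may come out non-positive in noisy
#' data; such rows are retained but flagged in the logical column
#' `flag_g_prime`.
#'
#' @param omega angular frequencies (rad/s), strictly increasing.
#' @param g_prime elastic moduli (Pa).
#' @param g_dprime viscous moduli (Pa), all > 0.
#' @param sem_g_prime,sem_g_dprime optional standard errors of the mean
#'   (Pa).
#' @param n_replicates optional replicate count per row.
#' @return a data frame of class `moduli_dataset`.
#' @export
moduli_dataset <- function(omega, g_prime, g_dprime,
                           sem_g_prime = NA_real_, sem_g_dprime = NA_real_,
                           n_replicates = NA_integer_) {
  if (length(omega) < 1) stop("empty dataset")
  if (any(omega <= 0)) stop("all omega must be > 0")
  if (any(diff(omega) <= 0)) stop("omega must be strictly increasing")
  if (any(g_dprime <= 0)) stop("g_dprime must be > 0 at every frequency")
  d <- data.frame(omega = omega, g_prime = g_prime, g_dprime = g_dprime,
                  sem_g_prime = sem_g_prime, sem_g_dprime = sem_g_dprime,
                  n_replicates = n_replicates,
                  flag_g_prime = g_prime <= 0)
  class(d) <- c("moduli_dataset", "data.frame")
  d
}

#' Read a moduli table from CSV
#'
#' Expects header columns `freq_hz`, `g_prime_pa`, `g_dprime_pa` and
#' optionally `sem_g_prime_pa`, `sem_g_dprime_pa`, `n`.  Ordinary
#' frequency is converted to angular frequency (`omega = 2 pi freq_hz`)
#' at this boundary; everything downstream works in rad/s.
#'
#' @param path CSV file path.
#' @return a [moduli_dataset].
#' @export
read_moduli_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("freq_hz", "g_prime_pa", "g_dprime_pa")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  moduli_dataset(
    omega = 2 * pi * d$freq_hz,
    g_prime = d$g_prime_pa,
    g_dprime = d$g_dprime_pa,
    sem_g_prime = if ("sem_g_prime_pa" %in% names(d)) d$sem_g_prime_pa else NA_real_,
    sem_g_dprime = if ("sem_g_dprime_pa" %in% names(d)) d$sem_g_dprime_pa else NA_real_,
    n_replicates = if ("n" %in% names(d)) d$n else NA_integer_
  )
}

#' Write a moduli table to CSV
#'
#' Inverse of [read_moduli_csv()]; angular frequency is written as
#' ordinary frequency in Hz.
#'
#' @param data a [moduli_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_moduli_csv <- function(data, path) {
  stopifnot(inherits(data, "moduli_dataset"))
  out <- data.frame(freq_hz = data$omega / (2 * pi),
                    g_prime_pa = data$g_prime,
                    g_dprime_pa = data$g_dprime,
                    sem_g_prime_pa = data$sem_g_prime,
                    sem_g_dprime_pa = data$sem_g_dprime,
                    n = data$n_replicates)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
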