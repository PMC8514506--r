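#' Control settings for the end-to-end pipeline
#'
#' Defaults mirror the experimental protocol: drives at 0.5-40 Hz
#' sampled for 10 s at 1 kHz with 1 um trap amplitude, three replicate
#' droplets, stretching of a 5-um droplet with 1-um beads in 600 pN/um
#' traps at 0.05 um/s with ~1% force noise, and 17-droplet fusion
#' datasets spanning radii 0.8-4 um.
#'
#' @param frequencies_hz drive frequencies (Hz).
#' @param n_replicates replicate droplets per condensate.
#' @param duration,sampling_rate oscillation trace length (s) and rate
#'   (Hz).
#' @param amplitude trap oscillation amplitude (um).
#' @param stretch_R,stretch_a droplet and bead radius for stretching
#'   (um).
#' @param stretch_kappa trap stiffness of both stretching traps
#'   (pN/um).
#' @param stretch_v pulling speed (um/s).
#' @param stretch_noise_frac force-noise SD as a fraction of the final
#'   ramp force.
#' @param fusion_radii droplet radii for the fusion dataset (um).
#' @param fusion_noise_frac fusion-time noise SD as a fraction of the
#'   fusion time at the mean radius.
#' @return a list of validated settings.
#' @export
pipeline_control <- function(frequencies_hz = c(0.5, 1, 2, 5, 10, 20, 40),
                             n_replicates = 3,
                             duration = 10, sampling_rate = 1000,
                             amplitude = 1,
                             stretch_R = 5, stretch_a = 1,
                             stretch_kappa = 600, stretch_v = 0.05,
                             stretch_noise_frac = 0.01,
                             fusion_radii = seq(0.8, 4, length.out = 17),
                             fusion_noise_frac = 0.1) {
  stopifnot(length(frequencies_hz) >= 4, all(frequencies_hz > 0),
            n_replicates >= 2, duration > 0, sampling_rate > 0,
            amplitude > 0)
  as.list(environment())
}

#' Run the full synthetic-experiment pipeline
#'
#' For each condensate fixture: simulates driven oscillation traces
#' with thermal noise at every drive frequency for several replicate
#' droplets, extracts moduli via cosine fits, aggregates replicates,
#' fits the Burgers model; simulates and analyses a droplet-stretching
#' experiment for the interfacial tension; simulates a fusion dataset
#' and fits the inverse fusion speed; and assembles the derived fusion
#' metrics.  All randomness derives deterministically from `seed`.
#'
#' @param seed top-level integer seed.
#' @param condensates list of fixtures as from [condensate_presets()].
#' @param control settings from [pipeline_control()].
#' @param out_dir optional directory; when given, the moduli tables,
#'   fit reports and the summary table are written there as CSV/JSON.
#' @param quiet suppress per-stage progress messages.
#' @return list with `summaries` (per-condensate
#'   [derived_metrics()] results), `table` (the [table1_report()]),
#'   `fits` (per-condensate `burgers_fit`s), `tensions`, and
#'   `fusion_fits`.
#' @export
run_pipeline <- function(seed, condensates = condensate_presets(),
                         control = pipeline_control(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  summaries <- list(); fits <- list(); tensions <- list(); fusion_fits <- list()
  for (ci in seq_along(condensates)) {
    cond <- condensates[[ci]]
    base <- (seed + 7919L * ci) %% 2100000000L
    say("[%s] oscillatory rheology: %d frequencies x %d replicates",
        cond$name, length(control$frequencies_hz), control$n_replicates)

    reps <- lapply(seq_len(control$n_replicates), function(r) {
      pairs <- lapply(seq_along(control$frequencies_hz), function(k) {
        fz <- control$frequencies_hz[k]
        cfg <- sim_config(trap_stiffness = cond$kappa_t,
                          sampling_rate = control$sampling_rate,
                          duration = control$duration,
                          seed = base + 100L * r + k)
        simulate_driven_trace(cond$params, cfg, omega = 2 * pi * fz,
                              amplitude = control$amplitude,
                              thermal_noise = TRUE)
      })
      extract_moduli(pairs, kappa_t = cond$kappa_t, a = 1)
    })
    dataset <- aggregate_replicates(reps)
    fit <- fit_burgers(dataset)
    fits[[cond$name]] <- fit
    say("[%s] Burgers fit: eta = %.3g Pa s, tau1 = %.3g ms",
        cond$name, fit$eta, 1000 * fit$params$tau1)

    ## droplet stretching for the interfacial tension
    cfg0 <- sim_config(trap_stiffness = control$stretch_kappa,
                       sampling_rate = control$sampling_rate,
                       duration = 1, seed = base + 1L)
    clean <- simulate_stretch_experiment(cond$gamma, control$stretch_R,
                                         control$stretch_a,
                                         control$stretch_kappa,
                                         control$stretch_kappa,
                                         control$stretch_v, cfg0)
    peak_force <- abs(control$stretch_v) * clean$force2$meta$chi_sys0 *
      (0.5 / abs(control$stretch_v))
    noisy <- simulate_stretch_experiment(cond$gamma, control$stretch_R,
                                         control$stretch_a,
                                         control$stretch_kappa,
                                         control$stretch_kappa,
                                         control$stretch_v, cfg0,
                                         noise_sd = control$stretch_noise_frac *
                                           peak_force)
    sx <- stretch_experiment(noisy$force1, noisy$force2,
                             control$stretch_kappa, control$stretch_kappa,
                             control$stretch_v, control$stretch_R,
                             control$stretch_a)
    tension <- analyze_stretch(sx)
    tensions[[cond$name]] <- tension
    say("[%s] stretching: gamma = %.3g pN/um", cond$name, tension$gamma)

    ## fusion dataset and inverse fusion speed
    fus <- simulate_fusion_dataset(
      cond$inverse_fusion_speed, control$fusion_radii,
      noise_sd = control$fusion_noise_frac * cond$inverse_fusion_speed *
        mean(control$fusion_radii),
      seed = base + 2L)
    ffit <- fit_fusion_speed(fus)
    fusion_fits[[cond$name]] <- ffit
    say("[%s] fusion: inverse speed = %.3g +/- %.2g ms/um",
        cond$name, ffit$inverse_speed, ffit$se)

    summaries[[cond$name]] <- derived_metrics(
      name = cond$name, eta = fit$eta, gamma = tension$gamma,
      tau1 = 1000 * fit$params$tau1,
      inverse_speed = ffit$inverse_speed, inverse_speed_se = ffit$se)

    if (!is.null(out_dir)) {
      write_moduli_csv(dataset, file.path(out_dir,
        paste0("moduli_", gsub("[^A-Za-z]", "_", cond$name), ".csv")))
      write_fit_json(fit, file.path(out_dir,
        paste0("burgers_fit_", gsub("[^A-Za-z]", "_", cond$name), ".json")))
    }
  }
  tab <- table1_report(summaries)
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, "summary_table.csv"),
                     row.names = FALSE)
    write_table_json(tab, file.path(out_dir, "summary_table.json"))
  }
  list(summaries = summaries, table = tab, fits = fits,
       tensions = tensions, fusion_fits = fusion_fits, seed = seed)
}
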