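#' Uniformly sampled time trace
#'
#' The raw material of every pipeline stage: one channel (trap position,
#' bead position, or trapping force) sampled on a uniform grid.  The
#' channel name determines the unit; conversions between volt and
#' physical channels go through a trap calibration, never implicitly.
#'
#' @param values ordered samples (>= 2, all finite).
#' @param dt sampling interval in seconds (> 0).
#' @param t0 start time in seconds.
#' @param channel one of `"trap_position_um"`, `"trap_position_v"`,
#'   `"bead_position_um"`, `"bead_position_v"`, `"force_pn"`,
#'   `"force_v"`.
#' @param meta free-form provenance list (seed, generator parameters,
#'   ground truth).
#' @return an object of class `time_trace`.
#' @export
time_trace <- function(values, dt, t0 = 0,
                       channel = c("bead_position_um", "trap_position_um",
                                   "trap_position_v", "bead_position_v",
                                   "force_pn", "force_v"),
                       meta = list()) {
  channel <- match.arg(channel)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  if (length(values) < 2) stop("need at least 2 samples")
  if (any(!is.finite(values))) stop("all values must be finite")
  structure(list(t0 = t0, dt = dt, values = as.numeric(values),
                 channel = channel, meta = meta),
            class = "time_trace")
}

#' Sample times of a trace
#'
#' @param trace a [time_trace].
#' @return numeric vector of sample times (s).
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "time_trace"))
  trace$t0 + trace$dt * (seq_along(trace$values) - 1)
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("time_trace: %d samples of %s at %g Hz (%.4g s)\n",
              length(x$values), x$channel, 1 / x$dt,
              x$dt * (length(x$values) - 1)))
  invisible(x)
}

#' Write a time trace to CSV
#'
#' Columns `time_s`, `value`, preceded by `#`-comment header lines
#' recording the channel, sampling interval and metadata (as one JSON
#' line), so a trace round-trips through [read_trace()].
#'
#' @param trace a [time_trace].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "time_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# channel: %s", trace$channel),
    sprintf("# dt_s: %.17g", trace$dt),
    sprintf("# t0_s: %.17g", trace$t0),
    sprintf("# meta: %s", as.character(jsonlite::toJSON(trace$meta,
                                                        auto_unbox = TRUE,
                                                        digits = NA)))
  ), con)
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              value = trace$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a time trace from CSV
#'
#' Parses the header comments written by [write_trace()] and validates
#' that the time column is a uniform grid (relative jitter below 1e-9);
#' a gap or irregularity is reported with the first offending row.
#'
#' @param path CSV file with `time_s`, `value` columns.
#' @return a [time_trace].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  channel <- get("channel")
  if (is.null(channel)) stop("missing '# channel:' header")
  valid <- c("trap_position_um", "trap_position_v", "bead_position_um",
             "bead_position_v", "force_pn", "force_v")
  if (!channel %in% valid) stop("unknown channel: ", channel)
  meta_json <- get("meta")
  meta <- if (is.null(meta_json)) list() else jsonlite::fromJSON(meta_json)

  d <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns time_s, value")
  dts <- diff(d$time_s)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > 1e-9 * max(abs(d$time_s), dt))
  if (length(bad))
    stop(sprintf("non-uniform sampling at row %d (dt = %g, expected %g)",
                 bad[1] + 1L, dts[bad[1]], dt))
  time_trace(d$value, dt = dt, t0 = d$time_s[1], channel = channel,
             meta = meta)
}

#' Convert physical-unit traces to detector volts
#'
#' Divides a position trace in um by the volt-to-um factor `epsilon`, or
#' a force trace in pN by `kappa_t * epsilon` (the raw force channel is
#' the bead displacement from the trap, read in volts).  Used to
#' fabricate realistic detector-unit inputs for the active-passive
#' calibration.
#'
#' @param trace a [time_trace] with channel in um or pN.
#' @param epsilon volt-to-um conversion (um/V).
#' @param kappa_t trap stiffness (pN/um); required for force channels.
#' @return a [time_trace] in the corresponding volt channel.
#' @export
trace_to_volts <- function(trace, epsilon, kappa_t = NULL) {
  stopifnot(inherits(trace, "time_trace"), epsilon > 0)
  ch <- trace$channel
  if (ch %in% c("trap_position_um", "bead_position_um")) {
    newch <- sub("_um$", "_v", ch)
    vals <- trace$values / epsilon
  } else if (ch == "force_pn") {
    if (is.null(kappa_t)) stop("kappa_t required to convert a force channel")
    newch <- "force_v"
    vals <- trace$values / (kappa_t * epsilon)
  } else {
    stop("trace is not in physical units: ", ch)
  }
  time_trace(vals, dt = trace$dt, t0 = trace$t0, channel = newch,
             meta = trace$meta)
}
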