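#' @keywords internal
"_PACKAGE"

PROTOCOL_KINDS <- c("membrane_test", "single_ap_10ms", "trains_500ms",
                    "mahp_train", "sag_steps", "spontaneous_izero")
GROUPS <- c("wpi5", "wpi9", "resident")
TREATMENTS <- c("sham", "occluded")

#' Describe a step or pulse-train stimulus
#'
#' Times are in seconds; amplitude is in pA for current clamp and mV for
#' voltage clamp.  For pulse trains, `pulse_width`, `n_pulses` and
#' `frequency` describe a train of identical pulses starting at `onset`.
#'
#' @param onset stimulus onset time (s).
#' @param duration total stimulus duration (s); for trains this is the span
#'   from the first pulse onset to the last pulse offset.
#' @param amplitude step amplitude (pA in current clamp, mV in voltage clamp).
#' @param pulse_width,n_pulses,frequency pulse-train geometry (s, count, Hz);
#'   leave `NULL` for a simple step.
#' @return An object of class `px_stimulus`.
#' @export
step_stimulus <- function(onset, duration, amplitude,
                          pulse_width = NULL, n_pulses = NULL, frequency = NULL) {
  stopifnot(is.numeric(onset), is.numeric(duration), duration > 0,
            is.finite(amplitude))
  if (!is.null(n_pulses) && n_pulses < 1) stop("n_pulses must be >= 1")
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 pulse_width = pulse_width, n_pulses = n_pulses,
                 frequency = frequency),
            class = "px_stimulus")
}

#' Construct a single recording sweep
#'
#' A sweep is one time series on a uniform grid: membrane voltage (mV) in
#' current clamp or pipette current (pA) in voltage clamp.
#'
#' @param t time vector in seconds, uniformly spaced.
#' @param y signal vector: mV (current clamp) or pA (voltage clamp).
#' @param rate sampling rate in Hz; must match the spacing of `t`.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param stim a [step_stimulus()] (optional).
#' @param holding holding level: command voltage (mV) in voltage clamp or
#'   baseline membrane voltage (mV) in current clamp.
#' @return An object of class `px_sweep` with elements `t`, `y`, `rate`,
#'   `mode`, `stim`, `holding`.
#' @export
sweep_ts <- function(t, y, rate,
                     mode = c("current_clamp", "voltage_clamp"),
                     stim = NULL, holding = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(length(t) == length(y), length(t) >= 2)
  if (!all(is.finite(y))) stop("signal must be finite")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - 1 / rate)) > 1e-6 / rate)
    stop("time grid spacing does not match sampling rate")
  if (!is.null(stim)) {
    if (stim$onset < t[1] || stim$onset + stim$duration > t[length(t)] + 1e-12)
      stop("stimulus window lies outside the sweep")
  }
  structure(list(t = t, y = y, rate = rate, mode = mode,
                 stim = stim, holding = holding),
            class = "px_sweep")
}

#' @export
print.px_sweep <- function(x, ...) {
  unit <- if (x$mode == "current_clamp") "mV" else "pA"
  cat(sprintf("<px_sweep> %s, %d samples @ %.3g kHz, %.1f ms, signal in %s\n",
              x$mode, length(x$t), x$rate / 1000,
              1000 * (x$t[length(x$t)] - x$t[1]), unit))
  if (!is.null(x$stim))
    cat(sprintf("  stimulus: %.4g at %.1f ms for %.1f ms\n", x$stim$amplitude,
                1000 * x$stim$onset, 1000 * x$stim$duration))
  invisible(x)
}

#' Bundle the sweeps of one protocol for one cell
#'
#' @param kind one of `r paste(PROTOCOL_KINDS, collapse = ", ")`.
#' @param sweeps list of [sweep_ts()] objects sharing clamp mode and rate.
#' @param cell_id cell identifier.
#' @param group maturation group: `"wpi5"`, `"wpi9"` or `"resident"`.
#' @param treatment `"sham"` or `"occluded"`.
#' @return An object of class `px_recording`.
#' @export
protocol_recording <- function(kind, sweeps, cell_id = NA_character_,
                               group = NA_character_, treatment = NA_character_) {
  kind <- match.arg(kind, PROTOCOL_KINDS)
  stopifnot(is.list(sweeps))
  if (length(sweeps)) {
    modes <- vapply(sweeps, `[[`, "", "mode")
    rates <- vapply(sweeps, `[[`, 0, "rate")
    if (length(unique(modes)) > 1L) stop("sweeps mix clamp modes")
    if (length(unique(rates)) > 1L) stop("sweeps mix sampling rates")
  }
  structure(list(kind = kind, sweeps = sweeps, cell_id = cell_id,
                 group = group, treatment = treatment),
            class = "px_recording")
}

#' @export
print.px_recording <- function(x, ...) {
  cat(sprintf("<px_recording> %s: %d sweep(s), cell %s [%s/%s]\n",
              x$kind, length(x$sweeps), x$cell_id, x$group, x$treatment))
  invisible(x)
}

# stimulus amplitudes of all sweeps in a recording
sweep_amplitudes <- function(rec) {
  vapply(rec$sweeps, function(s) if (is.null(s$stim)) NA_real_ else s$stim$amplitude, 0)
}

# sort sweeps by stimulus amplitude (ascending for depolarising ladders,
# i.e. by signed amplitude); stable for ties
sort_by_amplitude <- function(rec, decreasing = FALSE) {
  amp <- sweep_amplitudes(rec)
  rec$sweeps <- rec$sweeps[order(amp, decreasing = decreasing)]
  rec
}

# index window [i1, i2] of the stimulus step inside a sweep
stim_window <- function(sweep) {
  st <- sweep$stim
  if (is.null(st)) stop("sweep has no stimulus")
  i1 <- which(sweep$t >= st$onset - 1e-12)[1]
  i2 <- max(which(sweep$t <= st$onset + st$duration + 1e-12))
  c(i1, i2)
}
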