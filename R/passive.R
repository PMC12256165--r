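#' Passive membrane properties from the voltage-clamp test pulse
#'
#' The membrane test is a brief hyperpolarising voltage step (typically
#' 10 ms, -10 mV) from a holding voltage of -60 mV.  Series resistance is
#' read off the peak of the capacitive current transient, input resistance
#' off the steady-state current change, and membrane capacitance off the
#' area under the decaying transient between the peak and the steady state.
#'
#' @name passive
NULL

# mean current before the step (baseline) and index bounds of the step
vc_baseline <- function(sweep) {
  w <- stim_window(sweep)
  if (w[1] < 2L) stop("need a pre-step baseline of at least 1 ms")
  mean(sweep$y[seq_len(w[1] - 1L)])
}

#' Series resistance from the peak current
#'
#' \eqn{R_s = \Delta V / (I_{peak} - I_{baseline})}, where the peak is the
#' largest current deflection from baseline inside the step window.
#'
#' @param sweep a voltage-clamp [sweep_ts()] containing the test pulse.
#' @param delta_v command step amplitude in mV (default taken from the
#'   sweep's stimulus).
#' @return Series resistance in MOhm (positive).
#' @export
series_resistance <- function(sweep, delta_v = sweep$stim$amplitude) {
  stopifnot(sweep$mode == "voltage_clamp", is.finite(delta_v), delta_v != 0)
  base <- vc_baseline(sweep)
  w <- stim_window(sweep)
  dev <- sweep$y[w[1]:w[2]] - base
  ipk <- dev[which.max(abs(dev))]
  if (abs(ipk) < 1e-9) stop("no detectable current transient")
  # mV / pA = GOhm -> MOhm
  abs(delta_v / ipk) * 1000
}

#' Input resistance from the steady-state current
#'
#' \eqn{R_i = \Delta V / (I_{ss} - I_{baseline})} with the steady-state
#' current taken as the mean over the final 20\% of the step window.  For a
#' pipette in series with the membrane this returns \eqn{R_s + R_i}, which
#' approximates \eqn{R_i} when \eqn{R_s \ll R_i}.
#'
#' @inheritParams series_resistance
#' @return Input resistance in MOhm (positive).
#' @export
input_resistance <- function(sweep, delta_v = sweep$stim$amplitude) {
  stopifnot(sweep$mode == "voltage_clamp", is.finite(delta_v), delta_v != 0)
  base <- vc_baseline(sweep)
  iss <- vc_steady_state(sweep) - base
  if (abs(iss) < 1e-9) stop("zero steady-state current change: infinite resistance")
  abs(delta_v / iss) * 1000
}

vc_steady_state <- function(sweep) {
  w <- stim_window(sweep)
  n <- w[2] - w[1] + 1L
  i1 <- w[2] - max(1L, floor(0.2 * n)) + 1L
  mean(sweep$y[i1:w[2]])
}

#' Membrane capacitance from the transient charge
#'
#' Integrates the current above the steady state from the peak sample
#' (inclusive) to the end of the step, by the trapezoidal rule, and divides
#' by the command step: \eqn{C_m = \int (I - I_{ss})\,dt / \Delta V}.
#'
#' @inheritParams series_resistance
#' @return Membrane capacitance in pF (positive).
#' @export
membrane_capacitance <- function(sweep, delta_v = sweep$stim$amplitude) {
  stopifnot(sweep$mode == "voltage_clamp", is.finite(delta_v), delta_v != 0)
  base <- vc_baseline(sweep)
  w <- stim_window(sweep)
  iss <- vc_steady_state(sweep)
  dev <- sweep$y[w[1]:w[2]] - base
  pk <- which.max(abs(dev))
  seg <- sweep$y[(w[1] + pk - 1L):w[2]] - iss
  dt_ms <- 1000 / sweep$rate
  charge <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt_ms   # pA ms
  cm <- charge / delta_v                                      # pA ms / mV = pF
  if (!is.finite(cm) || cm <= 0)
    stop("non-positive transient charge: polarity mismatch or flat trace")
  cm
}

#' Passive summary of a membrane-test recording
#'
#' @param rec a `membrane_test` [protocol_recording()]; the first sweep
#'   (pre-protocol test pulse) is analysed.
#' @return list with `R_s`, `R_i`, `C_m` (MOhm, MOhm, pF) and the per-sweep
#'   `R_s_all` used for quality control.
#' @export
membrane_test_properties <- function(rec) {
  stopifnot(inherits(rec, "px_recording"), rec$kind == "membrane_test")
  if (!length(rec$sweeps)) stop("empty recording")
  rs_all <- vapply(rec$sweeps, series_resistance, 0)
  s <- rec$sweeps[[1L]]
  list(R_s = rs_all[1L], R_i = input_resistance(s),
       C_m = membrane_capacitance(s), R_s_all = rs_all)
}

#' Resting membrane potential from an I = 0 recording
#'
#' Mean voltage over the first 5 s of a zero-current recording.  Cells that
#' spike spontaneously during the recording are excluded (the baseline then
#' reflects pacemaking, not rest).
#'
#' @param sweep a current-clamp [sweep_ts()] recorded at I = 0, at least 5 s
#'   long.
#' @return list with `V_rest` (mV, `NA` when excluded) and `excluded`
#'   (logical: `TRUE` when spikes were detected).
#' @export
resting_potential <- function(sweep) {
  stopifnot(sweep$mode == "current_clamp")
  span <- sweep$t[length(sweep$t)] - sweep$t[1]
  if (span < 5 - 1e-9) stop("I = 0 recording shorter than 5 s")
  if (length(detect_spikes(sweep)$times)) {
    return(list(V_rest = NA_real_, excluded = TRUE))
  }
  keep <- sweep$t <= sweep$t[1] + 5 + 1e-12
  list(V_rest = mean(sweep$y[keep]), excluded = FALSE)
}
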