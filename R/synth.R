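#' Synthetic protocol generator
#'
#' Generates per-cell, per-protocol sweep sets from a spiking cell model
#' with known ground truth.  Subthreshold dynamics follow an adaptive
#' leaky integrate-and-fire membrane (hard threshold, spike-triggered
#' adaptation current); the spike waveform itself is a pasted, stylised
#' piecewise-linear shape whose kink times are snapped to the sampling
#' grid, so that every waveform feature the extractor measures (threshold,
#' peak, rate of rise, width at half height) has an exact closed-form
#' value recorded in the generator's ledger.  Measurement noise is
#' band-limited Gaussian voltage noise added to subthreshold samples;
#' pasted spike samples are left clean so that spike-level ledgers remain
#' exact oracles.
#'
#' @name synthdata
NULL

MAHP_MV_PER_NS <- 1.0    # mAHP kernel amplitude per unit AHP conductance
SAG_INDEX_PER_NS <- 0.08 # sag-index depression per unit sag conductance

#' Ground-truth parameters of one synthetic cell
#'
#' @param R_i_true input resistance (MOhm).
#' @param C_m_true membrane capacitance (pF).
#' @param R_s_true pipette series resistance (MOhm).
#' @param E_L leak reversal / resting potential (mV).
#' @param spike_threshold_true spike threshold (mV); also the voltage the
#'   extractor's 10 V/s rule recovers from the pasted waveform.
#' @param spike_peak spike peak voltage (mV).
#' @param rise_ms,fall_ms spike rise and fall times (ms; snapped to the
#'   sampling grid at generation time).
#' @param fahp_depth fast-AHP trough depth below threshold (mV).
#' @param reset post-spike reset voltage (mV).
#' @param refractory_ms duration of the post-trough recovery segment (ms).
#' @param adaptation_increment spike-triggered adaptation current step (pA);
#'   controls SFA.
#' @param adaptation_tau adaptation decay time constant (ms).
#' @param amp_decrement per-spike peak decrement within a train (mV);
#'   controls SAA.
#' @param width_decrement per-spike fractional narrowing of the waveform;
#'   controls SWA.
#' @param ahp_conductance medium-AHP strength (nS); the injected mAHP
#'   kernel has amplitude `ahp_conductance * 1 mV/nS`.
#' @param ahp_tau mAHP kernel decay time constant (ms).
#' @param sag_conductance sag strength (nS); the ground-truth sag index at
#'   -100 mV is `1 - 0.08 * sag_conductance`.
#' @param sag_tau sag relaxation time constant (ms).
#' @param pacemaker_drive tonic drive current at I = 0 (pA); the cell is
#'   spontaneously active when this drives the membrane past threshold.
#' @param block_current depolarisation-block ceiling (pA): steps at or
#'   above it collapse into a spikeless plateau.
#' @param noise_sd voltage noise SD (mV; band-limited to ~10 kHz).
#' @param seed optional per-cell seed.
#' @return list of class `px_synth_params`.
#' @export
synth_cell_params <- function(R_i_true = 870, C_m_true = 20.5, R_s_true = 8,
                              E_L = -60, spike_threshold_true = -34.5,
                              spike_peak = 36.3, rise_ms = 0.16, fall_ms = 0.76,
                              fahp_depth = 25, reset = -50, refractory_ms = 2,
                              adaptation_increment = 30, adaptation_tau = 200,
                              amp_decrement = 0.8, width_decrement = 0.03,
                              ahp_conductance = 2.35, ahp_tau = 50,
                              sag_conductance = 1, sag_tau = 80,
                              pacemaker_drive = 0, block_current = 150,
                              noise_sd = 0.1, seed = NULL) {
  p <- list(R_i_true = R_i_true, C_m_true = C_m_true, R_s_true = R_s_true,
            E_L = E_L, spike_threshold_true = spike_threshold_true,
            spike_peak = spike_peak, rise_ms = rise_ms, fall_ms = fall_ms,
            fahp_depth = fahp_depth, reset = reset,
            refractory_ms = refractory_ms,
            adaptation_increment = adaptation_increment,
            adaptation_tau = adaptation_tau,
            amp_decrement = amp_decrement, width_decrement = width_decrement,
            ahp_conductance = ahp_conductance, ahp_tau = ahp_tau,
            sag_conductance = sag_conductance, sag_tau = sag_tau,
            pacemaker_drive = pacemaker_drive, block_current = block_current,
            noise_sd = noise_sd, seed = seed)
  stopifnot(R_i_true > 0, C_m_true > 0, R_s_true >= 0,
            ahp_conductance >= 0, sag_conductance >= 0,
            adaptation_tau > 0, ahp_tau > 0, sag_tau > 0,
            spike_peak > spike_threshold_true, noise_sd >= 0)
  structure(p, class = "px_synth_params")
}

# membrane time constant in ms (R in MOhm -> GOhm, C in pF)
tau_m <- function(p) p$R_i_true * 1e-3 * p$C_m_true

# band-limited Gaussian voltage noise: white noise smoothed over 100 us,
# rescaled to the requested SD (emulates a ~10 kHz acquisition filter)
make_noise <- function(n, sd, rate) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  w <- max(1L, round(100e-6 * rate))
  x <- stats::rnorm(n + w)
  x <- stats::filter(x, rep(1 / w, w), sides = 1)
  x <- x[!is.na(x)][seq_len(n)]
  x * sd / stats::sd(x)
}

# stylised piecewise-linear spike shape on the grid of sampling period h (ms);
# returns the sample vector, the 0-based peak offset, and the analytic whh
spike_shape <- function(p, h, peak = p$spike_peak,
                        rise = p$rise_ms, fall = p$fall_ms,
                        recover_to = p$reset) {
  th <- p$spike_threshold_true
  trough <- th - p$fahp_depth
  n_flat <- max(2L, round(0.1 / h))
  n_r <- max(2L, round(rise / h))
  n_f <- max(2L, round(fall / h))
  n_rec <- max(1L, round(p$refractory_ms / h))
  v <- c(rep(th, n_flat),
         th + seq_len(n_r) / n_r * (peak - th),
         peak + seq_len(n_f) / n_f * (trough - peak),
         trough + seq_len(n_rec) / n_rec * (recover_to - trough))
  m <- (th + peak) / 2
  whh <- (n_r * h) / 2 + (n_f * h) * (peak - m) / (peak - trough)
  list(v = v, peak_offset = n_flat + n_r, whh = whh, peak = peak,
       trough = trough, n = length(v))
}

#' Simulate one current-clamp step sweep
#'
#' Adaptive leaky integrate-and-fire dynamics (Euler, one sample per grid
#' point) with pasted stylised spike waveforms.  Step amplitudes at or
#' above the cell's `block_current` produce a depolarisation-block sweep:
#' a spikeless plateau.
#'
#' @param p a [synth_cell_params()].
#' @param amplitude step current (pA).
#' @param duration_ms step duration (ms).
#' @param rate sampling rate (Hz).
#' @param pre_ms,post_ms baseline before and tail after the step (ms).
#' @return list with `sweep` (a [sweep_ts()]) and `ledger`: realised spike
#'   peak `times` (ms), `peaks` (mV), analytic `whh` (ms), `V_thresh`,
#'   `max_dvdt` (V/s), `fAHP` (mV, first-spike trough depth measured on the
#'   clean trace), and `blocked`.
#' @export
simulate_cc_step <- function(p, amplitude, duration_ms, rate = 5e4,
                             pre_ms = 50, post_ms = 100) {
  h <- 1000 / rate
  n_pre <- round(pre_ms / h); n_dur <- round(duration_ms / h)
  n_post <- round(post_ms / h)
  n <- n_pre + n_dur + n_post
  tt <- (seq_len(n) - 1L) * h / 1000
  R <- p$R_i_true * 1e-3            # GOhm
  C <- p$C_m_true
  v <- rep(p$E_L, n)
  in_paste <- logical(n)
  ledger <- list(times = numeric(0), peaks = numeric(0), whh = numeric(0),
                 paste_start = integer(0), blocked = FALSE,
                 V_thresh = p$spike_threshold_true,
                 max_dvdt = NA_real_, fAHP = NA_real_)
  i_on <- n_pre + 1L; i_off <- n_pre + n_dur

  if (amplitude >= p$block_current) {
    # depolarisation block: spike generation collapses into a plateau
    ledger$blocked <- TRUE
    tm <- tau_m(p)
    tstep <- (seq_len(n_dur) - 1L) * h
    v[i_on:i_off] <- -15 + (p$E_L + 15) * exp(-tstep / tm)
    tpost <- (seq_len(n_post)) * h
    v[(i_off + 1L):n] <- p$E_L + (v[i_off] - p$E_L) * exp(-tpost / tm)
  } else {
    vv <- p$E_L; w <- 0
    k <- 0L        # spikes fired so far in this sweep
    i <- i_on
    dec_w <- exp(-h / p$adaptation_tau)
    while (i <= n) {
      I <- if (i <= i_off) amplitude else 0
      vv <- vv + (h / C) * (-(vv - p$E_L) / R + I - w)
      w <- w * dec_w
      if (vv >= p$spike_threshold_true && i <= i_off) {
        # paste the k-th spike waveform
        shrink <- max(0.4, 1 - p$width_decrement * k)
        sh <- spike_shape(p, h,
                          peak = max(p$spike_peak - p$amp_decrement * k, 5),
                          rise = p$rise_ms * shrink, fall = p$fall_ms * shrink)
        j2 <- min(n, i + sh$n - 1L)
        v[i:j2] <- sh$v[seq_len(j2 - i + 1L)]
        in_paste[i:j2] <- TRUE
        ip <- i + sh$peak_offset - 1L
        if (ip <= n) {
          ledger$times <- c(ledger$times, (ip - 1L) * h)
          ledger$peaks <- c(ledger$peaks, sh$peak)
          ledger$whh <- c(ledger$whh, sh$whh)
          ledger$paste_start <- c(ledger$paste_start, i)
          if (k == 0L)
            ledger$max_dvdt <- (sh$peak - p$spike_threshold_true) /
              (max(2L, round(p$rise_ms * shrink / h)) * h)
        }
        k <- k + 1L
        w <- w * exp(-(j2 - i) * h / p$adaptation_tau) + p$adaptation_increment
        vv <- p$reset
        i <- j2 + 1L
        next
      }
      v[i] <- vv
      i <- i + 1L
    }
    # first-spike trough depth on the clean trace, over the extractor's
    # search window (first peak to next spike threshold or step end)
    ns <- length(ledger$times)
    if (ns >= 1L) {
      ip1 <- which(tt * 1000 >= ledger$times[1L])[1L]
      iw2 <- if (ns >= 2L) {
        nf <- max(2L, round(0.1 / h))
        ledger$paste_start[2L] + nf - 1L
      } else i_off
      ledger$fAHP <- p$spike_threshold_true - min(v[ip1:iw2])
    }
  }
  if (p$noise_sd > 0) {
    nz <- make_noise(n, p$noise_sd, rate)
    v[!in_paste] <- v[!in_paste] + nz[!in_paste]
  }
  st <- step_stimulus(onset = (i_on - 1L) * h / 1000,
                      duration = n_dur * h / 1000, amplitude = amplitude)
  list(sweep = sweep_ts(tt, v, rate, "current_clamp", st, holding = p$E_L),
       ledger = ledger)
}

#' Simulate the 500 ms multiple-spiking step ladder
#'
#' Steps increase from 0 pA until the cell's depolarisation-block ceiling
#' is reached (one blocked sweep is included, mirroring ladders that were
#' stopped at depolarisation block).
#'
#' @param p a [synth_cell_params()].
#' @param step_pA ladder increment (pA).
#' @param rate sampling rate (Hz).
#' @param max_amp safety ceiling on the ladder (pA).
#' @return list with `recording` (a `trains_500ms` [protocol_recording()])
#'   and `ledgers` (one per sweep, see [simulate_cc_step()]), plus
#'   `amplitudes`.
#' @export
simulate_trains <- function(p, step_pA = 10, rate = 5e4, max_amp = 400) {
  amps <- seq(0, max_amp, by = step_pA)
  sweeps <- list(); ledgers <- list(); used <- numeric(0)
  for (a in amps) {
    r <- simulate_cc_step(p, a, 500, rate)
    sweeps <- c(sweeps, list(r$sweep))
    ledgers <- c(ledgers, list(r$ledger))
    used <- c(used, a)
    if (r$ledger$blocked) break
  }
  list(recording = protocol_recording("trains_500ms", sweeps),
       ledgers = ledgers, amplitudes = used)
}

#' Simulate the 10 ms single action-potential ladder
#'
#' 10 ms steps from 0 pA in fixed increments at 200 kHz, stopped at the
#' first sweep whose voltage exceeds 0 mV inside the step window.
#'
#' @inheritParams simulate_trains
#' @return list with `recording` (a `single_ap_10ms`
#'   [protocol_recording()]), per-sweep `ledgers`, and `threshold_sweep`
#'   (index of the first suprathreshold sweep, `NA` if none).
#' @export
simulate_single_ap <- function(p, step_pA = 10, rate = 2e5, max_amp = 400) {
  amps <- seq(0, max_amp, by = step_pA)
  sweeps <- list(); ledgers <- list(); hit <- NA_integer_
  for (k in seq_along(amps)) {
    r <- simulate_cc_step(p, amps[k], 10, rate, pre_ms = 5, post_ms = 15)
    sweeps <- c(sweeps, list(r$sweep))
    ledgers <- c(ledgers, list(r$ledger))
    w <- stim_window(r$sweep)
    if (any(r$sweep$y[w[1]:w[2]] > 0)) { hit <- k; break }
  }
  list(recording = protocol_recording("single_ap_10ms", sweeps),
       ledgers = ledgers, threshold_sweep = hit)
}

#' Simulate the voltage-clamp membrane test
#'
#' Analytic current response of the two-resistor circuit (pipette
#' resistance in series with the membrane RC): a -10 mV, 10 ms command step
#' from -60 mV produces an instantaneous peak \eqn{\Delta V / R_s} decaying
#' with \eqn{\tau = C_m R_s R_i / (R_s + R_i)} to the steady state
#' \eqn{\Delta V / (R_s + R_i)}.
#'
#' @param p a [synth_cell_params()].
#' @param delta_v command step (mV).
#' @param rate sampling rate (Hz).
#' @param rs_values series resistance per sweep (MOhm); defaults to the
#'   cell's true Rs for both the pre- and post-protocol test pulse.
#' @return a `membrane_test` [protocol_recording()].
#' @export
simulate_membrane_test <- function(p, delta_v = -10, rate = 5e4,
                                   rs_values = rep(p$R_s_true, 2)) {
  h <- 1000 / rate
  n_pre <- round(5 / h); n_dur <- round(10 / h); n_post <- round(10 / h)
  n <- n_pre + n_dur + n_post
  tt <- (seq_len(n) - 1L) * h / 1000
  Ri <- p$R_i_true * 1e-3                       # GOhm
  v_hold <- -60
  sweeps <- lapply(rs_values, function(rs_mohm) {
    Rs <- rs_mohm * 1e-3
    i0 <- (v_hold - p$E_L) / (Rs + Ri)          # pA
    y <- rep(i0, n)
    # the sample at t = onset + duration is still at step level; the
    # off-transient begins one sample later
    io <- n_pre + 1L; ie <- n_pre + n_dur + 1L
    if (Rs > 0) {
      tau <- p$C_m_true * Rs * Ri / (Rs + Ri)   # ms
      ts <- (seq_len(ie - io + 1L) - 1L) * h
      y[io:ie] <- i0 + delta_v / (Rs + Ri) +
        delta_v * (1 / Rs - 1 / (Rs + Ri)) * exp(-ts / tau)
      tp <- (seq_len(n - ie)) * h
      y[(ie + 1L):n] <- i0 - delta_v * (1 / Rs - 1 / (Rs + Ri)) * exp(-tp / tau)
    } else {
      y[io:ie] <- i0 + delta_v / Ri             # ideal clamp: no transient
    }
    if (p$noise_sd > 0) y <- y + make_noise(n, 10 * p$noise_sd, rate)
    st <- step_stimulus(onset = n_pre * h / 1000, duration = n_dur * h / 1000,
                        amplitude = delta_v)
    sweep_ts(tt, y, rate, "voltage_clamp", st, holding = v_hold)
  })
  protocol_recording("membrane_test", sweeps)
}

# difference-of-exponentials kernel, normalised to unit trough depth
mahp_kernel <- function(t_ms, tau_d, tau_r) {
  g <- function(t) exp(-t / tau_d) - exp(-t / tau_r)
  tstar <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
  g(pmax(t_ms, 0)) / g(tstar)
}

#' Simulate the mAHP pulse-train protocol
#'
#' Ten 2 ms suprathreshold pulses at 50 Hz per sweep, repeated over ten
#' sweeps, from a -60 mV holding voltage.  The medium AHP is injected as an
#' analytic difference-of-exponentials kernel of amplitude
#' `ahp_conductance * 1 mV/nS` anchored at the end of the last spike
#' waveform, so its trough depth is known exactly.
#'
#' @param p a [synth_cell_params()].
#' @param n_sweeps,n_pulses protocol geometry.
#' @param freq pulse frequency (Hz).
#' @param pulse_pA,pulse_ms pulse amplitude and width.
#' @param rate sampling rate (Hz).
#' @param fail_sweeps indices of sweeps in which the final pulse fails to
#'   elicit a spike (exercises the 10-spike inclusion rule).
#' @return list with `recording` (a `mahp_train` [protocol_recording()])
#'   and `mahp_true` (mV).
#' @export
simulate_mahp_protocol <- function(p, n_sweeps = 10, n_pulses = 10, freq = 50,
                                   pulse_pA = 500, pulse_ms = 2, rate = 5e4,
                                   fail_sweeps = integer(0)) {
  h <- 1000 / rate
  v_hold <- -60
  onset_ms <- 100
  period_ms <- 1000 / freq
  train_ms <- (n_pulses - 1) * period_ms + pulse_ms
  total_ms <- onset_ms + train_ms + 350
  n <- round(total_ms / h)
  tt <- (seq_len(n) - 1L) * h / 1000
  A <- p$ahp_conductance * MAHP_MV_PER_NS
  # keep the spike trough at or above holding so the post-train minimum is
  # the injected kernel trough, not the last spike's fast AHP
  pshape <- p
  pshape$fahp_depth <- min(p$fahp_depth, p$spike_threshold_true - v_hold)
  sh <- spike_shape(pshape, h, recover_to = v_hold)
  sweeps <- vector("list", n_sweeps)
  for (s in seq_len(n_sweeps)) {
    v <- rep(v_hold, n)
    in_paste <- logical(n)
    pulses <- seq_len(n_pulses)
    if (s %in% fail_sweeps) pulses <- pulses[-n_pulses]
    wend <- NA_integer_
    for (k in pulses) {
      i <- round((onset_ms + (k - 1) * period_ms) / h) + 1L
      j2 <- min(n, i + sh$n - 1L)
      v[i:j2] <- sh$v[seq_len(j2 - i + 1L)]
      in_paste[i:j2] <- TRUE
      wend <- j2
    }
    if (A > 0 && !is.na(wend) && wend < n) {
      idx <- (wend + 1L):n
      ker <- A * mahp_kernel((idx - wend - 1L) * h, p$ahp_tau, p$ahp_tau / 10)
      v[idx] <- v[idx] - ker
    }
    if (p$noise_sd > 0) {
      nz <- make_noise(n, p$noise_sd, rate)
      v[!in_paste] <- v[!in_paste] + nz[!in_paste]
    }
    st <- step_stimulus(onset = onset_ms / 1000, duration = train_ms / 1000,
                        amplitude = pulse_pA, pulse_width = pulse_ms / 1000,
                        n_pulses = n_pulses, frequency = freq)
    sweeps[[s]] <- sweep_ts(tt, v, rate, "current_clamp", st, holding = v_hold)
  }
  list(recording = protocol_recording("mahp_train", sweeps), mahp_true = A)
}

#' Simulate the sag-potential step ladder
#'
#' 500 ms hyperpolarising steps of -10 pA increments from -60 mV until the
#' steady-state voltage reaches -100 mV.  The cell's ground-truth sag index
#' is a linear function of the steady-state voltage,
#' `s0 + 0.001 * sag_conductance * (V_ss + 100)`, with
#' `s0 = 1 - 0.08 * sag_conductance` its value at -100 mV; each step's
#' trace is a double-exponential relaxation whose sampled minimum is tuned
#' to the nominal sag voltage.
#'
#' @param p a [synth_cell_params()].
#' @param step_pA ladder increment (negative pA).
#' @param rate sampling rate (Hz).
#' @param max_steps safety cap on the ladder length.
#' @return list with `recording` (a `sag_steps` [protocol_recording()]),
#'   `sag_true` (index at -100 mV) and the nominal per-step table.
#' @export
simulate_sag_protocol <- function(p, step_pA = -10, rate = 5e4, max_steps = 25) {
  h <- 1000 / rate
  v_hold <- -60
  s0 <- max(1 - SAG_INDEX_PER_NS * p$sag_conductance, 0.2)
  ds <- 0.001 * p$sag_conductance          # index change per mV of V_ss
  tau1 <- tau_m(p); tau2 <- p$sag_tau
  R <- p$R_i_true * 1e-3
  n_pre <- round(100 / h); n_dur <- round(500 / h); n_post <- round(150 / h)
  n <- n_pre + n_dur + n_post
  tt <- (seq_len(n) - 1L) * h / 1000
  ts <- (seq_len(n_dur) - 1L) * h
  sweeps <- list(); steps <- NULL
  for (k in seq_len(max_steps)) {
    I <- step_pA * k
    v_sag <- v_hold + I * R                          # passive minimum
    D <- v_hold - v_sag
    # solve idx = s0 + ds (V_ss + 100) jointly with V_ss = V_hold - idx D
    v_ss <- (v_hold - D * s0 - 100 * D * ds) / (1 + D * ds)
    idx_nom <- (v_hold - v_ss) / (v_hold - v_sag)
    # tune the deep-exponential target so the sampled minimum hits v_sag
    shape <- function(vadj) v_hold + (vadj - v_hold) * (1 - exp(-ts / tau1)) +
      (v_ss - vadj) * (1 - exp(-ts / tau2))
    if (abs(v_ss - v_sag) < 1e-9) {
      vstep <- shape(v_sag)
    } else {
      f <- function(vadj) min(shape(vadj)) - v_sag
      vadj <- stats::uniroot(f, c(v_sag - 30, v_sag), tol = 1e-10)$root
      vstep <- shape(vadj)
    }
    v <- rep(v_hold, n)
    v[(n_pre + 1L):(n_pre + n_dur)] <- vstep
    tp <- seq_len(n_post) * h
    v[(n_pre + n_dur + 1L):n] <- v_hold +
      (vstep[n_dur] - v_hold) * exp(-tp / tau1)
    if (p$noise_sd > 0) v <- v + make_noise(n, p$noise_sd, rate)
    st <- step_stimulus(onset = n_pre * h / 1000, duration = n_dur * h / 1000,
                        amplitude = I)
    sweeps <- c(sweeps, list(sweep_ts(tt, v, rate, "current_clamp", st,
                                      holding = v_hold)))
    steps <- rbind(steps, data.frame(current = I, V_ss = v_ss, V_sag = v_sag,
                                     sag_index = idx_nom))
    if (v_ss <= -100) break
  }
  list(recording = protocol_recording("sag_steps", sweeps),
       sag_true = s0, per_step = steps)
}

#' Simulate a 5.5 s I = 0 recording
#'
#' Silent cells sit at the drive-shifted resting potential; pacemaking
#' cells (drive pushing the membrane past threshold) fire regularly at the
#' closed-form integrate-and-fire period.
#'
#' @param p a [synth_cell_params()].
#' @param duration_s recording length (s).
#' @param rate sampling rate (Hz).
#' @return list with `sweep` and `spontaneous_true`.
#' @export
simulate_izero <- function(p, duration_s = 5.5, rate = 1e4) {
  h <- 1000 / rate
  n <- round(duration_s * 1000 / h)
  tt <- (seq_len(n) - 1L) * h / 1000
  R <- p$R_i_true * 1e-3
  v_inf <- p$E_L + p$pacemaker_drive * R
  spont <- v_inf > p$spike_threshold_true
  tm <- tau_m(p)
  if (!spont) {
    v <- rep(v_inf, n)
    in_paste <- logical(n)
  } else {
    sh <- spike_shape(p, h)
    t_sub <- tm * log((v_inf - p$reset) / (v_inf - p$spike_threshold_true))
    period <- max(t_sub, 5) + sh$n * h          # ms
    v <- rep(p$reset, n); in_paste <- logical(n)
    i <- round(50 / h) + 1L
    v[seq_len(i - 1L)] <- p$spike_threshold_true - 1
    while (i <= n) {
      j2 <- min(n, i + sh$n - 1L)
      v[i:j2] <- sh$v[seq_len(j2 - i + 1L)]
      in_paste[i:j2] <- TRUE
      i_next <- i + round(period / h)
      if (j2 < n) {
        idx <- (j2 + 1L):min(n, i_next - 1L)
        if (length(idx))
          v[idx] <- v_inf + (p$reset - v_inf) * exp(-(idx - j2) * h / tm)
      }
      i <- i_next
    }
  }
  if (p$noise_sd > 0) {
    nz <- make_noise(n, p$noise_sd, rate)
    v[!in_paste] <- v[!in_paste] + nz[!in_paste]
  }
  list(sweep = sweep_ts(tt, v, rate, "current_clamp", NULL, holding = p$E_L),
       spontaneous_true = spont)
}
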