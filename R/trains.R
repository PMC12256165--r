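#' Spike-train analysis of 500 ms current steps
#'
#' Spikes are defined as contiguous excursions of the membrane voltage above
#' 0 mV; each spike is timed at its voltage maximum.  Per-sweep adaptation
#' statistics are computed from inter-spike intervals (ISIs), spike peaks and
#' per-spike widths; input-output slopes are fitted over the sweeps spanning
#' 0--80\% of the maximum spike count, and the irregularity/adaptation
#' measures are summarised at the sweep nearest 1.5x rheobase.
#'
#' @name spike_trains
NULL

#' Detect spikes in a current-clamp sweep
#'
#' One spike per contiguous region with V > 0 mV; the spike time is the time
#' of the region maximum.
#'
#' @param sweep a current-clamp [sweep_ts()].
#' @return list with `times` (ms), `peaks` (mV) and `peak_index`.
#' @export
detect_spikes <- function(sweep) {
  stopifnot(sweep$mode == "current_clamp")
  up <- sweep$y > 0
  if (!any(up)) return(list(times = numeric(0), peaks = numeric(0),
                            peak_index = integer(0)))
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- which(r$values)
  idx <- vapply(reg, function(k) {
    i <- starts[k]:ends[k]
    i[which.max(sweep$y[i])]
  }, 0L)
  list(times = 1000 * sweep$t[idx], peaks = sweep$y[idx], peak_index = idx)
}

#' Adaptation statistics of one spike train
#'
#' Direct evaluation of the train formulas: instantaneous frequency
#' \eqn{IF = 1/ISI_1}, coefficient of variation \eqn{CV = SD(ISI)/mean(ISI)}
#' (sample SD), spike frequency adaptation
#' \eqn{SFA = (f_{first} - f_{last})/f_{first} \times 100} with
#' \eqn{f = 1/ISI}, and amplitude/width adaptation
#' \eqn{SAA = (V^{max}_{first} - V^{max}_{last}) / V^{max}_{first} \times 100}
#' (same form for SWA on widths).
#'
#' @param spike_times spike peak times in ms.
#' @param spike_peaks spike peak voltages in mV (optional, for SAA).
#' @param spike_whh per-spike widths at half height in ms (optional, for SWA).
#' @return list with `IF` (Hz), `CV`, `SFA` (\%), `SAA` (\%), `SWA` (\%);
#'   entries are `NA` when too few spikes define them (IF/SAA/SWA need 2
#'   spikes, CV/SFA need 3).
#' @export
train_statistics <- function(spike_times, spike_peaks = NULL, spike_whh = NULL) {
  n <- length(spike_times)
  if (n >= 2L && any(diff(spike_times) <= 0))
    stop("spike times must be strictly increasing")
  isi <- diff(spike_times)                  # ms
  out <- list(IF = NA_real_, CV = NA_real_, SFA = NA_real_,
              SAA = NA_real_, SWA = NA_real_)
  if (n >= 2L) out$IF <- 1000 / isi[1L]     # Hz
  if (n >= 3L) {
    out$CV <- stats::sd(isi) / mean(isi)
    f <- 1 / isi
    out$SFA <- (f[1L] - f[length(f)]) / f[1L] * 100
  }
  adapt <- function(x) (x[1L] - x[length(x)]) / x[1L] * 100
  if (!is.null(spike_peaks) && length(spike_peaks) >= 2L)
    out$SAA <- adapt(spike_peaks)
  if (!is.null(spike_whh)) {
    w <- spike_whh[is.finite(spike_whh)]
    if (length(w) >= 2L) out$SWA <- adapt(w)
  }
  out
}

# per-sweep analysis of a 500 ms step: spikes, per-spike widths, statistics
analyse_sweep <- function(sweep) {
  sp <- detect_spikes(sweep)
  n <- length(sp$times)
  whh <- rep(NA_real_, n)
  thr_t <- rep(NA_real_, n)
  thr_v <- rep(NA_real_, n)
  if (n) {
    sd <- smooth_derivative(sweep, warn_rate = FALSE)
    for (i in seq_len(n)) {
      f <- spike_features_at(sweep, sp$peak_index[i], sd)
      if (!is.null(f)) {
        whh[i] <- f$whh; thr_t[i] <- f$threshold_time; thr_v[i] <- f$V_thresh
      }
    }
  }
  stats <- train_statistics(sp$times, sp$peaks, whh)
  c(list(current = if (is.null(sweep$stim)) NA_real_ else sweep$stim$amplitude,
         n_spikes = n, spike_times = sp$times, spike_peaks = sp$peaks,
         whh = whh, threshold_times = thr_t, threshold_v = thr_v),
    stats)
}

#' Rheobase, first-spike latency and fast afterhyperpolarisation
#'
#' All three are read off the first suprathreshold sweep of an increasing
#' 500 ms step ladder: rheobase is that sweep's current, latency the time
#' from step onset to the first spike's peak, and fAHP the drop from the
#' first spike's threshold to the voltage minimum between its peak and the
#' earlier of the next spike's threshold time or the step end.
#'
#' @param rec a `trains_500ms` [protocol_recording()] with increasing step
#'   amplitudes.
#' @return list with `rheobase` (pA), `latency` (ms), `fAHP` (mV, positive);
#'   all `NA` when no sweep is suprathreshold.
#' @export
rheobase_latency_fahp <- function(rec) {
  rec <- sort_by_amplitude(rec)
  for (s in rec$sweeps) {
    a <- analyse_sweep(s)
    if (a$n_spikes >= 1L) {
      onset_ms <- 1000 * s$stim$onset
      end_ms <- 1000 * (s$stim$onset + s$stim$duration)
      lat <- a$spike_times[1L] - onset_ms
      t_ms <- 1000 * s$t
      win_end <- if (a$n_spikes >= 2L && is.finite(a$threshold_times[2L]))
        a$threshold_times[2L] else end_ms
      sel <- t_ms >= a$spike_times[1L] & t_ms <= win_end
      fahp <- if (is.finite(a$threshold_v[1L]) && any(sel))
        a$threshold_v[1L] - min(s$y[sel]) else NA_real_
      return(list(rheobase = a$current, latency = lat, fAHP = fahp))
    }
  }
  list(rheobase = NA_real_, latency = NA_real_, fAHP = NA_real_)
}

#' Input-output slopes and maximum spike count
#'
#' Ordinary least-squares slopes of IF and SAA against injected current,
#' fitted from the first suprathreshold sweep up to and including the first
#' sweep whose spike count reaches 80\% of the maximum spike count.
#'
#' @param per_sweep data frame with columns `current`, `n_spikes`, `IF`,
#'   `SAA` (one row per sweep, currents increasing).
#' @return list with `IF_slope` (Hz/pA), `SAA_slope` (\%/pA),
#'   `max_spike_no`; slopes are `NA` with fewer than 3 usable points.
#' @export
io_fit <- function(per_sweep) {
  ps <- per_sweep[order(per_sweep$current), , drop = FALSE]
  max_n <- if (nrow(ps)) max(ps$n_spikes) else 0L
  out <- list(IF_slope = NA_real_, SAA_slope = NA_real_, max_spike_no = max_n)
  supra <- which(ps$n_spikes >= 1L)
  if (!length(supra) || max_n < 1L) return(out)
  first <- supra[1L]
  last <- which(ps$n_spikes >= 0.8 * max_n)[1L]
  rng <- ps[first:last, , drop = FALSE]
  ols_slope <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) return(NA_real_)
    unname(stats::coef(stats::lm(y[ok] ~ x[ok]))[2L])
  }
  out$IF_slope <- ols_slope(rng$current, rng$IF)
  out$SAA_slope <- ols_slope(rng$current, rng$SAA)
  out
}

#' Representative train measures at 1.5x rheobase
#'
#' CV, SFA and SWA depend non-linearly on injected current, so a single
#' representative sweep is chosen: the suprathreshold sweep whose current is
#' nearest 1.5x rheobase (exact ties broken toward the higher current).
#'
#' @param per_sweep data frame with columns `current`, `n_spikes`, `CV`,
#'   `SFA`, `SWA`.
#' @param rheobase rheobase current in pA (`NA` gives all-`NA` output).
#' @return list with `CV`, `SFA`, `SWA` and `current_used`.
#' @export
at_1p5_rheobase <- function(per_sweep, rheobase) {
  out <- list(CV = NA_real_, SFA = NA_real_, SWA = NA_real_,
              current_used = NA_real_)
  if (!is.finite(rheobase)) return(out)
  ps <- per_sweep[per_sweep$n_spikes >= 1L & is.finite(per_sweep$current), ,
                  drop = FALSE]
  if (!nrow(ps)) return(out)
  target <- 1.5 * rheobase
  d <- abs(ps$current - target)
  if (min(d) > 0.5 * target) {
    warning("no sweep within 50% of 1.5x rheobase")
    return(out)
  }
  cand <- which(d == min(d))
  pick <- cand[which.max(ps$current[cand])]   # ties toward higher current
  out$CV <- ps$CV[pick]; out$SFA <- ps$SFA[pick]; out$SWA <- ps$SWA[pick]
  out$current_used <- ps$current[pick]
  out
}

#' Full analysis of a 500 ms step ladder
#'
#' @param rec a `trains_500ms` [protocol_recording()].
#' @return list of class `px_train_analysis`: `per_sweep` (data frame),
#'   `rheobase`, `latency`, `fAHP`, `max_spike_no`, `IF_slope`, `SAA_slope`,
#'   `CV`, `SFA`, `SWA` (the latter three at 1.5x rheobase).
#' @export
analyse_trains <- function(rec) {
  stopifnot(inherits(rec, "px_recording"))
  rec <- sort_by_amplitude(rec)
  rows <- lapply(rec$sweeps, analyse_sweep)
  per_sweep <- do.call(rbind, lapply(rows, function(a)
    data.frame(current = a$current, n_spikes = a$n_spikes, IF = a$IF,
               CV = a$CV, SFA = a$SFA, SAA = a$SAA, SWA = a$SWA)))
  rlf <- rheobase_latency_fahp(rec)
  io <- io_fit(per_sweep)
  rep15 <- at_1p5_rheobase(per_sweep, rlf$rheobase)
  structure(c(list(per_sweep = per_sweep), rlf, io,
              rep15[c("CV", "SFA", "SWA")]),
            class = "px_train_analysis")
}

#' Medium afterhyperpolarisation amplitude
#'
#' Averages, point-wise, every sweep that fired exactly the commanded number
#' of spikes, and measures the drop from the holding voltage to the minimum
#' of the mean trace in the 250 ms following the end of the pulse train.
#'
#' @param rec a `mahp_train` [protocol_recording()] (10 sweeps of 10 pulses
#'   at 50 Hz in the standard protocol).
#' @return list with `mAHP` (mV, positive; `NA` when no sweep is valid) and
#'   `n_valid` (sweeps entering the average).
#' @export
mahp_amplitude <- function(rec) {
  stopifnot(inherits(rec, "px_recording"))
  if (!length(rec$sweeps)) return(list(mAHP = NA_real_, n_valid = 0L))
  s1 <- rec$sweeps[[1L]]
  n_target <- if (!is.null(s1$stim$n_pulses)) s1$stim$n_pulses else 10L
  valid <- vapply(rec$sweeps, function(s)
    length(detect_spikes(s)$times) == n_target, TRUE)
  if (!any(valid)) return(list(mAHP = NA_real_, n_valid = 0L))
  ys <- vapply(rec$sweeps[valid], `[[`, numeric(length(s1$y)), "y")
  mtrace <- rowMeans(as.matrix(ys))
  v_hold <- if (is.finite(s1$holding)) s1$holding else
    mean(mtrace[s1$t < s1$stim$onset])
  t_end <- s1$stim$onset + s1$stim$duration
  sel <- s1$t >= t_end & s1$t <= t_end + 0.250
  list(mAHP = v_hold - min(mtrace[sel]), n_valid = sum(valid))
}

#' Sag index from hyperpolarising step ladders
#'
#' For each 500 ms hyperpolarising step, the sag index is
#' \eqn{(V_{hold} - V_{ss}) / (V_{hold} - V_{sag})} with \eqn{V_{ss}} the
#' mean voltage over the last 10\% of the step and \eqn{V_{sag}} the minimum
#' voltage during the step.  The index at -100 mV is linearly interpolated
#' in \eqn{V_{ss}} between the two steps bracketing -100 mV.
#'
#' @param rec a `sag_steps` [protocol_recording()].
#' @return list of class `px_sag`: `per_step` data frame (`current`,
#'   `V_hold`, `V_ss`, `V_sag`, `sag_index`), `sag_index_at_m100`, and
#'   `flag` (`"ok"`, `"nearest"` when a single step within 2 mV of -100 mV
#'   was used, `"no_bracket"` when the measure is undefined).
#' @export
sag_index <- function(rec) {
  stopifnot(inherits(rec, "px_recording"))
  rows <- lapply(rec$sweeps, function(s) {
    w <- stim_window(s)
    v_hold <- if (is.finite(s$holding)) s$holding else mean(s$y[seq_len(w[1] - 1L)])
    n <- w[2] - w[1] + 1L
    i1 <- w[2] - max(1L, floor(0.1 * n)) + 1L
    v_ss <- mean(s$y[i1:w[2]])
    v_sag <- min(s$y[w[1]:w[2]])
    idx <- if (abs(v_hold - v_sag) < 1e-12) NA_real_ else
      (v_hold - v_ss) / (v_hold - v_sag)
    data.frame(current = if (is.null(s$stim)) NA_real_ else s$stim$amplitude,
               V_hold = v_hold, V_ss = v_ss, V_sag = v_sag, sag_index = idx)
  })
  per_step <- do.call(rbind, rows)
  per_step <- per_step[order(per_step$V_ss, decreasing = TRUE), , drop = FALSE]
  target <- -100
  at100 <- NA_real_
  flag <- "no_bracket"
  above <- which(per_step$V_ss >= target)
  below <- which(per_step$V_ss <= target)
  if (length(above) && length(below)) {
    i <- above[length(above)]; j <- below[1L]
    if (i == j) {                      # a step landed exactly at -100 mV
      at100 <- per_step$sag_index[i]; flag <- "ok"
    } else {
      v1 <- per_step$V_ss[i]; v2 <- per_step$V_ss[j]
      s1 <- per_step$sag_index[i]; s2 <- per_step$sag_index[j]
      at100 <- s1 + (s2 - s1) * (target - v1) / (v2 - v1)
      flag <- "ok"
    }
  } else if (any(abs(per_step$V_ss - target) <= 2)) {
    k <- which.min(abs(per_step$V_ss - target))
    at100 <- per_step$sag_index[k]; flag <- "nearest"
  }
  structure(list(per_step = per_step, sag_index_at_m100 = at100, flag = flag),
            class = "px_sag")
}

#' Spontaneous activity at I = 0
#'
#' @param sweep a current-clamp [sweep_ts()] recorded with no injected
#'   current.
#' @return `TRUE` if at least one spike is detected.
#' @export
spontaneous_activity <- function(sweep) {
  length(detect_spikes(sweep)$times) >= 1L
}
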