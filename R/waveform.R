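#' Single action-potential waveform analysis
#'
#' Spikes evoked by brief (10 ms) depolarising steps are analysed on traces
#' sampled at 200 kHz.  The voltage is smoothed with a 20-point (100 us)
#' sliding boxcar before differentiation; threshold is the voltage at which
#' the smoothed rate of rise exceeds 10 V/s, and spike width is measured at
#' the voltage midway between threshold and peak with sub-sample linear
#' interpolation.
#'
#' @name spike_waveform
NULL

DVDT_THRESHOLD <- 10    # V/s criterion for spike threshold
SMOOTH_WIN_S <- 100e-6  # boxcar width: 100 us (20 points at 200 kHz)

# centred boxcar moving average; even windows take one extra trailing point;
# edges shrink the window symmetrically
boxcar_smooth <- function(y, w) {
  n <- length(y)
  if (w <= 1L) return(y)
  if (n < w) stop("trace shorter than smoothing window")
  b <- (w - 1L) %/% 2L
  f <- w %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - b, 1L)
  hi <- pmin(i + f, n)
  # symmetric shrink at the edges
  k <- pmin(i - lo, hi - i)
  edge <- (i - lo) != (hi - i) & (lo == 1L | hi == n)
  lo[edge] <- i[edge] - k[edge]
  hi[edge] <- i[edge] + k[edge]
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

smoothing_window <- function(rate) max(1L, round(SMOOTH_WIN_S * rate))

#' Smoothed voltage derivative
#'
#' Applies the 100 us sliding boxcar, then a central-difference derivative.
#'
#' @param sweep a current-clamp [sweep_ts()].
#' @param warn_rate warn when the sampling rate is not the nominal 200 kHz
#'   (the window is rescaled to keep its 100 us duration).
#' @return list with `v_smooth` (mV) and `dvdt` (V/s), both aligned to
#'   `sweep$t`.
#' @export
smooth_derivative <- function(sweep, warn_rate = TRUE) {
  stopifnot(sweep$mode == "current_clamp")
  w <- smoothing_window(sweep$rate)
  if (warn_rate && abs(sweep$rate - 200e3) > 1)
    warning(sprintf("sampling rate %.3g kHz != 200 kHz; boxcar rescaled to %d points",
                    sweep$rate / 1000, w))
  vs <- boxcar_smooth(sweep$y, w)
  n <- length(vs)
  h <- 1 / sweep$rate
  d <- numeric(n)
  d[2:(n - 1)] <- (vs[3:n] - vs[1:(n - 2)]) / (2 * h)
  d[1] <- (vs[2] - vs[1]) / h
  d[n] <- (vs[n] - vs[n - 1]) / h
  list(v_smooth = vs, dvdt = d / 1000)  # mV/s -> V/s
}

# threshold index for the spike peaking at index `ipk`: scan backwards from
# the peak to the last sample whose smoothed dV/dt does not exceed the
# criterion, then take the next sample
threshold_index <- function(dvdt, ipk, criterion = DVDT_THRESHOLD) {
  if (ipk < 2L) return(NA_integer_)
  below <- which(dvdt[seq_len(ipk - 1L)] <= criterion)
  if (!length(below)) return(NA_integer_)
  j <- max(below)
  if (j + 1L > ipk) NA_integer_ else j + 1L
}

# linear-interpolated crossing time of level m between samples i and i+1
cross_time <- function(t, v, i, m) {
  t[i] + (m - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i])
}

# width at half height for the spike with peak at ipk and threshold at ithr
whh_interp <- function(t, v, ithr, ipk, v_thresh, v_max) {
  m <- (v_thresh + v_max) / 2
  up <- NULL
  for (i in seq(ipk - 1L, ithr)) {
    if (v[i] < m && v[i + 1L] >= m) { up <- i; break }
  }
  dn <- NULL
  for (i in seq(ipk, length(v) - 1L)) {
    if (v[i] >= m && v[i + 1L] < m) { dn <- i; break }
  }
  if (is.null(up) || is.null(dn)) return(NA_real_)
  1000 * (cross_time(t, v, dn, m) - cross_time(t, v, up, m))  # ms
}

# features of a single spike given its peak index and the derivative series
spike_features_at <- function(sweep, ipk, sd = NULL, criterion = DVDT_THRESHOLD) {
  if (is.null(sd)) sd <- smooth_derivative(sweep, warn_rate = FALSE)
  ithr <- threshold_index(sd$dvdt, ipk, criterion)
  if (is.na(ithr)) return(NULL)
  v_thresh <- sweep$y[ithr]
  v_max <- sweep$y[ipk]
  list(V_thresh = v_thresh, V_max = v_max,
       max_dvdt = max(sd$dvdt[ithr:ipk]),
       whh = whh_interp(sweep$t, sweep$y, ithr, ipk, v_thresh, v_max),
       threshold_time = 1000 * sweep$t[ithr],
       peak_time = 1000 * sweep$t[ipk],
       threshold_index = ithr, peak_index = ipk)
}

#' Action-potential waveform features
#'
#' Computes threshold (first exceedance of the 10 V/s smoothed rate of
#' rise, scanning back from the peak), peak voltage, maximum rate of rise,
#' and width at half height for the first spike in the sweep.
#'
#' @param sweep a current-clamp [sweep_ts()] containing at least one spike.
#' @param criterion rate-of-rise criterion in V/s (default 10).
#' @return list of class `px_ap_features`: `V_thresh` (mV), `V_max` (mV),
#'   `max_dvdt` (V/s), `whh` (ms), `threshold_time` and `peak_time` (ms).
#' @export
ap_features <- function(sweep, criterion = DVDT_THRESHOLD) {
  sp <- detect_spikes(sweep)
  if (!length(sp$times)) stop("no spike in sweep")
  sd <- smooth_derivative(sweep, warn_rate = FALSE)
  if (max(sd$dvdt) <= criterion)
    stop("rate of rise never exceeds the threshold criterion")
  f <- spike_features_at(sweep, sp$peak_index[1L], sd, criterion)
  if (is.null(f)) stop("no threshold crossing found before the peak")
  structure(f, class = "px_ap_features")
}

#' @export
print.px_ap_features <- function(x, ...) {
  cat(sprintf(
    "<px_ap_features> V_thresh %.2f mV, V_max %.2f mV, max dV/dt %.1f V/s, whh %.3f ms\n",
    x$V_thresh, x$V_max, x$max_dvdt, x$whh))
  invisible(x)
}

#' Find the first suprathreshold sweep of a 10 ms step ladder
#'
#' @param rec a `single_ap_10ms` [protocol_recording()] with strictly
#'   increasing step amplitudes.
#' @return index of the first sweep in which the voltage exceeds 0 mV inside
#'   the step window, or `NA` if none spikes.
#' @export
find_threshold_step <- function(rec) {
  stopifnot(inherits(rec, "px_recording"))
  amp <- sweep_amplitudes(rec)
  if (any(diff(amp) <= 0)) stop("step amplitudes must be strictly increasing")
  for (i in seq_along(rec$sweeps)) {
    s <- rec$sweeps[[i]]
    w <- stim_window(s)
    if (any(s$y[w[1]:w[2]] > 0)) return(i)
  }
  NA_integer_
}

#' Phase-plane representation of a sweep
#'
#' Returns time-ordered (V, dV/dt) pairs, and flags waveforms whose rising
#' phase carries a second local maximum of dV/dt below the global maximum --
#' the signature of a biphasic (axon-bearing) spike.
#'
#' @param sweep a current-clamp [sweep_ts()].
#' @return list with `v` (mV), `dvdt` (V/s) and `biphasic` (logical flag,
#'   `NA` when no spike is present).
#' @export
phase_plane <- function(sweep) {
  sd <- smooth_derivative(sweep, warn_rate = FALSE)
  sp <- detect_spikes(sweep)
  biphasic <- NA
  if (length(sp$times)) {
    ipk <- sp$peak_index[1L]
    ithr <- threshold_index(sd$dvdt, ipk)
    if (!is.na(ithr) && ipk - ithr >= 2L) {
      d <- sd$dvdt[ithr:ipk]
      # count rise-then-fall transitions of the derivative (plateaus merged):
      # a monophasic rising phase has one, a second component adds another
      s <- sign(round(diff(d), 6))
      s <- s[s != 0]
      n_peaks <- if (length(s) < 2L) 1L else
        sum(s[-length(s)] == 1 & s[-1] == -1) + as.integer(s[length(s)] == 1)
      biphasic <- n_peaks >= 2L
    }
  }
  list(v = sweep$y, dvdt = sd$dvdt, biphasic = biphasic)
}
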