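test_that("smoothed derivative preserves ramps and kills constants", {
  rate <- 2e5
  t <- (0:4000) / rate
  ramp <- sweep_ts(t, t * 1e3, rate, "current_clamp")  # 1 mV/ms
  d <- smooth_derivative(ramp)$dvdt
  interior <- 30:3970
  expect_equal(d[interior], rep(1, length(interior)), tolerance = 1e-9)
  flat <- sweep_ts(t, rep(-60, length(t)), rate, "current_clamp")
  expect_equal(max(abs(smooth_derivative(flat)$dvdt)), 0)
  short <- sweep_ts(t[1:5], rep(0, 5), rate, "current_clamp")
  expect_error(smooth_derivative(short), "window")
  expect_warning(smooth_derivative(cc_sweep(rep(0, 100), rate = 5e4)),
                 "rescaled")
})

test_that("boxcar smoothing and differencing commute (linear operators)", {
  set.seed(4)
  v <- cumsum(rnorm(2000))
  w <- 20L
  h <- 1 / 2e5
  diff_c <- function(x) (c(x[-1], x[length(x)]) - c(x[1], x[-length(x)])) / (2 * h)
  a <- diff_c(patchfx:::boxcar_smooth(v, w))
  b <- patchfx:::boxcar_smooth(diff_c(v), w)
  interior <- (w + 2):(length(v) - w - 2)
  expect_equal(a[interior], b[interior], tolerance = 1e-9)
})

test_that("half-height width follows similar-triangles arithmetic", {
  # triangular spike: threshold -34 mV at t = 0, peak 36 mV at 0.2 ms,
  # back to -34 mV at 0.5 ms; midpoint 1 mV -> whh = 0.25 ms
  rate <- 2e5; h <- 1 / rate
  up <- seq(-34, 36, length.out = 41)          # 0.2 ms rise
  down <- seq(36, -34, length.out = 61)[-1]    # 0.3 ms fall
  v <- c(rep(-34, 20), up, down, rep(-34, 20))
  t <- (seq_along(v) - 1) * h
  ithr <- 21L; ipk <- 21L + 40L
  expect_equal(patchfx:::whh_interp(t, v, ithr, ipk, -34, 36), 0.25,
               tolerance = 1e-9)
})

test_that("waveform features recover the generator ledger exactly", {
  p <- quiet_cell()
  sa <- simulate_single_ap(p)
  k <- find_threshold_step(sa$recording)
  expect_identical(k, sa$threshold_sweep)
  f <- ap_features(sa$recording$sweeps[[k]])
  lg <- sa$ledgers[[k]]
  expect_equal(f$V_thresh, lg$V_thresh, tolerance = 1e-12)
  expect_equal(f$V_max, lg$peaks[1], tolerance = 1e-12)
  expect_equal(f$whh, lg$whh[1], tolerance = 1e-10)
  # boxcar-smoothed maximum slope equals the analytic rise slope
  expect_equal(f$max_dvdt, lg$max_dvdt, tolerance = 0.02)
  expect_error(ap_features(cc_sweep(rep(-60, 4000), rate = 2e5)), "no spike")
})

test_that("whh is invariant to voltage offset and time shift", {
  p <- quiet_cell()
  sa <- simulate_single_ap(p)
  sw <- sa$recording$sweeps[[find_threshold_step(sa$recording)]]
  f0 <- ap_features(sw)
  shifted <- sw; shifted$t <- sw$t + 0.5
  expect_equal(ap_features(shifted)$whh, f0$whh, tolerance = 1e-12)
  # a uniform offset moves threshold and peak together, leaving whh fixed
  offset <- sw; offset$y <- sw$y + 7
  f1 <- ap_features(offset)
  expect_equal(f1$whh, f0$whh, tolerance = 1e-10)
  expect_equal(f1$V_thresh, f0$V_thresh + 7, tolerance = 1e-10)
})

test_that("threshold voltage is monotone in the rate-of-rise criterion", {
  p <- quiet_cell()
  sa <- simulate_single_ap(p)
  sw <- sa$recording$sweeps[[find_threshold_step(sa$recording)]]
  vts <- vapply(c(2, 5, 10, 50, 150), function(cr)
    ap_features(sw, criterion = cr)$V_thresh, 0)
  expect_true(all(diff(vts) >= -1e-12))
})

test_that("threshold-step search applies the V > 0 inside-the-step rule", {
  p <- quiet_cell()
  sa <- simulate_single_ap(p)
  expect_identical(find_threshold_step(sa$recording), sa$threshold_sweep)
  # all-subthreshold ladder: no sweep qualifies
  mk <- function(amp) {
    st <- step_stimulus(0.001, 0.010, amp)
    cc_sweep(rep(-60, 4000), rate = 2e5, stim = st)
  }
  sub <- protocol_recording("single_ap_10ms", lapply(c(10, 20, 30), mk))
  expect_true(is.na(find_threshold_step(sub)))
  # spike crossing 0 mV only after the step end does not satisfy the rule
  late <- mk(40)
  late$y[2600:2700] <- 30  # step ends at sample 2201
  rec <- protocol_recording("single_ap_10ms", list(mk(10), late))
  expect_true(is.na(find_threshold_step(rec)))
  # non-monotone amplitudes are rejected
  expect_error(find_threshold_step(
    protocol_recording("single_ap_10ms", list(mk(20), mk(10)))),
    "increasing")
})

test_that("phase plane flags a two-component rising phase only", {
  p <- quiet_cell()
  sa <- simulate_single_ap(p)
  sw <- sa$recording$sweeps[[find_threshold_step(sa$recording)]]
  expect_false(phase_plane(sw)$biphasic)
  # hand-built two-component rise: fast, shoulder, fast again (the phase
  # plane then shows two rising-phase dV/dt maxima)
  h_mv <- function(slope_vs, n) rep(slope_vs * 5e-3, n)   # mV per 5 us sample
  dv <- c(rep(0, 500), h_mv(300, 30), h_mv(20, 30), h_mv(400, 30),
          h_mv(-100, 216), rep(0, 500))
  v2 <- -60 + cumsum(dv)
  sw2 <- cc_sweep(v2, rate = 2e5)
  expect_true(phase_plane(sw2)$biphasic)
  # no spike: flag undefined
  expect_true(is.na(phase_plane(cc_sweep(rep(-60, 4000), rate = 2e5))$biphasic))
})
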