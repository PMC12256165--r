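test_that("spike detection returns one spike per suprazero region", {
  v <- rep(-60, 5e3)
  v[1000:1020] <- c(seq(-60, 35, length.out = 11), seq(28, -60, length.out = 10))
  v[1500:1520] <- c(seq(-60, 30, length.out = 11), seq(25, -60, length.out = 10))
  sw <- cc_sweep(v, rate = 1e4)
  sp <- detect_spikes(sw)
  expect_equal(sp$times, c(100.9, 150.9))
  expect_equal(sp$peaks, c(35, 30))
  expect_length(detect_spikes(cc_sweep(rep(-60, 100), rate = 1e4))$times, 0)
})

test_that("train statistics evaluate the adaptation formulas exactly", {
  s <- train_statistics(c(100, 110, 130, 160))
  expect_equal(s$IF, 100)
  expect_equal(s$CV, 0.5)                       # sd(10,20,30)/20
  expect_equal(s$SFA, (100 - 100 / 3) / 100 * 100, tolerance = 1e-12)
  expect_equal(train_statistics(c(0, 10), c(40, 30))$SAA, 25)
  # homogeneous train: all adaptation measures vanish
  h <- train_statistics(seq(0, 90, by = 10), rep(40, 10), rep(0.36, 10))
  expect_equal(h$CV, 0); expect_equal(h$SFA, 0)
  expect_equal(h$SAA, 0); expect_equal(h$SWA, 0)
  # too few spikes: per-metric NA
  two <- train_statistics(c(0, 10), c(40, 39), c(0.3, 0.3))
  expect_true(is.na(two$CV) && is.na(two$SFA))
  expect_false(is.na(two$IF) || is.na(two$SAA))
  expect_error(train_statistics(c(10, 5)), "increasing")
})

test_that("adaptation measures are scale-free and CV is time-rescale invariant", {
  t0 <- c(100, 112, 135, 170, 220)
  pk <- c(40, 38, 37, 36.5, 36.2)
  wh <- c(0.36, 0.34, 0.33, 0.32, 0.31)
  a <- train_statistics(t0, pk, wh)
  b <- train_statistics(t0[1] + (t0 - t0[1]) * 3, pk * 2, wh * 5)
  expect_equal(a$CV, b$CV, tolerance = 1e-12)
  expect_equal(a$SFA, b$SFA, tolerance = 1e-12)
  expect_equal(a$SAA, b$SAA, tolerance = 1e-12)
  expect_equal(a$SWA, b$SWA, tolerance = 1e-12)
})

test_that("rheobase, latency and fAHP come off the first suprathreshold sweep", {
  p <- quiet_cell()
  tr <- simulate_trains(p)
  r <- rheobase_latency_fahp(tr$recording)
  k <- which(vapply(tr$ledgers, function(l) length(l$times) > 0, TRUE))[1]
  expect_equal(r$rheobase, tr$amplitudes[k])
  lg <- tr$ledgers[[k]]
  on_ms <- 1000 * tr$recording$sweeps[[k]]$stim$onset
  expect_equal(r$latency, lg$times[1] - on_ms, tolerance = 1e-9)
  expect_equal(r$fAHP, lg$fAHP, tolerance = 1e-9)
  # with the default geometry the trough sits fahp_depth below threshold
  expect_equal(r$fAHP, p$fahp_depth, tolerance = 1e-9)
})

test_that("train extraction equals the generator ledger to 1e-10", {
  p <- quiet_cell()
  tr <- simulate_trains(p)
  for (k in seq_along(tr$ledgers)) {
    lg <- tr$ledgers[[k]]
    if (lg$blocked || length(lg$times) < 3) next
    ex <- patchfx:::analyse_sweep(tr$recording$sweeps[[k]])
    expect_equal(ex$spike_times, lg$times, tolerance = 1e-12)
    expect_equal(ex$spike_peaks, lg$peaks, tolerance = 1e-12)
    expect_equal(ex$whh, lg$whh, tolerance = 1e-10)
    ref <- train_statistics(lg$times, lg$peaks, lg$whh)
    for (m in c("IF", "CV", "SFA", "SAA", "SWA"))
      expect_equal(ex[[m]], ref[[m]], tolerance = 1e-10)
  }
})

test_that("input-output fit covers sweeps up to 80% of the maximum count", {
  ps <- data.frame(current = seq(20, 70, by = 10),
                   n_spikes = c(0, 1, 2, 3, 4, 10),
                   IF = c(NA, NA, 30, 45, 60, 150),
                   SAA = c(NA, NA, 4, 6, 8, 30))
  io <- io_fit(ps)
  expect_identical(io$max_spike_no, 10)
  # fit range ends at the first count >= 8: the final sweep, so the fit
  # includes the IF jump to 150
  fit_rng <- ps[2:6, ]
  ref <- unname(coef(lm(IF ~ current, fit_rng))[2])
  expect_equal(io$IF_slope, ref, tolerance = 1e-12)
  # exact line over the fit range returns its slope
  ps2 <- data.frame(current = seq(30, 80, by = 10),
                    n_spikes = c(1, 2, 4, 6, 8, 10),
                    IF = 1.5 * seq(30, 80, by = 10) - 20,
                    SAA = 0.8 * seq(30, 80, by = 10))
  io2 <- io_fit(ps2)
  expect_equal(io2$IF_slope, 1.5, tolerance = 1e-12)
  expect_equal(io2$SAA_slope, 0.8, tolerance = 1e-12)
  # one spike everywhere: no ISI, slopes undefined
  ps3 <- data.frame(current = c(30, 40, 50), n_spikes = 1, IF = NA_real_,
                    SAA = NA_real_)
  expect_true(is.na(io_fit(ps3)$IF_slope))
})

test_that("the 1.5x rheobase sweep is the nearest, ties upward", {
  ps <- data.frame(current = c(50, 60, 70), n_spikes = c(3, 5, 7),
                   CV = c(0.2, 0.3, 0.4), SFA = c(10, 20, 30),
                   SWA = c(1, 2, 3))
  expect_equal(at_1p5_rheobase(ps, 40)$current_used, 60)
  ps2 <- ps[ps$current != 50, ]
  expect_equal(at_1p5_rheobase(ps2, 44)$current_used, 70)  # 66 is nearer 70
  # exact tie between 60 and 80 at target 70: higher current wins
  ps3 <- data.frame(current = c(60, 80), n_spikes = c(3, 5),
                    CV = c(0.2, 0.4), SFA = c(10, 30), SWA = c(1, 3))
  expect_equal(at_1p5_rheobase(ps3, 140 / 3)$current_used, 80)
  expect_true(is.na(at_1p5_rheobase(ps, NA_real_)$CV))
  expect_warning(out <- at_1p5_rheobase(ps, 200), "50%")
  expect_true(is.na(out$CV))
})

test_that("mAHP averages only complete sweeps and reads the kernel trough", {
  p <- quiet_cell()
  ma <- simulate_mahp_protocol(p)
  m <- mahp_amplitude(ma$recording)
  expect_identical(m$n_valid, 10L)
  expect_equal(m$mAHP, ma$mahp_true, tolerance = 1e-3)
  # sweeps with 9 spikes are dropped from the average
  ma2 <- simulate_mahp_protocol(p, fail_sweeps = c(2, 5, 7))
  m2 <- mahp_amplitude(ma2$recording)
  expect_identical(m2$n_valid, 7L)
  expect_equal(m2$mAHP, ma$mahp_true, tolerance = 1e-3)
  # no AHP conductance: flat return to holding
  ma0 <- simulate_mahp_protocol(quiet_cell(ahp_conductance = 0))
  expect_equal(mahp_amplitude(ma0$recording)$mAHP, 0, tolerance = 1e-9)
  # no valid sweep at all
  ma3 <- simulate_mahp_protocol(p, fail_sweeps = 1:10)
  expect_true(is.na(mahp_amplitude(ma3$recording)$mAHP))
})

test_that("mAHP is invariant to sweep order and linear in the injected amplitude", {
  p <- quiet_cell()
  ma <- simulate_mahp_protocol(p)
  rec <- ma$recording
  rec$sweeps <- rev(rec$sweeps)
  expect_equal(mahp_amplitude(rec)$mAHP, mahp_amplitude(ma$recording)$mAHP)
  amps <- c(1, 2, 4)
  est <- vapply(amps, function(a) {
    m <- simulate_mahp_protocol(quiet_cell(ahp_conductance = a))
    mahp_amplitude(m$recording)$mAHP
  }, 0)
  expect_equal(est, amps, tolerance = 1e-3)
})

test_that("sag index evaluates the formula and interpolates at -100 mV", {
  s <- sag_index(protocol_recording("sag_steps", list(
    sag_step_sweep(-60, -100, -110, -50))))
  expect_equal(s$per_step$sag_index, 0.8, tolerance = 1e-12)
  expect_equal(s$sag_index_at_m100, 0.8, tolerance = 1e-12)
  # steps with (V_ss, index) = (-95, 0.95) and (-105, 0.91) -> 0.93
  sw1 <- sag_step_sweep(-60, -95, -60 - 35 / 0.95, -40)
  sw2 <- sag_step_sweep(-60, -105, -60 - 45 / 0.91, -60)
  s2 <- sag_index(protocol_recording("sag_steps", list(sw1, sw2)))
  expect_equal(s2$sag_index_at_m100, 0.93, tolerance = 1e-9)
  expect_identical(s2$flag, "ok")
  # no sag channel: V_sag equals V_ss, index 1
  s3 <- sag_index(protocol_recording("sag_steps", list(
    sag_step_sweep(-60, -101, -101, -50))))
  expect_equal(s3$per_step$sag_index, 1)
  # no bracketing pair and nothing within 2 mV: undefined
  s4 <- sag_index(protocol_recording("sag_steps", list(
    sag_step_sweep(-60, -80, -85, -20))))
  expect_identical(s4$flag, "no_bracket")
  expect_true(is.na(s4$sag_index_at_m100))
})

test_that("simulated sag ladders recover the ground-truth index", {
  for (g in c(0, 1, 2)) {
    p <- quiet_cell(sag_conductance = g)
    sg <- simulate_sag_protocol(p)
    s <- sag_index(sg$recording)
    expect_equal(s$sag_index_at_m100, sg$sag_true, tolerance = 0.01)
  }
  # monotone: more sag conductance, lower index
  est <- vapply(c(0, 0.5, 1, 2), function(g) {
    sag_index(simulate_sag_protocol(quiet_cell(sag_conductance = g))$recording)$sag_index_at_m100
  }, 0)
  expect_true(all(diff(est) < 0))
})

test_that("spontaneous activity is any spike at I = 0", {
  expect_false(spontaneous_activity(cc_sweep(rep(-60, 1e3), rate = 1e3)))
  v <- rep(-60, 1e3); v[500] <- 25
  expect_true(spontaneous_activity(cc_sweep(v, rate = 1e3)))
  p <- quiet_cell(pacemaker_drive = 35)
  expect_true(spontaneous_activity(simulate_izero(p, rate = 5e3)$sweep))
  expect_false(spontaneous_activity(simulate_izero(quiet_cell(), rate = 5e3)$sweep))
})
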