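# shared fixtures: small, quiet synthetic cells built in code

quiet_cell <- function(...) {
  args <- list(...)
  if (!"noise_sd" %in% names(args)) args$noise_sd <- 0
  do.call(synth_cell_params, args)
}

# a current-clamp sweep holding a hand-built voltage trace on a uniform grid
cc_sweep <- function(v, rate = 5e4, stim = NULL, holding = NA_real_) {
  t <- (seq_along(v) - 1) / rate
  sweep_ts(t, v, rate, "current_clamp", stim, holding)
}

# craft a sag step sweep with a known minimum and steady-state plateau:
# baseline, then the step dips to v_sag and settles at v_ss
sag_step_sweep <- function(v_hold, v_ss, v_sag, current, rate = 1e4,
                           pre_ms = 50, step_ms = 500, post_ms = 50) {
  h <- 1000 / rate
  n_pre <- round(pre_ms / h); n_dur <- round(step_ms / h)
  n_post <- round(post_ms / h)
  dip <- round(n_dur / 4)
  # one extra v_ss sample: the grid point at onset + duration is in-step
  step <- c(rep(v_sag, dip), rep(v_ss, n_dur - dip + 1))
  v <- c(rep(v_hold, n_pre), step, rep(v_hold, n_post - 1))
  st <- step_stimulus(n_pre * h / 1000, n_dur * h / 1000, current)
  cc_sweep(v, rate, st, holding = v_hold)
}
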