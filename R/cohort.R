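#' Synthetic cohort assembly
#'
#' Builds cohorts with the maturation-by-occlusion group structure the
#' statistics module expects: three maturation groups (5 wpi and 9 wpi
#' adult-born cells, plus resident cells) crossed with sham / occluded
#' treatment, with per-group parameter distributions, per-group
#' spontaneous-firing fractions, and treatment effect shifts.
#'
#' @name cohort
NULL

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study conditions of the source design: group means
#' around 870 MOhm input resistance, 20.5 pF capacitance, -34.5 mV
#' threshold, ~0.36 ms spike width, sag index 0.92, mAHP amplitudes
#' declining with maturation (2.35, 1.92, 1.29 mV), spontaneous fractions
#' (0.13, 0.47, 0.40), and a positive spike-amplitude shift under
#' occlusion.
#'
#' @param n cells per group per treatment (named by group, or a scalar).
#' @param treatments which treatments to generate.
#' @param spont_fraction per-group probability of spontaneous pacemaking.
#' @param mahp_mean per-group mean mAHP amplitude (mV).
#' @param mahp_sd between-cell SD of mAHP amplitude (mV).
#' @param vmax_occlusion_shift spike-peak increase under occlusion (mV).
#' @param rs_range uniform range of series resistance (MOhm).
#' @param noise_sd voltage noise SD (mV).
#' @param seed master seed; the whole cohort is a deterministic function
#'   of the spec and this seed.
#' @return list of class `px_cohort_spec`.
#' @export
cohort_spec <- function(n = c(wpi5 = 8, wpi9 = 8, resident = 8),
                        treatments = c("sham", "occluded"),
                        spont_fraction = c(wpi5 = 0.13, wpi9 = 0.47,
                                           resident = 0.40),
                        mahp_mean = c(wpi5 = 2.35, wpi9 = 1.92,
                                      resident = 1.29),
                        mahp_sd = 0.5,
                        vmax_occlusion_shift = 4,
                        rs_range = c(5, 12),
                        noise_sd = 0.1,
                        seed = 1L) {
  if (length(n) == 1L) n <- stats::setNames(rep(n, 3), GROUPS)
  stopifnot(all(names(n) %in% GROUPS), all(n >= 0),
            all(treatments %in% TREATMENTS),
            all(spont_fraction >= 0 & spont_fraction <= 1))
  structure(list(n = n, treatments = treatments,
                 spont_fraction = spont_fraction, mahp_mean = mahp_mean,
                 mahp_sd = mahp_sd,
                 vmax_occlusion_shift = vmax_occlusion_shift,
                 rs_range = rs_range, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "px_cohort_spec")
}

rnorm_clamped <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

# draw the ground-truth parameters of one cell (uses the current RNG stream)
draw_cell_params <- function(spec, group, treatment) {
  ri <- rnorm_clamped(1, 870, 220, 350, 1800)
  cm <- rnorm_clamped(1, 20.5, 3.5, 10, 35)
  rs <- stats::runif(1, spec$rs_range[1], spec$rs_range[2])
  el <- rnorm_clamped(1, -60.5, 1.5, -65, -57)
  th <- rnorm_clamped(1, -34.5, 1.5, -39, -30)
  pk <- rnorm_clamped(1, 36.3, 3, 28, 46) +
    if (treatment == "occluded") spec$vmax_occlusion_shift else 0
  spont <- stats::runif(1) < spec$spont_fraction[[group]]
  drive <- if (spont) (th + stats::runif(1, 2, 8) - el) / (ri * 1e-3) else 0
  mahp <- max(stats::rnorm(1, spec$mahp_mean[[group]], spec$mahp_sd), 0.05)
  s0 <- rnorm_clamped(1, 0.92, 0.02, 0.82, 0.985)
  synth_cell_params(
    R_i_true = ri, C_m_true = cm, R_s_true = rs, E_L = el,
    spike_threshold_true = th, spike_peak = pk,
    rise_ms = rnorm_clamped(1, 0.16, 0.02, 0.10, 0.24),
    fall_ms = rnorm_clamped(1, 0.76, 0.08, 0.5, 1.1),
    fahp_depth = rnorm_clamped(1, 25, 2, 18, 32),
    adaptation_increment = rnorm_clamped(1, 30, 5, 18, 42),
    amp_decrement = stats::runif(1, 0.4, 1.2),
    width_decrement = stats::runif(1, 0.01, 0.05),
    ahp_conductance = mahp / MAHP_MV_PER_NS,
    sag_conductance = (1 - s0) / SAG_INDEX_PER_NS,
    pacemaker_drive = drive,
    block_current = rnorm_clamped(1, 150, 25, 110, 230),
    noise_sd = spec$noise_sd)
}

#' Simulate the full protocol set for one cell
#'
#' @param p a [synth_cell_params()].
#' @param cell_id,group,treatment metadata attached to each recording.
#' @param protocols which protocols to generate.
#' @return list of class `px_cell_bundle` with `recordings` (named list of
#'   [protocol_recording()]) and `truth` (one-row data frame of
#'   ground-truth features).
#' @export
simulate_cell <- function(p, cell_id = "cell", group = NA_character_,
                          treatment = NA_character_,
                          protocols = PROTOCOL_KINDS) {
  recs <- list(); led <- list()
  if ("membrane_test" %in% protocols)
    recs$membrane_test <- simulate_membrane_test(p)
  if ("single_ap_10ms" %in% protocols) {
    sa <- simulate_single_ap(p)
    recs$single_ap_10ms <- sa$recording
    led$single_ap <- sa
  }
  if ("trains_500ms" %in% protocols) {
    tr <- simulate_trains(p)
    recs$trains_500ms <- tr$recording
    led$trains <- tr
  }
  if ("mahp_train" %in% protocols) {
    ma <- simulate_mahp_protocol(p)
    recs$mahp_train <- ma$recording
    led$mahp <- ma
  }
  if ("sag_steps" %in% protocols) {
    sg <- simulate_sag_protocol(p)
    recs$sag_steps <- sg$recording
    led$sag <- sg
  }
  if ("spontaneous_izero" %in% protocols) {
    iz <- simulate_izero(p)
    recs$spontaneous_izero <- protocol_recording("spontaneous_izero",
                                                 list(iz$sweep))
    led$izero <- iz
  }
  for (k in names(recs)) {
    recs[[k]]$cell_id <- cell_id; recs[[k]]$group <- group
    recs[[k]]$treatment <- treatment
  }
  truth <- cell_truth_row(p, led, cell_id, group, treatment)
  structure(list(cell_id = cell_id, group = group, treatment = treatment,
                 params = p, recordings = recs, ledgers = led, truth = truth),
            class = "px_cell_bundle")
}

# assemble the ground-truth feature row from the generator ledgers
cell_truth_row <- function(p, led, cell_id, group, treatment) {
  ap <- list(V_thresh = NA_real_, V_max = NA_real_, max_dvdt = NA_real_,
             whh = NA_real_)
  if (!is.null(led$single_ap) && !is.na(led$single_ap$threshold_sweep)) {
    lg <- led$single_ap$ledgers[[led$single_ap$threshold_sweep]]
    ap <- list(V_thresh = lg$V_thresh, V_max = lg$peaks[1],
               max_dvdt = lg$max_dvdt, whh = lg$whh[1])
  }
  rheo <- lat <- fahp <- NA_real_
  if (!is.null(led$trains)) {
    for (k in seq_along(led$trains$ledgers)) {
      lg <- led$trains$ledgers[[k]]
      if (!lg$blocked && length(lg$times)) {
        rheo <- led$trains$amplitudes[k]
        on_ms <- 1000 * led$trains$recording$sweeps[[k]]$stim$onset
        lat <- lg$times[1] - on_ms
        fahp <- lg$fAHP
        break
      }
    }
  }
  data.frame(cell_id = cell_id, group = group, treatment = treatment,
             R_i_true = p$R_i_true, C_m_true = p$C_m_true,
             R_s_true = p$R_s_true, E_L = p$E_L,
             V_thresh_true = ap$V_thresh, V_max_true = ap$V_max,
             max_dvdt_true = ap$max_dvdt, whh_true = ap$whh,
             rheobase_true = rheo, latency_true = lat, fAHP_true = fahp,
             mahp_true = if (!is.null(led$mahp)) led$mahp$mahp_true else NA_real_,
             sag_true = if (!is.null(led$sag)) led$sag$sag_true else NA_real_,
             spontaneous_true = if (!is.null(led$izero))
               led$izero$spontaneous_true else NA,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Deterministic under `(spec, spec$seed)`: the same spec always yields the
#' same cohort, and distinct seeds yield distinct cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param protocols protocols to generate per cell.
#' @param callback optional function called as `callback(bundle)` after
#'   each cell; when it returns anything non-`NULL` the bundle's traces are
#'   dropped from the cohort (streaming mode for large cohorts).
#' @return list of class `px_cohort` with `cells` (list of
#'   [simulate_cell()] bundles), `ground_truth` (one row per cell) and the
#'   `spec`.
#' @export
generate_cohort <- function(spec, protocols = PROTOCOL_KINDS, callback = NULL) {
  stopifnot(inherits(spec, "px_cohort_spec"))
  set.seed(spec$seed)
  cells <- list(); truth <- NULL
  for (g in names(spec$n)) {
    for (tr in spec$treatments) {
      ng <- spec$n[[g]]
      if (ng < 1) next
      for (i in seq_len(ng)) {
        id <- sprintf("%s_%s_%02d", g, tr, i)
        p <- draw_cell_params(spec, g, tr)
        b <- simulate_cell(p, id, g, tr, protocols)
        truth <- rbind(truth, b$truth)
        if (!is.null(callback)) {
          res <- callback(b)
          if (!is.null(res)) { cells[[id]] <- NULL; next }
        }
        cells[[id]] <- b
      }
    }
  }
  structure(list(cells = cells, ground_truth = truth, spec = spec),
            class = "px_cohort")
}

#' @export
print.px_cohort <- function(x, ...) {
  cat(sprintf("<px_cohort> %d cell(s)\n", nrow(x$ground_truth)))
  if (nrow(x$ground_truth))
    print(table(x$ground_truth$group, x$ground_truth$treatment))
  invisible(x)
}
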