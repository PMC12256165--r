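#' Per-cell feature extraction
#'
#' Runs every analysis module over the protocol recordings of one cell and
#' assembles the per-cell feature record (one row of the cohort feature
#' table).  Missing protocols yield `NA` for the affected features only;
#' the cell is not dropped.
#'
#' @param recordings named list of [protocol_recording()] objects (names
#'   from the protocol kinds), or a [simulate_cell()] bundle.
#' @param qc a [qc_rule()] applied to the pooled series-resistance
#'   measurements of the membrane test.
#' @return one-row data frame of class `px_features`.
#' @export
extract_cell_features <- function(recordings, qc = qc_rule()) {
  if (inherits(recordings, "px_cell_bundle")) {
    meta <- recordings[c("cell_id", "group", "treatment")]
    recordings <- recordings$recordings
  } else {
    r1 <- recordings[[1]]
    meta <- list(cell_id = r1$cell_id, group = r1$group,
                 treatment = r1$treatment)
  }
  out <- data.frame(cell_id = meta$cell_id, group = meta$group,
                    treatment = meta$treatment, qc_pass = NA,
                    R_s = NA_real_, R_i = NA_real_, C_m = NA_real_,
                    V_rest = NA_real_,
                    V_thresh = NA_real_, V_max = NA_real_,
                    max_dvdt = NA_real_, whh = NA_real_,
                    rheobase = NA_real_, latency = NA_real_, fAHP = NA_real_,
                    max_spike_no = NA_real_, IF_slope = NA_real_,
                    SAA_slope = NA_real_, ISI_CV = NA_real_, SFA = NA_real_,
                    SWA = NA_real_, mAHP = NA_real_, sag_index = NA_real_,
                    spontaneous = NA, stringsAsFactors = FALSE)

  mt <- recordings$membrane_test
  if (!is.null(mt)) {
    pp <- tryCatch(membrane_test_properties(mt), error = function(e) NULL)
    if (!is.null(pp)) {
      out$R_s <- pp$R_s; out$R_i <- pp$R_i; out$C_m <- pp$C_m
      out$qc_pass <- qc_series_resistance(pp$R_s_all, qc)
    }
  }
  iz <- recordings$spontaneous_izero
  if (!is.null(iz) && length(iz$sweeps)) {
    rp <- tryCatch(resting_potential(iz$sweeps[[1]]), error = function(e) NULL)
    if (!is.null(rp)) out$V_rest <- rp$V_rest
    out$spontaneous <- spontaneous_activity(iz$sweeps[[1]])
  }
  sa <- recordings$single_ap_10ms
  if (!is.null(sa)) {
    k <- tryCatch(find_threshold_step(sa), error = function(e) NA_integer_)
    if (!is.na(k)) {
      f <- tryCatch(ap_features(sa$sweeps[[k]]), error = function(e) NULL)
      if (!is.null(f)) {
        out$V_thresh <- f$V_thresh; out$V_max <- f$V_max
        out$max_dvdt <- f$max_dvdt; out$whh <- f$whh
      }
    }
  }
  tr <- recordings$trains_500ms
  if (!is.null(tr) && length(tr$sweeps)) {
    ta <- analyse_trains(tr)
    out$rheobase <- ta$rheobase; out$latency <- ta$latency
    out$fAHP <- ta$fAHP; out$max_spike_no <- ta$max_spike_no
    out$IF_slope <- ta$IF_slope; out$SAA_slope <- ta$SAA_slope
    out$ISI_CV <- ta$CV; out$SFA <- ta$SFA; out$SWA <- ta$SWA
  }
  ma <- recordings$mahp_train
  if (!is.null(ma)) out$mAHP <- mahp_amplitude(ma)$mAHP
  sg <- recordings$sag_steps
  if (!is.null(sg) && length(sg$sweeps))
    out$sag_index <- sag_index(sg)$sag_index_at_m100
  class(out) <- c("px_features", "data.frame")
  out
}

#' @export
print.px_features <- function(x, ...) {
  cat(sprintf("<px_features> %d cell(s)\n", nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Extract the feature table of a whole cohort
#'
#' @param cohort a `px_cohort` from [generate_cohort()], or a list of
#'   recording bundles.
#' @param qc a [qc_rule()].
#' @return data frame of class `px_features`, one row per cell.
#' @export
extract_cohort_features <- function(cohort, qc = qc_rule()) {
  cells <- if (inherits(cohort, "px_cohort")) cohort$cells else cohort
  rows <- lapply(cells, extract_cell_features, qc = qc)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("px_features", "data.frame")
  out
}
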