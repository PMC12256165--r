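#' Series-resistance quality-control rule
#'
#' Recordings are excluded when the pipette series resistance exceeds an
#' absolute ceiling at any point, or drifts by more than a fractional amount
#' relative to the first measurement of the recording.
#'
#' @param rs_max maximum acceptable series resistance (MOhm).
#' @param rs_change_max maximum acceptable fractional change relative to the
#'   first measurement.
#' @return An object of class `px_qc_rule`.
#' @export
qc_rule <- function(rs_max = 30, rs_change_max = 0.20) {
  stopifnot(rs_max > 0, rs_change_max > 0)
  structure(list(rs_max = rs_max, rs_change_max = rs_change_max),
            class = "px_qc_rule")
}

#' Apply the series-resistance QC rule
#'
#' @param rs_values series-resistance measurements (MOhm) pooled over the
#'   whole recording, in chronological order.
#' @param rule a [qc_rule()].
#' @return `TRUE` if the cell passes, `FALSE` otherwise.
#' @examples
#' qc_series_resistance(c(28, 29))        # TRUE
#' qc_series_resistance(c(20, 25))        # FALSE: 25% drift
#' @export
qc_series_resistance <- function(rs_values, rule = qc_rule()) {
  if (length(rs_values) < 1L) stop("need at least one Rs measurement")
  stopifnot(all(is.finite(rs_values)), all(rs_values > 0))
  if (any(rs_values > rule$rs_max)) return(FALSE)
  change <- (max(rs_values) - min(rs_values)) / rs_values[1]
  change <= rule$rs_change_max
}
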