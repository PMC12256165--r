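#' Relative qPCR quantification
#'
#' Amplification efficiency from a serial-dilution standard curve,
#' \eqn{E = 10^{-1/slope} - 1}, and relative expression by the
#' \eqn{2^{-\Delta\Delta Ct}} method: target Ct normalised to a
#' housekeeping gene per sample, then to the mean of the control condition.
#'
#' @name qpcr
NULL

#' Amplification efficiency from a standard curve
#'
#' Regresses Ct on log10(dilution factor) and converts the slope to an
#' efficiency: \eqn{E = 10^{-1/slope} - 1} (a perfect doubling per cycle
#' has slope -3.3219 and E = 1).
#'
#' @param dilutions serial dilution factors (e.g. 1, 10, 100, ...).
#' @param cts observed Ct values, one per dilution point.
#' @return list with `slope`, `intercept`, `E` and `r_squared`.
#' @export
efficiency_from_curve <- function(dilutions, cts) {
  stopifnot(length(dilutions) == length(cts))
  if (length(cts) < 3L) stop("need at least 3 dilution points")
  if (any(dilutions <= 0)) stop("dilution factors must be positive")
  fit <- stats::lm(cts ~ log10(dilutions))
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) warning("non-negative standard-curve slope")
  tss <- sum((cts - mean(cts))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
       E = 10^(-1 / slope) - 1, r_squared = r2)
}

#' Convert a standard-curve slope to an efficiency
#'
#' @param slope slope of Ct vs log10(dilution).
#' @return efficiency E.
#' @export
efficiency_from_slope <- function(slope) 10^(-1 / slope) - 1

#' Fold changes by the 2^(-ddCt) method
#'
#' Technical replicates are averaged on the Ct scale per sample and gene;
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} per sample;
#' \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}};
#' fold change \eqn{= 2^{-\Delta\Delta Ct}}.  An efficiency-corrected
#' variant \eqn{(1+E_{target})^{-\Delta Ct...}} is available but off by
#' default, matching the classic assumption E = 1.
#'
#' @param data data frame with columns `sample`, `condition`, `gene`, `ct`
#'   (one row per technical replicate; replicates optional).
#' @param target,reference gene names of the target and housekeeping gene.
#' @param control control condition name; its mean dCt defines the
#'   normalisation baseline.
#' @param normalise `"dct_mean"` (default: ddCt relative to mean control
#'   dCt) or `"fold_mean"` (folds computed against zero then rescaled by the
#'   mean control fold; both leave the control geometric structure intact).
#' @param efficiency optional list `list(target =, reference =)` of
#'   efficiencies for the corrected variant; `NULL` uses the classic 2^(-ddCt).
#' @return data frame of class `px_qpcr`: `sample`, `condition`, `dct`,
#'   `ddct`, `fold`.
#' @export
ddct_fold_changes <- function(data, target, reference, control = "sham",
                              normalise = c("dct_mean", "fold_mean"),
                              efficiency = NULL) {
  normalise <- match.arg(normalise)
  stopifnot(all(c("sample", "condition", "gene", "ct") %in% names(data)))
  if (!control %in% data$condition) stop("no samples in control condition")
  agg <- stats::aggregate(ct ~ sample + condition + gene, data = data, FUN = mean)
  wide_t <- agg[agg$gene == target, c("sample", "condition", "ct")]
  wide_r <- agg[agg$gene == reference, c("sample", "condition", "ct")]
  names(wide_t)[3] <- "ct_target"; names(wide_r)[3] <- "ct_ref"
  m <- merge(wide_t, wide_r[, c("sample", "ct_ref")], by = "sample")
  if (anyNA(m$ct_ref) || nrow(m) < nrow(wide_t))
    stop("missing housekeeping Ct for some sample(s)")
  base_t <- if (is.null(efficiency)) 2 else 1 + efficiency$target
  base_r <- if (is.null(efficiency)) 2 else 1 + efficiency$reference
  # dCt on the target base scale; with E = 1 both bases are 2 and this is
  # the textbook dCt = Ct_target - Ct_ref
  m$dct <- m$ct_target - log(base_r^m$ct_ref, base = base_t)
  if (normalise == "dct_mean") {
    ctrl_dct <- mean(m$dct[m$condition == control])
    m$ddct <- m$dct - ctrl_dct
    m$fold <- base_t^(-m$ddct)
  } else {
    raw_fold <- base_t^(-m$dct)
    ctrl_fold <- mean(raw_fold[m$condition == control])
    m$fold <- raw_fold / ctrl_fold
    m$ddct <- -log(m$fold, base = base_t)
  }
  out <- m[, c("sample", "condition", "dct", "ddct", "fold")]
  class(out) <- c("px_qpcr", "data.frame")
  out
}

#' @export
print.px_qpcr <- function(x, ...) {
  cat("<px_qpcr> fold changes by 2^(-ddCt)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Group summary and t-test on qPCR fold changes
#'
#' @param folds a `px_qpcr` data frame from [ddct_fold_changes()].
#' @param control control condition name.
#' @return list with per-condition mean and SEM of fold changes and the
#'   pooled two-sample t-test comparing the non-control condition(s) to
#'   control.
#' @export
qpcr_group_test <- function(folds, control = "sham") {
  by_cond <- split(folds$fold, folds$condition)
  summ <- data.frame(
    condition = names(by_cond),
    mean = vapply(by_cond, mean, 0),
    sem = vapply(by_cond, function(v) stats::sd(v) / sqrt(length(v)), 0),
    n = vapply(by_cond, length, 0L), row.names = NULL)
  other <- setdiff(names(by_cond), control)
  tt <- if (length(other) == 1L)
    student_t(by_cond[[control]], by_cond[[other]]) else NULL
  list(summary = summ, t_test = tt)
}
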