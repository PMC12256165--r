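#' Normality screening and transform ladder
#'
#' Group comparisons are gated on distributional screening: the
#' D'Agostino-Pearson omnibus test for samples of at least 8 values, the
#' Shapiro-Wilk test for smaller ones.  Datasets failing the screen are
#' checked with a normal-fit variance criterion, then pushed through a
#' ladder of standard transforms (log10, sqrt(x+1), 1/x, x+1); when nothing
#' normalises them the analysis falls back to mid-ranks.
#'
#' @name stats_normality
NULL

DP_MIN_N <- 8L  # "sufficiently large" cutoff for D'Agostino-Pearson

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness and kurtosis statistics into
#' \eqn{K^2 = Z_{skew}^2 + Z_{kurt}^2}, referred to a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2), `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < DP_MIN_N) stop("D'Agostino-Pearson requires n >= 8")
  if (stats::sd(x) == 0) stop("zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness component (D'Agostino 1970 transformation)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- .Machine$double.eps
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe-Glynn transformation)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  t2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z_k <- ((1 - 2 / (9 * a)) - t2) / sqrt(2 / (9 * a))

  k2 <- z_s^2 + z_k^2
  list(statistic = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_s, z_kurt = z_k)
}

#' Normality battery
#'
#' D'Agostino-Pearson omnibus test when n >= 8, Shapiro-Wilk otherwise.
#'
#' @param x numeric vector, n >= 3.
#' @param alpha significance level of the screen.
#' @return list with `normal` (logical), `test`, `statistic`, `p`.
#' @export
normality_battery <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("normality screening requires n >= 3")
  if (stats::sd(x) == 0) {
    return(list(normal = FALSE, test = "degenerate", statistic = NA_real_,
                p = NA_real_))
  }
  if (n >= DP_MIN_N) {
    r <- dagostino_pearson(x)
    list(normal = r$p > alpha, test = "dagostino_pearson",
         statistic = r$statistic, p = r$p)
  } else {
    r <- stats::shapiro.test(x)
    list(normal = r$p.value > alpha, test = "shapiro_wilk",
         statistic = unname(r$statistic), p = r$p.value)
  }
}

#' Fraction of dataset variance unexplained by a fitted normal
#'
#' Fits a normal distribution by mean and SD, regresses the ordered data on
#' the fitted-normal quantiles (a Q-Q regression), and reports
#' \eqn{1 - R^2}: the fraction of variance the normal fit cannot account
#' for.  Values above 0.10 mark the dataset as needing transformation.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `unexplained` (fraction) and `transform_needed`
#'   (logical, `unexplained > 0.10`).
#' @export
variance_explained_normal_fit <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < DP_MIN_N) stop("normal-fit variance check requires n >= 8")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance")
  q <- stats::qnorm(stats::ppoints(n), mean = mean(x), sd = s)
  r2 <- stats::cor(sort(x), q)^2
  unexp <- 1 - r2
  list(unexplained = unexp, transform_needed = unexp > 0.10)
}

PX_TRANSFORMS <- c("log10", "sqrt_plus1", "reciprocal", "plus1")

apply_transform <- function(x, name) {
  switch(name,
    none = x,
    log10 = if (all(x > 0)) log10(x) else NULL,
    sqrt_plus1 = if (all(x + 1 >= 0)) sqrt(x + 1) else NULL,
    reciprocal = if (all(x != 0)) 1 / x else NULL,
    plus1 = x + 1,
    rank = rank(x, ties.method = "average"),
    stop("unknown transform: ", name))
}

#' Transform ladder
#'
#' Tries each candidate transform in order and returns the first whose
#' result passes the normality battery; when none does, falls back to
#' mid-ranks of the pooled data.
#'
#' @param x numeric vector.
#' @param transforms candidate transform names, in order.
#' @param alpha screening level passed to [normality_battery()].
#' @return list with `transform` (name, `"rank"` for the fallback) and
#'   `values`.
#' @export
transform_ladder <- function(x, transforms = PX_TRANSFORMS, alpha = 0.05) {
  for (tr in transforms) {
    xt <- apply_transform(x, tr)
    if (is.null(xt)) next
    ok <- tryCatch(normality_battery(xt, alpha)$normal, error = function(e) FALSE)
    if (ok) return(list(transform = tr, values = xt))
  }
  list(transform = "rank", values = apply_transform(x, "rank"))
}

# the full screening ladder applied before an ANOVA: raw data when the
# battery passes or when a fitted normal leaves <= 10% of the variance
# unexplained; otherwise the transform ladder (possibly ranks)
ladder_normalise <- function(x, alpha = 0.05) {
  bat <- tryCatch(normality_battery(x, alpha), error = function(e) NULL)
  if (!is.null(bat) && bat$normal) return(list(transform = "none", values = x))
  if (length(x[is.finite(x)]) >= DP_MIN_N) {
    ve <- tryCatch(variance_explained_normal_fit(x), error = function(e) NULL)
    if (!is.null(ve) && !ve$transform_needed)
      return(list(transform = "none", values = x))
  }
  transform_ladder(x, alpha = alpha)
}
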