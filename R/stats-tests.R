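#' Group-comparison test families
#'
#' One-way comparisons across maturation groups use ANOVA with Tukey post
#' hocs when the data screen as normal, and Kruskal-Wallis with Dunn post
#' hocs otherwise.  Dual-factor comparisons (maturation x occlusion) use a
#' classical two-way ANOVA with Type II sums of squares on raw, transformed
#' or rank data as selected by the screening ladder, with Sidak-adjusted
#' sham-vs-occluded contrasts within each maturation level.
#'
#' @name stats_tests
NULL

new_stat_result <- function(...) structure(list(...), class = "px_stat_result")

#' @export
print.px_stat_result <- function(x, ...) {
  cat(sprintf("<px_stat_result> %s (transform: %s)\n", x$test, x$transform))
  if (!is.null(x$p) && length(x$p) == 1L)
    cat(sprintf("  statistic %.4g, p = %.4g\n", x$statistic, x$p))
  if (!is.null(x$effects)) {
    for (nm in rownames(x$effects))
      cat(sprintf("  %s: F = %.4g, p = %.4g\n", nm,
                  x$effects[nm, "F"], x$effects[nm, "p"]))
  }
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("  post hoc:\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %s: p_adj = %.4g\n", x$posthoc$contrast[i],
                  x$posthoc$p_adj[i]))
  }
  invisible(x)
}

# Dunn's post hoc z-tests on pooled ranks with tie correction;
# p-values Bonferroni-adjusted over all pairwise contrasts
dunn_posthoc <- function(x, g) {
  g <- droplevels(as.factor(g))
  N <- length(x)
  r <- rank(x, ties.method = "average")
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tcorr
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    z <- (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(v0 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    2 * stats::pnorm(-abs(z))
  })
  data.frame(contrast = paste(pairs[1, ], "-", pairs[2, ]),
             p = unname(res),
             p_adj = pmin(1, unname(res) * ncol(pairs)))
}

#' One-way comparison across groups
#'
#' @param x numeric response values.
#' @param g group labels (3 maturation groups in the standard design).
#' @param alpha screening level for the normality battery.
#' @return a `px_stat_result` with the omnibus test (`one_way_anova` +
#'   Tukey, or `kruskal_wallis` + Dunn), its statistic, df, p and post hoc
#'   table.
#' @export
one_way_family <- function(x, g, alpha = 0.05) {
  g <- droplevels(as.factor(g))
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tapply(x, g, length) < 2L)) stop("each group needs at least 2 values")
  bat <- normality_battery(x, alpha)
  if (bat$normal) {
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    new_stat_result(test = "one_way_anova", transform = "none",
                    statistic = an[1, "F value"],
                    df = c(an[1, "Df"], an[2, "Df"]),
                    p = an[1, "Pr(>F)"],
                    posthoc = data.frame(contrast = rownames(tk),
                                         p = tk[, "p adj"], p_adj = tk[, "p adj"],
                                         row.names = NULL),
                    alpha = alpha, normality = bat)
  } else {
    kw <- stats::kruskal.test(x, g)
    new_stat_result(test = "kruskal_wallis", transform = "none",
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p = kw$p.value,
                    posthoc = dunn_posthoc(x, g),
                    alpha = alpha, normality = bat)
  }
}

# Type II sums-of-squares two-way ANOVA via nested model comparisons
anova_type2 <- function(y, A, B) {
  A <- droplevels(as.factor(A)); B <- droplevels(as.factor(B))
  rss <- function(form) {
    mm <- stats::model.matrix(form)
    f <- stats::lm.fit(mm, y)
    c(sum(f$residuals^2), length(y) - f$rank)
  }
  full <- rss(~ A * B); add <- rss(~ A + B)
  onlyA <- rss(~ A); onlyB <- rss(~ B)
  ss <- c(A = onlyB[1] - add[1], B = onlyA[1] - add[1],
          `A:B` = add[1] - full[1])
  df <- c(A = nlevels(A) - 1L, B = nlevels(B) - 1L,
          `A:B` = (nlevels(A) - 1L) * (nlevels(B) - 1L))
  mse <- full[1] / full[2]
  Fv <- (ss / df) / mse
  p <- stats::pf(Fv, df, full[2], lower.tail = FALSE)
  list(table = cbind(SS = ss, df = df, F = Fv, p = p),
       df_resid = full[2], mse = mse)
}

sidak_adjust <- function(p, m = 3L) 1 - (1 - p)^m

# sham-vs-occluded contrast within each maturation level, from the cell-mean
# model: t on the difference of cell means with the pooled residual MSE
within_level_contrasts <- function(y, A, B, mse, df_resid, m_adjust = NULL) {
  A <- droplevels(as.factor(A)); B <- droplevels(as.factor(B))
  stopifnot(nlevels(B) == 2L)
  lev <- levels(A)
  if (is.null(m_adjust)) m_adjust <- length(lev)
  rows <- lapply(lev, function(a) {
    y1 <- y[A == a & B == levels(B)[1]]
    y2 <- y[A == a & B == levels(B)[2]]
    d <- mean(y1) - mean(y2)
    se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
    tt <- d / se
    p <- 2 * stats::pt(-abs(tt), df_resid)
    data.frame(contrast = sprintf("%s: %s - %s", a, levels(B)[1], levels(B)[2]),
               estimate = d, t = tt, p = p,
               p_adj = sidak_adjust(p, m_adjust))
  })
  do.call(rbind, rows)
}

#' Two-way comparison (maturation x occlusion)
#'
#' Applies the screening ladder to the pooled response, then a classical
#' two-factor ANOVA with Type II sums of squares (robust to the unbalanced
#' cell counts of patch-clamp datasets) on the raw, transformed, or
#' mid-ranked data.  Post hoc sham-vs-occluded contrasts within each
#' maturation level are Sidak-adjusted for the three comparisons:
#' \eqn{p_{adj} = 1 - (1 - p)^3}.
#'
#' @param x numeric response values.
#' @param maturation first factor (e.g. wpi5/wpi9/resident).
#' @param treatment second factor (e.g. sham/occluded, 2 levels).
#' @param alpha screening level.
#' @param posthoc compute within-level contrasts (skip for speed in
#'   simulation loops).
#' @return a `px_stat_result` with `transform`, an `effects` table (F and p
#'   for maturation, treatment and their interaction) and the `posthoc`
#'   contrast table.
#' @export
two_way_family <- function(x, maturation, treatment, alpha = 0.05,
                           posthoc = TRUE) {
  A <- droplevels(as.factor(maturation)); B <- droplevels(as.factor(treatment))
  ok <- is.finite(x) & !is.na(A) & !is.na(B)
  x <- x[ok]; A <- droplevels(A[ok]); B <- droplevels(B[ok])
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("need at least 2 levels per factor")
  if (any(table(A, B) == 0L)) stop("empty design cell")
  lad <- ladder_normalise(x, alpha)
  y <- lad$values
  a2 <- anova_type2(y, A, B)
  eff <- a2$table
  rownames(eff) <- c("maturation", "treatment", "interaction")
  ph <- NULL
  if (posthoc && nlevels(B) == 2L)
    ph <- within_level_contrasts(y, A, B, a2$mse, a2$df_resid)
  new_stat_result(test = "two_way_anova_type2", transform = lad$transform,
                  effects = eff, df_resid = a2$df_resid, posthoc = ph,
                  alpha = alpha)
}

#' Fisher's exact test on a 2 x 2 table of proportions
#'
#' Exact two-sided p by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param a,n1 successes and total in the first group.
#' @param b,n2 successes and total in the second group.
#' @return two-sided p-value.
#' @examples
#' fisher_2x2(79, 97, 74, 93)   # 0.85
#' @export
fisher_2x2 <- function(a, n1, b, n2) {
  stopifnot(a >= 0, b >= 0, a <= n1, b <= n2,
            a == round(a), b == round(b), n1 == round(n1), n2 == round(n2))
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2, byrow = TRUE)
  if (sum(tab) == 0 || any(rowSums(tab) == 0) ||
      all(tab[, 1] == 0) || all(tab[, 2] == 0)) {
    warning("degenerate margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Fisher's exact test on a 2 x k table (Freeman-Halton extension)
#'
#' @param successes,totals integer count vectors over k groups.
#' @param workspace workspace size for the exact network algorithm; tables
#'   whose margins exceed it raise an error rather than approximating.
#' @return exact two-sided p-value; reduces to [fisher_2x2()] when k = 2.
#' @examples
#' fisher_2xk(c(3, 8, 21), c(23, 17, 53))   # 0.034
#' @export
fisher_2xk <- function(successes, totals, workspace = 2e6) {
  stopifnot(length(successes) == length(totals), length(totals) >= 2,
            all(successes >= 0), all(successes <= totals),
            all(successes == round(successes)), all(totals == round(totals)))
  if (length(totals) == 2L)
    return(fisher_2x2(successes[1], totals[1], successes[2], totals[2]))
  tab <- rbind(successes, totals - successes)
  if (any(rowSums(tab) == 0)) {
    warning("degenerate margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab, workspace = workspace)$p.value
}

#' Bonferroni-corrected per-test alpha
#'
#' @param family_alpha family-wise error rate.
#' @param m number of tests in the family.
#' @param digits display rounding (3 decimals by default, as used when
#'   reporting corrected thresholds; `NULL` for the exact value).
#' @return per-test alpha.
#' @examples
#' bonferroni_alpha(0.05, 3)   # 0.017
#' @export
bonferroni_alpha <- function(family_alpha, m, digits = 3) {
  stopifnot(m >= 1, family_alpha > 0, family_alpha <= 1)
  a <- family_alpha / m
  if (is.null(digits)) a else round(a, digits)
}

#' Pooled-variance two-sample t-test
#'
#' Accepts either raw samples or per-group summaries (mean, SEM, n), the
#' form in which published group data are usually available.
#'
#' @param x,y raw samples, or `NULL` when using summaries.
#' @param mean1,sem1,n1,mean2,sem2,n2 group summaries.
#' @return list with `t`, `df` (\eqn{n_1 + n_2 - 2}) and two-sided `p`.
#' @export
student_t <- function(x = NULL, y = NULL,
                      mean1 = NULL, sem1 = NULL, n1 = NULL,
                      mean2 = NULL, sem2 = NULL, n2 = NULL) {
  if (!is.null(x) && !is.null(y)) {
    n1 <- length(x); n2 <- length(y)
    mean1 <- mean(x); mean2 <- mean(y)
    v1 <- stats::var(x); v2 <- stats::var(y)
  } else {
    stopifnot(!is.null(mean1), !is.null(sem1), !is.null(n1),
              !is.null(mean2), !is.null(sem2), !is.null(n2))
    v1 <- (sem1 * sqrt(n1))^2; v2 <- (sem2 * sqrt(n2))^2
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# all permutations of 1..n as an n! x n matrix
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation
#'
#' Mid-rank Spearman r, with an exact permutation p-value for n <= 9 and
#' the t-approximation above.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `r`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need n >= 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r <- stats::cor(rx, ry)
  if (n <= 9L) {
    pm <- perm_matrix(n)
    ryp <- matrix(ry[pm], nrow(pm))
    rxc <- rx - mean(rx)
    ryc <- ryp - mean(ry)
    rp <- as.vector(ryc %*% rxc) /
      sqrt(sum(rxc^2) * rowSums(ryc^2))
    p <- mean(abs(rp) >= abs(r) - 1e-12)
    method <- "exact_permutation"
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t_approximation"
  }
  list(r = r, p = p, n = n, method = method)
}
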