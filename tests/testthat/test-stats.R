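test_that("D'Agostino-Pearson omnibus matches an independent reference", {
  # frozen reference values computed with an independent implementation of
  # the omnibus K2 statistic on these exact vectors
  x <- c(9.574494, 2.606457, 3.611415, 4.175414, 3.058653, 3.105440,
         6.496279, 4.766090, 5.305315, 9.379956, 5.713972, 10.433504,
         9.562904, 5.648041, 8.792134, 5.935361, 3.212399, 4.385343,
         4.990355, 6.976328)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 2.5289453415, tolerance = 1e-9)
  expect_equal(r$p, 0.2823881684, tolerance = 1e-8)
  y <- c(0.553756, 1.026951, 0.219467, 0.255981, 3.249461, 0.392919,
         3.756943, 1.868092, 0.955307, 0.366367, 0.436733, 0.705851)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 6.7835869802, tolerance = 1e-9)
  expect_equal(r2$p, 0.0336482749, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("normality battery switches test by sample size and calibrates", {
  set.seed(1)
  small <- rnorm(6)
  expect_identical(normality_battery(small)$test, "shapiro_wilk")
  expect_identical(normality_battery(rnorm(30))$test, "dagostino_pearson")
  expect_error(normality_battery(c(1, 2)), "n >= 3")
  expect_false(normality_battery(rep(3, 10))$normal)
  # type-I rate near the nominal 5% on normal draws
  set.seed(2)
  rej <- mean(replicate(600, !normality_battery(rnorm(40))$normal))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
  # power against a strong log-normal
  set.seed(3)
  pow <- mean(replicate(200, !normality_battery(exp(rnorm(100)))$normal))
  expect_gt(pow, 0.9)
})

test_that("normal-fit variance criterion separates normal from heavy-tailed", {
  set.seed(5)
  clean <- qnorm(ppoints(40), 10, 2)       # exact normal quantiles
  v <- variance_explained_normal_fit(clean)
  expect_lt(v$unexplained, 0.005)
  expect_false(v$transform_needed)
  flagged <- mean(replicate(100, {
    x <- c(rnorm(30), rnorm(4, 25, 1))     # a few gross outliers
    variance_explained_normal_fit(x)$transform_needed
  }))
  expect_gt(flagged, 0.8)
  expect_silent(variance_explained_normal_fit(rnorm(8)))  # n = 8 boundary
  expect_error(variance_explained_normal_fit(rep(2, 10)), "variance")
})

test_that("transform ladder picks log10 for log-normal data, ranks for bimodal", {
  set.seed(8)
  ln <- exp(rnorm(60, 2, 0.8))
  expect_identical(transform_ladder(ln)$transform, "log10")
  nn <- rnorm(60)
  expect_identical(patchfx:::ladder_normalise(nn)$transform, "none")
  bim <- c(rnorm(40, -10, 0.3), rnorm(40, 10, 0.3))
  expect_identical(transform_ladder(bim)$transform, "rank")
})

test_that("one-way family routes by normality and finds a shifted group", {
  set.seed(12)
  g <- rep(c("a", "b", "c"), each = 30)
  same <- rnorm(90)
  r0 <- one_way_family(same, g)
  expect_gt(r0$p, 0.01)
  shifted <- same + (g == "b") * 1
  pow <- mean(replicate(60, {
    y <- rnorm(90) + (g == "b") * 1
    one_way_family(y, g)$p < 0.05
  }))
  expect_gt(pow, 0.8)
  # identical groups: p near 1, no post hoc hits
  r1 <- one_way_family(rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 3),
                       rep(c("a", "b", "c"), each = 5))
  expect_gt(r1$p, 0.99)
  expect_true(all(r1$posthoc$p_adj > 0.9))
  expect_error(one_way_family(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Kruskal-Wallis route applies the tie-corrected statistic", {
  x <- c(0, 0, 0, 0.1, 10, 10, 0, 0.1, 10, 0, 10, 10)
  g <- rep(c("a", "b", "c"), each = 4)
  r <- one_way_family(x, g)
  expect_identical(r$test, "kruskal_wallis")
  expect_equal(r$statistic, unname(kruskal.test(x, factor(g))$statistic),
               tolerance = 1e-12)
  expect_identical(nrow(r$posthoc), 3L)
})

test_that("Type II two-way ANOVA matches the reference implementation", {
  skip_if_not_installed("car")
  set.seed(3)
  A <- factor(rep(c("g1", "g2", "g3"), times = c(14, 9, 20)))
  B <- factor(unlist(lapply(c(14, 9, 20), function(n)
    sample(rep(c("s", "o"), length.out = n)))))
  y <- rnorm(43) + (A == "g2") * 0.8 + (B == "o") * 0.5
  a2 <- patchfx:::anova_type2(y, A, B)
  ref <- car::Anova(lm(y ~ A * B), type = 2)
  expect_equal(unname(a2$table[, "SS"]), ref[["Sum Sq"]][1:3],
               tolerance = 1e-10)
  expect_equal(unname(a2$table[, "p"]), ref[["Pr(>F)"]][1:3],
               tolerance = 1e-10)
})

test_that("within-level contrasts match cell-mean model t-tests", {
  skip_if_not_installed("emmeans")
  set.seed(6)
  A <- factor(rep(c("g1", "g2", "g3"), each = 12))
  B <- factor(rep(rep(c("o", "s"), each = 6), 3))
  y <- rnorm(36) + (A == "g1" & B == "o") * 1.5
  a2 <- patchfx:::anova_type2(y, A, B)
  ph <- patchfx:::within_level_contrasts(y, A, B, a2$mse, a2$df_resid)
  em <- summary(emmeans::contrast(emmeans::emmeans(lm(y ~ A * B), ~ B | A),
                                  "pairwise", adjust = "none"))
  expect_equal(ph$p, em$p.value, tolerance = 1e-10)
  expect_equal(ph$p_adj, 1 - (1 - em$p.value)^3, tolerance = 1e-10)
})

test_that("rank two-way ANOVA is invariant under monotone transforms", {
  set.seed(9)
  A <- factor(rep(c("a", "b", "c"), each = 16))
  B <- factor(rep(rep(c("s", "o"), each = 8), 3))
  y <- c(rnorm(24, -10, 0.3), rnorm(24, 10, 0.3))[sample(48)]
  r1 <- two_way_family(y, A, B, posthoc = FALSE)
  expect_identical(r1$transform, "rank")
  r2 <- two_way_family(2 * y + 5, A, B, posthoc = FALSE)
  expect_identical(r2$transform, "rank")
  expect_equal(r1$effects[, "p"], r2$effects[, "p"], tolerance = 1e-12)
  expect_error(two_way_family(rnorm(10), rep(c("a", "b"), 5), rep("s", 10)),
               "2 levels")
})

test_that("Sidak adjustment is closed-form and dominates the raw p", {
  expect_equal(patchfx:::sidak_adjust(0.05, 3), 1 - 0.95^3)
  expect_equal(patchfx:::sidak_adjust(0.05, 3), 0.142625)
  ps <- seq(0, 1, by = 0.01)
  expect_true(all(patchfx:::sidak_adjust(ps, 3) >= ps))
  eq <- patchfx:::sidak_adjust(ps, 3) == ps
  expect_identical(which(eq), c(1L, length(ps)))
})

test_that("Fisher 2x2 equals brute-force enumeration and is symmetric", {
  brute <- function(a, n1, b, n2) {
    s <- a + b
    xs <- max(0, s - n2):min(n1, s)
    pr <- dhyper(xs, n1, n2, s)
    sum(pr[pr <= dhyper(a, n1, n2, s) * (1 + 1e-7)])
  }
  set.seed(5)
  for (i in 1:200) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    p1 <- suppressWarnings(fisher_2x2(a, n1, b, n2))
    expect_equal(p1, brute(a, n1, b, n2), tolerance = 1e-9)
    expect_equal(p1, suppressWarnings(fisher_2x2(b, n2, a, n1)),
                 tolerance = 1e-12)                        # swap groups
    expect_equal(p1, suppressWarnings(fisher_2x2(n1 - a, n1, n2 - b, n2)),
                 tolerance = 1e-12)                        # swap outcomes
  }
  expect_equal(fisher_2x2(5, 10, 5, 10), 1)
  expect_warning(fisher_2x2(0, 5, 0, 7), "degenerate")
})

test_that("2xk Fisher reduces to 2x2 and handles degenerate tables", {
  set.seed(6)
  for (i in 1:50) {
    n1 <- sample(1:25, 1); n2 <- sample(1:25, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    expect_equal(suppressWarnings(fisher_2xk(c(a, b), c(n1, n2))),
                 suppressWarnings(fisher_2x2(a, n1, b, n2)),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_2xk(c(4, 4, 4), c(10, 10, 10)), 1)
  expect_warning(fisher_2xk(c(0, 0, 0), c(5, 5, 5)), "degenerate")
})

test_that("Bonferroni-corrected alpha is reported at display precision", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 3, digits = NULL), 0.05 / 3)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("pooled t-test agrees between raw data and summary input", {
  set.seed(7)
  x <- rnorm(8, 1); y <- rnorm(12, 0.2)
  a <- student_t(x, y)
  b <- student_t(mean1 = mean(x), sem1 = sd(x) / sqrt(8), n1 = 8,
                 mean2 = mean(y), sem2 = sd(y) / sqrt(12), n2 = 12)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_identical(a$df, 18)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  same <- student_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(student_t(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("Spearman correlation: exact small-n permutation and t approximation", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$r, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$r, -1)
  set.seed(2)
  x <- rnorm(7); y <- rnorm(7)
  s <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman")
  expect_identical(s$method, "exact_permutation")
  expect_equal(s$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(s$p, ref$p.value, tolerance = 1e-9)
  big <- spearman_cor(rnorm(25), rnorm(25))
  expect_identical(big$method, "t_approximation")
  expect_error(spearman_cor(rep(1, 6), rnorm(6)), "constant")
  # mean r near zero under independence
  set.seed(14)
  rs <- replicate(300, spearman_cor(runif(20), runif(20))$r)
  expect_lt(abs(mean(rs)), 0.05)
})
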