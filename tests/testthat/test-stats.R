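# Within-subject ANOVA, Friedman test, effect size, post-hoc power.

test_that("rm_anova F for a two-level factor equals the paired t squared", {
  set.seed(61)
  n <- 12
  d <- data.frame(subject_id = rep(1:n, 2),
                  cond = rep(c("x", "y"), each = n),
                  value = rnorm(2 * n))
  a <- rm_anova(d, dv = "value", factors = "cond")
  tt <- t.test(d$value[d$cond == "y"], d$value[d$cond == "x"], paired = TRUE)
  expect_equal(a$table$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$table$p, tt$p.value, tolerance = 1e-12)
  expect_equal(a$table$df2, n - 1)
})

test_that("rm_anova matches the frozen 2x2 decomposition fixture", {
  # Sums of squares verified against a textbook repeated-measures
  # decomposition (stats::aov with Error(subject/(A*B)) gives the same).
  Y <- matrix(c(3, 5, 4, 6,
                2, 4, 5, 7,
                6, 8, 5, 9,
                4, 4, 6, 8), 4, 4, byrow = TRUE)
  a <- rm_anova(anova_fixture_long(Y), dv = "value", factors = c("A", "B"))
  tab <- a$table
  rowA <- tab[tab$effect == "A", ]
  rowB <- tab[tab$effect == "B", ]
  rowAB <- tab[tab$effect == "A:B", ]
  expect_equal(rowA$ss_effect, 12.25)
  expect_equal(rowA$ss_error, 6.75)
  expect_equal(rowA$F, 49 / 9, tolerance = 1e-12)
  expect_equal(rowB$ss_effect, 16)
  expect_equal(rowB$ss_error, 2)
  expect_equal(rowB$F, 24, tolerance = 1e-12)
  expect_equal(rowAB$ss_effect, 1)
  expect_equal(rowAB$ss_error, 1)
  expect_equal(rowAB$F, 3, tolerance = 1e-12)
  expect_equal(rowA$partial_eta2, 12.25 / 19, tolerance = 1e-12)
  expect_equal(rowB$partial_eta2, 16 / 18, tolerance = 1e-12)
})

test_that("rm_anova agrees with stats::aov on random balanced designs", {
  set.seed(62)
  for (rep in 1:3) {
    n <- 8
    Y <- matrix(rnorm(n * 4), n, 4)
    d <- anova_fixture_long(Y)
    mine <- rm_anova(d, dv = "value", factors = c("A", "B"))$table
    d$subject <- factor(d$subject_id)
    d$A <- factor(d$A)
    d$B <- factor(d$B)
    ref <- summary(aov(value ~ A * B + Error(subject / (A * B)), data = d))
    refF <- c(A = ref[["Error: subject:A"]][[1]]$`F value`[1],
              B = ref[["Error: subject:B"]][[1]]$`F value`[1],
              `A:B` = ref[["Error: subject:A:B"]][[1]]$`F value`[1])
    expect_equal(mine$F[match(names(refF), mine$effect)], unname(refF),
                 tolerance = 1e-8)
  }
})

test_that("rm_anova p-values are uniform under the null", {
  set.seed(63)
  pvals <- replicate(1000, {
    Y <- matrix(rnorm(6 * 4), 6, 4)
    a <- rm_anova(anova_fixture_long(Y), dv = "value", factors = c("A", "B"))
    a$table$p[a$table$effect == "A:B"]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("rm_anova rejects malformed designs", {
  d <- anova_fixture_long(matrix(rnorm(12), 3, 4))
  expect_error(rm_anova(d[-1, ], dv = "value", factors = c("A", "B")),
               "complete")
  d$A <- "one-level"
  expect_error(rm_anova(d, dv = "value", factors = c("A", "B")), "2 levels")
})

test_that("simple effects are paired t tests within moderator levels", {
  set.seed(64)
  Y <- matrix(rnorm(10 * 4), 10, 4)
  d <- anova_fixture_long(Y)
  se <- simple_effects(d, dv = "value", factor = "A", within = "B")
  expect_equal(nrow(se), 2)
  tt <- t.test(Y[, 3], Y[, 1], paired = TRUE)  # A at B = b1
  expect_equal(se$F[se$level == "b1"], unname(tt$statistic)^2,
               tolerance = 1e-12)
  expect_equal(se$p[se$level == "b1"], tt$p.value, tolerance = 1e-12)
})

test_that("friedman_test handles ties, degeneracy, and matches stats::", {
  # identical columns: no rank variation at all
  x <- matrix(rep(c(1, 2, 3, 4, 5), 3), 5, 3)
  expect_equal(friedman_test(x)$chi2, 0)
  # tie-free data: equals stats::friedman.test exactly
  set.seed(65)
  y <- matrix(rnorm(8 * 4), 8, 4)
  mine <- friedman_test(y)
  ref <- friedman.test(y)
  expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$tie_correction, 1)
  # two conditions: direction agrees with the sign of the rank-sum difference
  z <- matrix(c(1, 2, 1, 1, 3, 4, 2, 5), 4, 2)
  f2 <- friedman_test(z)
  expect_gt(f2$chi2, 0)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
})

test_that("exact Friedman p matches an independent permutation oracle", {
  x <- matrix(c(3, 1, 2,
                2, 2, 4,
                5, 3, 3,
                1, 4, 2,
                2, 5, 4), 5, 3, byrow = TRUE)
  mine <- friedman_test(x, exact = TRUE)
  orc <- oracle_friedman_exact(x)
  expect_equal(mine$chi2, orc$obs, tolerance = 1e-12)
  expect_equal(mine$p, orc$p, tolerance = 1e-12)
  expect_equal(mine$method, "exact permutation")
})

test_that("pairwise Friedman follow-ups are Bonferroni scaled", {
  set.seed(66)
  x <- matrix(rnorm(10 * 3), 10, 3)
  x[, 3] <- x[, 3] + 2
  f <- friedman_test(x, pairwise = TRUE)
  expect_equal(nrow(f$contrasts), 3)
  expect_equal(f$contrasts$p_bonferroni,
               pmin(1, f$contrasts$p_raw * 3))
})

test_that("cohen_f2 is the R2 odds transform", {
  expect_equal(cohen_f2(0.5), 1)
  expect_equal(cohen_f2(0), 0)
  # inverting the definition at the published effect size
  expect_equal(cohen_f2(0.491 / 1.491), 0.491, tolerance = 1e-12)
  expect_error(cohen_f2(1), "\\[0, 1\\)")
})

test_that("noncentral-F power behaves analytically", {
  # null effect: power equals alpha exactly
  expect_equal(regression_posthoc_power(0, 7, 46, 0.05)$power, 0.05,
               tolerance = 1e-12)
  # strictly increasing in f2, N and alpha
  p1 <- regression_posthoc_power(0.2, 7, 46)$power
  p2 <- regression_posthoc_power(0.3, 7, 46)$power
  p3 <- regression_posthoc_power(0.3, 7, 60)$power
  p4 <- regression_posthoc_power(0.3, 7, 46, 0.10)$power
  expect_gt(p2, p1)
  expect_gt(p3, p2)
  expect_gt(p4, p2)
  # the two lambda conventions coincide at these df (df1 + df2 + 1 = N)
  pw <- regression_posthoc_power(0.491, 7, 46)
  expect_equal(pw$lambda, 0.491 * (pw$df1 + pw$df2 + 1))
  expect_error(regression_posthoc_power(0.3, 7, 8), "degrees of freedom")
  expect_error(regression_posthoc_power(-0.1, 7, 46), ">= 0")
})
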