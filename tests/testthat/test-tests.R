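# The 8-observation worked example used in several tests:
# heterozygotes {0, 2, 6, 8}, code-0 homozygotes {0, 2}, code-2 {0, 4}.
eight_obs <- female_sample(c(1, 1, 1, 1, 0, 0, 2, 2),
                           c(0, 2, 6, 8, 0, 2, 0, 4))

test_that("median deviations are computed within each genotype group", {
  md <- median_deviations(female_sample(rep(1, 4), c(0, 2, 6, 8)))
  expect_equal(md$z, c(4, 2, 2, 4))   # group median 4

  md0 <- median_deviations(female_sample(rep(2, 3), c(5, 5, 5)))
  expect_equal(md0$z, c(0, 0, 0))

  # homozygote groups are centered on their own medians before pooling
  md2 <- median_deviations(female_sample(c(0, 0, 2, 2), c(0, 2, 0, 4)))
  expect_equal(md2$z, c(1, 1, 2, 2))

  md3 <- median_deviations(eight_obs)
  s <- md3$summary
  expect_equal(c(s$n0, s$n1, s$n2), c(2, 4, 2))
  expect_equal(s$mean_z_het, 3)
  expect_equal(s$mean_z_hom, 1.5)
  expect_equal(s$var_z_het, 4 / 3)
  expect_equal(s$var_z_hom, 1 / 3)
  expect_equal(s$group_variances, c(2, 40 / 3, 8))
  expect_error(median_deviations(list(genotypes = numeric(), phenotypes = numeric())))
})

test_that("variance test matches the hand-evaluated statistic and df", {
  vt <- variance_test(eight_obs)
  expect_true(vt$valid)
  expect_equal(vt$statistic, 1.5 / sqrt(5 / 12), tolerance = 1e-10)
  expect_equal(vt$df, 75 / 17, tolerance = 1e-10)   # ~ 4.412
  expect_equal(vt$direction, 1L)
  # p agrees with the upper-tail t probability at those values
  expect_equal(vt$p.value, pt(1.5 / sqrt(5 / 12), 75 / 17, lower.tail = FALSE))
  # two-sided variant doubles the tail
  vt2 <- variance_test(eight_obs, alternative = "two.sided")
  expect_equal(vt2$p.value, 2 * vt$p.value)
})

test_that("variance test agrees with Welch t.test on the deviations", {
  set.seed(42)
  for (i in 1:20) {
    d <- sim_dataset(80, 0.3, a = 0.4, noise = 0.3)
    fs <- female_sample(d$g, d$y)
    md <- median_deviations(fs)
    z1 <- md$z[fs$genotypes == 1]
    zh <- md$z[fs$genotypes != 1]
    ref <- t.test(z1, zh, alternative = "greater")
    vt <- variance_test(fs)
    expect_equal(vt$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(vt$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(vt$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("symmetric deviations give statistic 0 and one-sided p 0.5", {
  fs <- female_sample(c(1, 1, 1, 1, 0, 0, 2, 2),
                      c(-1, 1, -2, 2, -1, 1, -2, 2))
  vt <- variance_test(fs)
  expect_equal(vt$statistic, 0)
  expect_equal(vt$p.value, 0.5)
})

test_that("variance test degenerates gracefully", {
  # a single heterozygote
  r <- variance_test(female_sample(c(1, 0, 0, 2), c(1, 2, 3, 4)))
  expect_false(r$valid)
  expect_true(is.na(r$p.value))
  # all deviations zero in both pools
  r2 <- variance_test(female_sample(c(1, 1, 0, 0), c(3, 3, 7, 7)))
  expect_false(r2$valid)
  # no heterozygotes at all
  r3 <- variance_test(female_sample(c(0, 0, 2, 2), c(1, 2, 3, 4)))
  expect_false(r3$valid)
})

test_that("weighted test equals the normal-equations WLS oracle", {
  g <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  y <- c(0.1, 0.5, 1.2, 1.0, 2.5, 4.0, 2.2, 2.4, 2.9)  # unequal group spreads
  vg <- tapply(y, g, var)
  w <- 1 / vg[as.character(g)]
  oracle <- wls_normal_equations(g, y, as.numeric(w))
  wt <- weighted_association_test(female_sample(g, y))
  expect_true(wt$valid)
  expect_equal(wt$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(wt$df, 7)
  expect_equal(wt$p.value,
               2 * pt(abs(oracle$statistic), 7, lower.tail = FALSE),
               tolerance = 1e-10)
  # and with lm(weights = ) as a second, independent route
  fit <- summary(lm(y ~ g, weights = as.numeric(w)))
  expect_equal(wt$statistic, fit$coefficients["g", "t value"], tolerance = 1e-10)
  expect_equal(wt$p.value, fit$coefficients["g", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("weighted test is flat when all group means are equal", {
  wt <- weighted_association_test(
    female_sample(c(0, 0, 1, 1, 2, 2), c(1, -1, 2, -2, 1, -1)))
  expect_true(wt$valid)
  expect_equal(wt$statistic, 0)
  expect_equal(wt$p.value, 1)
})

test_that("weighted test degenerates on small or constant groups", {
  # a present group with a single member
  expect_false(weighted_association_test(
    female_sample(c(0, 0, 0, 1), c(1, 2, 3, 4)))$valid)
  # a present group with zero variance
  expect_false(weighted_association_test(
    female_sample(c(0, 0, 1, 1), c(5, 5, 1, 2)))$valid)
  # monomorphic
  expect_false(weighted_association_test(
    female_sample(rep(1, 6), rnorm(6)))$valid)
})

test_that("standard test matches lm and handles degeneracies", {
  set.seed(7)
  g <- rbinom(40, 2, 0.4)
  y <- 0.3 * g + rnorm(40)
  st <- standard_association_test(female_sample(g, y))
  fit <- summary(lm(y ~ g))
  expect_equal(st$statistic, fit$coefficients["g", "t value"], tolerance = 1e-10)
  expect_equal(st$df, 38)
  expect_equal(st$p.value, fit$coefficients["g", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(st$direction, 1L)

  expect_false(standard_association_test(female_sample(rep(2, 5), rnorm(5)))$valid)
  # perfect fit: p -> 0 with a warning
  expect_warning(
    pf <- standard_association_test(female_sample(c(0, 1, 2, 1), c(0, 2, 4, 2))),
    "perfect fit")
  expect_equal(pf$p.value, 0)
})

test_that("equal group variances collapse the weighted test onto OLS", {
  g <- c(0, 0, 1, 1, 2, 2)
  y <- c(0, 1, 5, 6, 3, 4)   # every group has variance 0.5
  wt <- weighted_association_test(female_sample(g, y))
  st <- standard_association_test(female_sample(g, y))
  expect_equal(wt$statistic, st$statistic, tolerance = 1e-12)
  expect_equal(wt$p.value, st$p.value, tolerance = 1e-12)
})

test_that("stouffer combination reproduces hand values and symmetries", {
  # equal weights: known two-test combinations
  expect_equal(stouffer_combine(0.5, 0.5), 0.5)
  z <- qnorm(c(0.01, 0.2), lower.tail = FALSE)
  expect_equal(stouffer_combine(0.01, 0.2),
               pnorm(sum(z) / sqrt(2), lower.tail = FALSE))
  # symmetry and weight-degeneracy
  expect_equal(stouffer_combine(0.03, 0.4), stouffer_combine(0.4, 0.03))
  expect_equal(stouffer_combine(0.03, 0.9, w1 = 1, w2 = 0), 0.03,
               tolerance = 1e-12)
  expect_equal(stouffer_combine(0.03, 0.9, w1 = 3, w2 = 3),
               stouffer_combine(0.03, 0.9), tolerance = 1e-12)
  # clamping
  expect_warning(p0 <- stouffer_combine(0, 0.5), "clamped")
  expect_true(p0 > 0 && p0 < 1e-100)
  expect_error(stouffer_combine(0.1, 0.2, w1 = 0, w2 = 0), "weights")
})

test_that("combined test combines its two components with equal weights", {
  set.seed(11)
  d <- sim_dataset(400, 0.3, a = 0.15, noise = 0.2)
  fs <- female_sample(d$g, d$y)
  ct <- combined_test(fs)
  expect_true(ct$valid)
  expect_equal(ct$p.value,
               stouffer_combine(variance_test(fs)$p.value,
                                weighted_association_test(fs)$p.value),
               tolerance = 1e-12)
  # invalid component propagates
  bad <- female_sample(c(0, 0, 0, 1), c(1, 2, 3, 4))
  expect_false(combined_test(bad)$valid)
})

test_that("all four p-values are location invariant and T_var is scale invariant", {
  set.seed(5)
  for (i in 1:10) {
    d <- sim_dataset(150, 0.25, a = 0.3, noise = 0.1)
    fs <- female_sample(d$g, d$y)
    fs_shift <- female_sample(d$g, d$y + 137.5)
    p <- c(standard_association_test(fs)$p.value, variance_test(fs)$p.value,
           weighted_association_test(fs)$p.value, combined_test(fs)$p.value)
    p_shift <- c(standard_association_test(fs_shift)$p.value,
                 variance_test(fs_shift)$p.value,
                 weighted_association_test(fs_shift)$p.value,
                 combined_test(fs_shift)$p.value)
    expect_equal(p, p_shift, tolerance = 1e-8)

    fs_scale <- female_sample(d$g, d$y * 3.7)
    expect_equal(variance_test(fs)$statistic, variance_test(fs_scale)$statistic,
                 tolerance = 1e-8)
    expect_equal(variance_test(fs)$p.value, variance_test(fs_scale)$p.value,
                 tolerance = 1e-8)
  }
})
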