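#' Median-centered absolute deviations by genotype group
#'
#' Transforms phenotypes to absolute deviations from the median of each
#' individual's own genotype group, `z = |y - median(y_group)|`. These
#' deviations are the raw material of the Brown-Forsythe-type variance test:
#' under equal group variances the deviations of heterozygotes and (pooled)
#' homozygotes have equal means. Homozygote groups (codes 0 and 2) are each
#' centered on their own median before pooling, so a mean shift between the
#' two homozygote classes does not masquerade as variance heterogeneity.
#'
#' @param sample A [female_sample()] (or coercible list).
#'
#' @return A list with elements:
#'   * `z`: numeric vector of deviations, aligned with the sample order;
#'   * `summary`: a `"group_summary"` with per-group counts (`n0`, `n1`,
#'     `n2`), the heterozygote and pooled-homozygote deviation means
#'     (`mean_z_het`, `mean_z_hom`) and variances (`var_z_het`, `var_z_hom`,
#'     `n - 1` denominator), and the three per-group phenotype variances
#'     (`group_variances`, `NA` for groups with fewer than two members).
#'
#' @examples
#' fs <- female_sample(c(1, 1, 1, 1), c(0, 2, 6, 8))
#' median_deviations(fs)$z   # 4 2 2 4
#' @export
median_deviations <- function(sample) {
  s <- as_female_sample(sample)
  g <- s$genotypes
  y <- s$phenotypes
  z <- numeric(s$n)
  for (j in 0:2) {
    i <- g == j
    if (any(i)) z[i] <- abs(y[i] - stats::median(y[i]))
  }
  het <- g == 1L
  z1 <- z[het]
  zh <- z[!het]
  n0 <- sum(g == 0L); n1 <- sum(het); n2 <- sum(g == 2L)
  gv <- vapply(0:2, function(j) {
    i <- g == j
    if (sum(i) >= 2L) stats::var(y[i]) else NA_real_
  }, numeric(1))
  summary <- structure(list(
    n0 = n0, n1 = n1, n2 = n2,
    mean_z_het = if (n1 > 0L) mean(z1) else NA_real_,
    mean_z_hom = if (n0 + n2 > 0L) mean(zh) else NA_real_,
    var_z_het = if (n1 >= 2L) stats::var(z1) else NA_real_,
    var_z_hom = if (n0 + n2 >= 2L) stats::var(zh) else NA_real_,
    group_variances = gv), class = "group_summary")
  list(z = z, summary = summary)
}

# Core of the heterozygote-variance test on raw vectors; returns
# c(statistic, df, p, direction, valid). alternative: 1 = upper tail
# (heterozygotes more variable), 2 = two-sided.
.var_core <- function(g, y, alternative = 1L) {
  het <- g == 1L
  y1 <- y[het]
  n1 <- length(y1)
  nh <- length(y) - n1
  if (n1 < 2L || nh < 2L) return(c(NA, NA, NA, NA, 0))
  z1 <- abs(y1 - stats::median(y1))
  i0 <- g == 0L
  y0 <- y[i0]; y2 <- y[!het & !i0]
  zh <- c(if (length(y0)) abs(y0 - stats::median(y0)),
          if (length(y2)) abs(y2 - stats::median(y2)))
  v1 <- stats::var(z1)
  vh <- stats::var(zh)
  if (v1 <= 0 && vh <= 0) return(c(NA, NA, NA, NA, 0))
  a1 <- v1 / n1
  a2 <- vh / nh
  se2 <- a1 + a2
  stat <- (mean(z1) - mean(zh)) / sqrt(se2)
  df <- se2^2 / (a1^2 / (n1 - 1) + a2^2 / (nh - 1))
  p <- if (alternative == 1L) {
    stats::pt(stat, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  }
  c(stat, df, p, sign(stat), 1)
}

# Weighted least-squares slope test core. weights: per-observation, already
# validated > 0. Returns c(statistic, df, p, direction, valid). A zero
# residual sum of squares (perfect fit) maps to p = 0 with a warning.
.slope_core <- function(g, y, w = NULL) {
  n <- length(y)
  if (n < 3L) return(c(NA, NA, NA, NA, 0))
  if (is.null(w)) {
    mx <- mean(g); my <- mean(y)
    dx <- g - mx
    sxx <- sum(dx * dx)
    if (sxx <= 0) return(c(NA, NA, NA, NA, 0))
    sxy <- sum(dx * (y - my))
    syy <- sum((y - my)^2)
  } else {
    sw <- sum(w)
    mx <- sum(w * g) / sw; my <- sum(w * y) / sw
    dx <- g - mx
    sxx <- sum(w * dx * dx)
    if (sxx <= 0) return(c(NA, NA, NA, NA, 0))
    sxy <- sum(w * dx * (y - my))
    syy <- sum(w * (y - my)^2)
  }
  b <- sxy / sxx
  rss <- syy - b * sxy
  df <- n - 2
  if (rss <= max(1e-12 * syy, 0)) {
    warning("perfect fit (zero residual variance); p-value set to 0",
            call. = FALSE)
    return(c(Inf * sign(b), df, 0, sign(b), 1))
  }
  se <- sqrt(rss / df / sxx)
  stat <- b / se
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  c(stat, df, p, sign(b), 1)
}

.wls_core <- function(g, y) {
  nn <- tabulate(g + 1L, nbins = 3L)
  present <- nn > 0L
  if (sum(present) < 2L) return(c(NA, NA, NA, NA, 0))
  if (any(nn[present] < 2L)) return(c(NA, NA, NA, NA, 0))
  vv <- rep(NA_real_, 3L)
  for (j in which(present)) vv[j] <- stats::var(y[g == j - 1L])
  if (any(vv[present] <= 0)) return(c(NA, NA, NA, NA, 0))
  w <- 1 / vv[g + 1L]
  .slope_core(g, y, w)
}

.ols_core <- function(g, y) {
  .slope_core(g, y)
}

.match_alternative <- function(alternative) {
  alternative <- match.arg(alternative, c("greater", "two.sided"))
  if (alternative == "greater") 1L else 2L
}

#' Test for inflated phenotypic variance in heterozygous females
#'
#' A two-group Brown-Forsythe-type test comparing the spread of the trait in
#' heterozygous females (genotype code 1) against the pooled homozygotes
#' (codes 0 and 2, each median-centered on its own group). Under random
#' X-inactivation with inactivation ratio `theta` a QTL with expressed-allele
#' gap `d` inflates the heterozygote variance by `theta * (1 - theta) * d^2`,
#' so the default alternative is one-sided: heterozygotes have the *larger*
#' variance. The statistic is a Welch-type t ratio on the median-centered
#' absolute deviations and is referred to a t distribution with
#' Satterthwaite degrees of freedom.
#'
#' @param sample A [female_sample()] (or coercible list).
#' @param alternative `"greater"` (default; upper-tail test of inflated
#'   heterozygote variance) or `"two.sided"`.
#'
#' @return An `"xassoc_result"` with `statistic`, `df`, `p.value`,
#'   `direction` (sign of the heterozygote-minus-homozygote deviation mean
#'   difference) and `valid`. Degenerate inputs (fewer than two heterozygotes
#'   or two pooled homozygotes, or both deviation variances zero) give
#'   `valid = FALSE` rather than an error.
#'
#' @examples
#' fs <- female_sample(c(1, 1, 1, 1, 0, 0, 2, 2), c(0, 2, 6, 8, 0, 2, 0, 4))
#' variance_test(fs)   # statistic ~ 2.32, df ~ 4.41
#' @seealso [weighted_association_test()], [combined_test()]
#' @export
variance_test <- function(sample, alternative = c("greater", "two.sided")) {
  s <- as_female_sample(sample)
  alt <- .match_alternative(alternative)
  r <- .var_core(s$genotypes, s$phenotypes, alt)
  method <- sprintf("Heterozygote variance inflation test (%s)",
                    c("one-sided", "two-sided")[alt])
  if (!r[5]) {
    return(.invalid_result(method,
      "requires >= 2 heterozygotes, >= 2 pooled homozygotes and a positive deviation variance"))
  }
  .test_result(method, statistic = r[1], df = r[2], p.value = r[3],
               direction = as.integer(r[4]), valid = TRUE)
}

#' Weighted association test accounting for variance heterogeneity
#'
#' Weighted least-squares regression of the trait on the genotype code
#' (0/1/2), each individual weighted by the inverse of the empirical
#' phenotype variance of its own genotype group. The weights absorb the
#' variance inflation that X-inactivation induces in heterozygotes, so the
#' slope test keeps (slightly exceeds) the power of the standard test when
#' group variances differ and collapses to it exactly when they are equal.
#' Two-sided t test of the slope on `n - 2` degrees of freedom.
#'
#' @inheritParams variance_test
#' @return An `"xassoc_result"`; `valid = FALSE` when the SNP is monomorphic
#'   among the sampled females or any present genotype group has fewer than
#'   two members or zero phenotype variance (the weight would be undefined).
#' @examples
#' set.seed(1)
#' g <- rbinom(500, 2, 0.3)
#' y <- 0.2 * g + rnorm(500)
#' weighted_association_test(female_sample(g, y))
#' @export
weighted_association_test <- function(sample) {
  s <- as_female_sample(sample)
  r <- .wls_core(s$genotypes, s$phenotypes)
  method <- "Weighted association test (inverse group-variance weights)"
  if (!r[5]) {
    return(.invalid_result(method,
      "requires >= 2 genotype groups, each with >= 2 members and positive variance"))
  }
  .test_result(method, statistic = r[1], df = r[2], p.value = r[3],
               direction = as.integer(r[4]), valid = TRUE)
}

#' Standard association test (ordinary least squares)
#'
#' Ordinary least-squares regression of the trait on the female genotype code
#' (0/1/2) ignoring variance heterogeneity, as in conventional GWAS handling
#' of the X chromosome. Two-sided t test of the slope on `n - 2` degrees of
#' freedom.
#'
#' @inheritParams variance_test
#' @return An `"xassoc_result"`; `valid = FALSE` for monomorphic SNPs or
#'   samples of fewer than three individuals.
#' @examples
#' fs <- female_sample(c(0, 0, 1, 1, 2, 2), c(1, -1, 2, -2, 1, -1))
#' standard_association_test(fs)$p.value   # 1: all group means equal
#' @export
standard_association_test <- function(sample) {
  s <- as_female_sample(sample)
  r <- .ols_core(s$genotypes, s$phenotypes)
  method <- "Standard association test (OLS)"
  if (!r[5]) {
    return(.invalid_result(method,
      "requires a polymorphic SNP and >= 3 individuals"))
  }
  .test_result(method, statistic = r[1], df = r[2], p.value = r[3],
               direction = as.integer(r[4]), valid = TRUE)
}

#' Combine two p-values by Stouffer's Z-score method
#'
#' Each p-value is mapped to a Z score by `Z = qnorm(1 - p)` and the weighted
#' sum `(w1 * Z1 + w2 * Z2) / sqrt(w1^2 + w2^2)` is mapped back through the
#' upper tail of the standard normal. With equal weights this is the classic
#' `(Z1 + Z2) / sqrt(2)` combination; with one weight zero it returns the
#' other p-value unchanged. p-values at (or beyond) 0 or 1 are clamped to
#' `[1e-300, 1 - 1e-16]` with a warning before transformation.
#'
#' @param p1,p2 p-values in (0, 1); vectors recycle.
#' @param w1,w2 Non-negative weights, not both zero (default equal weights).
#'
#' @return The combined p-value(s).
#' @examples
#' stouffer_combine(1.1e-6, 0.45)   # ~ 2.9e-4
#' stouffer_combine(5.6e-4, 0.59)   # ~ 0.016
#' @export
stouffer_combine <- function(p1, p2, w1 = 1, w2 = 1) {
  if (any(w1 < 0) || any(w2 < 0) || any(w1 + w2 <= 0)) {
    stop("weights must be non-negative and not both zero", call. = FALSE)
  }
  clamp <- function(p, who) {
    if (any(!is.finite(p))) stop(who, " must be a finite probability", call. = FALSE)
    out <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    if (any(p <= 0 | p >= 1)) {
      warning(who, " outside (0, 1); clamped to [1e-300, 1 - 1e-16]",
              call. = FALSE)
    }
    out
  }
  z1 <- stats::qnorm(clamp(p1, "p1"), lower.tail = FALSE)
  z2 <- stats::qnorm(clamp(p2, "p2"), lower.tail = FALSE)
  zc <- (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2)
  stats::pnorm(zc, lower.tail = FALSE)
}

#' Combined test of variance inflation and weighted association
#'
#' Equal-weight Stouffer combination of the heterozygote-variance test
#' p-value and the weighted association test p-value. The two components
#' respond to complementary features of the data (spread vs location) and are
#' independent under the null, so the combination is calibrated and gains
#' power whenever the variance test contributes signal.
#'
#' @inheritParams variance_test
#' @return An `"xassoc_result"` whose `statistic` is the combined Z score
#'   (`df` absent); `valid = FALSE` if either component test is invalid.
#'   `direction` is inherited from the weighted slope.
#' @examples
#' set.seed(1)
#' g <- rbinom(800, 2, 0.3)
#' y <- 0.1 * g + rnorm(800) + (g == 1) * rnorm(800, 0, 0.5)
#' combined_test(female_sample(g, y))
#' @export
combined_test <- function(sample, alternative = c("greater", "two.sided")) {
  s <- as_female_sample(sample)
  alt <- .match_alternative(alternative)
  v <- .var_core(s$genotypes, s$phenotypes, alt)
  w <- .wls_core(s$genotypes, s$phenotypes)
  method <- "Combined variance + weighted association test (Stouffer)"
  if (!v[5] || !w[5]) {
    return(.invalid_result(method, "a component test is invalid"))
  }
  p <- stouffer_combine(v[3], w[3])
  .test_result(method, statistic = stats::qnorm(p, lower.tail = FALSE),
               df = NA_real_, p.value = p, direction = as.integer(w[4]),
               valid = TRUE)
}

# All four p-values on raw vectors, in the order
# (standard, variance, weighted, combined); NA where a test is invalid.
# Shared by the scenario runner and the chromosome scan.
.four_pvalues <- function(g, y, alternative = 1L) {
  ps <- .ols_core(g, y)[3]
  pv <- .var_core(g, y, alternative)[3]
  pw <- .wls_core(g, y)[3]
  pc <- if (!is.na(pv) && !is.na(pw)) {
    zc <- (stats::qnorm(min(max(pv, 1e-300), 1 - 1e-16), lower.tail = FALSE) +
           stats::qnorm(min(max(pw, 1e-300), 1 - 1e-16), lower.tail = FALSE)) / sqrt(2)
    stats::pnorm(zc, lower.tail = FALSE)
  } else {
    NA_real_
  }
  c(standard = ps, variance = pv, weighted = pw, combined = pc)
}
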