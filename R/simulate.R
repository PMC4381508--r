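#' Specify one simulation scenario
#'
#' Collects the parameters of a single Monte-Carlo scenario: genotypes are
#' drawn under Hardy-Weinberg equilibrium at minor allele frequency `maf`,
#' and phenotypes follow the X-inactivation model `y = mu + g + e` with
#' `e ~ N(0, sigma2)`. The QTL's additive (per-allele) effect is `a`, so the
#' two homozygote classes sit `2 * a` apart; a heterozygous female expresses
#' one of her two alleles and takes the genotypic value of either homozygote,
#' the trait-raising one with probability `theta` (0.5 = balanced random
#' X-inactivation). Extra heterozygote-specific noise with variance
#' `extra_noise_frac * sigma2` models variance heterogeneity beyond
#' X-inactivation.
#'
#' @param n Number of females per replicate.
#' @param maf Minor allele frequency of the QTL, in (0, 0.5].
#' @param a Additive per-allele effect (trait units); the expressed-genotype
#'   gap of a heterozygote is `2 * a`.
#' @param theta Inactivation ratio in `[0, 1]`: probability that a
#'   heterozygote expresses the trait-raising allele. 0.5 reproduces complete
#'   uniform random X-inactivation; 0 or 1 is complete skewing (no
#'   heterozygote variance inflation).
#' @param extra_noise_frac Variance of additional heterozygote-only noise, as
#'   a fraction of `sigma2` (0, 0.1 and 0.2 are the levels studied in the
#'   power tables).
#' @param mu Population mean (default 0; all tests are location invariant).
#' @param sigma2 Residual variance (default 1, a standard normal error).
#' @param alpha Per-test significance level for rejection rates.
#' @param replicates Number of Monte-Carlo replicates (default 20000; use
#'   1e5 for full-precision table reproduction).
#' @param seed Integer seed; the scenario result is fully reproducible from
#'   the spec.
#' @param null_model If `TRUE` the phenotype is drawn independently of the
#'   genotype (`y = mu + e`), for type-I error studies.
#'
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec(n = 1000, maf = 0.3, a = 0.1, replicates = 500, seed = 1)
#' @export
scenario_spec <- function(n, maf, a = 0, theta = 0.5, extra_noise_frac = 0,
                          mu = 0, sigma2 = 1, alpha = 0.05,
                          replicates = 20000L, seed = 1L,
                          null_model = FALSE) {
  stopifnot(n >= 1, maf > 0, maf <= 0.5, theta >= 0, theta <= 1,
            extra_noise_frac >= 0, sigma2 > 0, alpha > 0, alpha < 1,
            replicates >= 1)
  structure(list(
    n = as.integer(n), maf = maf, a = a, theta = theta,
    extra_noise_frac = extra_noise_frac, mu = mu, sigma2 = sigma2,
    alpha = alpha, replicates = as.integer(replicates),
    seed = as.integer(seed), null_model = isTRUE(null_model)),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario: n = %d, MAF = %g, a = %g, theta = %g, extra noise = %g%%%s\n",
    x$n, x$maf, x$a, x$theta, 100 * x$extra_noise_frac,
    if (x$null_model) " [null model]" else ""))
  cat(sprintf("  mu = %g, sigma2 = %g, alpha = %g, replicates = %d, seed = %d\n",
              x$mu, x$sigma2, x$alpha, x$replicates, x$seed))
  invisible(x)
}

#' Simulate female genotypes under Hardy-Weinberg equilibrium
#'
#' Each genotype code (count of the minor allele) is drawn independently with
#' probabilities `(1 - p)^2`, `2 p (1 - p)`, `p^2` for codes 0, 1, 2, i.e.
#' as a Binomial(2, `maf`) draw. Uses the current R random-number stream.
#'
#' @param n Number of females.
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Integer vector of genotype codes.
#' @examples
#' set.seed(1)
#' table(simulate_genotypes(1000, 0.3))
#' @export
simulate_genotypes <- function(n, maf) {
  stopifnot(n >= 1, maf > 0, maf <= 0.5)
  stats::rbinom(n, 2L, maf)
}

#' Simulate phenotypes under the X-inactivation model
#'
#' Given genotype codes and a [scenario_spec()], draws one phenotype vector.
#' Homozygotes take genotypic values 0 (code 0) and `2 * a` (code 2). Each
#' heterozygote expresses one allele: genotypic value `2 * a` with
#' probability `theta`, else 0, which inflates the heterozygote phenotypic
#' variance by `theta * (1 - theta) * (2 * a)^2` (see
#' [expected_het_variance()]). Residual error is `N(0, sigma2)`;
#' heterozygotes optionally receive independent extra noise with variance
#' `extra_noise_frac * sigma2`. Under `null_model` the phenotype is
#' `mu + e`, independent of genotype.
#'
#' @param genotypes Integer vector of codes in `{0, 1, 2}`.
#' @param spec A [scenario_spec()].
#' @return Numeric phenotype vector. Uses the current R random-number stream.
#' @examples
#' sp <- scenario_spec(n = 500, maf = 0.3, a = 0.5, seed = 1)
#' set.seed(1)
#' g <- simulate_genotypes(sp$n, sp$maf)
#' y <- simulate_phenotypes(g, sp)
#' @export
simulate_phenotypes <- function(genotypes, spec) {
  n <- length(genotypes)
  sd_e <- sqrt(spec$sigma2)
  if (spec$null_model) {
    return(spec$mu + stats::rnorm(n, 0, sd_e))
  }
  d <- 2 * spec$a
  gv <- numeric(n)
  gv[genotypes == 2L] <- d
  het <- genotypes == 1L
  nh <- sum(het)
  if (nh > 0L) gv[het] <- d * stats::rbinom(nh, 1L, spec$theta)
  y <- spec$mu + gv + stats::rnorm(n, 0, sd_e)
  if (spec$extra_noise_frac > 0 && nh > 0L) {
    y[het] <- y[het] +
      stats::rnorm(nh, 0, sqrt(spec$extra_noise_frac * spec$sigma2))
  }
  y
}

#' Analytic heterozygote phenotypic variance
#'
#' Closed-form variance of the trait among heterozygous females under the
#' X-inactivation model: expressing one of two genotypic values `d` apart
#' with probability `theta` contributes Bernoulli variance
#' `theta * (1 - theta) * d^2` on top of the residual variance (including any
#' heterozygote-specific extra noise). Serves as the analytic oracle for
#' [simulate_phenotypes()].
#'
#' @param d Gap between the two expressed genotypic values (for a scenario
#'   with additive per-allele effect `a`, `d = 2 * a`).
#' @param theta Inactivation ratio in `[0, 1]`.
#' @param sigma2 Residual variance.
#' @param extra_noise_frac Heterozygote extra-noise variance as a fraction of
#'   `sigma2`.
#' @return The heterozygote phenotypic variance
#'   `theta * (1 - theta) * d^2 + sigma2 * (1 + extra_noise_frac)`.
#' @examples
#' expected_het_variance(1, 0.5)    # 1.25
#' expected_het_variance(1, 0.75)   # 1.1875
#' @export
expected_het_variance <- function(d, theta, sigma2 = 1, extra_noise_frac = 0) {
  stopifnot(sigma2 > 0, theta >= 0, theta <= 1, extra_noise_frac >= 0)
  theta * (1 - theta) * d^2 + sigma2 * (1 + extra_noise_frac)
}

# Save/restore the global RNG state so scenario runs do not disturb the
# caller's stream.
.hold_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.release_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Run one Monte-Carlo scenario
#'
#' Simulates `replicates` independent datasets under the scenario, applies
#' all four tests (standard, variance, weighted, combined) to each, and
#' reports the fraction of valid results with p-value below `alpha` --- the
#' type-I error rate under `null_model`, the power otherwise. Also records
#' the joint rejection rate of the standard and variance tests together with
#' the product of their marginal rates (the value expected were the two tests
#' independent), and per-test Monte-Carlo standard errors
#' `sqrt(r * (1 - r) / replicates_used)`.
#'
#' Reproducibility: the scenario seeds a dedicated L'Ecuyer-CMRG stream and
#' draws each replicate from its own RNG substream, so results are
#' bit-identical for identical specs and independent of replicate order; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [scenario_spec()].
#' @param alternative Sidedness of the variance test (and of the variance
#'   component inside the combined test): `"greater"` (default) or
#'   `"two.sided"`.
#' @return An object of class `"scenario_result"`: a list with `spec`,
#'   `rates` (named rejection rates for standard/variance/weighted/combined),
#'   `mc_se`, `joint` (standard AND variance), `expected_joint` (product of
#'   marginals), `replicates_used` (valid replicates per test) and
#'   `n_invalid`.
#' @examples
#' sp <- scenario_spec(n = 300, maf = 0.3, a = 0.2, replicates = 200, seed = 7)
#' run_scenario(sp)
#' @export
run_scenario <- function(spec, alternative = c("greater", "two.sided")) {
  stopifnot(inherits(spec, "scenario_spec"))
  alt <- .match_alternative(alternative)
  held <- .hold_rng()
  on.exit(.release_rng(held))
  set.seed(spec$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  R <- spec$replicates
  pmat <- matrix(NA_real_, R, 4L)
  for (r in seq_len(R)) {
    assign(".Random.seed", stream, envir = globalenv())
    g <- stats::rbinom(spec$n, 2L, spec$maf)
    y <- simulate_phenotypes(g, spec)
    pmat[r, ] <- .four_pvalues(g, y, alt)
    stream <- parallel::nextRNGSubStream(stream)
  }
  valid <- !is.na(pmat)
  used <- colSums(valid)
  rej <- pmat < spec$alpha
  rates <- colSums(rej, na.rm = TRUE) / used
  names(rates) <- names(used) <- c("standard", "variance", "weighted", "combined")
  both <- valid[, 1L] & valid[, 2L]
  joint <- if (any(both)) mean(rej[both, 1L] & rej[both, 2L]) else NA_real_
  structure(list(
    spec = spec,
    alternative = c("greater", "two.sided")[alt],
    rates = rates,
    mc_se = sqrt(rates * (1 - rates) / used),
    joint = joint,
    expected_joint = unname(rates[1L] * rates[2L]),
    replicates_used = used,
    n_invalid = R - used), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %s rate at alpha = %g (%% of %d replicates):\n",
              if (x$spec$null_model) "Type-I error" else "Rejection",
              x$spec$alpha, x$spec$replicates))
  cat(sprintf("    standard %.1f | variance %.1f | weighted %.1f | combined %.1f\n",
              100 * x$rates[1], 100 * x$rates[2], 100 * x$rates[3],
              100 * x$rates[4]))
  cat(sprintf("    standard & variance jointly: %.1f (%.1f expected under independence)\n",
              100 * x$joint, 100 * x$expected_joint))
  if (any(x$n_invalid > 0)) {
    cat("    invalid replicates:",
        paste(sprintf("%s %d", names(x$n_invalid), x$n_invalid), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Run a grid of simulation scenarios
#'
#' Evaluates [run_scenario()] for every row of a scenario table and returns
#' (optionally writes) a results table mirroring the layout of the type-I
#' error and power tables: one row per scenario with the four rejection rates
#' in percent plus the joint and independence-expected standard-and-variance
#' rates.
#'
#' @param scenarios A data frame, or path to a whitespace/tab-delimited file
#'   with a header row, with columns `n` and `maf` and optionally `a`,
#'   `theta`, `extra_noise_frac`, `mu`, `sigma2`, `alpha`, `replicates`,
#'   `seed`, `null_model` (missing columns take the [scenario_spec()]
#'   defaults; `seed` defaults to the row number).
#' @param out Optional path; when given, the results table is written there
#'   as a tab-delimited file.
#' @inheritParams run_scenario
#' @param verbose Print each scenario result as it completes.
#' @return A data frame with the scenario parameters and columns `standard`,
#'   `variance`, `weighted`, `combined`, `joint_std_var`, `expected_joint`
#'   (percentages), `mc_se_max` (percent), and `invalid_max`.
#' @export
run_scenario_grid <- function(scenarios, out = NULL,
                              alternative = c("greater", "two.sided"),
                              verbose = FALSE) {
  if (is.character(scenarios)) {
    scenarios <- utils::read.table(scenarios, header = TRUE,
                                   stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(scenarios), all(c("n", "maf") %in% names(scenarios)))
  defaults <- list(a = 0, theta = 0.5, extra_noise_frac = 0, mu = 0,
                   sigma2 = 1, alpha = 0.05, replicates = 20000L,
                   null_model = FALSE)
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    row <- as.list(scenarios[i, , drop = FALSE])
    for (nm in names(defaults)) if (is.null(row[[nm]])) row[[nm]] <- defaults[[nm]]
    if (is.null(row$seed)) row$seed <- i
    sp <- scenario_spec(n = row$n, maf = row$maf, a = row$a,
                        theta = row$theta,
                        extra_noise_frac = row$extra_noise_frac,
                        mu = row$mu, sigma2 = row$sigma2, alpha = row$alpha,
                        replicates = row$replicates, seed = row$seed,
                        null_model = as.logical(row$null_model))
    res <- run_scenario(sp, alternative)
    if (verbose) print(res)
    data.frame(
      n = sp$n, maf = sp$maf, a = sp$a, theta = sp$theta,
      extra_noise_frac = sp$extra_noise_frac, alpha = sp$alpha,
      replicates = sp$replicates, seed = sp$seed,
      null_model = sp$null_model,
      standard = 100 * res$rates[["standard"]],
      variance = 100 * res$rates[["variance"]],
      weighted = 100 * res$rates[["weighted"]],
      combined = 100 * res$rates[["combined"]],
      joint_std_var = 100 * res$joint,
      expected_joint = 100 * res$expected_joint,
      mc_se_max = 100 * max(res$mc_se),
      invalid_max = max(res$n_invalid))
  })
  result <- do.call(rbind, rows)
  rownames(result) <- NULL
  if (!is.null(out)) {
    utils::write.table(result, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  result
}
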