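# Independent oracles used across the test files. These deliberately take
# different computational routes from the package code they check.

# Weighted least-squares slope and its t statistic by explicitly solving the
# two normal equations X'WX beta = X'Wy with solve().
wls_normal_equations <- function(g, y, w) {
  X <- cbind(1, g)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * y)
  beta <- solve(XtWX, XtWy)
  resid <- y - X %*% beta
  sigma2 <- sum(w * resid^2) / (length(y) - 2)
  covb <- sigma2 * solve(XtWX)
  list(slope = beta[2], se = sqrt(covb[2, 2]),
       statistic = beta[2] / sqrt(covb[2, 2]))
}

# Exact HWE distribution by direct evaluation of the conditional probability
# of each genotype configuration with factorial() (exact in double precision
# for <= 30 alleles), rather than the package's log-gamma recurrence route.
hwe_enumeration_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n0 + n1           # allele "a" count (symmetric in the labelling)
  if (na == 0 || na == 2 * n) return(1)
  configs <- list()
  for (h in 0:min(na, 2 * n - na)) {
    if ((na - h) %% 2 != 0) next
    aa <- (na - h) / 2
    bb <- n - h - aa
    if (aa < 0 || bb < 0) next
    prob <- factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) *
      2^h * factorial(na) * factorial(2 * n - na) / factorial(2 * n)
    configs[[length(configs) + 1]] <- c(h = h, prob = prob)
  }
  tab <- do.call(rbind, configs)
  obs <- tab[tab[, "h"] == n1, "prob"]
  min(1, sum(tab[tab[, "prob"] <= obs * (1 + 1e-10), "prob"]))
}

# One simulated dataset under the X-inactivation phenotype model, bypassing
# scenario_spec (used where a raw (g, y) pair is handy).
sim_dataset <- function(n, maf, a = 0, theta = 0.5, noise = 0, null = FALSE) {
  g <- rbinom(n, 2L, maf)
  if (null) return(list(g = g, y = rnorm(n)))
  gv <- numeric(n)
  gv[g == 2L] <- 2 * a
  het <- g == 1L
  gv[het] <- 2 * a * rbinom(sum(het), 1L, theta)
  y <- gv + rnorm(n)
  if (noise > 0) y[het] <- y[het] + rnorm(sum(het), 0, sqrt(noise))
  list(g = g, y = y)
}
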