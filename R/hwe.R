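#' Exact test of Hardy-Weinberg equilibrium from female genotype counts
#'
#' Exact conditional test of Hardy-Weinberg proportions given the observed
#' genotype counts of a biallelic SNP. Conditional on the allele counts, the
#' number of heterozygotes under HWE follows the classical exact distribution
#' `P(n_het) = n! / (n_AA! n_Aa! n_aa!) * 2^n_het * n_A! n_a! / (2n)!`;
#' the p-value is the total probability of all heterozygote counts no more
#' probable than the observed one (the standard exact test, no mid-p
#' correction, as in common GWAS toolkits).
#'
#' @param n0,n1,n2 Non-negative genotype counts (major homozygote,
#'   heterozygote, minor homozygote; the labelling is symmetric).
#' @return The exact p-value in (0, 1]; monomorphic SNPs return 1.
#' @examples
#' hwe_exact_test_females(0, 2, 0)
#' hwe_exact_test_females(50, 0, 50)   # extreme heterozygote deficit
#' @export
hwe_exact_test_females <- function(n0, n1, n2) {
  n0 <- as.integer(n0); n1 <- as.integer(n1); n2 <- as.integer(n2)
  stopifnot(length(n0) == 1L, length(n1) == 1L, length(n2) == 1L,
            n0 >= 0L, n1 >= 0L, n2 >= 0L)
  n <- n0 + n1 + n2
  if (n < 1L) stop("at least one genotype required", call. = FALSE)
  rare <- min(2L * n0 + n1, 2L * n2 + n1)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  hom_rare <- (rare - hets) %/% 2L
  hom_common <- n - hets - hom_rare
  keep <- hom_common >= 0L
  hets <- hets[keep]; hom_rare <- hom_rare[keep]; hom_common <- hom_common[keep]
  logp <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(hets + 1) -
    lgamma(hom_common + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2L * n - rare + 1) - lgamma(2L * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n1, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-10)]))
}
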