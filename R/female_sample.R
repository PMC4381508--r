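#' Construct a female genotype-phenotype sample
#'
#' Bundles the genotype codes and quantitative trait values of the female
#' individuals analysed at one SNP. Genotype codes count copies of the
#' reference (conventionally the minor) allele, so heterozygotes carry code 1.
#' Pairs with a missing genotype or phenotype are dropped before construction;
#' all tests in this package operate on the complete pairs only.
#'
#' @param genotypes Integer-like vector of genotype codes in `{0, 1, 2}`;
#'   `NA` entries allowed (dropped pairwise).
#' @param phenotypes Numeric vector of trait values, same length as
#'   `genotypes`; `NA` entries allowed (dropped pairwise).
#'
#' @return An object of class `"female_sample"`: a list with elements
#'   `genotypes` (integer), `phenotypes` (double) and `n` (number of complete
#'   pairs).
#'
#' @examples
#' fs <- female_sample(c(0, 1, 1, 2, NA), c(0.3, -1.2, 0.8, 2.1, 0.0))
#' fs$n
#' @export
female_sample <- function(genotypes, phenotypes) {
  if (length(genotypes) != length(phenotypes)) {
    stop("genotypes and phenotypes must have identical length", call. = FALSE)
  }
  keep <- !(is.na(genotypes) | is.na(phenotypes))
  g <- genotypes[keep]
  y <- as.numeric(phenotypes[keep])
  if (length(g) == 0L) {
    stop("no complete genotype-phenotype pairs", call. = FALSE)
  }
  gi <- as.integer(round(as.numeric(g)))
  if (any(gi < 0L | gi > 2L) || any(abs(as.numeric(g) - gi) > 1e-8)) {
    stop("genotype codes must be 0, 1, or 2", call. = FALSE)
  }
  structure(list(genotypes = gi, phenotypes = y, n = length(gi)),
            class = "female_sample")
}

#' Coerce to a female sample
#'
#' @param x A `"female_sample"`, or a list with elements `genotypes` and
#'   `phenotypes`.
#' @return A `"female_sample"` object.
#' @export
as_female_sample <- function(x) {
  if (inherits(x, "female_sample")) return(x)
  if (is.list(x) && !is.null(x$genotypes) && !is.null(x$phenotypes)) {
    return(female_sample(x$genotypes, x$phenotypes))
  }
  stop("cannot coerce to female_sample: supply genotypes and phenotypes",
       call. = FALSE)
}

#' @export
print.female_sample <- function(x, ...) {
  tab <- tabulate(x$genotypes + 1L, nbins = 3L)
  cat(sprintf(
    "Female sample: %d individuals (n0 = %d, n1 = %d, n2 = %d)\n",
    x$n, tab[1L], tab[2L], tab[3L]))
  invisible(x)
}
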