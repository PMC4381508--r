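#' Write a small synthetic PLINK fixture for scan testing
#'
#' Generates a self-contained bed/bim/fam fileset plus a tab-delimited
#' phenotype file, used to exercise the scan pipeline end to end. Three
#' flavours are available:
#'
#' * `"qc"`: 10 SNPs with three planted quality-control violations (one SNP
#'   below the MAF threshold, one above the missingness threshold, one with
#'   an extreme heterozygote deficit failing the female HWE test) plus one
#'   female with a high genotype missing rate and two males; exactly 7 SNPs
#'   survive the default QC.
#' * `"vqtl"`: SNPs in Hardy-Weinberg proportions with a phenotype whose
#'   variance (but not mean) is inflated in heterozygotes of one planted SNP
#'   --- a pure variance QTL that the heterozygote-variance test detects and
#'   the standard test does not.
#' * `"null"`: genotypes and an independent standard-normal trait.
#'
#' @param prefix Output fileset prefix; writes `<prefix>.bed`, `.bim`,
#'   `.fam` and `<prefix>.pheno`.
#' @param type Fixture flavour.
#' @param n Number of females (ignored by `"qc"`, which is a fixed design).
#' @param n_snps Number of SNPs (ignored by `"qc"`).
#' @param maf Minor allele frequency used for random genotypes.
#' @param het_extra_var Extra phenotype variance (in units of the residual
#'   variance 1) given to heterozygotes of the planted SNP in the `"vqtl"`
#'   fixture.
#' @param seed Integer seed; the fixture is reproducible.
#' @return Invisibly, a list with `prefix`, `type`, `planted` (SNP ID of the
#'   planted variance QTL, or `NA`) and `expected_qc_survivors`.
#' @export
write_scan_fixture <- function(prefix, type = c("qc", "vqtl", "null"),
                               n = 500L, n_snps = 20L, maf = 0.3,
                               het_extra_var = 1.5, seed = 1L) {
  type <- match.arg(type)
  held <- .hold_rng()
  on.exit(.release_rng(held))
  set.seed(seed)
  if (type == "qc") {
    out <- .qc_fixture(prefix)
  } else {
    nf <- as.integer(n)
    m <- as.integer(n_snps)
    G <- matrix(stats::rbinom(nf * m, 2L, maf), nf, m)
    iid <- sprintf("f%04d", seq_len(nf))
    rownames(G) <- iid
    y <- stats::rnorm(nf)
    planted <- NA_character_
    if (type == "vqtl") {
      j <- max(1L, m %/% 2L)
      planted <- sprintf("snp%03d", j)
      het <- G[, j] == 1L
      y[het] <- y[het] + stats::rnorm(sum(het), 0, sqrt(het_extra_var))
    }
    fam <- data.frame(fid = iid, iid = iid, pat = 0L, mat = 0L, sex = 2L,
                      pheno = -9L)
    bim <- data.frame(chr = "X", snp_id = sprintf("snp%03d", seq_len(m)),
                      cm = 0L, pos = 100000L * seq_len(m), a1 = "A", a2 = "C")
    write_plink(G, fam, bim, prefix)
    utils::write.table(data.frame(iid = iid, trait1 = y),
                       paste0(prefix, ".pheno"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- list(prefix = prefix, type = type, planted = planted,
                expected_qc_survivors = m)
  }
  invisible(out)
}

# Fixed 10-SNP QC fixture: 60 clean females, 1 high-missingness female,
# 2 males. SNPs 1-7 pass all filters; snp008 has MAF 1/120, snp009 has 8/60
# calls missing, snp010 has a total heterozygote deficit (40/0/20).
.qc_fixture <- function(prefix) {
  nf <- 61L
  iid <- c(sprintf("f%02d", 1:61), "m01", "m02")
  m <- 10L
  G <- matrix(0L, 63L, m, dimnames = list(iid, NULL))
  clean <- c(rep(0L, 29L), rep(1L, 25L), rep(2L, 6L))
  for (j in 1:7) {
    # rotate the clean pattern so the seven SNPs are not identical columns
    G[1:60, j] <- clean[(seq.int(0L, 59L) + 7L * j) %% 60L + 1L]
  }
  G[1:60, 8L] <- c(1L, rep(0L, 59L))
  G[1:60, 9L] <- c(rep(NA_integer_, 8L), rep(0L, 26L), rep(1L, 20L), rep(2L, 6L))
  G[1:60, 10L] <- c(rep(0L, 40L), rep(2L, 20L))
  # female 61: missing at 6 of 10 SNPs -> individual missing rate 60%
  G[61L, 1:6] <- NA_integer_
  sex <- c(rep(2L, 61L), 1L, 1L)
  fam <- data.frame(fid = iid, iid = iid, pat = 0L, mat = 0L, sex = sex,
                    pheno = -9L)
  bim <- data.frame(chr = "X", snp_id = sprintf("snp%03d", 1:10), cm = 0L,
                    pos = 100000L * (1:10), a1 = "A", a2 = "C")
  write_plink(G, fam, bim, prefix)
  y <- stats::rnorm(63L)
  utils::write.table(data.frame(iid = iid, trait1 = y),
                     paste0(prefix, ".pheno"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(prefix = prefix, type = "qc", planted = NA_character_,
                 expected_qc_survivors = 7L))
}
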