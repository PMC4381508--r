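#' Read a phenotype table
#'
#' Tab-delimited file with a header row; the first column holds sample IDs
#' matching the fam file's individual IDs, remaining columns are quantitative
#' traits.
#'
#' @param path Path to the phenotype file.
#' @return A data frame; the first column is character, trait columns numeric.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(ph) < 2L) {
    stop("phenotype file needs a sample-ID column plus at least one trait",
         call. = FALSE)
  }
  ph[[1L]] <- as.character(ph[[1L]])
  for (j in 2:ncol(ph)) ph[[j]] <- as.numeric(ph[[j]])
  ph
}

#' Apply standard GWAS quality control to a PLINK dataset
#'
#' Restricts to females, removes individuals with a high genotype missing
#' rate, then filters SNPs on (in this order, configurable) missing rate,
#' minor allele frequency and the exact Hardy-Weinberg test in females.
#' Thresholds follow PLINK's exclusion conventions: an individual or SNP is
#' excluded when its missing rate exceeds the threshold, a SNP when its MAF
#' or female HWE p-value falls below the threshold. The defaults (MAF 5%,
#' missing rates 10%, HWE p 5e-5) are the standard GWAS QC settings.
#' Surviving SNPs are recoded so that genotype codes count the minor allele
#' among the retained females. Each excluded SNP is attributed to the first
#' filter it fails.
#'
#' @param plink A `"plink_data"` from [read_plink()], or a list with elements
#'   `genotypes`, `bim`, `fam` of the same shape.
#' @param maf MAF threshold (exclude below).
#' @param snp_miss SNP missing-rate threshold (exclude above).
#' @param ind_miss Individual missing-rate threshold (exclude above).
#' @param hwe Female HWE exact-p threshold (exclude below).
#' @param female_code Sex code in the fam file that denotes females
#'   (PLINK convention: 2).
#' @param snp_filter_order Order in which the three SNP filters are applied
#'   for exclusion attribution; individuals are always filtered first.
#' @param verbose Emit a log of exclusion tallies.
#' @return An object of class `"xwas_qc"`: `genotypes` (retained females x
#'   surviving SNPs, minor-allele counts), `snps` (per-SNP records for all
#'   input SNPs: identifiers, positions, alleles as minor/major, female
#'   genotype counts, `maf`, `call_rate`, `hwe_p`, `qc_pass`, `fail`),
#'   `samples` (retained female IDs), `tally` (named exclusion counts) and
#'   `thresholds`.
#' @export
apply_qc <- function(plink, maf = 0.05, snp_miss = 0.10, ind_miss = 0.10,
                     hwe = 5e-5, female_code = 2,
                     snp_filter_order = c("missingness", "maf", "hwe"),
                     verbose = TRUE) {
  snp_filter_order <- match.arg(snp_filter_order, several.ok = TRUE)
  if (length(unique(snp_filter_order)) != 3L) {
    stop("snp_filter_order must be a permutation of missingness, maf, hwe",
         call. = FALSE)
  }
  G <- plink$genotypes
  fam <- plink$fam
  bim <- plink$bim
  is_female <- fam$sex == female_code
  n_males <- sum(!is_female)
  Gf <- G[is_female, , drop = FALSE]
  # individual missingness first, on females across all SNPs
  ind_rate <- rowMeans(is.na(Gf))
  keep_ind <- ind_rate <= ind_miss
  Gf <- Gf[keep_ind, , drop = FALSE]
  nf <- nrow(Gf)
  m <- ncol(Gf)
  rec <- data.frame(
    snp_id = bim$snp_id, chr = bim$chr, pos = bim$pos,
    a1 = bim$a1, a2 = bim$a2,
    n0 = NA_integer_, n1 = NA_integer_, n2 = NA_integer_,
    n_missing = NA_integer_, maf = NA_real_, call_rate = NA_real_,
    hwe_p = NA_real_, qc_pass = FALSE, fail = NA_character_,
    stringsAsFactors = FALSE)
  flip <- logical(m)
  for (j in seq_len(m)) {
    gj <- Gf[, j]
    called <- !is.na(gj)
    nc <- sum(called)
    rec$n_missing[j] <- nf - nc
    rec$call_rate[j] <- if (nf > 0) nc / nf else 0
    if (nc == 0L) {
      rec$n0[j] <- rec$n1[j] <- rec$n2[j] <- 0L
      rec$maf[j] <- 0; rec$hwe_p[j] <- 1
      next
    }
    af1 <- mean(gj[called]) / 2            # frequency of allele a1
    flip[j] <- af1 > 0.5                   # minor allele is a2: recode
    if (flip[j]) {
      gj[called] <- 2L - gj[called]
      rec$a1[j] <- bim$a2[j]; rec$a2[j] <- bim$a1[j]
    }
    cnt <- tabulate(gj[called] + 1L, nbins = 3L)
    rec$n0[j] <- cnt[1L]; rec$n1[j] <- cnt[2L]; rec$n2[j] <- cnt[3L]
    rec$maf[j] <- (cnt[2L] + 2L * cnt[3L]) / (2L * nc)
    rec$hwe_p[j] <- hwe_exact_test_females(cnt[1L], cnt[2L], cnt[3L])
  }
  fails <- list(
    missingness = (1 - rec$call_rate) > snp_miss,
    maf = rec$maf < maf,
    hwe = rec$hwe_p < hwe)
  fail_lab <- rep(NA_character_, m)
  for (f in rev(snp_filter_order)) fail_lab[fails[[f]]] <- f
  rec$fail <- fail_lab
  rec$qc_pass <- is.na(fail_lab)
  Gout <- Gf[, rec$qc_pass, drop = FALSE]
  surv <- which(rec$qc_pass)
  for (k in seq_along(surv)) {
    if (flip[surv[k]]) Gout[, k] <- 2L - Gout[, k]
  }
  colnames(Gout) <- rec$snp_id[surv]
  tally <- c(males = n_males,
             individuals_missingness = sum(!keep_ind),
             snp_missingness = sum(fail_lab == "missingness", na.rm = TRUE),
             snp_maf = sum(fail_lab == "maf", na.rm = TRUE),
             snp_hwe = sum(fail_lab == "hwe", na.rm = TRUE),
             snps_surviving = length(surv))
  if (verbose) {
    message(sprintf(
      "QC: %d females retained (%d male, %d high-missingness excluded); SNP filter order %s",
      nf, n_males, sum(!keep_ind), paste(snp_filter_order, collapse = " -> ")))
    message(sprintf(
      "QC: %d/%d SNPs survive (excluded: %d missingness, %d MAF, %d HWE)",
      length(surv), m, tally[["snp_missingness"]], tally[["snp_maf"]],
      tally[["snp_hwe"]]))
  }
  structure(list(genotypes = Gout, snps = rec, samples = rownames(Gf),
                 tally = tally,
                 thresholds = c(maf = maf, snp_miss = snp_miss,
                                ind_miss = ind_miss, hwe = hwe),
                 snp_filter_order = snp_filter_order),
            class = "xwas_qc")
}

#' @export
print.xwas_qc <- function(x, ...) {
  cat(sprintf("XWAS QC: %d females x %d surviving SNPs (of %d input)\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$snps)))
  cat("  exclusions:",
      paste(sprintf("%s %d", names(x$tally), x$tally), collapse = ", "), "\n")
  invisible(x)
}

#' Chromosome-wide association scan with all four tests
#'
#' Runs the standard, heterozygote-variance, weighted and combined tests for
#' every surviving SNP against every requested trait. For each SNP x trait
#' pair the sample is restricted to females with both a called genotype and
#' an observed trait value. Results carry the Bonferroni-corrected
#' significance threshold `alpha / n_snps_tested`.
#'
#' @param qc An `"xwas_qc"` object from [apply_qc()] (QC is assumed done),
#'   or a list with `genotypes` (females x SNPs minor-allele counts, sample
#'   IDs as rownames) and `snps` (data frame with `snp_id`, `chr`, `pos`).
#' @param phenotypes Data frame whose first column holds sample IDs (see
#'   [read_phenotypes()]), or a numeric matrix with sample rownames.
#' @param traits Character vector of trait columns to test (default: all).
#' @param alpha Genome-wide significance level used for the Bonferroni
#'   threshold.
#' @param alternative Sidedness of the variance test component.
#' @return An object of class `"scan_table"`: `results` (one row per SNP x
#'   trait, sorted by position, with per-test `statistic`, `df`, `p`,
#'   `valid` columns), `bonferroni_threshold`, `n_snps_tested`, `alpha`,
#'   `traits`.
#' @export
run_scan <- function(qc, phenotypes, traits = NULL, alpha = 0.05,
                     alternative = c("greater", "two.sided")) {
  alt <- .match_alternative(alternative)
  G <- qc$genotypes
  snps <- qc$snps
  if (!is.null(snps$qc_pass)) snps <- snps[snps$qc_pass, , drop = FALSE]
  snps <- snps[match(colnames(G), snps$snp_id), , drop = FALSE]
  if (is.data.frame(phenotypes)) {
    ids <- as.character(phenotypes[[1L]])
    ph <- as.matrix(phenotypes[, -1L, drop = FALSE])
    rownames(ph) <- ids
  } else {
    ph <- as.matrix(phenotypes)
  }
  if (is.null(traits)) traits <- colnames(ph)
  missing_traits <- setdiff(traits, colnames(ph))
  if (length(missing_traits)) {
    stop("traits not in phenotype table: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  common <- intersect(rownames(G), rownames(ph))
  if (length(common) == 0L) {
    stop("no sample IDs shared between genotypes and phenotypes",
         call. = FALSE)
  }
  G <- G[common, , drop = FALSE]
  ph <- ph[common, traits, drop = FALSE]
  m <- ncol(G)
  tests <- c("standard", "variance", "weighted", "combined")
  rows <- vector("list", m * length(traits))
  k <- 0L
  for (tr in traits) {
    yall <- ph[, tr]
    for (j in seq_len(m)) {
      gj <- G[, j]
      ok <- !is.na(gj) & !is.na(yall)
      g <- gj[ok]; y <- yall[ok]
      cnt <- tabulate(g + 1L, nbins = 3L)
      cores <- list(
        standard = .ols_core(g, y),
        variance = .var_core(g, y, alt),
        weighted = .wls_core(g, y))
      cores$combined <- if (cores$variance[5] && cores$weighted[5]) {
        p <- stouffer_combine(cores$variance[3], cores$weighted[3])
        c(stats::qnorm(p, lower.tail = FALSE), NA, p, cores$weighted[4], 1)
      } else {
        c(NA, NA, NA, NA, 0)
      }
      row <- list(snp_id = snps$snp_id[j], chr = snps$chr[j],
                  pos = snps$pos[j], trait = tr,
                  maf = if (!is.null(snps$maf)) snps$maf[j] else
                    (cnt[2L] + 2L * cnt[3L]) / (2L * max(sum(cnt), 1L)),
                  n0 = cnt[1L], n1 = cnt[2L], n2 = cnt[3L])
      for (t in tests) {
        cr <- cores[[t]]
        row[[paste0(t, "_stat")]] <- cr[1]
        row[[paste0(t, "_df")]] <- cr[2]
        row[[paste0(t, "_p")]] <- cr[3]
        row[[paste0(t, "_valid")]] <- as.logical(cr[5])
      }
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  res <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  res <- res[order(res$trait, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res,
                 bonferroni_threshold = alpha / m,
                 n_snps_tested = m, alpha = alpha, traits = traits),
            class = "scan_table")
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf(
    "Association scan: %d SNPs x %d trait(s); Bonferroni threshold %.3g (alpha = %g)\n",
    x$n_snps_tested, length(x$traits), x$bonferroni_threshold, x$alpha))
  for (t in c("standard", "variance", "weighted", "combined")) {
    p <- x$results[[paste0(t, "_p")]]
    i <- which.min(p)
    if (length(i)) {
      cat(sprintf("  top %-8s: %s (%s) p = %.3g%s\n", t,
                  x$results$snp_id[i], x$results$trait[i], p[i],
                  if (p[i] < x$bonferroni_threshold) " *chromosome-wide significant*" else ""))
    }
  }
  invisible(x)
}

#' Write a scan table to a tab-delimited file
#'
#' @param scan A `"scan_table"` from [run_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scan, path) {
  utils::write.table(scan$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fraction of SNPs where the weighted test beats the standard test
#'
#' For each p-value cutoff, restricts to SNP x trait results where at least
#' one of the weighted and standard tests reaches the cutoff (the "top"
#' associations), and reports the fraction of those where the weighted test
#' gives the smaller p-value. Ties count 0.5, so two equally powerful tests
#' give exactly 0.5. A fraction above 0.5 that grows at stringent cutoffs
#' indicates higher power of the weighted test, the signature of variance
#' heterogeneity.
#'
#' @param scan A `"scan_table"` or its `results` data frame.
#' @param cutoffs Numeric vector of p-value cutoffs.
#' @param trait Optional trait name to restrict to.
#' @return A data frame with columns `cutoff`, `n_snps` (selected at that
#'   cutoff) and `fraction` (`NA` when no SNP is selected).
#' @export
power_comparison_fraction <- function(scan, cutoffs = c(0.05, 0.01, 1e-3, 1e-4),
                                      trait = NULL) {
  res <- if (inherits(scan, "scan_table")) scan$results else scan
  if (!is.null(trait)) res <- res[res$trait %in% trait, , drop = FALSE]
  ok <- res$weighted_valid & res$standard_valid
  wp <- res$weighted_p[ok]
  sp <- res$standard_p[ok]
  out <- lapply(cutoffs, function(cu) {
    sel <- pmin(wp, sp) < cu
    n <- sum(sel)
    frac <- if (n > 0L) {
      (sum(wp[sel] < sp[sel]) + 0.5 * sum(wp[sel] == sp[sel])) / n
    } else {
      NA_real_
    }
    data.frame(cutoff = cu, n_snps = n, fraction = frac)
  })
  do.call(rbind, out)
}
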