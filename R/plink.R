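# PLINK 1 binary fileset (bed/bim/fam) reader and writer.
#
# bed layout: magic bytes 0x6c 0x1b, then a mode byte (0x01 = SNP-major),
# then ceiling(n_samples / 4) bytes per SNP, two bits per sample packed
# low-to-high within each byte: 00 = homozygous A1, 01 = missing,
# 10 = heterozygous, 11 = homozygous A2. Genotypes are decoded as counts of
# the A1 allele (the first allele column of the bim file).

# 256 x 4 lookup: byte value + 1 -> the four sample codes it packs.
.plink_decode_lut <- local({
  lut <- matrix(NA_integer_, 256L, 4L)
  map <- c(2L, NA_integer_, 1L, 0L)  # bit pairs 00, 01, 10, 11
  for (b in 0:255) {
    for (k in 0:3) {
      bits <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      lut[b + 1L, k + 1L] <- map[bits + 1L]
    }
  }
  lut
})

#' Read a PLINK binary fileset
#'
#' Reads genotypes from a PLINK 1 bed/bim/fam trio into an integer matrix of
#' A1-allele counts (0/1/2, `NA` = missing), samples in rows (fam order) and
#' SNPs in columns (bim order). Only the SNP-major layout (mode byte 0x01)
#' is supported, which is what all modern tools write.
#'
#' @param bed Path to the `.bed` file, or a fileset prefix (the three paths
#'   are then formed by appending `.bed`/`.bim`/`.fam`).
#' @param bim,fam Paths to the `.bim` and `.fam` files; defaults derived from
#'   `bed`.
#' @return A list of class `"plink_data"`: `genotypes` (integer matrix,
#'   `dimnames` = sample IDs x SNP IDs), `bim` (data frame: `chr`, `snp_id`,
#'   `cm`, `pos`, `a1`, `a2`) and `fam` (data frame: `fid`, `iid`, `pat`,
#'   `mat`, `sex`, `pheno`).
#' @examples
#' prefix <- file.path(tempdir(), "toy")
#' write_scan_fixture(prefix, type = "null", n = 20, n_snps = 3, seed = 1)
#' pl <- read_plink(prefix)
#' dim(pl$genotypes)
#' @export
read_plink <- function(bed, bim = NULL, fam = NULL) {
  if (!grepl("\\.bed$", bed)) {
    prefix <- bed
    bed <- paste0(prefix, ".bed")
    if (is.null(bim)) bim <- paste0(prefix, ".bim")
    if (is.null(fam)) fam <- paste0(prefix, ".fam")
  } else {
    if (is.null(bim)) bim <- sub("\\.bed$", ".bim", bed)
    if (is.null(fam)) fam <- sub("\\.bed$", ".fam", bed)
  }
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pat", "mat",
                                            "sex", "pheno"))
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chr", "snp_id", "cm", "pos",
                                            "a1", "a2"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  bps <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic bytes): ", bed, call. = FALSE)
  }
  if (raw[3L] != as.raw(0x01)) {
    stop("unsupported bed layout (expected SNP-major mode byte 0x01): ", bed,
         call. = FALSE)
  }
  if (length(raw) != 3L + bps * m) {
    stop(sprintf(
      "bed size mismatch: %s has %d data bytes but %d samples x %d SNPs need %d",
      bed, length(raw) - 3L, n, m, bps * m), call. = FALSE)
  }
  body <- as.integer(raw[-(1:3)]) + 1L
  # decode all SNPs at once: (4 * bps) x m matrix of codes, then trim padding
  codes <- matrix(t(.plink_decode_lut[body, , drop = FALSE]), nrow = 4L * bps)
  geno <- codes[seq_len(n), , drop = FALSE]
  dimnames(geno) <- list(fam_df$iid, bim_df$snp_id)
  structure(list(genotypes = geno, bim = bim_df, fam = fam_df),
            class = "plink_data")
}

#' @export
print.plink_data <- function(x, ...) {
  cat(sprintf("PLINK data: %d samples x %d SNPs (%d female, %d male)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$fam$sex == 2), sum(x$fam$sex == 1)))
  invisible(x)
}

#' Write a PLINK binary fileset
#'
#' Inverse of [read_plink()]: encodes a matrix of A1-allele counts into the
#' SNP-major bed layout and writes the accompanying bim and fam tables.
#'
#' @param genotypes Integer matrix (samples x SNPs) of A1-allele counts in
#'   `{0, 1, 2, NA}`.
#' @param fam Data frame with columns `fid`, `iid`, `pat`, `mat`, `sex`,
#'   `pheno` (one row per sample).
#' @param bim Data frame with columns `chr`, `snp_id`, `cm`, `pos`, `a1`,
#'   `a2` (one row per SNP).
#' @param prefix Output fileset prefix; writes `<prefix>.bed`,
#'   `<prefix>.bim`, `<prefix>.fam`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(genotypes, fam, bim, prefix) {
  stopifnot(nrow(genotypes) == nrow(fam), ncol(genotypes) == nrow(bim))
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  bps <- ceiling(n / 4)
  # code -> bit pair: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  bits <- matrix(1L, 4L * bps, m)  # pad with the missing pattern
  gi <- genotypes
  enc <- c(3L, 2L, 0L)[gi + 1L]
  enc[is.na(enc)] <- 1L
  bits[seq_len(n), ] <- enc
  shift <- rep(c(1L, 4L, 16L, 64L), bps)
  bytes <- matrix(bits * shift, nrow = 4L)
  packed <- as.raw(colSums(matrix(bytes, nrow = 4L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(packed, con)
  utils::write.table(fam[, c("fid", "iid", "pat", "mat", "sex", "pheno")],
                     paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bim[, c("chr", "snp_id", "cm", "pos", "a1", "a2")],
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
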