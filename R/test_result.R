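# Light-weight container for the outcome of one test on one SNP/trait.
# Invalid results (degenerate group structure, zero variances) carry NA
# fields and valid = FALSE so a chromosome-wide scan never aborts on one SNP.

.test_result <- function(method, statistic = NA_real_, df = NA_real_,
                         p.value = NA_real_, direction = NA_integer_,
                         valid = FALSE, note = NULL) {
  structure(
    list(method = method, statistic = statistic, df = df, p.value = p.value,
         direction = direction, valid = valid, note = note),
    class = "xassoc_result")
}

.invalid_result <- function(method, note) {
  .test_result(method, note = note)
}

#' @export
print.xassoc_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!x$valid) {
    cat("  invalid result:", if (is.null(x$note)) "degenerate input" else x$note,
        "\n")
    return(invisible(x))
  }
  cat(sprintf("  statistic = %.4g", x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %.4g", x$df))
  cat(sprintf(", p-value = %.4g\n", x$p.value))
  if (!is.na(x$direction)) {
    cat("  direction:", c("-1 (negative)", "0", "+1 (positive)")[x$direction + 2L],
        "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
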