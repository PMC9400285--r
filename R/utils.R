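# Internal helpers shared across modules.

#' The fifteen KIR genes
#'
#' Gene symbols of the 15 expressed killer immunoglobulin-like receptor genes
#' at chromosome 19q13.4. The two pseudogenes (KIR2DP1, KIR3DP1) are excluded
#' from genotyping and are dropped when an allele database is loaded.
#'
#' @return Character vector of 15 gene symbols.
#' @export
kir_genes <- function() {
  c("KIR2DL1", "KIR2DL2", "KIR2DL3", "KIR2DL4", "KIR2DL5A", "KIR2DL5B",
    "KIR3DL1", "KIR3DL2", "KIR3DL3", "KIR2DS1", "KIR2DS2", "KIR2DS3",
    "KIR2DS4", "KIR2DS5", "KIR3DS1")
}

kir_pseudogenes <- function() c("KIR2DP1", "KIR3DP1")

# Deterministic 31-bit substream seed from a base seed and a string key.
# Keeps per-gene / per-cell RNG streams reproducible under reordering.
derive_seed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 97) %% 2147483629) + 1L
}

# Vectorised reverse complement on plain character vectors (N preserved).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_nucleotides <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters other than A/C/G/T/N", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Atomic write: write to a sibling temp file, then rename into place.
write_atomic <- function(lines_or_fun, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  if (is.function(lines_or_fun)) {
    lines_or_fun(tmp)
  } else {
    writeLines(lines_or_fun, tmp)
  }
  file.rename(tmp, path)
  invisible(path)
}

# 6-significant-digit, locale-independent number formatting for TSV output.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

write_tsv <- function(df, path) {
  write_atomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }, path)
}
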