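# Shared test fixtures, built in code.

# Construct a kir_alignments directly from a named list read_id -> alleles,
# bypassing the aligner (mirrors its output contract).
make_alignments <- function(gene, entries) {
  entries <- lapply(entries, sort)
  entries <- entries[order(names(entries))]
  structure(list(gene = gene,
                 alleles = sort(unique(unlist(entries, use.names = FALSE))),
                 entries = entries,
                 x_r = vapply(entries, length, integer(1))),
            class = "kir_alignments")
}

# Construct a kir_allele_probs directly.
make_probs <- function(gene, probs, n_reads = 10, converged = TRUE) {
  structure(list(gene = gene, probs = probs, n_reads = n_reads,
                 converged = converged, iterations = 1L),
            class = "kir_allele_probs")
}

# Write a FASTA in the IPD-KIR header dialect.
write_ipd_fasta <- function(names, seqs, path = tempfile(fileext = ".fasta")) {
  lines <- character(0)
  for (i in seq_along(names)) {
    lines <- c(lines, sprintf(">KIR:KIR%05d %s %d bp", i, names[i],
                              nchar(seqs[i])), seqs[i])
  }
  writeLines(lines, path)
  path
}

# Write a sorted, indexed BAM from alignment records.
# reads: data.frame(qname, flag, chrom, pos [1-based], seq)
write_test_bam <- function(reads, contigs) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                  reads$qname, reads$flag, reads$chrom, reads$pos,
                  nchar(reads$seq), reads$seq)
  writeLines(c(hdr, body), sam)
  bam0 <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam0, tempfile())
  Rsamtools::indexBam(sorted)
  sorted
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# The shared 3-gene synthetic database used by the heavier tests.
fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- make_synthetic_database(
      n_genes = 3, alleles_per_gene = 6, allele_length = 1000,
      divergence = 20, synonymous_siblings = 2, seed = 7)
    db
  }
})
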