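# Exact-match read-to-allele alignment. A read supports an allele when the
# read (or its reverse complement) contains a contiguous exact substring of
# the allele of length >= min(read length, min_alignment_length): the
# operational form of a 100%-identity local alignment filter. No mismatches
# or gaps are tolerated within the matched span, and reads containing N never
# match.

#' Test a single read against a single allele at 100% identity
#'
#' Reference (brute-force) matcher: returns TRUE iff the read or its reverse
#' complement contains a contiguous exact substring of the allele of length at
#' least `min(nchar(read), min_alignment_length)`. [align_readset()] uses an
#' indexed implementation whose results are contractually identical to this
#' function.
#'
#' @param read_sequence Read nucleotide string (A/C/G/T/N).
#' @param allele_sequence Allele nucleotide string.
#' @param min_alignment_length Minimum exact-match span in bp (default 50).
#' @return Logical.
#' @export
match_read <- function(read_sequence, allele_sequence,
                       min_alignment_length = 50) {
  stopifnot(nchar(read_sequence) > 0, nchar(allele_sequence) > 0)
  read_sequence <- toupper(read_sequence)
  allele_sequence <- toupper(allele_sequence)
  assert_nucleotides(read_sequence, "read sequence")
  assert_nucleotides(allele_sequence, "allele sequence")
  if (grepl("N", read_sequence, fixed = TRUE)) return(FALSE)
  k <- min(nchar(read_sequence), min_alignment_length)
  for (strand_read in c(read_sequence, revcomp(read_sequence))) {
    n_win <- nchar(strand_read) - k + 1
    for (s in seq_len(n_win)) {
      if (grepl(substr(strand_read, s, s + k - 1), allele_sequence,
                fixed = TRUE)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Hash of every length-k substring of each allele -> integer allele indices.
build_window_index <- function(allele_seqs, k) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (a in seq_along(allele_seqs)) {
    s <- allele_seqs[a]
    n_win <- nchar(s) - k + 1
    if (n_win < 1) next
    wins <- unique(substring(s, seq_len(n_win), seq_len(n_win) + k - 1))
    for (w in wins) idx[[w]] <- c(idx[[w]], a)
  }
  idx
}

#' Align a read set against one gene's alleles
#'
#' Computes, for every read, the set of alleles it matches at 100% identity
#' under the [match_read()] rule. Reads matching no allele are dropped (they
#' carry no information for the EM). The internal backend uses a substring
#' index; results equal brute-force scanning. The optional `blast` backend
#' shells out to NCBI `blastn` at 100% identity and parses tabular output; it
#' exists for parity checking and is never required.
#'
#' @param reads A `kir_readset`.
#' @param alleles data.frame of allele records for one gene (columns
#'   `full_name`, `sequence`), e.g. a subset of `db$records`.
#' @param min_alignment_length Minimum exact-match span in bp (default 50).
#' @param backend `"internal"` (default) or `"blast"`.
#' @return A `kir_alignments`: list with `gene`, `alleles` (sorted union of
#'   matched allele names), `entries` (named list mapping read_id to the
#'   character vector of matched allele full names), `x_r` (integer vector of
#'   per-read match counts).
#' @export
align_readset <- function(reads, alleles, min_alignment_length = 50,
                          backend = c("internal", "blast")) {
  backend <- match.arg(backend)
  stopifnot(inherits(reads, "kir_readset"))
  if (nrow(alleles) == 0) {
    stop("empty allele list for alignment", call. = FALSE)
  }
  if (backend == "blast") {
    return(align_readset_blast(reads, alleles, min_alignment_length))
  }
  seqs <- toupper(reads$reads$sequence)
  ids <- reads$reads$read_id
  assert_nucleotides(seqs, "read sequences")
  allele_seqs <- toupper(alleles$sequence)
  names(allele_seqs) <- alleles$full_name

  entries <- vector("list", length(ids))
  has_n <- grepl("N", seqs, fixed = TRUE)
  rc <- character(length(seqs))
  rc[!has_n] <- revcomp(seqs[!has_n])
  k_full <- min_alignment_length
  index <- NULL
  for (i in seq_along(ids)) {
    if (has_n[i]) next
    rd <- seqs[i]
    k <- min(nchar(rd), k_full)
    hit <- logical(length(allele_seqs))
    if (k == k_full) {
      if (is.null(index)) index <- build_window_index(allele_seqs, k_full)
      for (strand_read in c(rd, rc[i])) {
        n_win <- nchar(strand_read) - k + 1
        for (s in seq_len(n_win)) {
          a <- index[[substr(strand_read, s, s + k - 1)]]
          if (!is.null(a)) hit[a] <- TRUE
        }
      }
    } else {
      # short read: whole-read containment on either strand
      for (strand_read in c(rd, rc[i])) {
        hit <- hit | vapply(allele_seqs, grepl, logical(1),
                            pattern = strand_read, fixed = TRUE,
                            USE.NAMES = FALSE)
      }
    }
    if (any(hit)) entries[[i]] <- sort(names(allele_seqs)[hit])
  }
  names(entries) <- ids
  entries <- entries[!vapply(entries, is.null, logical(1))]
  entries <- entries[order(names(entries))]
  new_alignments(reads$gene, entries)
}

new_alignments <- function(gene, entries) {
  structure(list(gene = gene,
                 alleles = sort(unique(unlist(entries, use.names = FALSE))),
                 entries = entries,
                 x_r = vapply(entries, length, integer(1))),
            class = "kir_alignments")
}

# External-BLAST parity backend: blastn -perc_identity 100, tabular output,
# filtered to HSP length >= min(read length, min_alignment_length).
align_readset_blast <- function(reads, alleles, min_alignment_length = 50) {
  blastn <- Sys.which("blastn")
  makedb <- Sys.which("makeblastdb")
  if (blastn == "" || makedb == "") {
    stop("blastn/makeblastdb not found on PATH; use backend='internal'",
         call. = FALSE)
  }
  wd <- tempfile("blastaln")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  db_fa <- file.path(wd, "alleles.fasta")
  rd_fa <- file.path(wd, "reads.fasta")
  aseq <- Biostrings::DNAStringSet(toupper(alleles$sequence))
  names(aseq) <- alleles$full_name
  Biostrings::writeXStringSet(aseq, db_fa)
  rseq <- Biostrings::DNAStringSet(toupper(reads$reads$sequence))
  names(rseq) <- seq_along(reads$reads$read_id)  # avoid id whitespace issues
  Biostrings::writeXStringSet(rseq, rd_fa)
  system2(makedb, c("-in", db_fa, "-dbtype", "nucl"), stdout = FALSE)
  # ungapped, prohibitive mismatch penalty, tiny X-dropoff: extension stops
  # at the first mismatch, so every reported HSP is a maximal exact run and
  # the 100%-identity filter matches the internal exact-substring rule
  out <- system2(blastn,
                 c("-query", rd_fa, "-db", db_fa, "-perc_identity", "100",
                   "-outfmt", shQuote("6 qseqid sseqid pident length"),
                   "-dust", "no", "-soft_masking", "false",
                   "-max_target_seqs", "1000000", "-task", "blastn",
                   "-word_size", "11", "-reward", "1", "-penalty", "-5",
                   "-ungapped", "-xdrop_ungap", "2", "-evalue", "1e6"),
                 stdout = TRUE)
  entries <- list()
  if (length(out) > 0) {
    tab <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("q", "s", "pident", "len"))
    rid <- reads$reads$read_id[as.integer(tab$q)]
    rlen <- nchar(reads$reads$sequence)[as.integer(tab$q)]
    keep <- tab$pident == 100 & tab$len >= pmin(rlen, min_alignment_length)
    tab <- tab[keep, , drop = FALSE]
    rid <- rid[keep]
    if (nrow(tab) > 0) {
      entries <- lapply(split(tab$s, rid), function(x) sort(unique(x)))
    }
  }
  entries <- entries[order(names(entries))]
  new_alignments(reads$gene, entries)
}

#' Write read-to-allele matches as TSV
#'
#' @param alignments A `kir_alignments`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  df <- data.frame(
    gene = alignments$gene,
    read_id = rep(names(alignments$entries), alignments$x_r),
    allele_full_name = unlist(alignments$entries, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @export
print.kir_alignments <- function(x, ...) {
  cat(sprintf("KIR alignments: %s, %d reads matched, %d alleles\n",
              x$gene, length(x$entries), length(x$alleles)))
  invisible(x)
}
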