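# Synthetic allele databases and WES-like read sets with known truth
# genotypes. These stand in for cohort BAMs and the curated allele release in
# all tests: the generator controls allele divergence, synonymous sibling
# structure, sequencing depth, and per-base error rate.

#' Generate a synthetic multi-allele KIR gene database
#'
#' For each gene a random base sequence is drawn, and `alleles_per_gene`
#' primary variants are derived by substituting `divergence` bases at
#' positions private to each variant, so every pair of primary alleles within
#' a gene differs at `2 * divergence` positions (at least `divergence`
#' guaranteed by construction). Each primary variant defines a coding group
#' (designation digits 1-3); `synonymous_siblings` additional members per
#' group differ from their primary only at two further private positions,
#' emulating non-exonic/silent differences that collapse to the same
#' protein-level group.
#'
#' Gene symbols are taken from the 15-gene KIR universe, so synthetic
#' databases satisfy the same invariants as a loaded release.
#'
#' @param n_genes Number of genes (1-15).
#' @param alleles_per_gene Primary (coding-distinct) alleles per gene.
#' @param allele_length Allele sequence length in bp.
#' @param divergence Number of substituted positions private to each primary
#'   allele.
#' @param synonymous_siblings Extra same-coding-group members per primary
#'   allele.
#' @param seed Integer RNG seed; the same seed reproduces the database
#'   byte-for-byte.
#' @return A `kir_allele_db`.
#' @export
make_synthetic_database <- function(n_genes = 3, alleles_per_gene = 6,
                                    allele_length = 1000, divergence = 20,
                                    synonymous_siblings = 0, seed = 1) {
  stopifnot(n_genes >= 1, n_genes <= 15, alleles_per_gene >= 1,
            allele_length >= 1, divergence >= 1, synonymous_siblings >= 0)
  sib_div <- 2L  # substitutions per synonymous sibling
  need <- alleles_per_gene * (divergence + synonymous_siblings * sib_div)
  if (divergence * alleles_per_gene > allele_length || need > allele_length) {
    stop("divergence x alleles_per_gene exceeds allele_length", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  genes <- kir_genes()[seq_len(n_genes)]
  withr::with_seed(seed, {
    recs <- list()
    for (gene in genes) {
      base <- sample(bases, allele_length, replace = TRUE)
      pos_pool <- sample.int(allele_length, need)
      k <- 0
      for (i in seq_len(alleles_per_gene)) {
        prim_pos <- pos_pool[k + seq_len(divergence)]
        k <- k + divergence
        primary <- base
        for (p in prim_pos) primary[p] <- sample(setdiff(bases, base[p]), 1)
        grp <- sprintf("%s*%03d", gene, i)
        recs[[length(recs) + 1]] <- data.frame(
          gene = gene, full_name = paste0(grp, "01"), coding_group = grp,
          sequence = paste(primary, collapse = ""), stringsAsFactors = FALSE)
        for (s in seq_len(synonymous_siblings)) {
          sib_pos <- pos_pool[k + seq_len(sib_div)]
          k <- k + sib_div
          sib <- primary
          for (p in sib_pos) sib[p] <- sample(setdiff(bases, primary[p]), 1)
          recs[[length(recs) + 1]] <- data.frame(
            gene = gene, full_name = sprintf("%s%02d", grp, s + 1),
            coding_group = grp, sequence = paste(sib, collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
    records <- do.call(rbind, recs)
  })
  records <- records[order(records$gene, records$full_name), , drop = FALSE]
  rownames(records) <- NULL
  db <- structure(list(version = sprintf("synthetic(seed=%d)", seed),
                       records = records, groups = NULL),
                  class = "kir_allele_db")
  db$groups <- build_coding_groups(db)
  db
}

#' Write an allele database to FASTA
#'
#' Headers follow the IPD-KIR dialect (`KIR:SYN<n> <full_name> <length> bp`)
#' so written databases round-trip through [load_allele_database()].
#'
#' @param db A `kir_allele_db`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_allele_fasta <- function(db, path) {
  stopifnot(inherits(db, "kir_allele_db"))
  seqs <- Biostrings::DNAStringSet(db$records$sequence)
  names(seqs) <- sprintf("KIR:SYN%05d %s %d bp", seq_len(nrow(db$records)),
                         db$records$full_name, nchar(db$records$sequence))
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' Simulate WES-like reads from a truth genotype
#'
#' Emits `ceiling(depth * allele_length / read_length)` reads in total,
#' hitting the target mean coverage. A homozygous truth (one allele name)
#' draws all reads from that allele; a heterozygous truth (two names) draws
#' half from each. Each read is a uniformly positioned substring of its
#' source allele with i.i.d. substitution errors at `error_rate`; read ids
#' encode the source allele and start position for oracle checks.
#'
#' @param db A `kir_allele_db` containing the truth alleles.
#' @param gene Gene symbol.
#' @param truth_alleles One or two full allele names present in `db`.
#' @param depth Target mean coverage (x).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability in [0, 1).
#' @param seed Integer RNG seed.
#' @param revcomp_half Emit every second read reverse-complemented, to
#'   exercise strand handling (default FALSE: forward strand only).
#' @return A `kir_readset`: list with `gene`, `reads` (data.frame with
#'   `read_id`, `sequence`).
#' @export
simulate_reads <- function(db, gene, truth_alleles, depth = 30,
                           read_length = 100, error_rate = 0, seed = 1,
                           revcomp_half = FALSE) {
  stopifnot(inherits(db, "kir_allele_db"), depth > 0, read_length >= 1,
            error_rate >= 0, error_rate < 1,
            length(truth_alleles) %in% c(1, 2))
  idx <- match(truth_alleles, db$records$full_name)
  if (anyNA(idx)) {
    stop(sprintf("truth allele not in database: %s",
                 truth_alleles[which(is.na(idx))[1]]), call. = FALSE)
  }
  if (any(db$records$gene[idx] != gene)) {
    stop("truth allele does not belong to the requested gene", call. = FALSE)
  }
  src_seqs <- db$records$sequence[idx]
  allele_length <- nchar(src_seqs[1])
  if (read_length > allele_length) {
    stop("read_length exceeds allele length", call. = FALSE)
  }
  n_total <- ceiling(depth * allele_length / read_length)
  if (length(truth_alleles) == 2) {
    n_per <- c(ceiling(n_total / 2), floor(n_total / 2))
  } else {
    n_per <- n_total
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    for (a in seq_along(truth_alleles)) {
      L <- nchar(src_seqs[a])
      starts <- sample.int(L - read_length + 1, n_per[a], replace = TRUE)
      rd <- substring(src_seqs[a], starts, starts + read_length - 1)
      if (error_rate > 0) {
        rd <- vapply(rd, function(s) {
          v <- strsplit(s, "", fixed = TRUE)[[1]]
          hit <- which(stats::runif(length(v)) < error_rate)
          for (p in hit) v[p] <- sample(setdiff(bases, v[p]), 1)
          paste(v, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      ids <- c(ids, sprintf("%s|%s|%d|r%05d", gene, truth_alleles[a],
                            starts, seq_along(starts) +
                              (if (a == 2) n_per[1] else 0L)))
      seqs <- c(seqs, rd)
    }
    if (revcomp_half && length(seqs) > 1) {
      flip <- seq(2, length(seqs), by = 2)
      seqs[flip] <- revcomp(seqs[flip])
    }
  })
  structure(list(gene = gene,
                 reads = data.frame(read_id = ids, sequence = seqs,
                                    stringsAsFactors = FALSE)),
            class = "kir_readset")
}

#' Construct a read set from raw vectors
#'
#' @param gene Gene symbol.
#' @param read_id Character vector of read identifiers.
#' @param sequence Character vector of read sequences.
#' @return A `kir_readset`.
#' @export
kir_readset <- function(gene, read_id, sequence) {
  stopifnot(length(read_id) == length(sequence))
  if (length(sequence) > 0 && any(nchar(sequence) == 0)) {
    stop("empty read sequence", call. = FALSE)
  }
  structure(list(gene = gene,
                 reads = data.frame(read_id = as.character(read_id),
                                    sequence = toupper(as.character(sequence)),
                                    stringsAsFactors = FALSE)),
            class = "kir_readset")
}

#' @export
print.kir_readset <- function(x, ...) {
  cat(sprintf("KIR read set: %s, %d reads\n", x$gene, nrow(x$reads)))
  invisible(x)
}
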