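# KIR allele nucleotide database: loading, coding-region collapse.

#' Load a KIR allele nucleotide database from FASTA
#'
#' Parses a FASTA file in the IPD-KIR nucleotide release dialect, in which each
#' header carries an allele designation token of the form `GENE*digits`
#' (e.g. `KIR:KIR00001 KIR2DL1*0010101 5314 bp`). One record is created per
#' entry; sequences are upper-cased. Entries for the two KIR pseudogenes
#' (KIR2DP1, KIR3DP1) are dropped: genotyping covers the 15 expressed genes.
#'
#' The protein-level coding group of every allele is computed by truncating the
#' numeric designation to its first three digits (digits 1-3 of a KIR allele
#' name encode the protein variant; later digits encode synonymous and
#' non-coding differences). Alleles sharing a coding group differ only at
#' non-exonic sites or by silent mutations and are merged at call time.
#'
#' @param fasta_path Path to the allele FASTA file.
#' @param gene_filter Optional character vector of gene symbols to keep.
#' @param version Free-text release label stored on the database.
#' @return An object of class `kir_allele_db`: a list with elements
#'   `version`, `records` (data.frame with columns `gene`, `full_name`,
#'   `coding_group`, `sequence`) and `groups` (named character vector mapping
#'   `full_name` to `coding_group`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">KIR:KIR00001 KIR2DL1*0010101 100 bp", "ACGTACGT"), fa)
#' db <- load_allele_database(fa)
#' db$records$coding_group
#' @export
load_allele_database <- function(fasta_path, gene_filter = NULL,
                                 version = basename(fasta_path)) {
  if (!file.exists(fasta_path)) {
    stop(sprintf("allele database not found: %s", fasta_path), call. = FALSE)
  }
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) {
                     stop(sprintf("unreadable FASTA '%s': %s",
                                  fasta_path, conditionMessage(e)),
                          call. = FALSE)
                   })
  if (length(seqs) == 0) {
    stop(sprintf("empty allele FASTA: %s", fasta_path), call. = FALSE)
  }
  headers <- names(seqs)
  tok <- regmatches(headers, regexpr("[A-Za-z0-9]+\\*[0-9]+", headers))
  missing <- lengths(regmatches(headers,
                                gregexpr("[A-Za-z0-9]+\\*[0-9]+", headers))) == 0
  if (any(missing)) {
    stop(sprintf("FASTA header without a GENE*digits allele token: '%s'",
                 headers[which(missing)[1]]), call. = FALSE)
  }
  gene <- sub("\\*.*$", "", tok)
  keep_pseudo <- !(gene %in% kir_pseudogenes())
  unknown <- !(gene %in% c(kir_genes(), kir_pseudogenes()))
  if (any(unknown)) {
    stop(sprintf("header names unknown KIR gene '%s' (header '%s')",
                 gene[which(unknown)[1]], headers[which(unknown)[1]]),
         call. = FALSE)
  }
  if (!is.null(gene_filter)) keep_pseudo <- keep_pseudo & gene %in% gene_filter

  full_name <- tok[keep_pseudo]
  gene <- gene[keep_pseudo]
  sequence <- toupper(as.character(seqs)[keep_pseudo])
  if (anyDuplicated(full_name)) {
    stop(sprintf("duplicate allele name in database: %s",
                 full_name[duplicated(full_name)][1]), call. = FALSE)
  }
  if (length(full_name) == 0) {
    stop("no allele records remain after gene filtering", call. = FALSE)
  }
  if (any(nchar(sequence) == 0)) {
    stop("allele with empty sequence in database", call. = FALSE)
  }

  records <- data.frame(gene = gene, full_name = full_name,
                        coding_group = coding_group_name(full_name),
                        sequence = sequence, stringsAsFactors = FALSE)
  records <- records[order(records$gene, records$full_name), , drop = FALSE]
  rownames(records) <- NULL
  db <- structure(list(version = version, records = records,
                       groups = NULL), class = "kir_allele_db")
  db$groups <- build_coding_groups(db)
  db
}

# 3-digit truncation of the numeric designation; shorter designations are
# right-padded with zeros (with a warning), per the grouping convention.
coding_group_name <- function(full_name) {
  gene <- sub("\\*.*$", "", full_name)
  digits <- sub("^.*\\*", "", full_name)
  short <- nchar(digits) < 3
  if (any(short)) {
    warning(sprintf("allele designation shorter than 3 digits, zero-padded: %s",
                    paste(full_name[short], collapse = ", ")), call. = FALSE)
    digits[short] <- formatC(digits[short], width = 3, flag = "-")
    digits[short] <- gsub(" ", "0", digits[short])
  }
  paste0(gene, "*", substr(digits, 1, 3))
}

#' Build the full-name to coding-group mapping of a database
#'
#' @param db A `kir_allele_db`.
#' @return Named character vector: `full_name` -> `coding_group`.
#' @export
build_coding_groups <- function(db) {
  stopifnot(inherits(db, "kir_allele_db"))
  stats::setNames(db$records$coding_group, db$records$full_name)
}

#' Collapse allele probabilities to protein-level coding groups
#'
#' Sums the probability estimates of alleles belonging to the same coding
#' group (alleles differing only at non-exonic sites or by silent mutations).
#' Total probability mass is conserved.
#'
#' @param probs Named numeric vector of non-negative allele probabilities,
#'   keyed by full allele name.
#' @param groups Named character vector mapping full names to coding groups,
#'   as from [build_coding_groups()].
#' @return Named numeric vector keyed by coding group.
#' @export
collapse_probabilities <- function(probs, groups) {
  if (length(probs) == 0) return(stats::setNames(numeric(0), character(0)))
  if (any(probs < 0)) stop("negative probability", call. = FALSE)
  unknown <- setdiff(names(probs), names(groups))
  if (length(unknown) > 0) {
    stop(sprintf("allele not present in group mapping: %s", unknown[1]),
         call. = FALSE)
  }
  g <- groups[names(probs)]
  out <- vapply(split(unname(probs), g), sum, numeric(1))
  out[order(names(out))]
}

#' Tabulate a loaded allele database
#'
#' @param db A `kir_allele_db`.
#' @return data.frame with columns `gene`, `full_name`, `coding_group`,
#'   `length` (sequence length in bp).
#' @export
allele_catalogue <- function(db) {
  stopifnot(inherits(db, "kir_allele_db"))
  data.frame(gene = db$records$gene, full_name = db$records$full_name,
             coding_group = db$records$coding_group,
             length = nchar(db$records$sequence), stringsAsFactors = FALSE)
}

#' Write the allele catalogue as TSV
#'
#' @param db A `kir_allele_db`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_allele_catalogue <- function(db, path) {
  write_tsv(allele_catalogue(db), path)
  invisible(path)
}

#' Flag coding groups with internally divergent sequences
#'
#' Verification routine for the truncation-based collapse: for each coding
#' group with more than one member, computes pairwise percent identity of the
#' member sequences (global alignment) and flags groups whose members differ
#' at more than `max_divergence` of aligned positions. Nomenclature truncation
#' should only merge near-identical sequences; a flagged group indicates a
#' mislabelled database entry.
#'
#' @param db A `kir_allele_db`.
#' @param max_divergence Maximum tolerated fraction of differing aligned
#'   positions within a group (default 0.05).
#' @return data.frame of flagged groups (`coding_group`, `min_identity`);
#'   zero rows when all groups verify.
#' @export
verify_coding_groups <- function(db, max_divergence = 0.05) {
  stopifnot(inherits(db, "kir_allele_db"))
  flagged <- list()
  for (grp in unique(db$records$coding_group)) {
    members <- db$records$sequence[db$records$coding_group == grp]
    if (length(members) < 2) next
    min_pid <- 100
    for (i in seq_len(length(members) - 1)) {
      for (j in seq(i + 1, length(members))) {
        aln <- Biostrings::pairwiseAlignment(members[i], members[j],
                                             type = "global")
        min_pid <- min(min_pid, Biostrings::pid(aln))
      }
    }
    if ((100 - min_pid) / 100 > max_divergence) {
      flagged[[grp]] <- data.frame(coding_group = grp, min_identity = min_pid,
                                   stringsAsFactors = FALSE)
    }
  }
  if (length(flagged) == 0) {
    return(data.frame(coding_group = character(0), min_identity = numeric(0)))
  }
  out <- do.call(rbind, flagged)
  rownames(out) <- NULL
  out
}

#' @export
print.kir_allele_db <- function(x, ...) {
  cat(sprintf("KIR allele database (%s): %d alleles, %d coding groups, %d genes\n",
              x$version, nrow(x$records), length(unique(x$records$coding_group)),
              length(unique(x$records$gene))))
  invisible(x)
}
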