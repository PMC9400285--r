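# End-to-end genotyping of one sample: extract -> align -> bootstrapped EM
# -> coding collapse -> threshold, per gene.

#' Genotype all KIR genes of one sample
#'
#' Composes the four pipeline stages for every gene region: read extraction
#' from the alignment file, 100%-identity matching against that gene's
#' alleles, bootstrapped EM allele probability estimation, and threshold
#' calling on coding-group-collapsed probabilities. Genes with no extracted
#' or no matching reads yield `no_call` with reason `no_reads`; per-gene
#' failures are recorded on the call, not raised.
#'
#' Each gene uses an RNG substream derived from `config$seed` and the gene
#' name, so results do not depend on gene order.
#'
#' @param alignment_path Coordinate-sorted, indexed BAM or CRAM.
#' @param db A `kir_allele_db`.
#' @param regions `GRanges` with `gene` metadata ([read_gene_regions()]).
#' @param config A `kir_em_config`.
#' @param min_alignment_length Minimum exact-match span for the aligner.
#' @param exclude_duplicates Drop duplicate-marked reads.
#' @return A `kir_genotype_result`: list with `calls` (named list of
#'   `kir_genotype_call` per gene), `config`, `min_alignment_length`.
#' @export
genotype_sample <- function(alignment_path, db, regions,
                            config = em_config(), min_alignment_length = 50,
                            exclude_duplicates = FALSE) {
  stopifnot(inherits(db, "kir_allele_db"), inherits(config, "kir_em_config"))
  readsets <- extract_kir_reads(alignment_path, regions,
                                exclude_duplicates = exclude_duplicates)
  calls <- list()
  for (gene in names(readsets)) {
    calls[[gene]] <- genotype_readset(readsets[[gene]], db, config,
                                      min_alignment_length)
  }
  structure(list(calls = calls, config = config,
                 min_alignment_length = min_alignment_length),
            class = "kir_genotype_result")
}

#' Genotype one gene from an extracted read set
#'
#' The per-gene core of [genotype_sample()], usable directly on simulated or
#' pre-extracted reads.
#'
#' @param reads A `kir_readset`.
#' @param db A `kir_allele_db`.
#' @param config A `kir_em_config`; the gene's RNG substream is derived from
#'   `config$seed` and the gene name.
#' @param min_alignment_length Minimum exact-match span for the aligner.
#' @return A `kir_genotype_call`.
#' @export
genotype_readset <- function(reads, db, config = em_config(),
                             min_alignment_length = 50) {
  gene <- reads$gene
  alleles <- db$records[db$records$gene == gene, , drop = FALSE]
  if (nrow(reads$reads) == 0 || nrow(alleles) == 0) {
    return(new_genotype_call(gene, "no_call", character(0), "no_reads",
                             stats::setNames(numeric(0), character(0))))
  }
  aln <- align_readset(reads, alleles, min_alignment_length)
  if (length(aln$entries) < config$min_reads) {
    return(new_genotype_call(gene, "no_call", character(0), "no_reads",
                             stats::setNames(numeric(0), character(0))))
  }
  gene_config <- config
  gene_config$seed <- derive_seed(config$seed, gene)
  probs <- tryCatch(bootstrap_probabilities(aln, gene_config),
                    error = function(e) e)
  if (inherits(probs, "error")) {
    return(new_genotype_call(gene, "no_call", character(0), "no_reads",
                             stats::setNames(numeric(0), character(0))))
  }
  call_genotype(probs, t_threshold = config$t_threshold,
                groups = db$groups,
                call_unconverged = config$call_unconverged)
}

#' Genotype calls as a table
#'
#' @param result A `kir_genotype_result`, or a named list of
#'   `kir_genotype_call`.
#' @param sample Sample label for the first column.
#' @return data.frame with columns `sample`, `gene`, `zygosity`, `allele1`,
#'   `allele2`, `reason`.
#' @export
genotype_calls_table <- function(result, sample = "sample") {
  calls <- if (inherits(result, "kir_genotype_result")) result$calls
           else result
  rows <- lapply(calls, function(cl) {
    data.frame(sample = sample, gene = cl$gene, zygosity = cl$zygosity,
               allele1 = if (length(cl$alleles) >= 1) cl$alleles[1] else NA,
               allele2 = if (length(cl$alleles) >= 2) cl$alleles[2] else NA,
               reason = cl$no_call_reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele probabilities as a long table
#'
#' @param result A `kir_genotype_result` or named list of calls.
#' @param sample Sample label.
#' @return data.frame with columns `sample`, `gene`, `coding_group`,
#'   `probability`.
#' @export
allele_probabilities_table <- function(result, sample = "sample") {
  calls <- if (inherits(result, "kir_genotype_result")) result$calls
           else result
  rows <- lapply(calls, function(cl) {
    pv <- cl$probabilities
    if (length(pv) == 0) return(NULL)
    data.frame(sample = sample, gene = cl$gene, coding_group = names(pv),
               probability = unname(pv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), gene = character(0),
                      coding_group = character(0), probability = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Write the three genotyping outputs
#'
#' Emits `allele_probabilities.tsv`, `genotype_calls.tsv` and
#' `run_params.json` (the runtime hyperparameters) into `out_dir`. Floating
#' point values are fixed to 6 significant digits so identical inputs and
#' seed give byte-identical outputs.
#'
#' @param result A `kir_genotype_result`.
#' @param out_dir Output directory (created if needed).
#' @param sample Sample label.
#' @return Paths of the files written, invisibly.
#' @export
write_genotype_outputs <- function(result, out_dir, sample = "sample") {
  stopifnot(inherits(result, "kir_genotype_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probs <- allele_probabilities_table(result, sample)
  probs$probability <- fmt_num(probs$probability)
  p1 <- write_tsv(probs, file.path(out_dir, "allele_probabilities.tsv"))
  p2 <- write_tsv(genotype_calls_table(result, sample),
                  file.path(out_dir, "genotype_calls.tsv"))
  params <- result$config
  attributes(params) <- list(names = names(params))
  p3 <- file.path(out_dir, "run_params.json")
  write_atomic(function(tmp) {
    jsonlite::write_json(c(params,
                           list(min_alignment_length =
                                  result$min_alignment_length,
                                tool = "kirtype",
                                version = as.character(
                                  utils::packageVersion("kirtype")))),
                         tmp, auto_unbox = TRUE, pretty = TRUE)
  }, p3)
  invisible(c(p1, p2, p3))
}

#' @export
print.kir_genotype_result <- function(x, ...) {
  cat(sprintf("KIR genotyping result (%d genes):\n", length(x$calls)))
  for (cl in x$calls) print(cl)
  invisible(x)
}
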