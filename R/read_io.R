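# BAM/CRAM read extraction over the KIR gene regions, and per-region mean
# coverage. Coordinates are BED-style 0-based half-open at the interface and
# converted to 1-based GRanges internally.

#' Read a BED file of KIR gene regions
#'
#' Expects 4 columns: chrom, start (0-based), end (half-open), gene symbol.
#' A clearly-labelled synthetic example region file is shipped at
#' `system.file("extdata", "kir_regions_synthetic.bed", package = "kirtype")`;
#' for real data users must supply coordinates matched to their reference
#' build.
#'
#' @param bed_path Path to the BED file.
#' @return A `GRanges` with a `gene` metadata column (1-based coordinates).
#' @export
read_gene_regions <- function(bed_path) {
  if (!file.exists(bed_path)) {
    stop(sprintf("region BED not found: %s", bed_path), call. = FALSE)
  }
  tab <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "gene"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  if (any(tab$start >= tab$end)) {
    stop("BED region with start >= end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end))
  S4Vectors::mcols(gr)$gene <- tab$gene
  gr
}

#' Construct gene regions from vectors
#'
#' @param gene Gene symbols.
#' @param chrom Contig names.
#' @param start,end 0-based half-open coordinates in bp.
#' @return A `GRanges` with a `gene` metadata column.
#' @export
gene_regions <- function(gene, chrom, start, end) {
  stopifnot(all(start < end))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  S4Vectors::mcols(gr)$gene <- gene
  gr
}

check_alignment_file <- function(alignment_path, regions) {
  if (!file.exists(alignment_path)) {
    stop(sprintf("alignment file not found: %s", alignment_path),
         call. = FALSE)
  }
  is_cram <- grepl("\\.cram$", alignment_path, ignore.case = TRUE)
  idx <- paste0(alignment_path, if (is_cram) ".crai" else ".bai")
  idx2 <- sub("\\.[^.]+$", if (is_cram) ".crai" else ".bai", alignment_path)
  if (!file.exists(idx) && !file.exists(idx2)) {
    stop(sprintf("missing index (.bai/.crai) for %s", alignment_path),
         call. = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(alignment_path)[[1]]$targets
  absent <- setdiff(unique(as.character(GenomicRanges::seqnames(regions))),
                    names(hdr))
  if (length(absent) > 0) {
    stop(sprintf("contig absent from alignment header: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

read_flag_param <- function(exclude_duplicates) {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isDuplicate = if (exclude_duplicates) FALSE else NA)
}

#' Extract reads overlapping the KIR gene regions
#'
#' A read enters a gene's read set iff its aligned reference span overlaps
#' that gene's region by at least `min_mapped_overlap` bases; a read spanning
#' two regions appears in both. Unmapped, secondary and supplementary
#' alignments are excluded; duplicate-marked reads are kept unless
#' `exclude_duplicates`. Sequences are taken as stored in the file (no
#' reverse-complementing). Mate pairs are treated as independent reads, with
#' a `/1` / `/2` suffix disambiguating shared query names; output is sorted
#' by read id so extraction is independent of file order.
#'
#' @param alignment_path Coordinate-sorted, indexed BAM or CRAM.
#' @param regions `GRanges` with `gene` metadata, from [read_gene_regions()].
#' @param min_mapped_overlap Minimum overlap in bp (default 1).
#' @param exclude_duplicates Drop duplicate-marked reads (default FALSE).
#' @return Named list (by gene) of `kir_readset`.
#' @export
extract_kir_reads <- function(alignment_path, regions, min_mapped_overlap = 1,
                              exclude_duplicates = FALSE) {
  check_alignment_file(alignment_path, regions)
  out <- list()
  for (i in seq_along(regions)) {
    region <- regions[i]
    gene <- S4Vectors::mcols(region)$gene
    param <- Rsamtools::ScanBamParam(
      which = region, flag = read_flag_param(exclude_duplicates),
      what = c("qname", "seq", "flag"))
    ga <- GenomicAlignments::readGAlignments(alignment_path, param = param)
    if (length(ga) > 0) {
      ov <- overlap_widths(ga, region)
      ga <- ga[ov >= min_mapped_overlap]
    }
    if (length(ga) > 0) {
      flag <- S4Vectors::mcols(ga)$flag
      suffix <- ifelse(bitwAnd(flag, 1L) > 0L,
                       ifelse(bitwAnd(flag, 64L) > 0L, "/1", "/2"), "")
      ids <- paste0(S4Vectors::mcols(ga)$qname, suffix)
      seqs <- as.character(S4Vectors::mcols(ga)$seq)
      ord <- order(ids, seqs)
      out[[gene]] <- kir_readset(gene, ids[ord], seqs[ord])
    } else {
      out[[gene]] <- kir_readset(gene, character(0), character(0))
    }
  }
  out
}

#' Mean per-base depth of primary alignments over a region
#'
#' @param alignment_path Coordinate-sorted, indexed BAM or CRAM.
#' @param region A single-element `GRanges`.
#' @return Mean depth: total aligned bases inside the region divided by
#'   region length.
#' @export
mean_region_coverage <- function(alignment_path, region) {
  stopifnot(length(region) == 1)
  check_alignment_file(alignment_path, region)
  param <- Rsamtools::ScanBamParam(which = region,
                                   flag = read_flag_param(FALSE))
  ga <- GenomicAlignments::readGAlignments(alignment_path, param = param)
  if (length(ga) == 0) return(0)
  sum(overlap_widths(ga, region)) / GenomicRanges::width(region)
}

# bp of each alignment's reference span falling inside the (single) region
overlap_widths <- function(ga, region) {
  pmax(0L, pmin(GenomicAlignments::end(ga), GenomicRanges::end(region)) -
             pmax(GenomicAlignments::start(ga),
                  GenomicRanges::start(region)) + 1L)
}

#' Per-gene mean coverage table
#'
#' @param alignment_path Coordinate-sorted, indexed BAM or CRAM.
#' @param regions `GRanges` with `gene` metadata.
#' @return data.frame with columns `gene`, `mean_depth`.
#' @export
coverage_table <- function(alignment_path, regions) {
  depth <- vapply(seq_along(regions), function(i) {
    mean_region_coverage(alignment_path, regions[i])
  }, numeric(1))
  data.frame(gene = S4Vectors::mcols(regions)$gene, mean_depth = depth,
             stringsAsFactors = FALSE)
}

#' Write per-gene read sets as FASTA
#'
#' One file per gene, named `<sample>.<gene>.fasta`.
#'
#' @param readsets Named list of `kir_readset`.
#' @param out_dir Output directory (created if needed).
#' @param sample Sample label used in file names.
#' @return Character vector of written paths, invisibly.
#' @export
write_readset_fasta <- function(readsets, out_dir, sample = "sample") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (rs in readsets) {
    path <- file.path(out_dir, sprintf("%s.%s.fasta", sample, rs$gene))
    seqs <- Biostrings::DNAStringSet(rs$reads$sequence)
    names(seqs) <- rs$reads$read_id
    Biostrings::writeXStringSet(seqs, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
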