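# Internal quality-control instruments: Shannon entropies of calls and
# probability vectors, hyperparameter entropy grids, replicate concordance,
# coverage profiling, and donor-mixture negative controls.

#' Shannon entropy in bits
#'
#' For a numeric input, treats the values as non-negative weights, normalizes
#' to a probability vector q and returns `-sum(q * log2(q))` (with
#' `0 * log 0 = 0`). For a character or factor input, treats the values as a
#' multiset of categorical outcomes and uses their empirical frequencies.
#' An unambiguous homozygous probability vector (1, 0, ...) has entropy 0; a
#' clean heterozygous vector (0.5, 0.5, 0, ...) has entropy 1; more uniform
#' vectors exceed 1.
#'
#' @param x Non-negative numeric weights, or a categorical multiset.
#' @return Entropy in bits (log2).
#' @export
shannon_entropy <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.numeric(table(x))
  }
  if (length(x) == 0) stop("empty input to shannon_entropy", call. = FALSE)
  if (any(x < 0)) stop("negative weight", call. = FALSE)
  s <- sum(x)
  if (s == 0) stop("all-zero weights", call. = FALSE)
  q <- x / s
  q <- q[q > 0]
  -sum(q * log2(q))
}

# Canonical string key for a genotype call: zygosity + unordered alleles,
# or the no-call reason. no_call is a first-class category.
genotype_key <- function(call) {
  if (call$zygosity == "no_call") {
    paste0("no_call:", call$no_call_reason)
  } else {
    paste0(call$zygosity, ":", paste(sort(call$alleles), collapse = "/"))
  }
}

#' Genotype-call entropy over a hyperparameter grid
#'
#' For every cell (p, t) of the grid, reruns bootstrapped EM plus threshold
#' calling `iterations` times with distinct derived seeds and computes the
#' log2 Shannon entropy of the empirical distribution of genotype calls
#' (heterozygous calls compared as unordered pairs; no-calls are a category).
#' A perfectly self-consistent caller gives entropy 0.
#'
#' @param alignments A `kir_alignments`.
#' @param p_values Bootstrap fractions to scan.
#' @param t_values Calling thresholds to scan.
#' @param iterations Reruns per cell.
#' @param config Base `kir_em_config` (alpha, n_boot, seed are taken from it).
#' @param groups Optional coding-group mapping applied before thresholding.
#' @return A `kir_entropy_grid`: list with `p_values`, `t_values`, `entropy`
#'   (|p| x |t| matrix, bits), `iterations`.
#' @export
genotype_entropy_grid <- function(alignments,
                                  p_values = seq(0.2, 0.8, by = 0.1),
                                  t_values = seq(0.05, 0.40, by = 0.05),
                                  iterations = 500,
                                  config = em_config(), groups = NULL) {
  stopifnot(iterations >= 1)
  ent <- matrix(NA_real_, nrow = length(p_values), ncol = length(t_values),
                dimnames = list(p = fmt_num(p_values), t = fmt_num(t_values)))
  for (i in seq_along(p_values)) {
    for (j in seq_along(t_values)) {
      keys <- character(iterations)
      for (k in seq_len(iterations)) {
        cfg <- config
        cfg$p <- p_values[i]
        cfg$t_threshold <- t_values[j]
        cfg$seed <- derive_seed(config$seed,
                                sprintf("cell_%d_%d_iter_%d", i, j, k))
        probs <- bootstrap_probabilities(alignments, cfg)
        keys[k] <- genotype_key(call_genotype(probs, cfg$t_threshold, groups,
                                              cfg$call_unconverged))
      }
      ent[i, j] <- shannon_entropy(keys)
    }
  }
  structure(list(p_values = p_values, t_values = t_values, entropy = ent,
                 iterations = iterations), class = "kir_entropy_grid")
}

#' Concordance of genotype calls between replicate samples
#'
#' Two calls are concordant when their zygosity and unordered (collapsed)
#' allele names are identical; a no-call matches a no-call. Reports the
#' per-gene fraction of concordant pairs, the overall fraction pooling all
#' genes, and normal-approximation 95% confidence intervals
#' (`phat +/- 1.96 sqrt(phat (1 - phat) / n)`).
#'
#' @param calls_a,calls_b Genotype tables as from [genotype_calls_table()]
#'   (columns `sample`, `gene`, `zygosity`, `allele1`, `allele2`).
#' @param pairing data.frame with columns `sample_a`, `sample_b` pairing
#'   samples of `calls_a` with their replicates in `calls_b`.
#' @return data.frame with columns `gene` (including an `"overall"` row),
#'   `n_pairs`, `concordance`, `ci_lower`, `ci_upper`.
#' @export
replicate_concordance <- function(calls_a, calls_b, pairing) {
  stopifnot(nrow(pairing) > 0,
            all(c("sample_a", "sample_b") %in% names(pairing)))
  key_of <- function(df) {
    al <- ifelse(is.na(df$allele1), "", df$allele1)
    a2 <- ifelse(is.na(df$allele2), "", df$allele2)
    lo <- pmin(al, a2); hi <- pmax(al, a2)
    ifelse(df$zygosity == "no_call", "no_call",
           paste0(df$zygosity, ":", lo, "/", hi))
  }
  ka <- stats::setNames(key_of(calls_a), paste(calls_a$sample, calls_a$gene))
  kb <- stats::setNames(key_of(calls_b), paste(calls_b$sample, calls_b$gene))
  genes <- sort(unique(c(calls_a$gene, calls_b$gene)))
  rows <- list()
  n_all <- 0; c_all <- 0
  for (g in genes) {
    n <- 0; conc <- 0
    for (r in seq_len(nrow(pairing))) {
      a <- ka[paste(pairing$sample_a[r], g)]
      b <- kb[paste(pairing$sample_b[r], g)]
      if (is.na(a) || is.na(b)) {
        warning(sprintf("pair (%s, %s) missing gene %s; skipped",
                        pairing$sample_a[r], pairing$sample_b[r], g),
                call. = FALSE)
        next
      }
      n <- n + 1
      conc <- conc + as.integer(a == b)
    }
    if (n == 0) next
    phat <- conc / n
    half <- 1.96 * sqrt(phat * (1 - phat) / n)
    rows[[g]] <- data.frame(gene = g, n_pairs = n, concordance = phat,
                            ci_lower = max(0, phat - half),
                            ci_upper = min(1, phat + half),
                            stringsAsFactors = FALSE)
    n_all <- n_all + n; c_all <- c_all + conc
  }
  phat <- c_all / n_all
  half <- 1.96 * sqrt(phat * (1 - phat) / n_all)
  rows[["overall"]] <- data.frame(gene = "overall", n_pairs = n_all,
                                  concordance = phat,
                                  ci_lower = max(0, phat - half),
                                  ci_upper = min(1, phat + half),
                                  stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Donor-mixture negative-control read set
#'
#' Builds a "pseudo" read set for one gene by pooling the reads of several
#' donors and sampling uniformly until the output holds the rounded mean
#' donor read count — a read set with no single coherent genotype, used as a
#' negative control: its allele-probability entropy should exceed that of
#' any pure donor.
#'
#' @param donor_readsets List of at least two `kir_readset` for one gene.
#' @param seed Integer RNG seed (same seed, same output).
#' @return A `kir_readset`.
#' @export
make_pseudo_readset <- function(donor_readsets, seed = 1) {
  if (length(donor_readsets) < 2) {
    stop("at least two donor read sets are required", call. = FALSE)
  }
  genes <- unique(vapply(donor_readsets, function(x) x$gene, character(1)))
  if (length(genes) != 1) {
    stop("donor read sets must all belong to one gene", call. = FALSE)
  }
  counts <- vapply(donor_readsets, function(x) nrow(x$reads), numeric(1))
  target <- round(mean(counts))
  pool_id <- unlist(lapply(seq_along(donor_readsets), function(i) {
    paste0("d", i, ":", donor_readsets[[i]]$reads$read_id)
  }))
  pool_seq <- unlist(lapply(donor_readsets, function(x) x$reads$sequence))
  withr::with_seed(seed, {
    take <- sample.int(length(pool_id), target, replace = FALSE)
  })
  kir_readset(genes, pool_id[take], pool_seq[take])
}

#' Bin samples by coverage and summarize entropies
#'
#' @param coverage Numeric vector of per-sample mean coverages.
#' @param entropy Numeric vector of matching allele-probability entropies.
#' @param bin_width Coverage bin width (> 0).
#' @return data.frame with one row per non-empty bin: `bin_lower`,
#'   `bin_upper`, `n`, `median_entropy`, `q1`, `q3`.
#' @export
coverage_entropy_profile <- function(coverage, entropy, bin_width = 10) {
  stopifnot(length(coverage) == length(entropy), length(coverage) > 0)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  lo <- floor(coverage / bin_width) * bin_width
  rows <- lapply(sort(unique(lo)), function(b) {
    e <- entropy[lo == b]
    q <- stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(bin_lower = b, bin_upper = b + bin_width, n = length(e),
               median_entropy = q[2], q1 = q[1], q3 = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.kir_entropy_grid <- function(x, ...) {
  cat(sprintf("Genotype-entropy grid: %d p x %d t, %d iterations/cell\n",
              length(x$p_values), length(x$t_values), x$iterations))
  print(round(x$entropy, 3))
  invisible(x)
}
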