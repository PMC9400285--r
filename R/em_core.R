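# Bootstrapped expectation-maximization over the allele x read alignment
# matrix, and thresholding of the resulting allele probabilities into
# genotype calls.
#
# The alignment matrix M (m alleles x n reads) starts with column r holding
# 1/x_r on the x_r alleles read r matches. Each EM step computes the
# expectation vector E_a = sum_r M[a,r], then re-weights every column by E
# and renormalizes it (a Bayesian update with E as prior and M as
# likelihood). Iteration stops when the sum of squared changes in M drops to
# the convergence threshold alpha. The final E, divided by the read count n,
# is the vector of allele probability estimates.

#' EM run configuration
#'
#' Bundles the genotyper's hyperparameters. Defaults are the operating point
#' used throughout the validation analyses: `alpha = 1e-5`, `n_boot = 100`,
#' `p = 0.5`, `t_threshold = 0.25`.
#'
#' @param alpha Convergence threshold on the sum of squared changes in the
#'   alignment matrix between consecutive iterations.
#' @param n_boot Number of bootstrap subsamples.
#' @param p Fraction of reads drawn in each bootstrap, in (0, 1].
#' @param t_threshold Probability threshold for genotype calling, in (0, 1).
#' @param seed Integer RNG seed for the bootstrap draws.
#' @param max_iterations Iteration cap per EM run.
#' @param min_reads Minimum matched reads required to attempt genotyping.
#' @param replace Draw bootstrap reads with replacement (default FALSE:
#'   subsampling without replacement).
#' @param call_unconverged Call genotypes even when some bootstrap EM runs
#'   hit `max_iterations` (default FALSE: emit a `not_converged` no-call).
#' @return An object of class `kir_em_config`.
#' @export
em_config <- function(alpha = 1e-5, n_boot = 100, p = 0.5, t_threshold = 0.25,
                      seed = 1L, max_iterations = 1000L, min_reads = 1L,
                      replace = FALSE, call_unconverged = FALSE) {
  stopifnot(alpha > 0, n_boot >= 1, p > 0, p <= 1,
            t_threshold > 0, t_threshold < 1,
            max_iterations >= 1, min_reads >= 1)
  structure(list(alpha = alpha, n_boot = as.integer(n_boot), p = p,
                 t_threshold = t_threshold, seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 min_reads = as.integer(min_reads), replace = replace,
                 call_unconverged = call_unconverged),
            class = "kir_em_config")
}

#' Initialize the allele x read alignment matrix
#'
#' Column r of the matrix distributes unit mass uniformly over the `x_r`
#' alleles read r matched: `M[a, r] = 1/x_r` if r matched a, else 0. Every
#' column sums to 1.
#'
#' @param alignments A `kir_alignments` with at least one read.
#' @param alleles Optional character vector fixing the row order (defaults to
#'   the sorted union of matched alleles).
#' @return A `kir_alignment_matrix`: list with `alleles`, `reads`, `M`.
#' @export
initialize_alignment_matrix <- function(alignments, alleles = NULL) {
  stopifnot(inherits(alignments, "kir_alignments"))
  if (length(alignments$entries) == 0) {
    stop("no aligned reads: cannot initialize alignment matrix",
         call. = FALSE)
  }
  if (is.null(alleles)) alleles <- alignments$alleles
  reads <- names(alignments$entries)
  M <- matrix(0, nrow = length(alleles), ncol = length(reads),
              dimnames = list(alleles, reads))
  for (r in seq_along(reads)) {
    hit <- alignments$entries[[r]]
    M[hit, r] <- 1 / length(hit)
  }
  structure(list(alleles = alleles, reads = reads, M = M),
            class = "kir_alignment_matrix")
}

#' Run expectation-maximization to convergence
#'
#' Iterates the expectation (`E_a = sum_r M[a,r]`) and Bayesian column
#' update (`M'[a,r] = M[a,r] E_a / sum_a M[a,r] E_a`) until the sum of
#' squared changes in M is at most `alpha`, or `max_iterations` is reached.
#' Column stochasticity is preserved by every update, so `sum(E) = n` at
#' every step; the returned probabilities are `E / n`.
#'
#' @param M0 A `kir_alignment_matrix` from [initialize_alignment_matrix()].
#' @param alpha Convergence threshold (see [em_config()]).
#' @param max_iterations Iteration cap; on hitting it the result is returned
#'   with `converged = FALSE` (never an error).
#' @param gene Gene label carried on the result.
#' @param keep_matrix Attach the final alignment matrix as element `M`
#'   (diagnostics; default FALSE).
#' @return A `kir_allele_probs`: list with `gene`, `probs` (named numeric
#'   summing to 1), `n_reads`, `converged`, `iterations`.
#' @export
em_iterate <- function(M0, alpha = 1e-5, max_iterations = 1000,
                       gene = NA_character_, keep_matrix = FALSE) {
  stopifnot(inherits(M0, "kir_alignment_matrix"))
  M <- M0$M
  m <- nrow(M); n <- ncol(M)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    E <- rowSums(M)
    W <- M * E                      # recycles E down each column
    cs <- colSums(W)
    Mn <- W / rep(cs, each = m)
    delta <- sum((Mn - M)^2)
    M <- Mn
    if (delta <= alpha) { converged <- TRUE; break }
  }
  E <- rowSums(M)
  out <- structure(list(gene = gene,
                        probs = E / n,
                        n_reads = n, converged = converged,
                        iterations = iter),
                   class = "kir_allele_probs")
  if (keep_matrix) out$M <- M
  out
}

#' Bootstrapped allele probability estimation
#'
#' Runs `n_boot` EM estimations, each on `ceiling(p * N)` reads drawn
#' uniformly (without replacement by default) from the N aligned reads, and
#' averages the resulting probability vectors. Alleles absent from a
#' subsample contribute probability 0 in that bootstrap. Averaging over
#' subsamples counters the EM's tendency to lock onto homozygous local
#' optima driven by small asymmetries in the alignment data. Deterministic
#' given `config$seed`.
#'
#' @param alignments A `kir_alignments`.
#' @param config A `kir_em_config`.
#' @return A `kir_allele_probs`; `converged` is TRUE iff every bootstrap EM
#'   run converged, `iterations` is the maximum over bootstraps.
#' @export
bootstrap_probabilities <- function(alignments, config = em_config()) {
  stopifnot(inherits(alignments, "kir_alignments"),
            inherits(config, "kir_em_config"))
  N <- length(alignments$entries)
  if (N < config$min_reads) {
    stop(sprintf("too few aligned reads (%d < min_reads %d)",
                 N, config$min_reads), call. = FALSE)
  }
  alleles <- alignments$alleles
  n_draw <- max(1L, as.integer(ceiling(config$p * N)))
  acc <- stats::setNames(numeric(length(alleles)), alleles)
  all_converged <- TRUE
  max_iter_seen <- 0L
  withr::with_seed(config$seed, {
    for (b in seq_len(config$n_boot)) {
      idx <- sample.int(N, n_draw, replace = config$replace)
      sub <- new_alignments(alignments$gene, alignments$entries[idx])
      M0 <- initialize_alignment_matrix(sub)
      est <- em_iterate(M0, alpha = config$alpha,
                        max_iterations = config$max_iterations,
                        gene = alignments$gene)
      acc[names(est$probs)] <- acc[names(est$probs)] + est$probs
      all_converged <- all_converged && est$converged
      max_iter_seen <- max(max_iter_seen, est$iterations)
    }
  })
  structure(list(gene = alignments$gene, probs = acc / config$n_boot,
                 n_reads = N, converged = all_converged,
                 iterations = max_iter_seen),
            class = "kir_allele_probs")
}

no_call_reasons <- function() {
  c("none", "no_reads", "none_above_threshold",
    "more_than_two_above_threshold", "not_converged")
}

new_genotype_call <- function(gene, zygosity, alleles, reason, probs) {
  structure(list(gene = gene, zygosity = zygosity, alleles = alleles,
                 no_call_reason = reason, probabilities = probs),
            class = "kir_genotype_call")
}

#' Threshold allele probabilities into a genotype call
#'
#' Alleles with probability strictly greater than `t_threshold` (after
#' coding-group collapse when `groups` is supplied) determine the call:
#' exactly one above threshold is a homozygous call (the allele counted
#' twice), exactly two is a heterozygous call, and zero or more than two
#' yields a no-call with the corresponding reason. Ties at exactly the
#' threshold fall below it.
#'
#' @param probs A `kir_allele_probs`.
#' @param t_threshold Calling threshold in (0, 1).
#' @param groups Optional full-name to coding-group mapping; when given,
#'   probabilities are collapsed before thresholding and calls are made on
#'   coding groups.
#' @param call_unconverged Call even if `probs$converged` is FALSE.
#' @return A `kir_genotype_call`: list with `gene`, `zygosity`
#'   (`"homozygous"`, `"heterozygous"` or `"no_call"`), `alleles` (length 2
#'   or 0), `no_call_reason`, `probabilities` (the thresholded, possibly
#'   collapsed vector).
#' @export
call_genotype <- function(probs, t_threshold = 0.25, groups = NULL,
                          call_unconverged = FALSE) {
  stopifnot(inherits(probs, "kir_allele_probs"),
            t_threshold > 0, t_threshold < 1)
  pv <- probs$probs
  if (!is.null(groups)) pv <- collapse_probabilities(pv, groups)
  if (!probs$converged && !call_unconverged) {
    return(new_genotype_call(probs$gene, "no_call", character(0),
                             "not_converged", pv))
  }
  above <- names(pv)[pv > t_threshold]
  if (length(above) == 1) {
    new_genotype_call(probs$gene, "homozygous", rep(above, 2), "none", pv)
  } else if (length(above) == 2) {
    new_genotype_call(probs$gene, "heterozygous", sort(above), "none", pv)
  } else if (length(above) == 0) {
    new_genotype_call(probs$gene, "no_call", character(0),
                      "none_above_threshold", pv)
  } else {
    new_genotype_call(probs$gene, "no_call", character(0),
                      "more_than_two_above_threshold", pv)
  }
}

#' @export
print.kir_genotype_call <- function(x, ...) {
  if (x$zygosity == "no_call") {
    cat(sprintf("%s: no_call (%s)\n", x$gene, x$no_call_reason))
  } else {
    cat(sprintf("%s: %s %s\n", x$gene, x$zygosity,
                paste(x$alleles, collapse = "/")))
  }
  invisible(x)
}

#' @export
print.kir_allele_probs <- function(x, ...) {
  cat(sprintf("KIR allele probabilities: %s, %d reads, converged=%s\n",
              x$gene, x$n_reads, x$converged))
  top <- sort(x$probs, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(x$probs > 0)))]
  for (i in seq_along(top)) {
    cat(sprintf("  %-22s %.4f\n", names(top)[i], top[i]))
  }
  invisible(x)
}
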