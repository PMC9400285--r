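# Downstream statistics over called genotypes: allele frequencies,
# copy-number (KIR-space) encoding, carrier association tests with
# multiple-testing correction, and genetic effect models ranked by BIC.

#' Per-gene allele frequencies from a genotype table
#'
#' Every called sample contributes two allele copies per gene (a homozygote
#' contributes two copies of one coding group); no-call rows are excluded
#' from numerator and denominator. Genes with zero called samples are
#' omitted with a warning. Frequencies sum to 1 within each gene.
#'
#' @param table Genotype table with columns `sample`, `gene`, `zygosity`,
#'   `allele1`, `allele2` (coding-group names), as from
#'   [genotype_calls_table()].
#' @return data.frame with columns `gene`, `coding_group`, `frequency`,
#'   sorted by gene then decreasing frequency.
#' @export
allele_frequencies <- function(table) {
  stopifnot(nrow(table) > 0)
  rows <- list()
  for (g in sort(unique(table$gene))) {
    sub <- table[table$gene == g & table$zygosity != "no_call", , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("gene %s has no called samples; omitted", g),
              call. = FALSE)
      next
    }
    copies <- c(sub$allele1, sub$allele2)
    freq <- table(copies) / (2 * nrow(sub))
    rows[[g]] <- data.frame(gene = g, coding_group = names(freq),
                            frequency = as.numeric(freq),
                            stringsAsFactors = FALSE)
    rows[[g]] <- rows[[g]][order(-rows[[g]]$frequency,
                                 rows[[g]]$coding_group), , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Encode genotypes as a samples x alleles copy-number matrix
#'
#' Represents each sample as a point in "KIR-space": one column per coding
#' group in `allele_universe`, holding 0, 1 or 2 copies. A homozygous call
#' puts 2 in one column, a heterozygous call 1 in each of two columns, and a
#' no-call contributes zeros for that gene.
#'
#' @param table Genotype table (see [allele_frequencies()]).
#' @param allele_universe Ordered character vector of coding-group names
#'   covering every called allele.
#' @return Integer matrix with sample ids as row names and
#'   `allele_universe` as column names.
#' @export
encode_kir_space <- function(table, allele_universe = NULL) {
  called <- table[table$zygosity != "no_call", , drop = FALSE]
  seen <- unique(c(called$allele1, called$allele2))
  seen <- seen[!is.na(seen)]
  if (is.null(allele_universe)) {
    allele_universe <- sort(seen)
  } else if (length(setdiff(seen, allele_universe)) > 0) {
    stop(sprintf("called allele outside the universe: %s",
                 setdiff(seen, allele_universe)[1]), call. = FALSE)
  }
  samples <- unique(table$sample)
  M <- matrix(0L, nrow = length(samples), ncol = length(allele_universe),
              dimnames = list(samples, allele_universe))
  for (r in seq_len(nrow(called))) {
    s <- called$sample[r]
    M[s, called$allele1[r]] <- M[s, called$allele1[r]] + 1L
    M[s, called$allele2[r]] <- M[s, called$allele2[r]] + 1L
  }
  M
}

new_assoc_result <- function(allele, trait, test, statistic, p_value,
                             odds_ratio = NA_real_, direction = NA_character_,
                             counts = NULL, degenerate = FALSE) {
  structure(list(allele = allele, trait = trait, test = test,
                 statistic = statistic, p_value = p_value,
                 adjusted_p = NA_real_, odds_ratio = odds_ratio,
                 direction = direction, counts = counts,
                 degenerate = degenerate),
            class = "kir_assoc_result")
}

#' Carrier association with a binary trait (Fisher's exact test)
#'
#' Builds the 2x2 carrier-by-trait contingency table and returns the
#' two-sided exact p-value (sum of hypergeometric table probabilities not
#' exceeding that of the observed table) and the sample odds ratio
#' `ad / bc` (0 and Inf allowed). A degenerate margin (all-TRUE or
#' all-FALSE vector) yields p = 1 with the result flagged.
#'
#' @param carrier Logical vector: sample has >= 1 copy of the allele.
#' @param trait Logical vector, same length.
#' @param allele,trait_label Labels carried on the result.
#' @return A `kir_assoc_result` with fields `p_value`, `odds_ratio`,
#'   `counts` (the 2x2 table), `direction` (`"positive"`/`"negative"`),
#'   `degenerate`.
#' @export
carrier_association_fisher <- function(carrier, trait, allele = "allele",
                                       trait_label = "trait") {
  stopifnot(length(carrier) == length(trait), length(carrier) >= 2,
            !anyNA(carrier), !anyNA(trait))
  carrier <- as.logical(carrier); trait <- as.logical(trait)
  counts <- matrix(c(sum(carrier & trait), sum(carrier & !trait),
                     sum(!carrier & trait), sum(!carrier & !trait)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(carrier = c("yes", "no"),
                                   trait = c("yes", "no")))
  if (all(carrier) || !any(carrier) || all(trait) || !any(trait)) {
    return(new_assoc_result(allele, trait_label, "fisher_exact",
                            statistic = NA_real_, p_value = 1,
                            odds_ratio = NA_real_, counts = counts,
                            degenerate = TRUE))
  }
  ft <- stats::fisher.test(counts, alternative = "two.sided")
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  or <- (a * d) / (b * c)  # sample OR, not the conditional MLE
  new_assoc_result(allele, trait_label, "fisher_exact",
                   statistic = or, p_value = ft$p.value, odds_ratio = or,
                   direction = if (is.nan(or) || or >= 1) "positive"
                               else "negative",
                   counts = counts)
}

#' Carrier association with a continuous trait (Mann-Whitney U test)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing trait values in
#' carriers versus non-carriers. The p-value is exact (full rank-assignment
#' null) when the smaller group has at most 8 observations and there are no
#' ties, and otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param carrier Logical vector: sample has >= 1 copy of the allele.
#' @param values Numeric trait values, same length.
#' @param allele,trait_label Labels carried on the result.
#' @return A `kir_assoc_result` with `statistic` (U for the carrier group),
#'   `p_value`, `direction`, and group medians in `counts`.
#' @export
carrier_association_mwu <- function(carrier, values, allele = "allele",
                                    trait_label = "trait") {
  stopifnot(length(carrier) == length(values), !anyNA(carrier),
            !anyNA(values))
  carrier <- as.logical(carrier)
  x <- values[carrier]; y <- values[!carrier]
  if (length(x) == 0 || length(y) == 0) {
    stop("both carrier and non-carrier groups must be non-empty",
         call. = FALSE)
  }
  ties <- anyDuplicated(values) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # all observations tied: no evidence either way
  med <- c(carrier = stats::median(x), non_carrier = stats::median(y))
  new_assoc_result(allele, trait_label, "mann_whitney_u",
                   statistic = unname(wt$statistic), p_value = p,
                   direction = if (med[1] >= med[2]) "positive"
                               else "negative",
                   counts = med)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement. Input order is preserved.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @param method `"bonferroni"` (default) or `"benjamini_hochberg"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p_values,
                           method = c("bonferroni", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values,
                  method = if (method == "bonferroni") "bonferroni" else "BH")
}

#' Scan all alleles of a copy-number matrix against one trait
#'
#' Applies [carrier_association_fisher()] (binary trait) or
#' [carrier_association_mwu()] (continuous trait) to every allele column
#' with carrier frequency at least `min_allele_freq`, then adjusts p-values.
#'
#' @param copies Samples x alleles copy-number matrix
#'   ([encode_kir_space()]).
#' @param trait Per-sample trait vector (logical or numeric), aligned with
#'   the matrix rows.
#' @param min_allele_freq Minimum carrier fraction for an allele to be
#'   tested (default 0.01).
#' @param adjust Adjustment method passed to [adjust_pvalues()].
#' @return data.frame with one row per tested allele: `allele`, `test`,
#'   `statistic`, `p_value`, `adjusted_p`, `odds_ratio`, `direction`.
#' @export
scan_carrier_associations <- function(copies, trait, min_allele_freq = 0.01,
                                      adjust = "bonferroni") {
  stopifnot(nrow(copies) == length(trait))
  binary <- is.logical(trait) || all(trait %in% c(0, 1))
  rows <- list()
  for (al in colnames(copies)) {
    carrier <- copies[, al] >= 1
    if (mean(carrier) < min_allele_freq || all(carrier)) next
    res <- if (binary) {
      carrier_association_fisher(carrier, as.logical(trait), allele = al)
    } else {
      carrier_association_mwu(carrier, trait, allele = al)
    }
    rows[[al]] <- data.frame(allele = al, test = res$test,
                             statistic = res$statistic,
                             p_value = res$p_value,
                             odds_ratio = res$odds_ratio,
                             direction = res$direction,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(allele = character(0), test = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0), odds_ratio = numeric(0),
                      direction = character(0)))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- adjust_pvalues(out$p_value, adjust)
  rownames(out) <- NULL
  out[, c("allele", "test", "statistic", "p_value", "adjusted_p",
          "odds_ratio", "direction")]
}

# Genotype copy count -> model covariate.
effect_encodings <- function() {
  list(dominant = function(c) as.numeric(c >= 1),
       semidominant = function(c) as.numeric(c),
       recessive = function(c) as.numeric(c == 2))
}

#' Fit dominant / semi-dominant / recessive effect models
#'
#' Models a continuous phenotype as a linear function of an allele's encoded
#' genotype, `phenotype = m * x(genotype) + b`, under three genotype
#' encodings: dominant (2 copies -> 1, 1 -> 1, 0 -> 0), semi-dominant
#' (2 -> 2, 1 -> 1, 0 -> 0: homozygotes twice as expressive), and recessive
#' (2 -> 1, 1 -> 0, 0 -> 0: only homozygotes have an effect). Each encoding
#' is fit by ordinary least squares and scored with
#' `BIC = n log(rss / n) + k log(n)` with k = 3 free parameters (slope,
#' intercept, error variance); the model with minimum BIC is selected. Only
#' BIC differences/ranks are meaningful. An encoding with fewer than two
#' distinct covariate values is skipped and flagged.
#'
#' @param copies Integer vector of per-sample allele copy counts (0/1/2).
#' @param phenotype Numeric phenotype, same length, n >= 3.
#' @return A `kir_effect_fit`: list with `fits` (data.frame: `model`,
#'   `slope`, `intercept`, `n`, `rss`, `bic`, `fitted`) and `best` (name of
#'   the minimum-BIC model).
#' @export
fit_effect_models <- function(copies, phenotype) {
  stopifnot(length(copies) == length(phenotype), length(copies) >= 3,
            all(copies %in% 0:2), !anyNA(phenotype))
  n <- length(phenotype)
  rows <- list()
  for (model in names(effect_encodings())) {
    x <- effect_encodings()[[model]](copies)
    if (length(unique(x)) < 2) {
      rows[[model]] <- data.frame(model = model, slope = NA, intercept = NA,
                                  n = n, rss = NA, bic = NA, fitted = FALSE,
                                  stringsAsFactors = FALSE)
      next
    }
    fit <- stats::lm.fit(cbind(intercept = 1, x = x), phenotype)
    rss <- sum(fit$residuals^2)
    bic <- if (rss == 0) -Inf else n * log(rss / n) + 3 * log(n)
    rows[[model]] <- data.frame(model = model,
                                slope = unname(fit$coefficients["x"]),
                                intercept =
                                  unname(fit$coefficients["intercept"]),
                                n = n, rss = rss, bic = bic, fitted = TRUE,
                                stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  fitted <- fits[fits$fitted, , drop = FALSE]
  if (nrow(fitted) == 0) stop("no encoding could be fit", call. = FALSE)
  best <- fitted$model[which.min(fitted$bic)]
  structure(list(fits = fits, best = best), class = "kir_effect_fit")
}

#' @export
print.kir_effect_fit <- function(x, ...) {
  cat("Genetic effect model comparison (min-BIC selection):\n")
  print(x$fits, digits = 4)
  cat(sprintf("best model: %s\n", x$best))
  invisible(x)
}

#' @export
print.kir_assoc_result <- function(x, ...) {
  cat(sprintf("%s vs %s [%s]: p = %.4g", x$allele, x$trait, x$test,
              x$p_value))
  if (!is.na(x$odds_ratio)) cat(sprintf(", OR = %.3g", x$odds_ratio))
  if (x$degenerate) cat(" (degenerate margin)")
  cat("\n")
  invisible(x)
}
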