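# Downstream statistics: frequencies, KIR-space encoding, carrier tests,
# multiple-testing adjustment, effect models.

geno_table <- function() {
  data.frame(
    sample = c("s1", "s2", "s3"),
    gene = "KIR2DL4",
    zygosity = c("homozygous", "heterozygous", "no_call"),
    allele1 = c("KIR2DL4*005", "KIR2DL4*005", NA),
    allele2 = c("KIR2DL4*005", "KIR2DL4*001", NA),
    stringsAsFactors = FALSE)
}

test_that("allele frequencies count two copies per called sample", {
  freq <- allele_frequencies(geno_table())
  expect_equal(freq$frequency[freq$coding_group == "KIR2DL4*005"], 0.75)
  expect_equal(freq$frequency[freq$coding_group == "KIR2DL4*001"], 0.25)
  expect_equal(sum(freq$frequency), 1)

  allnc <- geno_table()
  allnc$zygosity <- "no_call"
  allnc$allele1 <- allnc$allele2 <- NA
  more <- rbind(geno_table(), transform(allnc, gene = "KIR2DL1"))
  expect_warning(freq2 <- allele_frequencies(more), "KIR2DL1")
  expect_false("KIR2DL1" %in% freq2$gene)
})

test_that("KIR-space encoding gives 0/1/2 copies and correct row sums", {
  M <- encode_kir_space(geno_table())
  expect_equal(M["s1", "KIR2DL4*005"], 2L)
  expect_equal(M["s2", "KIR2DL4*005"], 1L)
  expect_equal(M["s2", "KIR2DL4*001"], 1L)
  expect_equal(unname(rowSums(M)), c(2, 2, 0))

  two <- rbind(geno_table(),
               data.frame(sample = c("s1", "s2", "s3"), gene = "KIR2DL1",
                          zygosity = "homozygous", allele1 = "KIR2DL1*002",
                          allele2 = "KIR2DL1*002", stringsAsFactors = FALSE))
  M2 <- encode_kir_space(two)
  expect_equal(unname(rowSums(M2)), c(4, 4, 2))  # 2 x called genes
  expect_error(encode_kir_space(geno_table(), allele_universe = "other"),
               "outside the universe")
})

test_that("Fisher p-values equal the hypergeometric tail sums", {
  # [[3,1],[1,3]]: two-sided p = 34/70 by full enumeration over X in 0..4
  carrier <- rep(c(TRUE, FALSE), each = 4)
  trait <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  res <- carrier_association_fisher(carrier, trait)
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)
  expect_equal(res$direction, "positive")

  # [[4,0],[0,4]]: p = 2/70
  res2 <- carrier_association_fisher(rep(c(TRUE, FALSE), each = 4),
                                     rep(c(TRUE, FALSE), each = 4))
  expect_equal(res2$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(res2$odds_ratio, Inf)

  # degenerate margin: flagged, p = 1
  res3 <- carrier_association_fisher(c(TRUE, TRUE, FALSE, FALSE),
                                     rep(FALSE, 4))
  expect_equal(res3$p_value, 1)
  expect_true(res3$degenerate)
})

test_that("Mann-Whitney p-values match rank enumeration and symmetry", {
  res <- carrier_association_mwu(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$direction, "negative")

  # swapping group labels leaves p unchanged
  res_sw <- carrier_association_mwu(c(FALSE, FALSE, TRUE, TRUE),
                                    c(1, 2, 3, 4))
  expect_equal(res_sw$p_value, res$p_value)

  # identical constant groups: p = 1 (tie-corrected approximation)
  res_t <- carrier_association_mwu(c(TRUE, TRUE, FALSE, FALSE),
                                   c(5, 5, 5, 5))
  expect_equal(res_t$p_value, 1)

  expect_error(carrier_association_mwu(rep(TRUE, 4), 1:4), "non-empty")
})

test_that("adjustment implements Bonferroni capping and BH step-up", {
  expect_equal(adjust_pvalues(rep(0.01, 20))[1], 0.2)
  expect_equal(adjust_pvalues(rep(0.2, 10))[1], 1)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "benjamini_hochberg"),
               c(0.03, 0.03, 0.03))
  set.seed(61)
  p <- stats::runif(50)
  bonf <- adjust_pvalues(p)
  bh <- adjust_pvalues(p, "benjamini_hochberg")
  expect_true(all(bonf >= p & bonf <= 1))
  expect_true(all(bh >= p - 1e-12))
  # BH adjusted values are monotone in raw-p order
  expect_true(all(diff(bh[order(p)]) >= -1e-12))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("carrier scan tests frequent alleles and adjusts p-values", {
  set.seed(62)
  n <- 60
  copies <- cbind(common = rbinom(n, 2, 0.5), rare = rbinom(n, 2, 0.002))
  rownames(copies) <- sprintf("s%02d", 1:n)
  trait <- rbinom(n, 1, 0.5)
  res <- scan_carrier_associations(copies, trait == 1,
                                   min_allele_freq = 0.05)
  expect_equal(res$allele, "common")
  expect_equal(res$test, "fisher_exact")
  expect_true(all(res$adjusted_p >= res$p_value))
  resc <- scan_carrier_associations(copies, rnorm(n), min_allele_freq = 0.05)
  expect_equal(resc$test, "mann_whitney_u")
})

test_that("effect encodings follow the dominant/semi-dominant/recessive maps", {
  set.seed(63)
  copies <- c(rep(0, 10), rep(1, 10), rep(2, 10))
  # noiseless dominant phenotype: dominant fits exactly, lowest BIC
  y <- 10 - 5 * as.numeric(copies >= 1)
  fit <- fit_effect_models(copies, y)
  dom <- fit$fits[fit$fits$model == "dominant", ]
  expect_equal(dom$rss, 0)
  expect_equal(dom$slope, -5)
  expect_equal(dom$intercept, 10)
  expect_equal(fit$best, "dominant")

  # noiseless semi-dominant and recessive phenotypes select their model
  fit_s <- fit_effect_models(copies, 1 + 2 * copies)
  expect_equal(fit_s$best, "semidominant")
  fit_r <- fit_effect_models(copies, 3 + 4 * as.numeric(copies == 2))
  expect_equal(fit_r$best, "recessive")
})

test_that("model selection is invariant to phenotype shift and scale", {
  set.seed(64)
  copies <- sample(0:2, 120, replace = TRUE)
  y <- 5 * as.numeric(copies == 2) + rnorm(120, sd = 3)
  base <- fit_effect_models(copies, y)
  expect_equal(fit_effect_models(copies, y + 100)$best, base$best)
  expect_equal(fit_effect_models(copies, y * 7.3)$best, base$best)
})

test_that("without heterozygotes, dominant and recessive fits coincide", {
  set.seed(65)
  copies <- rep(c(0, 2), each = 15)
  y <- 2 + 3 * (copies == 2) + rnorm(30)
  fit <- fit_effect_models(copies, y)
  dom <- fit$fits[fit$fits$model == "dominant", ]
  rec <- fit$fits[fit$fits$model == "recessive", ]
  expect_equal(dom$slope, rec$slope)
  expect_equal(dom$rss, rec$rss)
  expect_equal(dom$bic, rec$bic)

  # constant covariate under an encoding: that model is skipped
  all_carrier <- rep(c(1, 2), 6)
  fit3 <- fit_effect_models(all_carrier, rnorm(12))
  expect_false(fit3$fits$fitted[fit3$fits$model == "dominant"])
  expect_true(fit3$fits$fitted[fit3$fits$model == "semidominant"])
})
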