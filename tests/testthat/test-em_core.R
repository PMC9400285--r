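# Expectation-maximization, bootstrapping, and threshold calling.

# (the EM reference oracle and random instance generator live in
# helper-oracles.R)

test_that("alignment matrix initialization spreads unit mass over matches", {
  aln <- make_alignments("KIR2DL1", list(r1 = c("A", "B"), r2 = "A",
                                         r3 = c("B", "C")))
  M0 <- initialize_alignment_matrix(aln)
  expect_equal(unname(colSums(M0$M)), c(1, 1, 1))
  expect_equal(M0$M[, "r1"], c(A = 0.5, B = 0.5, C = 0))
  expect_equal(M0$M[, "r2"], c(A = 1, B = 0, C = 0))
  empty <- make_alignments("KIR2DL1", stats::setNames(list(), character(0)))
  expect_error(initialize_alignment_matrix(empty), "no aligned reads")
})

test_that("EM fixed points match hand-derived cases", {
  # single read, single allele: immediate certainty
  p1 <- em_iterate(initialize_alignment_matrix(
    make_alignments("g", list(r1 = "A"))))
  expect_equal(unname(p1$probs["A"]), 1)
  expect_equal(p1$iterations, 1L)
  expect_true(p1$converged)

  # two reads with disjoint matches: symmetric fixed point 0.5/0.5
  p2 <- em_iterate(initialize_alignment_matrix(
    make_alignments("g", list(r1 = "A", r2 = "B"))))
  expect_equal(unname(p2$probs[c("A", "B")]), c(0.5, 0.5))

  # an unambiguous read pulls an ambiguous one to its allele
  p3 <- em_iterate(initialize_alignment_matrix(
    make_alignments("g", list(r1 = "A", r2 = c("A", "B")))), alpha = 1e-12)
  expect_gt(p3$probs["A"], 0.999)
  expect_lt(p3$probs["B"], 0.001)

  # fully symmetric ambiguity persists (the motivation for bootstrapping)
  p4 <- em_iterate(initialize_alignment_matrix(
    make_alignments("g", list(r1 = c("A", "B"), r2 = c("A", "B")))))
  expect_equal(unname(p4$probs[c("A", "B")]), c(0.5, 0.5))
})

test_that("EM agrees with the loop-coded oracle on random instances", {
  set.seed(41)
  for (i in 1:25) {
    entries <- random_instance()
    aln <- make_alignments("g", entries)
    got <- em_iterate(initialize_alignment_matrix(aln), alpha = 1e-8,
                      keep_matrix = TRUE)
    want <- em_oracle(entries, alpha = 1e-8)
    expect_equal(got$probs, want$probs, tolerance = 1e-10)
    # invariants: columns stay stochastic, expectation mass equals n
    expect_equal(unname(colSums(got$M)), rep(1, length(entries)),
                 tolerance = 1e-12)
    expect_equal(sum(got$probs), 1, tolerance = 1e-12)
  }
})

test_that("iteration cap yields converged = FALSE, never an error", {
  aln <- make_alignments("g", list(r1 = "A", r2 = c("A", "B")))
  p <- em_iterate(initialize_alignment_matrix(aln), alpha = 1e-300,
                  max_iterations = 3)
  expect_false(p$converged)
  expect_equal(p$iterations, 3L)
})

test_that("degenerate bootstrap reduces to plain EM", {
  aln <- make_alignments("g", list(r1 = "A", r2 = c("A", "B"), r3 = "B"))
  cfg <- em_config(n_boot = 1, p = 1, seed = 5)
  expect_equal(bootstrap_probabilities(aln, cfg)$probs,
               em_iterate(initialize_alignment_matrix(aln))$probs,
               tolerance = 1e-12)
})

test_that("bootstrap is deterministic, label-invariant, and symmetric", {
  aln <- make_alignments("g", list(r1 = "A", r2 = "B", r3 = c("A", "B")))
  cfg <- em_config(n_boot = 200, p = 0.5, seed = 17)
  pr <- bootstrap_probabilities(aln, cfg)
  # same seed twice: identical
  expect_identical(pr$probs, bootstrap_probabilities(aln, cfg)$probs)
  # symmetric generator: A and B within Monte-Carlo tolerance
  expect_lt(abs(pr$probs["A"] - pr$probs["B"]), 0.05)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-9)
  # relabeling reads leaves the estimate unchanged
  relabeled <- make_alignments("g", list(x1 = "A", x2 = "B",
                                         x3 = c("A", "B")))
  expect_equal(bootstrap_probabilities(relabeled, cfg)$probs, pr$probs)

  # unanimous alignments give certainty for any seed and fraction
  unan <- make_alignments("g", list(r1 = "A", r2 = "A", r3 = "A"))
  for (s in 1:3) {
    pu <- bootstrap_probabilities(unan, em_config(n_boot = 20, p = 0.4,
                                                  seed = s))
    expect_equal(unname(pu$probs["A"]), 1)
  }
  expect_error(
    bootstrap_probabilities(aln, em_config(min_reads = 10, seed = 1)),
    "too few")
})

test_that("thresholding implements the one/two/none-or-many rule", {
  hom <- call_genotype(make_probs("g", c(A = 0.90, B = 0.10)), 0.5)
  expect_equal(hom$zygosity, "homozygous")
  expect_equal(hom$alleles, c("A", "A"))

  het <- call_genotype(make_probs("g", c(A = 0.55, B = 0.40, C = 0.05)),
                       0.25)
  expect_equal(het$zygosity, "heterozygous")
  expect_equal(het$alleles, c("A", "B"))

  many <- call_genotype(make_probs("g", c(A = 0.40, B = 0.35, C = 0.25)),
                        0.2)
  expect_equal(many$zygosity, "no_call")
  expect_equal(many$no_call_reason, "more_than_two_above_threshold")

  none <- call_genotype(make_probs("g", c(A = 0.3, B = 0.3, C = 0.4)), 0.6)
  expect_equal(none$no_call_reason, "none_above_threshold")

  # ties at exactly t fall below threshold (strict comparison)
  tie <- call_genotype(make_probs("g", c(A = 0.25, B = 0.75)), 0.25)
  expect_equal(tie$zygosity, "homozygous")
  expect_equal(tie$alleles, c("B", "B"))

  # collapse before thresholding merges sibling mass
  groups <- c(A1 = "A", A2 = "A", B1 = "B")
  coll <- call_genotype(make_probs("g", c(A1 = 0.3, A2 = 0.3, B1 = 0.4)),
                        0.35, groups = groups)
  expect_equal(coll$zygosity, "heterozygous")
  expect_equal(coll$alleles, c("A", "B"))

  # non-convergence blocks the call unless explicitly allowed
  nc <- make_probs("g", c(A = 0.9, B = 0.1), converged = FALSE)
  expect_equal(call_genotype(nc, 0.25)$no_call_reason, "not_converged")
  expect_equal(call_genotype(nc, 0.25, call_unconverged = TRUE)$zygosity,
               "homozygous")
})

test_that("raising t never turns a none-above-threshold into a call", {
  set.seed(43)
  for (i in 1:30) {
    p <- stats::runif(4); p <- p / sum(p)
    probs <- make_probs("g", stats::setNames(p, LETTERS[1:4]))
    ts <- sort(stats::runif(5, 0.05, 0.95))
    none_seen <- FALSE
    for (t in ts) {
      cl <- call_genotype(probs, t)
      if (none_seen) {
        expect_equal(cl$no_call_reason, "none_above_threshold")
      }
      if (cl$zygosity == "no_call" &&
          cl$no_call_reason == "none_above_threshold") {
        none_seen <- TRUE
      }
    }
  }
})

test_that("readset genotyping handles empty and synonymous-sibling input", {
  db <- fixture_db()
  empty <- kir_readset("KIR2DL1", character(0), character(0))
  cl <- genotype_readset(empty, db, em_config(seed = 1))
  expect_equal(cl$zygosity, "no_call")
  expect_equal(cl$no_call_reason, "no_reads")

  # reads simulated from either synonymous sibling collapse to the same call
  cfg <- em_config(seed = 3)
  c1 <- genotype_readset(simulate_reads(db, "KIR2DL3", "KIR2DL3*00101",
                                        depth = 20, seed = 9), db, cfg)
  c2 <- genotype_readset(simulate_reads(db, "KIR2DL3", "KIR2DL3*00102",
                                        depth = 20, seed = 9), db, cfg)
  expect_equal(c1$zygosity, "homozygous")
  expect_equal(c1$alleles, c2$alleles)
  expect_equal(c1$alleles[1], "KIR2DL3*001")
})
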