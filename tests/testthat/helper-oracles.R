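# Independent reference oracles used to cross-check the implementation.
# These are deliberately written as direct enumerations / elementwise loops,
# not via the code paths they check.

# EM recurrence coded as plain loops: M[a,r] = 1/x_r; E_a = sum_r M[a,r];
# M'[a,r] = M[a,r] E_a / sum_a M[a,r] E_a; stop when sum (M'-M)^2 <= alpha.
em_oracle <- function(entries, alpha = 1e-5, max_iterations = 1000) {
  alleles <- sort(unique(unlist(entries)))
  reads <- sort(names(entries))
  entries <- entries[reads]
  m <- length(alleles); n <- length(reads)
  M <- matrix(0, m, n, dimnames = list(alleles, reads))
  for (r in reads) for (a in entries[[r]]) M[a, r] <- 1 / length(entries[[r]])
  for (it in seq_len(max_iterations)) {
    E <- numeric(m)
    for (a in 1:m) for (r in 1:n) E[a] <- E[a] + M[a, r]
    Mn <- M
    for (r in 1:n) {
      denom <- 0
      for (a in 1:m) denom <- denom + M[a, r] * E[a]
      for (a in 1:m) Mn[a, r] <- M[a, r] * E[a] / denom
    }
    delta <- sum((Mn - M)^2)
    M <- Mn
    if (delta <= alpha) break
  }
  E <- numeric(m); for (a in 1:m) E[a] <- sum(M[a, ])
  list(probs = stats::setNames(E / n, alleles), iterations = it, M = M)
}

# Random read-to-allele match structure (m <= m_max alleles, n <= n_max reads).
random_instance <- function(m_max = 6, n_max = 50) {
  m <- sample(2:m_max, 1)
  n <- sample(2:n_max, 1)
  alleles <- LETTERS[1:m]
  entries <- lapply(1:n, function(r) sort(sample(alleles, sample(1:m, 1))))
  names(entries) <- sprintf("r%03d", 1:n)
  entries
}

# Two-sided Fisher p by full hypergeometric enumeration of the 2x2 table
# [[a, b], [c, d]] with fixed margins: sum of probabilities of tables no
# more probable than the observed one.
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; n <- a + b + c + d; c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (no ties assumed).
mwu_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  u_of <- function(g1) {
    a <- vals[g1]; b <- vals[-g1]
    sum(outer(a, b, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  us <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}
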