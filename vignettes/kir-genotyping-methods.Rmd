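---
title: "Methods: KIR allele genotyping by bootstrapped expectation-maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KIR allele genotyping by bootstrapped expectation-maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirtype)
```

## The problem

The killer immunoglobulin-like receptor (KIR) locus on chromosome 19q13.4
holds 15 expressed, highly polymorphic genes (plus two pseudogenes) whose
protein variants tune natural-killer-cell activation through allele-specific
binding of HLA class I. Curated nucleotide databases document hundreds of
named alleles per release; allele names encode the protein variant in
designation digits 1–3, with later digits reserved for synonymous and
non-coding differences. `kirtype` infers, for each KIR gene of one sample,
a homozygous or heterozygous genotype over these protein-level (3-digit)
*coding groups* from ordinary aligned whole-exome sequencing reads — no
bespoke primers, arrays, or manual review.

## The model

### Read–allele matching at 100% identity

Reads overlapping a gene's genomic region are tested against every
documented allele of that gene. A read $r$ *supports* allele $a$ when $r$ or
its reverse complement contains a contiguous exact substring of $a$'s
sequence of length at least $\min(|r|, L)$, with $L$ = 50 nt by default
(`min_alignment_length`). This is an explicit, deterministic
operationalization of "local alignment filtered at 100% identity": no
mismatches or gaps are tolerated inside the matched span, reads containing
`N` never match, and the length floor suppresses spurious short exact seeds.
`match_read()` is the brute-force reference; `align_readset()` uses a
substring index and is contractually identical. An optional BLAST backend
(`backend = "blast"`) reproduces the same rule by disabling extension
through mismatches (ungapped mode, prohibitive mismatch penalty, minimal
X-dropoff), and exists only for cross-checking.

One consequence worth understanding: a maximal-scoring aligner that
*extends* through mismatches would report one long, less-than-100%-identity
alignment and discard it, whereas this rule keeps any clean 50 nt window.
Closely related alleles therefore share more reads under this rule than
under extension-based semantics; the EM is designed to resolve exactly this
ambiguity, but see *Limitations*.

### Expectation-maximization over the alignment matrix

Let $x_r$ be the number of alleles read $r$ supports. The $m \times n$
alignment matrix starts as

$$M^{(0)}_{a,r} = \begin{cases} 1/x_r & r \text{ supports } a \\ 0 &
\text{otherwise,} \end{cases}$$

so every column distributes unit mass over its matched alleles. Each
iteration computes the expectation vector $E_a = \sum_r M_{a,r}$ and then
re-weights every column by it,

$$M'_{a,r} = \frac{M_{a,r}\,E_a}{\sum_a M_{a,r}\,E_a},$$

a Bayesian update with $E$ as prior and the current column as likelihood.
Column stochasticity is preserved, hence $\sum_a E_a = n$ at every step.
Iteration stops when $\sum_{a,r} (M'_{a,r} - M_{a,r})^2 \le \alpha$
(default $\alpha = 10^{-5}$) or after `max_iterations` (default 1000; the
result is then flagged `converged = FALSE` and, by default, downgraded to a
no-call with reason `not_converged`). The final probabilities are $E/n$: the
recurrence itself leaves $E$ on the read-count scale, and dividing by $n$
puts the estimates in $[0,1]$ where they are comparable with the calling
threshold.

### Bootstrapping

Ambiguous columns are winner-take-all under this update: any asymmetry in
the unambiguous read counts is amplified until the weaker allele's mass
drains away, so a single EM run is biased toward homozygous solutions. The
estimator therefore averages `n_boot` = 100 EM runs, each on
$\lceil p N \rceil$ reads (default $p = 0.5$) drawn uniformly *without*
replacement — "fraction $p$ of the alignments" reads naturally as
subsampling; a with-replacement mode sits behind `replace = TRUE`. Alleles
absent from a subsample contribute probability 0 in that bootstrap. One
seed governs a sample; each gene derives an RNG substream from the seed and
the gene name, so results are invariant to gene order.

### Thresholding and coding-group collapse

Before calling, full-name probabilities are summed within coding groups
(`collapse_probabilities()`): WES cannot distinguish alleles that differ
only at non-exonic sites or by silent changes, and the 3-digit designation
truncation encodes exactly that equivalence. The collapse conserves total
mass and is idempotent. Because exon annotations are not shipped in the
nucleotide FASTA, truncation — not re-translation — implements the merge;
`verify_coding_groups()` optionally flags groups whose members' sequences
differ at more than 5% of aligned positions, which would indicate a
mislabelled entry.

Calling then applies a strict threshold $t$ (default 0.25): alleles with
collapsed probability $> t$ form the solution set. Exactly one above
threshold is a homozygous call (the allele counted twice), exactly two is a
heterozygous call, zero or more than two is a no-call with reason
`none_above_threshold` / `more_than_two_above_threshold`. Ties at exactly
$t$ fall below it. Raising $t$ can only shrink the solution set, so a
no-call for lack of mass is never rescued by a larger $t$.

## Hyperparameters

| name | meaning | default | notes |
|------|---------|---------|-------|
| `alpha` | EM convergence threshold (sum of squared matrix changes) | 1e-5 | smaller = sharper WTA fixed points, more iterations |
| `n_boot` | bootstrap count | 100 | averaging noise shrinks as $1/\sqrt{n_{boot}}$ |
| `p` | bootstrap fraction, (0, 1] | 0.5 | without replacement |
| `t_threshold` | calling threshold, (0, 1) | 0.25 | strict comparison |
| `min_alignment_length` | exact-match floor, nt | 50 | conservative for ~100 nt WES reads |
| `max_iterations` | EM cap | 1000 | hit ⇒ `not_converged` |
| `min_reads` | minimum matched reads | 1 | below ⇒ `no_call(no_reads)` |

The genotype-entropy grid (`genotype_entropy_grid()`) is the instrument for
choosing `p` and `t`: rerunning the bootstrapped caller many times under
each $(p, t)$ cell and measuring the log2 Shannon entropy of the empirical
call distribution (no-call is a first-class category; heterozygous calls
compare as unordered pairs). A self-consistent caller has entropy 0.

## Validation instruments

* **Entropy of probability vectors** — `shannon_entropy()` of a collapsed
  probability vector is 0 for clean homozygotes $(1, 0, \dots)$, 1 bit for
  clean heterozygotes $(0.5, 0.5, 0, \dots)$, and larger when mass spreads:
  an ambiguity meter that needs no truth labels.
* **Replicate concordance** — `replicate_concordance()` scores paired
  samples per gene: identical zygosity plus identical unordered collapsed
  alleles, with no-call matching no-call. Normal-approximation 95%
  confidence intervals $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$ accompany
  each fraction. Excluding no-calls would overstate consistency, so they
  count.
* **Coverage profiling** — `coverage_entropy_profile()` bins samples by
  mean region coverage (`mean_region_coverage()`) and summarizes entropy
  per bin (median, quartiles); ambiguity should rise only at low coverage.
* **Donor-mixture negative controls** — `make_pseudo_readset()` pools reads
  from several donors and samples down to the rounded mean donor read
  count: a read set with no coherent underlying genotype. Its
  allele-probability entropy should exceed every pure donor's entropy,
  which the test suite verifies on synthetic mixtures of four homozygous
  donors (observed mixture medians ≈ 1.8–2 bits against pure-donor
  entropies ≈ 0).

## The synthetic-data generator

`make_synthetic_database()` emulates a curated allele release: per gene a
random 1000 nt base sequence, with each of `alleles_per_gene` primary
alleles carrying `divergence` substitutions at positions private to that
allele (pairwise Hamming distance is therefore `2 * divergence`), and
optional synonymous siblings per coding group differing at 2 further
private positions — the non-exonic/silent differences the collapse must
absorb. `simulate_reads()` emits
$\lceil \text{depth} \times \text{allele length} / \text{read length}
\rceil$ uniformly positioned substrings (heterozygous truths split reads
evenly between the two alleles) with i.i.d. substitution errors; read ids
encode the source allele and position so tests can check oracle-level
placement. Substitution-only errors are deliberate: the matcher is
identity-based, so an indel simply deletes a match and exercises nothing
further.

What the generator does **not** emulate: the real locus's segmental
homology between *genes* (reads here never cross genes), paired-end
structure, base-quality variation, coverage waviness, and the heavily
skewed real allele frequency spectrum. Passing recovery tests on this
generator therefore demonstrates the estimator's correctness under clean
ambiguity structure, not field accuracy on cohort BAMs.

Default simulation conditions used by the heavier tests and by
`scripts/acceptance.R` (chosen once as typical WES-like values): 3 genes ×
6 alleles × 1000 nt at divergence 20, 100 nt error-free reads at 30×
depth, default hyperparameters; entropy grids use a single-allele gene at
4× depth with 50 reruns per cell over $p \in \{0.2..0.8\}$, $t \in
\{0.05..0.40\}$; effect-model simulations use $n = 500$ phenotypes with
genotypes drawn under Hardy–Weinberg at allele frequency 0.5 (the standard
genetics simulation default), slope 5 and noise sd 10.

## Downstream statistics

Called genotypes become a samples × coding-groups copy-number matrix
(`encode_kir_space()`), each called gene contributing two copies. Carrier
status (≥ 1 copy) is the unit of association: two-sided Fisher's exact
tests for binary traits (sample odds ratio $ad/bc$ reported; degenerate
margins yield $p = 1$ and a flag) and two-sided Mann-Whitney U for
continuous traits (exact null when the smaller group has ≤ 8 observations
and no ties, tie- and continuity-corrected normal approximation
otherwise). Bonferroni correction is the default adjustment;
Benjamini-Hochberg is provided because exploratory scans are convention-
ally reported as FDRs. Samples with a no-call at the relevant gene are
excluded pairwise.

`fit_effect_models()` compares three genotype encodings of an allele's
effect on a continuous phenotype — dominant $(0,1,1)$, semi-dominant
$(0,1,2)$, recessive $(0,0,1)$ over copy counts $(0,1,2)$ — by ordinary
least squares under $y = m\,x(\text{genotype}) + b$, ranked by
$\mathrm{BIC} = n \ln(\mathrm{rss}/n) + k \ln n$ with $k = 3$ (slope,
intercept, error variance). All three encodings share $k$, so the ranking
reduces to residual sums of squares; only BIC differences and ranks are
meaningful, and selection is invariant to shifting or rescaling the
phenotype. At realistic effect/noise ratios the encodings are highly
collinear: at slope 5, noise sd 10, $n = 500$, the lack-of-fit
noncentrality caps correct-model selection near 93–95%, so model selection
at this scale should be read as evidence, not proof, of an inheritance
mode.

## Numerical and design choices

* Probabilities are `E / n`; bootstrap averages are means of normalized
  vectors (an unnormalized-average variant would weight bootstraps by read
  count, which subsampling makes constant anyway).
* Bootstrap draws are without replacement by default (`replace` flips
  this). `ceiling(p * N)` guarantees at least one read.
* Threshold comparisons are strict; equality is below threshold.
* Designations shorter than 3 digits are right-zero-padded for grouping,
  with a warning.
* The two pseudogenes are dropped at database load; KIR2DL5A and KIR2DL5B
  are kept as separate genes.
* BED coordinates are 0-based half-open at every interface; GRanges
  conversion is internal. The shipped region file is a clearly-labelled
  synthetic placeholder — supply build-matched coordinates for real data.
* Mate pairs are independent reads (`/1`, `/2` suffixes); duplicate-marked
  reads are kept unless `exclude_duplicates`.
* TSV numbers are written at 6 significant digits so identical inputs and
  seed give byte-identical outputs.
* Per-gene and per-cell RNG substreams derive from a polynomial string
  hash of (seed, label), keeping runs reproducible under reordering.

## Limitations

* **Close alleles under the exact-window rule.** Alleles within a gene
  share many exact ≥ 50 nt windows when their distance is a few percent;
  ambiguous reads resolve by winner-take-all, so systematically asymmetric
  ambiguity (an artifact of where the distinguishing sites fall relative
  to read length) can push a true heterozygote toward a ~0.75/0.25 split
  whose minor allele sits just below $t = 0.25$. On the default synthetic
  conditions this costs a few percent of heterozygous calls; raising
  `min_alignment_length` or lowering `t` trades it against other errors.
* Gene copy-number variation (presence/absence haplotypes common at this
  locus) is out of scope: every gene is assumed diploid.
* No phasing across genes, no quality-aware weighting, no indel-tolerant
  matching.
* Association scans are univariate with pairwise deletion; population
  structure must be handled by subsetting upstream.
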