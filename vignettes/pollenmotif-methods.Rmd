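---
title: "Methods: discovering pollen-specific promoter motifs with pollenmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering pollen-specific promoter motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pollenmotif)
```

This vignette explains the statistical machinery inside `pollenmotif`, the
choices behind its defaults, what the synthetic-data generator does and does
not emulate, and the package's known limitations.

## The scientific question

Hydroxyproline-rich glycoproteins (HRGPs) are a superfamily of plant
cell-wall proteins. A minority of HRGP genes is expressed almost exclusively
in mature pollen, and the hypothesis under test is that shared promoter
elements — binding sites of pollen-active transcription factors — drive that
pattern. The package operationalizes the question as a discriminative
problem: which position weight matrices (PWMs) separate the promoters of
pollen-specific HRGPs (the foreground) from HRGPs not expressed in pollen
(the background), survive a cross-species conservation test, and carry
predictive power for pollen expression levels?

## Tissue specificity and gene sets

Expression values (TPM-scale, non-negative) are transformed as
$y = \log_2(x + 1)$, and any transformed value below 1 is set to 0. The
zeroing threshold acts on the *log* scale — a raw value below 1 can never
contribute — which makes "not expressed in pollen" a crisp, reproducible
event rather than a tail of small numbers. Replicate samples are aggregated
per tissue by the **median** of the transformed values; the median is robust
to a single aberrant library and the same statistic is used everywhere a
per-tissue value is needed, so Tau and the reported expression levels are
mutually consistent.

The tissue-specificity index over $n \ge 2$ tissues,
$$\tau = \frac{\sum_{i=1}^{n} (1 - x_i / \max_j x_j)}{n - 1},$$
is 0 for a uniform profile, 1 for single-tissue expression, lies in
$[0, 1]$, and is invariant to rescaling the profile. A gene is
tissue-specific when $\tau > 0.85$ (strict inequality; the boundary value
is excluded) and its tissue is the argmax of the profile, with lexicographic
tie-breaking so classification is deterministic. All-zero profiles get
$\tau = \mathrm{NA}$ and are never classified. Expression tiers compare a
gene's pollen value to the population mean in units of the population
(ddof = 0) standard deviation: above $\mu + 3\sigma$ is extremely high,
between $\mu + 2\sigma$ and $\mu + 3\sigma$ high.

The foreground is the set of pollen-specific genes; the background is the
set of genes whose aggregated pollen value is exactly 0 after the transform.
Genes expressed in pollen but not pollen-specific belong to neither set, so
the two sets are disjoint by construction.

## Discriminative discovery

Discovery is a two-stage replacement for an ensemble of external
discovery tools, designed so the filtering and regression layers above it
see the same kind of object (candidate PWMs with foreground/background
statistics) that an ensemble would produce; externally produced MEME files
can be injected at the same point.

**Seeding.** For each $k \in [6, 16]$ (configurable sub-range), every k-mer
present in the foreground is scored by the hypergeometric tail
$P(X \ge h_{fg})$ for drawing $n_{fg}$ genes from $n_{fg} + n_{bg}$ with
$h_{fg} + h_{bg}$ marked, where $h$ counts *genes containing the k-mer* on
either strand (presence, not multiplicity — promoters are long enough that
multiplicity mostly measures length). The top 50 seeds per length are
retained; the top `n_refine` (default 5) are refined.

**ZOOPS EM.** Each foreground sequence carries at most one motif site at an
unknown position and strand; elsewhere it follows the order-0 background.
The E-step computes the posterior over site placements (and the no-site
alternative) under a uniform position prior; the M-step re-estimates the
PWM from expected site counts with a Dirichlet pseudocount of 0.25 per base
and the site prior from the expected site fraction. The reported objective
— the observed-data log-likelihood up to the constant background term, plus
the Dirichlet penalty — is non-decreasing by EM theory, and the package
asserts this in its tests. Iteration stops at a gain below `em_tol`
(default 1e-4) or 100 iterations. ZOOPS rather than OOPS because a promoter
need not contain a site.

**The low-confidence flag.** EM is a maximizer: run on a foreground with no
shared motif it still returns *something* — a smeared average of the best
random window of each sequence. Such motifs behave pathologically
downstream (they re-find their own training windows, inflating foreground
coverage). Calibration runs with planted motifs versus motif-free
foregrounds show the two regimes are cleanly separated by information
content: noise-refined motifs stay at 0.79–1.01 bits/column while motifs
refined on genuinely shared sites reach 1.20–1.40 bits/column. The default
`min_ic_per_col = 1.1` sits in that gap; flagged motifs are excluded by the
pipeline before any filter sees them.

## Scanning and coverage

Windows are scored with the log-odds matrix
$s_j(b) = \log_2(p_{jb} / q_b)$ against the order-0 background $q$
(estimated from the background promoter set; motif probabilities floored at
$10^{-4}$ so scores stay finite). Exact p-values come from the standard
dynamic program: per-column scores are discretized onto a shared integer
grid (10,000 bins across the score range), the per-column score
distributions under iid background are convolved, and the survival function
gives $P(S \ge s)$ for every achievable score. The discretization error of
any reported p-value is bounded by the probability mass within
$w \cdot \text{granularity}$ of the threshold, and tests verify agreement
with brute-force enumeration of all $4^L$ windows for $L \le 8$.

Both strands are scanned (the minus strand by scanning the
reverse-complemented sequence and mapping positions back), and occurrences
with $p < 10^{-4}$ are reported — the conventional scanning default,
exposed as a flag because every coverage count depends on it. A gene is
*covered* by a motif when it has at least one occurrence; coverage
percentages are rounded to the nearest integer (half away from zero), and
the relative frequency is the unrounded foreground fraction divided by the
background fraction. For the regression features, each gene contributes
$-\log_{10}$ of its best occurrence p-value, or 0 when it has none —
absence is treated as uninformative rather than as evidence.

One consequence of the $10^{-4}$ threshold worth knowing: on 1 kb promoters
a motif whose score distribution is dense near the threshold hits roughly
$2 \times 990 \times 10^{-4} \approx 0.2$ genes-per-gene by chance, i.e.
about 26 of 132 background genes. Sharp, near-consensus motifs have
achievable p-values far below the threshold and much lower chance coverage.
Background coverage bounds must be read against that chance floor.

## Motif similarity

Two PWMs are compared by sliding one across the other (both orientations,
at least 4 overlapping columns): aligned column pairs contribute
$1 - r$ (Pearson correlation of the two 4-vectors; constant columns score
0 against another constant column and 1 otherwise), and every unaligned
column of either motif is penalized by its distance to a background column,
so degenerate offsets cannot win by shrinking the overlap. The best offset's
distance is ranked against the same statistic computed for column-shuffled
copies of the target (default 2000 shuffles, seeded), giving
$p = (1 + \#\{d_{null} \le d_{obs}\}) / (N + 1)$. The shuffle count is
chosen so the smallest achievable p-value ($1/(N+1) \approx 5 \times
10^{-4}$) sits below the 0.001 similarity threshold with room for one
coincidental null hit. A Monte-Carlo null was chosen over an exact DP null
because it is simple, seedable, and adequate at the 0.001 operating point;
consequently the package does not reproduce any external tool's printed
similarity p-values, only the similar/dissimilar decision.

Redundancy removal applies the rule "of two similar motifs, drop the one
covering fewer foreground genes": motifs are considered from most to least
covered (ties: higher information content, then name) and kept only if
dissimilar to everything already kept. On conflict chains (A~B~C with A, C
dissimilar) this retains the maximal dissimilar set {A, C}, which tests
verify against a brute-force minimal-removal oracle.

## Conservation

Each foreground promoter is aligned to its ortholog by global
Needleman–Wunsch with affine gaps (match +2, mismatch −1, gap open 10,
extension 0.1 — the substitution scores are declared here since only the
gap penalties are canonical for promoter alignment). The alignment is
delegated to Biostrings' pairwise aligner; tests check its optimality
against exhaustive enumeration on short strings. An occurrence is conserved
when the ortholog has an occurrence of the same motif (same scan settings)
whose start maps to the same alignment column within ±3 columns — a small
tolerance absorbing alignment ambiguity around the site; at 10% sequence
divergence the calibration tests call preserved sites conserved and ablated
sites non-conserved in ≥95% of cases. A *motif* is conserved when at least
half (`min_frac = 0.5`) of the foreground genes carrying it have a
conserved occurrence; genes without an ortholog leave the denominator. Both
the tolerance and the fraction are flags: the per-occurrence rule is
stated in the source methodology only as "same position", and the
occurrence-to-motif aggregation is not stated at all, so both choices are
explicit and documented rather than implicit.

## Filters and the union

**Filter A** (relaxed): foreground coverage ≥ 11 (of 13), background
coverage ≤ 30 (of 132), conserved. Both bounds are inclusive; the
background bound is read inclusively because the published coverage tables
are consistent with ≤ 30. With other gene-set sizes the pipeline scales the
bounds proportionally. **Filter B** (rigorous): at least one similarity
match (p < 0.001) to the binding motif of a TF whose pollen expression is
≥ 1 (log2), conservation, and occurrence bounds (defaults ≥ 10 foreground,
≤ 30 background — the smallest values consistent with published Filter-B
coverages, exposed as flags); redundant survivors are removed. The final
set is the union of A- and B-survivors keyed by motif identity (similarity
p < 0.001 counts as identity; the higher-coverage member survives and
inherits both provenance flags). Redundancy is resolved *after* filtering,
matching the published workflow order; filtering first matters because a
noisy variant with inflated foreground coverage would otherwise absorb a
cleaner variant before the background bound could reject it.

## Regression

Features are the genes × motifs matrix of $-\log_{10}$ best scan p-values;
the target is each gene's mean pollen log-expression. The model is
gradient-boosted regression trees with depth-1 stumps, row subsampling 0.3,
minimum 5 observations behind a split, learning rate 0.1, and 100 rounds —
the classical GBM configuration for this analysis, implemented with
xgboost (`min_child_weight = 5` stands in for a minimum split size, and
squared-error splitting is used; the original analysis used an absolute-
error *split criterion* with squared-error loss, a combination xgboost does
not offer — at depth 1 on these features the distinction is immaterial).
Evaluation is 3-fold cross-validation with contiguous, unshuffled folds
(the classical KFold); out-of-fold predictions are pooled and a single
Pearson r with its two-sided p is computed on all (true, predicted) pairs —
pooling, rather than averaging per-fold correlations, is the only reading
consistent with reporting one r and one p over all genes. Because folds are
contiguous, the pipeline presents genes in a seeded random order; a
class-sorted gene list would place every foreground gene in one fold and
leave the training folds with no pollen-expressed gene at all. Feature
importances (gain-based, normalized to sum 1) come from a refit on all
genes with the same hyperparameters and seed.

## The synthetic-data generator

The generator emulates, under one seed, everything the analysis consumes:

* **Promoters** — iid sequences (default uniform base composition, which
  keeps the analytic p-value checks exact; an AT-rich plant-like
  composition is a flag away) of 1 kb, 13 foreground + 132 background
  genes; for each planted motif, sites sampled from its PWM are inserted at
  uniform non-overlapping positions, random strand, in exactly
  `round(coverage × n)` genes per set, with a truth table of every
  insertion.
* **Orthologs** — copies with point substitutions at rate 0.10 and 1–5 bp
  indels at rate 0.002 per position, applied only outside planted windows;
  conserved sites are copied intact, non-conserved sites are overwritten
  with random sequence. Indels are kept short and outside sites so "same
  aligned position" stays well-defined for preserved sites.
* **Expression** — 11 tissues × 10 replicate samples (≈ the 113-sample
  scale of the real compendium; the per-tissue breakdown of the real data
  is not public, so replicates are balanced). Foreground genes draw a
  pollen log2 level from U(6, 14) — the range of published pollen-specific
  HRGP levels — with 0.25-sd replicate noise, and sub-threshold values
  elsewhere, so their Tau is ~1 with pollen argmax; background genes are 0
  in pollen and expressed in 2–6 random other tissues. A regression mode
  pins each gene's mean pollen level to a supplied target.
* **Known-TF database** — every planted motif under a pollen-expressed TF
  name (log2 expression ≥ 1), plus decoy motifs of which half are
  sub-threshold, so the expression gate and the matcher are both exercised.
* **Regression studies** — `gen_regression_data()` draws sparse
  scan-like features directly (hit probability `coverage`, strengths
  U(4, 8)), a weighted linear signal, and Gaussian noise scaled to a
  requested population $R^2$.

What the generator deliberately does **not** emulate: promoter grammar
(positional preference, TATA geometry, nucleosome exclusion), correlated
tissue profiles, compositional heterogeneity along the promoter, and real
orthology complications (rearrangements, missing orthologs). Passing tests
on synthetic data therefore demonstrate that the *machinery* is correct and
calibrated — not that the biological conclusions of any particular real
dataset are reproduced.

## Problem sizes used in the checks

The planted-recovery study runs the full pipeline on the canonical 13/132
configuration over 10 seeds with discovery restricted to lengths 11–13
around the planted width 12; recovery is expected in ≥ 9 of 10 seeds and
motif-free control runs must pass nothing. Planted motifs default to width
12 with 0.95 consensus-base probability: at the $10^{-4}$ scan threshold on
1 kb promoters, sites of narrower or softer motifs are undetectable by
construction (their achievable p-value classes sit above the threshold), so
this is the regime in which coverage-based filtering is a meaningful test.
The SNR-recovery study uses 1000 genes so the cross-validated correlation
approaches the population value ($r = \sqrt{0.4} \approx 0.63$); at a few
hundred genes boosting underfit dominates and the estimate is both lower
and noisier. Conservation calibration uses 52 planted/ablated sites at 10%
divergence; the scan-p-value oracle enumerates all $4^8$ windows.

## Known limitations

* The discovery stage is a two-algorithm stand-in for a multi-tool
  ensemble; it finds compact, high-information motifs and will not recover
  dyad or very soft motifs that specialized tools catch.
* Similarity p-values are Monte-Carlo and conservative for partial
  overlaps; matches need roughly 13 of 16 columns in common to clear
  p < 0.001 at the default shuffle count.
* The conservation test presumes a mostly collinear promoter pair; it makes
  no attempt at orthology inference or rearrangement handling.
* Exact reproduction of any published run requires the original databases
  and external binaries; this package reproduces the method, its
  arithmetic, and its behavior under controlled conditions.
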