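---
title: "Methods behind guildscan: from paired-end reads to co-abundance guilds and clinical associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind guildscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildscan)
```

## What the package computes

`guildscan` reimplements, at desk scale and with full test coverage, the
analysis chain used to ask whether a treatment shifts the gut microbiota of
a paired (before/after) two-arm cohort and whether those shifts track
clinical improvement:

1. paired-end 16S read QC (end trimming, overlap merging, length and
   expected-error filtering),
2. greedy 97%-identity OTU clustering and count-table construction,
3. rarefaction, alpha diversity and five bounded beta-diversity metrics
   with PCA/PCoA, MANOVA and PERMANOVA,
4. SparCC-style basis correlations between core OTUs,
5. co-abundance group (CAG) detection by Ward clustering with
   PERMANOVA-validated splits, and
6. clinical statistics: HOMA indices, LOCF, paired tests, ANCOVA, and the
   CAG-by-clinical Spearman association grid.

A synthetic-data module generates every input with known ground truth, so
each stage is validated by recovery rather than by fixture files.

## Read quality control

Three rules run in fixed order. (i) Both read ends are trimmed inward to
the first base with Phred quality strictly above 20; interior bases are
never touched. (ii) Mates merge when they share an ungapped overlap of at
least 50 bp; within the overlap the higher-quality base wins and keeps the
larger of the two qualities. We deliberately do not recompute a posterior
quality for agreeing bases — the downstream expected-error filter is then
slightly conservative, which only discards borderline reads. The merge
mismatch tolerance is not dictated by the procedure we emulate; we default
to 10% of the overlap, the common read-merger convention, and expose it.
(iii) Merged reads are kept iff length $\ge 400$ bp and expected errors
$\sum_i 10^{-Q_i/10} < 0.5$, both bounds strict on the failing side.

The trimming rule scans from both ends rather than truncating at the first
internal low-quality base; this follows the procedure's wording ("both
ends ... truncated"), though some merger tools truncate 3' only. Phred+33
encoding is assumed throughout.

## OTU clustering and table transforms

Clustering is greedy centroid formation: unique sequences are visited in
decreasing abundance (ties broken lexicographically, which makes the
centroid set independent of read order), and a sequence joins the first
centroid with global-alignment identity $\ge 0.97$, where identity counts
matching columns over all alignment columns. Chimera removal is omitted:
the synthetic templates contain none, and the original pipelines delegate
it to tool internals out of scope here.

Rarefaction subsamples reads without replacement to a fixed depth (default
5,000 reads/sample, configurable); samples below depth are dropped with a
warning. The "normalized, log-transformed" table used for ordination is
$\log_{10}(\text{relative abundance} + 10^{-6})$; the pseudocount is a
configurable choice, as the emulated analysis does not define it. The
core-OTU filter keeps OTUs observed in strictly more than 20% of samples.

## Diversity and ordination

Alpha metrics: observed richness; bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$; Shannon in log base 2 and Simpson as
$1-\sum p_i^2$ (the QIIME-1 conventions; "Simpson's index" is ambiguous
between $1-D$ and $1/D$, and we take $1-D$ so the index lies in $[0,1]$).
Paired before/after comparisons use the two-sided Wilcoxon signed-rank
test with the classic zero-drop rule; at small $n$ the exact p-value is
verified in the test suite against enumeration of all $2^n$ sign patterns.

All five beta metrics are bounded in $[0,1]$: Bray-Curtis, binary Jaccard,
weighted (Ruzicka) Jaccard, unweighted UniFrac (unique over observed
branch length), and weighted UniFrac in the normalized form
$\sum_b \ell_b |p_A - p_B| / \sum_b \ell_b (p_A + p_B)$ — the normalized
variant is chosen precisely so that all five metrics are comparable on one
scale. PCoA uses Gower double-centering; negative eigenvalues are reported
unmodified rather than corrected (Cailliez/Lingoes adjustments are not
part of the emulated analysis), and coordinates come from the positive
part of the spectrum. MANOVA on ordination scores uses Wilks' lambda on
the first two components by default — the two that are plotted — since the
emulated analysis does not state a count.

PERMANOVA is the one-way pseudo-F of Anderson (2001),
$F = \frac{SS_A/(a-1)}{SS_W/(N-a)}$ with
$SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$, and a seeded
label-permutation p-value with the +1 correction
$p = (1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$, which cannot return zero. On
1-D Euclidean data it reproduces the classical ANOVA F exactly (a test
asserts this), and its null p-value distribution is verified uniform.

## SparCC basis correlations

Relative abundances are compositions: closing counts to a constant sum
induces a spurious average correlation of $-1/(D-1)$ between unrelated
taxa. The estimator works from the closure-invariant log-ratio variances
$t_{ij} = \mathrm{var}\log(x_i/x_j)$ and the sparsity approximation
$t_{i\cdot} \approx (D-2)\,\omega_i + \sum_j \omega_j$, solved as a linear
system for the basis variances $\omega$, giving
$\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to $[-1,1]$.

Pairs violating sparsity are handled by iterative exclusion: the strongest
pair with $|\rho| > 0.1$ is removed from the sums and the system re-solved.
We iterate exclusion to convergence (until no pair exceeds the threshold
or the system would become singular) rather than stopping after a fixed
small number of rounds. The reason is structural: with guild-structured
communities a substantial fraction of pairs is genuinely correlated — four
guilds of ten OTUs make 23% of pairs correlated — and a fixed ~10-round
cap leaves the basis variances inflated and every between-guild
correlation biased toward $-0.2$. When the surviving pairs are truly
uncorrelated the converged solution is exact, which is what the planted
recovery tests measure. A cap remains available via `max_exclusions`.
Nonpositive solved variances (possible at small $D$) zero out the affected
OTU's correlations with a warning rather than silently clipping.

The point estimate is the element-wise median over 20 Dirichlet
(`counts + 1`) fraction draws — the cited algorithm's aggregation, robust
to draw outliers. Pseudo-p-values resample whole samples with replacement
(100 bootstraps by default), re-run the full estimator, and report
two-sided $(1 + \#\{|\rho_b| \ge |\rho|\})/(1+B)$; the meaningless
diagonal is set to the smallest attainable value $1/(1+B)$. One-sided
p-values are not offered; the two-sided form is the conservative default
where the emulated analysis is silent.

## CAG detection

OTUs are clustered by Ward linkage (`ward.D` Lance-Williams update) on the
correlation distance $d = 1 - \rho$. We use the plain $1-\rho$ transform
rather than $\sqrt{2(1-\rho)}$: both are monotone in $\rho$, so they
reorder nothing; the choice only rescales merge heights, and is exposed.
OTU labels are sorted before clustering so that ties, and hence the
partition, are independent of input order.

Splits are validated top-down: at each dendrogram node, PERMANOVA (999
permutations) compares the two child memberships on the restricted
distance matrix, and the split is accepted iff $p \le \alpha$ with
$\alpha = 0.001$ and both children hold at least two OTUs (a node whose
best split isolates a single OTU stays whole). The boundary is accepted
($\le$ rather than $<$) deliberately: with the +1-corrected permutation
p-value, the smallest attainable p at 999 permutations is exactly 0.001,
so a strict inequality could never accept any split at this $\alpha$; the
reference analysis evidently operated at the boundary, having produced a
multi-CAG partition under exactly these settings. The emulated analysis
states the ingredients (Ward, PERMANOVA, 999 permutations, $P < 0.001$)
but not the traversal; the top-down acceptance rule used here is
deterministic and reproduces a fixed CAG count on fixed input.

A granularity limit follows from the permutation floor: a node of $2k$
OTUs admits only $\binom{2k}{k}$ balanced relabelings, so for nodes of
about ten OTUs the chance of re-drawing the observed labeling already
floors the p-value near 0.009 — well above $\alpha = 0.001$. Splits are
therefore only ever accepted at nodes of roughly twenty OTUs and larger,
which sets the smallest detectable guild size at this $\alpha$.

CAG abundance is the sum of member-OTU relative abundances, so CAG columns
conserve the per-sample core-OTU total exactly. The exported network keeps
edges with $\rho$ strictly above 0.4 — positive correlations only by
default, since the display rule we emulate speaks of "R higher than 0.4";
an absolute-value mode is available. CAGs with no qualifying edge are
flagged excluded-from-display rather than dropped.

## Clinical statistics

HOMA indices use the Matthews 1985 forms,
$\mathrm{HOMA\text{-}IR} = \mathrm{FBG} \times \mathrm{insulin}/22.5$ and
$\mathrm{HOMA\text{-}\beta} = 20\,\mathrm{insulin}/(\mathrm{FBG}-3.5)$,
with glucose in mmol/L and insulin in uIU/mL; the emulated analysis uses
the indices without defining them, and these are the standard clinical
forms for those units. LOCF carries the most recent prior observation
forward and never alters observed values; subjects without a baseline are
excluded. Paired endpoints use the two-tailed paired t test; between-arm
contrasts use ANCOVA (`endpoint ~ baseline + arm`). The CAG-clinical grid
is Spearman correlation on per-subject deltas (week 12 minus week 0) for
both sides — the "changes associated with improvements" framing supports
deltas, and an endpoint-value mode exists for the alternative reading.
Ties take average ranks; small-sample p-values are exact.

## The synthetic-data generator

Log basis abundances are multivariate normal with exchangeable block
covariance: unit variance, correlation `within_corr` inside guilds and
`between_corr` across (default 0), around per-OTU means drawn once from
$N(0, \texttt{basis\_logmean\_sd}^2)$ with default spread 1 — chosen to
produce the 1-2 decade abundance range typical of genus-level gut
profiles. Basis abundances are exponentiated, closed, and observed through
multinomial sampling at a fixed library size (default 10,000 reads). This
matches the generative model under which the basis-correlation estimator
is well-posed, which is the point: estimator recovery is testable against
known truth. The latent basis matrix is returned alongside the counts for
oracle checks.

Paired cohorts draw week-0 and week-12 samples independently from the
same per-subject model (shared OTU means), multiply target-guild basis
abundances by $2^{\mathrm{lfc}}$ in the treated arm(s) before closure, and
couple clinical deltas linearly to the true guild relative-abundance
deltas plus Gaussian noise. Arms carry the trial's labels (`MET`, `AMC`).

What the generator does *not* emulate: within-subject longitudinal
autocorrelation (timepoints are exchangeable under the null by
construction, which is exactly what the null tests need, but real repeated
measures are correlated); overdispersion beyond multinomial; chimeras,
primers, or taxonomic realism; missing-at-random clinical visits. Passing
recovery tests therefore demonstrates correctness of the estimators under
their own assumptions, not robustness to real-data violations of them.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to make every property
measurable yet quick on a laptop: cohorts of 50 subjects per arm,
4 guilds of 10 OTUs, 200 samples for estimator-recovery checks, 999
permutations where a partition decision depends on the p-value and 99 for
calibration sweeps, 100 bootstrap resamples, and 20 Dirichlet draws.
Degenerate inputs are first-class: empty reads after trimming, all-zero
samples, constant clinical columns, all-zero paired differences and
non-PSD covariance requests all have defined error or masking behavior,
tested individually. All randomized routines take an explicit seed and
restore the caller's RNG state; repeated calls are byte-identical.

## Known limitations

Greedy centroid clustering is order-dependent by design (resolved by the
abundance/lexicographic rule) and quadratic in unique sequences — fine at
desk scale, not a USEARCH replacement. The PERMANOVA engine is one-way
only, which is all the CAG split test and the arm comparisons need.
Exclusion-to-convergence SparCC can discard many pairs on dense
correlation structures; the excluded pairs are logged per draw. UniFrac
requires a rooted tree covering all OTUs and does not randomize root
placement. The CLI (`exec/guildscan`) is a thin file-IO wrapper over the
functions documented here; the R interface is primary.
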