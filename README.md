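# guildscan

Gut-microbiome studies of paired two-arm trials ask two linked questions:
does treatment shift the community, and do the shifts track clinical
improvement? `guildscan` is an R package that implements the full analysis
chain for that design at desk scale — from paired-end 16S rRNA amplicon
reads to operational taxonomic units (OTUs), diversity and ordination
statistics, composition-corrected co-abundance groups (CAGs), and
CAG-clinical association grids — together with a synthetic-data module
that generates every input with known ground truth, so each stage is
validated by recovery tests rather than by canned fixtures.

## The core statistics

**SparCC basis correlations.** Relative abundances are compositional:
closing counts to a constant sum biases the naive Pearson correlation of
unrelated taxa toward −1/(D−1). The estimator works from the
closure-invariant log-ratio variances *t*<sub>ij</sub> = var log(x_i/x_j),
solves the sparsity approximation
*t*<sub>i·</sub> ≈ (D−2)ω<sub>i</sub> + Σ<sub>j</sub>ω<sub>j</sub> for the
latent basis variances ω, and reports
ρ<sub>ij</sub> = (ω<sub>i</sub>+ω<sub>j</sub>−t<sub>ij</sub>)/(2√(ω<sub>i</sub>ω<sub>j</sub>)),
with iterative exclusion of sparsity-violating pairs and bootstrap
pseudo-p-values.

**CAG detection.** Core OTUs (prevalence strictly > 20%) are clustered by
Ward linkage on d = 1 − ρ; each dendrogram split must be confirmed by
one-way PERMANOVA (pseudo-F on squared distances, 999 seeded label
permutations, accepted at p ≤ 0.001, both children ≥ 2 OTUs). A CAG's
abundance is the sum of its members' relative abundances; the co-abundance
network keeps edges with ρ > 0.4.

**Everything around them**: three-rule read QC (Q20 end trimming, ≥ 50 bp
overlap merging, length ≥ 400 and expected errors < 0.5), greedy 97%
centroid OTU clustering, rarefaction to 5,000 reads/sample, Chao1 /
Shannon / Simpson alpha diversity, Bray-Curtis / Jaccard / UniFrac
distances with PCA, PCoA and MANOVA, paired microbiota-shift comparisons
(Mann-Whitney), and the clinical layer (HOMA-IR/HOMA-β, LOCF, paired t,
ANCOVA with baseline covariate, Spearman delta-vs-delta grids).

## Worked example

Plant a guild that doubles in both arms and is negatively coupled to
fasting glucose, then recover it end to end:

```r
library(guildscan)

gs  <- guild_spec(n_guilds = 4, otus_per_guild = 10, within_corr = 0.8)
eff <- effect_spec(target_guilds = 2, log2_fold_change = 1, arm = "both",
                   clinical_couplings = list(
                     FBG = list(guild = 2, slope = -1, sd = 0.02)))
ch  <- generate_paired_cohort(50, gs, eff, seed = 1234)
tab <- bind_timepoints(ch)

core <- core_otus(tab, 0.20)
sr   <- sparcc(core, n_draws = 20, n_bootstrap = 100, seed = 777)
d    <- correlation_distance(sr$rho)
part <- partition_by_permanova(ward_tree(d), d, alpha = 0.001,
                               n_perm = 999, seed = 778)
part
#> <cag_partition> 40 OTUs in 4 CAGs (sizes: 10, 10, 10, 10)

ab  <- cag_abundance(relative_abundance(core), part)
compare_cag_paired(ab, tab$sample_meta, arm = "MET")[2, c("cag", "p.value",
                                                          "direction")]
#>    cag      p.value direction
#> 2 CAG2 1.818734e-05 increased
```

The partition recovers the four planted guilds exactly, the planted CAG is
flagged as significantly increased within each arm (Wilcoxon signed-rank),
and its per-subject abundance delta correlates negatively with the fasting
glucose delta in the Spearman association grid
(`cag_clinical_association()`).

A thin command-line wrapper (`exec/guildscan`) exposes the main stages
(`simulate`, `qc`, `table`, `alpha`, `beta`, `sparcc`, `cag`) for shell
pipelines; the R functions are the primary interface.

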