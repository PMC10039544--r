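---
title: "Methods: multi-level co-expression networks for two-trait designs"
author: "multinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level co-expression networks for two-trait designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(multinet)
```

# The problem and the design levels

An expression experiment with two crossed categorical traits — a primary
trait (usually disease status) and a secondary trait (region, tissue,
timepoint, age) — admits several network designs. Pooling all samples
maximizes power but hides condition-specific topology: a module whose
genes are co-regulated only in disease looks, in the pooled network, like
a weaker version of an ordinary module. `multinet` therefore constructs

* level 1 — the combined network over all samples,
* level 2 — one network per primary-trait level,
* level 3 — one network per secondary-trait level,

and integrates them by module mapping, trait association, preservation
testing, and dynamics. The trait order is declared by the user and never
inferred; the primary trait drives the nomenclature (combined modules
`M<k>`, level-2 modules `<prefix>M<k>` with per-condition prefixes such
as `d`/`c`, level-3 modules `<condition>-<k>`).

Sample-size guidance: subsets below 12 samples trigger a warning —
correlation networks estimated from fewer samples are noisy, and the
subsampling analysis below (`subsample_accuracy`) exists precisely to
check, per dataset, how far a test set can shrink before preservation
conclusions degrade.

# Normalization

Raw counts are converted to `log2(RPKM + pseudocount)`, with library
sizes taken as column sums (the choice of total mapped reads versus
column sums is a toss-up for the downstream correlations; column sums
keep the operation self-contained). The pseudocount defaults to 1 so a
zero count maps to 0 and the transform is monotone; it is configurable.
Pre-normalized input skips the step (`normalize = FALSE` /
`method = "none"`). An optional `min_count_sum` filter removes genes
whose total count is below a threshold, default off. Genes with zero
variance within a design subset are dropped from that subset's network
(their correlation is undefined); this is logged per network.

# Network construction

The adjacency is `a_ij = |r_ij|^β` (unsigned default; the signed variant
`((1 + r)/2)^β` is available) with Pearson `r`. The topological overlap
matrix follows the standard form with `TOM_ii = 1`. Average-linkage
clustering of `1 − TOM` gives the dendrogram, whose leaf order is stored
for the dynamics analyses.

## The adaptive, multi-scale tree cut

Cutting the tree is the one place where this package departs from a
fixed recipe, because the three design levels put modules at very
different absolute TOM scales: a module co-expressed in all samples sits
at within-module dissimilarity ~0.9 under `β = 12`, while the *same
biology* diluted into the combined network (active in 20 of 36 samples,
pairwise `r ≈ 0.45`) lives at dissimilarity 0.9999 — no single static
cut height can serve both. The cut therefore works in rounds:

1. **Rescale.** Off-diagonal dissimilarities are affinely mapped so the
   0.5 % quantile sits at 0 and the maximum at 1. Average linkage is
   invariant to affine maps, so this changes heights, not tree shape.
2. **Scan.** Static cuts at up to 128 candidate heights are evaluated;
   a cluster is *eligible* as a module when (a) it has at least
   `min_module_size` genes, (b) it is cohesive — mean within-cluster
   dissimilarity well below its mean dissimilarity to the rest (the
   bar is set by `deep_split`), and (c) its mean within-cluster |r|
   exceeds a multiple (2.0 at the default `deep_split = 2`) of the
   null expectation `E|r| = sqrt(2/π)/sqrt(n − 1)`. Criterion (c) is
   what rejects the chance-correlation clusters that hierarchical
   clustering always produces on noise, and it adapts automatically to
   the sample size of the design level. The cut maximizing the number
   of eligible clusters (ties: most genes covered) wins.
3. **Peel and repeat.** Eligible clusters are removed and the remainder
   is re-rescaled and re-cut, so condition-diluted modules at finer
   dissimilarity scales surface in later rounds. Ten rounds are far
   more than ever needed in practice.
4. **Prune.** Genes whose |kME| to their cluster's eigengene is below
   half the cluster median are released to grey; a cluster that then
   falls below `min_module_size` dissolves. This keeps the size
   threshold meaningful for the coherent core rather than the padded
   branch.

Known limitations: a dataset that is one single module with no noise
background yields no module (there is nothing to separate it from); and
clusters may still carry some absorbed noise genes, which dilutes module
purity but not recall — on the canned fixture, ≥ 95 % of each planted
always-active module's genes land in one detected module. All steps are
deterministic: identical input and parameters give identical assignments
and leaf orders. Merging of modules with correlated eigengenes
(`1 − cor(ME)` below `merge_cut_height`) runs iteratively when the cut
height is positive; 0 disables merging. Inputs larger than
`max_block_size` are pre-partitioned by k-means on the genes' leading
eigen-features (a deterministic, fixed-seed approximation of single-block
construction) and blocks are cut independently.

Defaults: `power = 6`, `min_module_size = 30`, `merge_cut_height = 0.15`,
`deep_split = 2`, `max_block_size = 5000`. The canned analysis
configuration (`eae_like_parameters()`) uses power 12, minimum size 100
and no merging. A helper (`soft_threshold_fit`) reports the scale-free
fit index per candidate power but never auto-selects one.

## Eigengenes

A module eigengene is the first right singular vector of the module's
standardized genes × samples block: unit Euclidean norm, sign aligned so
its correlation with the module's mean standardized profile is
non-negative. Unit-norm scores (rather than variance-1 scores) are the
scaling under which the outlier-module filter below uses its threshold
as printed. Single-gene modules fall back to the standardized,
unit-normalized gene with a warning.

# Outlier-module filtering

A module driven by one sample is noise for every downstream analysis.
The filter removes the sample with the largest |eigengene| entry and
computes the sample variance (n − 1 denominator) of the rest; the module
is flagged when that variance falls below 0.02. With unit-norm
eigengenes an evenly spread module over n samples keeps variance
≈ 1/(n − 1) (0.029 at n = 36), while a single-sample module collapses to
near zero, so the constant separates the two regimes across the sample
sizes this package targets; it is used as a constant, not rescaled by n.
One emergent consequence worth knowing: a condition-specific module seen
at the *combined* level concentrates its eigengene in the active
condition's samples and can sit near the threshold — in the canned
fixture the combined-level disease-only module lands just below 0.02 at
some seeds. The module is always cleanly retained at the design level
where it is fully active, which is also where the preservation analysis
interrogates it. Ties for the largest |eigengene| remove the first
sample in column order (logged). Filtering is idempotent.

# Module mapping

The universe for a pair of networks is the intersection of their
analyzed (post-filter) genes, grey included; modules are non-grey
labels. The overlap p-value is the upper hypergeometric tail computed
via `phyper(..., log.p = TRUE)`, exact to ~1e-15 in log space against
pmf enumeration. FDR is BH across all module pairs of one table (not per
row) — a choice; per-reference-module adjustment would be the
alternative. Best matches break p-value ties by larger overlap, then
lower label. Pairs of networks sharing samples are `cross-design`
(overlap confounded by the shared samples; useful for tracing a module
across levels, not for biology); disjoint sample sets give
`between-design` pairs. The same hypergeometric machinery serves
arbitrary user gene sets (`gene_set_overlap`); sets with no expressed
member are dropped with a warning. `build_trace_graph` serializes the
correspondence star around a focus module with `-log10 p` edge weights
capped at 320.

# Trait association

Each module eigengene is modelled as
`eigengene ~ trait1 + trait2 + trait1:trait2` and tested by factorial
ANOVA with **Type-II** sums of squares (via `car::Anova`): two-trait
disease designs are routinely unbalanced (e.g. 20 vs 16), where Type-II
is the standard choice and for balanced data it coincides with the
classical decomposition. Empty cells in the trait cross drop the
interaction with a warning. BH-FDR is applied per term across modules
(the joint-across-terms alternative was rejected as it mixes hypotheses
of different character). Because an eigengene is a univariate summary of
multivariate data, a PERMANOVA option (`vegan::adonis2`, Anderson's
pseudo-F) runs on Euclidean distances between the samples'
standardized module-expression profiles; its permutation p uses the +1
convention, so `p ≥ 1/(1 + n_perm)`. Null calibration of both tests is
exercised in the test suite (type-I rate and KS uniformity). The ANOVA
calibration runs on a balanced 2 × 4 layout with 4 samples per cell
(n = 32; 36 is not divisible into a balanced 2 × 4 design).

# Preservation and the phenotype-permutation test

`Zsummary` follows the density/connectivity scheme with a deliberately
reduced statistic set: four density statistics (mean within-module |cor|
in the test data, mean adjacency, proportion of variance explained by
the test eigengene, mean |kME|) and three connectivity statistics
(reference–test correlation of kIM, kME, and the vectorized
within-module correlation matrices). The null is `n_label_perm` random
gene sets of the module's size drawn from the genes shared by reference
and test (default 100; per-module RNG streams derived from the seed so
module order is irrelevant). `z_density` and `z_connectivity` are
medians of their groups; `z_summary` is their mean; `≤ 2` not preserved,
2–10 weak, `> 10` strong, boundary values in the lower category. Because
the statistic set is a reduction of the full published collection,
absolute Z values differ from other implementations; categories and
contrasts are the meaningful output. A statistic whose null sd is 0 gets
Z = 0 with a warning — the practically relevant case is test ≡
reference, where every connectivity correlation is identically 1; the
self-comparison then rests on the density side alone, which the test
suite verifies still classifies planted modules as strongly preserved.
Modules sharing under half their genes with the test data are skipped.

The permutation test asks whether an observed `Zsummary` is lower than
expected when the primary trait is uninformative. Each permutation
shuffles the trait labels (group sizes preserved — e.g. always 20
reference / 16 test), rebuilds the network on the randomized reference
subset with the same parameters as the observed run, removes
single-sample-driven modules, scores preservation in the randomized test
subset, and contributes the `Zsummary` of the module whose size is
closest to the module of interest (ties toward the smaller module;
size-matching matters because `Zsummary` grows with module size).
Permutations with no surviving module are excluded and counted. The
p-value is exact counting with no +1 correction: 39 of 2000 null scores
at or below the observed score is p = 0.0195 precisely. Inside each
permutation the Z computation may use fewer label permutations than the
observed run (default 30 vs 100) — a cost/precision trade-off that
affects only the spread of the null, symmetrically.

`subsample_accuracy` turns the "how many samples do I need" question
into a measurement: categories at the full test size are the ground
truth, categories are recomputed on random subsamples of each requested
size, and accuracy is the fraction of modules whose 0/1/2 score
(`≤ 2` → 0, 2–10 → 1, `> 10` → 2) matches the truth.

# Differential co-expression

Fisher's r-to-z applied per gene pair between two conditions; at least 4
samples per condition (the variance term requires n > 3); correlations
at |r| = 1 (degenerate synthetic data) are clipped to 0.999999 with a
warning. `module_pairs_dc` tests all C(m, 2) pairs of a module with BH
across those pairs (the scope of the adjustment is per module analysis —
a choice) and reports the count of significant pairs and the fraction
with higher co-expression in condition 1, plus both correlation matrices
for heatmap-style display.

# Module dynamics

`flow_table` counts shared genes between the modules of consecutive
networks (grey never contributes; zero edges are omitted) and annotates
each edge with the hypergeometric overlap p; the JSON export is
sankey-ready. `tom_flow` tracks every gene of a focus module through the
stored dendrogram leaf orders and summarizes a **dispersion score** per
network: mean pairwise leaf distance of the tracked genes divided by its
expectation under uniform random placement, `(G + 1)/3` for G leaves.
The score is an invented quantification — the corresponding visual
analysis is traditionally qualitative — introduced so that "interspersed
early, refined late" becomes a testable number: ~1 under random
placement (verified by simulation in the test suite), ≪ 1 when the
tracked genes sit together in the tree.

# The synthetic-data generator

Each planted module follows a single-factor model: in samples belonging
to an *active* cell of the trait cross,
`x_gs = λ_g f_s + sqrt(1 − λ_g²) ε_gs`, with a per-module latent factor
`f_s ~ N(0,1)` and Gaussian noise; in inactive cells the gene is pure
noise. The expected within-module correlation in active cells is λ²
(0.81 at the default λ = 0.9, matched by the empirical mean in the
tests). λ may be a per-gene vector, which creates genuine hub genes and
lets connectivity-preservation behave non-trivially. Optional per-cell
mean shifts exercise the trait-association path; an optional spike
sample (+10 on all module genes in one sample) plants a single-sample
outlier module for the filter. Generation is bit-identical under a fixed
seed. Gaussian noise on the log scale, rather than a count model, is the
deliberate scope: the workflow consumes log-scale values, and a
negative-binomial front-end would test the normalization step, not the
network machinery.

The canned fixture (`eae_like_fixture`) mirrors the shape of a
two-condition, four-region astrocyte profiling design: 20 disease + 16
wildtype samples, a 150-gene module co-expressed only in disease cells,
a 150-gene module active everywhere, a 100-gene spike module, 1600 noise
genes. What passing tests on it show: the workflow separates
condition-specific from constitutive co-expression, flags single-sample
artifacts, and keeps its statistics calibrated under the null. What they
do not show: robustness to count noise, batch effects, correlated noise
structure, or modules with partial (rather than all-or-none) condition
specificity — real data properties the generator intentionally omits.

# Problem sizes and reproducibility

The shipped analyses run at desk scale by design: the canned fixture has
2000 genes × 36 samples; the permutation-test demonstrations use a
500-gene reduction with 50 label permutations and 30 within-Z
permutations; the null-calibration checks use 10,000 Fisher-z pairs and
2000 ANOVA replicates. A full-scale study would raise the permutation
count (the reference analysis scale is 2000) and `n_label_perm` to 100+;
nothing in the code changes, only wall-clock time. Every stage seed is
derived deterministically from one global seed, so stages are
individually rerunnable and a rerun with the same config and seed
reproduces all tables byte for byte.
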