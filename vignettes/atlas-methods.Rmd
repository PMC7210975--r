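---
title: "Methods: expression-inferred CNV calling, marker statistics and interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-inferred CNV calling, marker statistics and interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatlas)
```

# Scope

`scatlas` re-implements, as tested and reusable statistics, the bespoke
computations common to multi-tissue single-cell tumor atlases of lung
adenocarcinoma: classifying tumor-tissue epithelial cells as malignant
from expression-inferred copy-number perturbation; threshold-defined
differential marker and signature selection with quartile survival
stratification; tissue-preference statistics on subset composition; a
permutation-based receptor--ligand interaction network; and a
gene--gene association network built from Gene Ontology term overlap.
Clustering, trajectory inference and curated ligand--receptor
databases are deliberately out of scope: cluster labels, signature
sets and pair tables are *inputs*.

# Normalization model

Raw UMI counts are filtered per cell (mitochondrial UMI fraction at
most 20%, total UMIs in [100, 150000], detected genes in
[200, 10000], all bounds inclusive) and per gene (expressed in at
least 0.1% of cells, by the ceiling rule). Counts are then scaled per
cell to a fixed total and log-transformed:

$$x_{cg} = \log_2\!\left(1 + \frac{n_{cg}}{\sum_g n_{cg}} \cdot 10^6\right)$$

The scale factor is configurable; $10^6$ makes values
transcripts-per-million-like and is the package default. Relative
expression subtracts each gene's mean across cells and caps magnitudes
at 10, with no variance scaling. A zero count maps to exactly zero
log-normalized expression; the sparse representation preserves this
identity rather than approximating it.

# CNV-based malignancy calling

The procedure infers chromosomal gains and losses from smoothed
deviations of chromosomally ordered expression, not from DNA:

1. **Reference mix.** Putative malignant cells (all epithelial-lineage
   cells of tumor-derived tissues) are diluted with normal-lung
   epithelial cells sampled without replacement until they are at most
   20% of the mix. The spike-ins stabilize the per-gene baseline; they
   are scored like any other cell but flagged in the output. If the
   pool is too small, the whole pool is used and a warning raised.
2. **Gene gate.** Genes expressed in fewer than 10 cells or with mean
   log2 expression below 0.1 are removed (both bounds inclusive on the
   keep side).
3. **Z-scores** per gene across the mix, using the population standard
   deviation (denominator $n$; fixed so oracle tests are exact), clipped
   to $[-3, 3]$ so single outlier cells cannot dominate a window.
4. **Smoothing.** Genes are sorted by (chromosome, start) and averaged
   in 100-gene moving windows within each chromosome (stride 1, windows
   fully inside the chromosome). Chromosomes with fewer genes than the
   window collapse to a single flagged window rather than being dropped,
   keeping genome coverage.
5. **Per-cell centering** of the window profile (the mean of each
   cell's genome-wide profile is subtracted), removing cell-level
   offsets.
6. **Scoring.** Each cell gets `ms`, the mean of its squared window
   values, and `corr`, the Pearson correlation of its profile with the
   average profile of the top `ceiling(0.05 n)` cells. The ranking
   statistic behind "top 5%" is `ms` — it is the only per-cell scalar
   available at that step; this choice is configurable in spirit but
   fixed as the default. A cell is malignant when `ms > 0.02` or
   `corr > 0.2`, both strict.

Cells with a zero-variance window profile have no defined correlation;
they are reported `NA` and can never pass the correlation arm.
Spike-in normals participate in the Z-score means/SDs and in the
top-5% ranking (they rank low by construction).

## Why the synthetic default genome has 5,000 genes

The correlation threshold of 0.2 presumes profiles with many
effectively independent windows, as on a real transcriptome
(thousands of positioned genes per genome, hundreds of independent
100-gene blocks). Calibration runs during development showed that a
2,000-gene genome over 10 chromosomes leaves only ~20 independent
windows per cell, so pure noise correlations of normal cells with the
reference exceed 0.2 about 8% of the time — the threshold would sit
inside the noise band and no threshold-faithful test could hold a 5%
false-positive bound. The default cohort therefore carries 500 genes
per chromosome (~50 independent windows), where the same thresholds
behave as they do on real data. This is a property of the emulated
world, chosen once; it was not tuned against any particular test
statistic.

# Marker and signature statistics

Differential markers between two cell groups are gated and tested as
follows: a gene is *tested* only if expressed (log-normalized value
strictly positive) in more than 25% of cells of at least one group;
log2 fold change is the difference of group means of log2 values (the
data are already in log space; a "de-log, average, re-log" variant is
available via `fc_method = "expm"`); significance uses the two-sided
equal-variance Student's t test with Bonferroni correction over the
number of genes actually tested (upstream toolkits are silent on the
denominator; the tested set is the defensible choice because only
those hypotheses are evaluated). A marker passes when fold
change (strictly above 1 for subset signatures, absolute value above
0.585 ≈ log2 1.5 for stage comparisons), raw p < 0.01 and adjusted
p < 0.01 all hold. Genes with zero pooled variance get p = 1 and a
`degenerate` flag.

Signature scores are plain means of log-normalized expression over a
gene set, per cell and optionally per sample. Survival stratification
labels samples at or below the 25th percentile of the score "low" and
at or above the 75th "high" (linear, type-7 quantiles — no
interpolation rule is standard in this literature, so the R default is
used and fixed), discards the middle half, truncates follow-up at 10
years (deaths beyond the horizon become censored observations at the
horizon; an `exclude_beyond` flag instead drops them, covering the
ambiguity in how such cohorts describe the rule) and applies the
two-sided log-rank test from the `survival` package.

Variable genes are selected by mean log expression strictly inside
(0.0125, 3) and variance/mean dispersion Z-standardized within 20
equal-count mean bins, keeping genes above 0.5. The stromal
partition runs PCA on the centered variable-gene matrix, splits cells
by the sign of the first principal component (sign oriented so cells
high in the first marker set score positive — PCA signs are arbitrary,
so orientation must come from the markers), and labels a cell only if
its average log-normalized marker expression strictly exceeds 1,
otherwise `undetermined`.

# Composition statistics

For a subset-by-tissue-origin count table, expected counts come from
the margins ($E_{ij} = r_i c_j / N$), enrichment is reported both as
the Pearson residual $(O-E)/\sqrt{E}$ and as the observed/expected
ratio $R_{O/E} = O/E$, and the chi-square statistic is the sum of
squared residuals (no continuity correction). Per-sample immune
proportions exclude the epithelial lineage from the denominator by
default; a flag also removes stromal lineages, since "non-epithelial
compartment" and "after removing epithelial and stromal populations"
describe different denominators and both are legitimate questions.
Group differences in per-sample fractions use the two-sided
equal-variance Student's t test.

# Receptor–ligand permutation network

For each ligand--receptor pair and ordered cluster pair (a: ligand
side, b: receptor side), the interaction score is the average of the
two cluster-mean log expressions, defined only when each partner is
expressed in strictly more than 25% of its cluster's cells — the gate
is evaluated independently per partner, matching the behavior of the
tool this statistic emulates. Cluster labels are permuted uniformly
1,000 times; the one-sided p-value is the fraction of permuted scores
at least as large as the observed one, without pseudocount by default
(`(k+1)/(n+1)` behind a flag). One seeded permutation stream is shared
across all pairs, which makes runs reproducible and p-values across
pairs comparable (at the cost of weak dependence between them).
Undefined observed scores get p = 1. Calibration is assessed over the
*defined* combinations: gated-out combinations can never be declared
significant, so including them would deflate the nominal level by
construction.

Four filters then apply, in any order (they commute): collagen pairs
(symbol matching `^COL[0-9]`) are removed; same-lineage cluster pairs
are removed; clusters at or below 0.1% of the immune + stromal cells
are removed — epithelial clusters are not part of that compartment and
pass through, since the networks of interest explicitly include tumor
cells; p-values at or above 0.05 are removed. Counts of surviving
interactions per directed cluster pair form the interaction heat map;
no symmetrization is applied to the data.

# GO-Jaccard gene network

Marker genes are connected when the Jaccard index (intersection over
union) of their GO Biological Process term sets strictly exceeds 0.05.
Term sets are taken as supplied — no ancestor propagation, as none is
described for this statistic; genes with no BP terms are excluded
before pairing and reported, and isolated genes are dropped from the
node list. Only structural properties are testable: network membership
depends on the annotation release, so no specific gene count is
asserted anywhere.

# The synthetic cohort generator

`simulate_counts()` draws UMI counts from a negative binomial with
per-cell lognormal library-size factors and per-group gene mean
profiles. The default cohort: 1,200 cells in 6 groups (malignant and
normal epithelial, T/NK, myeloid, fibroblast, endothelial) across
nLung/tLung/mBrain with known planted preferences; 5,000 genes on 10
chromosomes with evenly spaced positions (windowing needs order, not
realistic coordinates); whole-chromosome fold-2 gains on chromosomes 1
and 2 in the malignant group; 40-gene marker blocks with log2 effect 2
per group; two planted ligand--receptor signals; NB dispersion 0.5
(variance $\mu + 0.5\mu^2$, typical droplet-data overdispersion);
baseline gene means lognormal(log 0.2, 1) giving a few hundred UMIs
per cell; a 2% mitochondrial fraction carried by dedicated `MT-SIM`
genes. The normal-lung epithelial pool (600 cells) is sized so the
reference mix can reach the 20% malignant ceiling without pool
exhaustion. Zero inflation, batch effects, doublets, ambient RNA and
pseudotime structure are *not* emulated — a green test establishes
correctness of the statistics under the stated model, not robustness
to those artifacts. All generators are seeded and restore the global
RNG state.

`null_sim_config()` builds identical-mean cohorts with no planted
structure; every type-I-error and calibration check runs on it.

# Numerical choices and degenerate inputs

* Population (not sample) SD in CNV Z-scores; sample variance in the
  dispersion statistic (matching the respective conventions upstream).
* Boundary conventions: QC and CNV gene gates are inclusive;
  malignancy, marker, PCT, Jaccard and significance thresholds are
  strict, following how each rule is written (">" versus ranges).
* Bonferroni adjustment is `min(1, p * n_tested)`.
* Zero-variance genes are dropped before Z-scoring (with a warning);
  degenerate t-tests return p = 1 flagged; empty margins in
  contingency tables are dropped with a warning; an exhausted spike-in
  pool is a warning, not an error.
* Quantile interpolation is type 7 throughout.
* Scoring requires at least 20 cells so the top-5% reference contains
  at least one cell.

# Known limitations

* The malignancy caller assumes broad (many-gene) copy-number
  segments; focal amplifications below the window scale are invisible.
* Marker statistics use the equal-variance t test by design fidelity,
  not because it is optimal for droplet counts.
* Ligand--receptor pairs are simple gene pairs; multi-subunit
  complexes (minimum over subunits) are a documented extension point.
* The shared permutation stream makes p-values weakly dependent across
  pairs; with 1,000 permutations the p-value grid is 0.001-coarse.
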