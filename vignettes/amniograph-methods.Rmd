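---
title: "Models and methods behind amniograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amniograph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

amniograph analyses single-cell RNA-seq data from peri-gastrulation primate
embryos, centred on the question of how the amnion's ISL1-dependent
signalling program supports mesoderm formation. This vignette explains the
statistical models each stage implements, the parameters that matter, and
the design decisions taken where the methodology was genuinely open. The
package ships a synthetic embryo-atlas generator so that every stage can be
exercised against known ground truth; what that generator does and does not
emulate is described at the end.

## The synthetic embryo atlas

`simulate_dataset()` draws two conditions — wild type and ISL1 mutant — each
with eight populations: epiblast (Epi), two amnion states (AM-1, AM-2), two
mesoderm states (meso-1, meso-2), endoderm, trophoblast, and extraembryonic
mesenchyme. Population weights default to Epi 0.35, AM 0.10 + 0.10, meso
0.10 + 0.10, Endo 0.10, Trophoblast 0.10, ExE-Mech 0.15, normalized to a
simplex; the mutant moves the mesoderm weight (0.10 per cluster reduced to
0.01) onto the amnion clusters, emulating the failure of mesoderm formation
with cells accumulating in the amnion compartment.

Counts are negative binomial: gene `g` in cell `c` has
`x_gc ~ NB(mean = L_c * r_gc, dispersion theta)` with variance
`mu + mu^2/theta` and `theta = 10` by default. Library sizes `L_c` are
lognormal with log-mean `ln 5000` and log-sd 0.4, so the expected per-cell
total is `exp(ln 5000 + 0.4^2/2) ~ 5416`. Per-type expression profiles
`r_gc` are built from a lognormal baseline with:

* 25 marker genes per population, 8-fold elevated in their own type;
* a 51-gene ISL1 regulon (the TF plus 50 targets, including highly expressed
  BMP4- and WNT6-like genes) elevated 5-fold in amnion; in the mutant
  condition every regulon gene's rate in amnion cells is multiplied by
  `delta = 0.3` *without* renormalizing the cell's profile, so the expected
  mutant value is exactly `delta` times the wild-type one;
* three CG-like reporter genes with zero endogenous rate outside
  trophoblast; inside trophoblast each accounts for 20% of transcripts,
  reflecting the extreme dominance of choriogonadotropin output in that
  lineage — this is what makes the genes usable as exclusive ambient
  reporters;
* thirteen mitochondrial genes calibrated to a 3% share in every type;
* twenty naive-state and twenty primed-state pluripotency genes whose
  epiblast rate is proportional to `1 - t` and `t` respectively, where `t`
  is a latent uniform pseudotime private to each epiblast cell.

Ambient contamination is mixed at the *rate* level: the sampling rate is
`(1 - rho) * endogenous + rho * b`, where the ambient profile `b` is the
library-size-weighted aggregate endogenous profile of the condition's cells.
Mixing rates (rather than adding counts post hoc) keeps per-cell totals
calibrated and makes `rho` identifiable by the estimator below. Defaults
`rho = 0.10` and `delta = 0.3` are simulation choices — plausible magnitudes
for droplet contamination and a strong knockout effect — not measured
values, since the contamination level and effect-size distribution in the
primate data are not reported.

A single Day-14-like snapshot is simulated: no batch effects, no doublets,
no multi-day structure, because cross-batch integration is out of the
package's scope and the downstream statistics do not need them.

## QC and ambient RNA

`apply_qc_filters()` drops cells first — mitochondrial fraction at or above
7.5% ("below 7.5%" is read strictly, so a cell at exactly 0.075 is dropped)
or fewer than 500 expressed genes (the gene-count threshold varies per
sample in practice, so it is a configurable parameter) — and then drops
genes expressed in fewer than three of the *retained* cells. Ordering cells
before genes makes the gene filter refer to analysed cells, and the
operation is idempotent.

`estimate_ambient_fraction()` uses the exclusive-marker strategy: CG-family
genes are expressed only by trophoblast, so any CG counts observed in
POU5F1-positive epiblast cells must be ambient. With `b` the aggregate count
profile over all cell-containing barcodes (normalized to a simplex; no
empty-droplet data is assumed), the estimate is the Poisson
maximum-likelihood ratio of observed to expected-if-fully-ambient reporter
counts:

    rho_hat = sum(reporter counts in epiblast) /
              sum(N_c * sum(b[reporters]))     , clamped to [0, 1].

`correct_ambient()` removes `round(rho * N_c * b_g)` from each entry,
clamped at zero. This deterministic per-entry subtraction deliberately
replaces the published redistribution-style correction: the estimation
logic is the specified part of the method, the removal internals are not,
and determinism makes the correction exactly reproducible and testable.
Corrected counts never exceed the originals and stay integral.

## Normalization and differential expression

The normalization model is a regularized negative binomial with an *offset*
mean structure: `mu_gc = N_c * p_g`, where `p_g` is the gene's share of the
grand total. This replaces a per-gene regression on log-depth: for data
whose expected composition is depth-proportional (as the simulated data and
most UMI data approximately are) the expectation structure is the same,
while degenerate per-gene fits are far rarer. Per-gene dispersions are
maximum-likelihood with the means fixed, bounded to `[0.01, 1e6]` (the
upper bound is the Poisson limit, reported for genes with no detectable
overdispersion), and regularized by Gaussian-kernel regression of
`log10 theta` on `log10 mean` with Silverman's-rule bandwidth. When the
matrix is very large the dispersions are estimated on a seeded 2000-cell
subset; the offsets always use all cells. Pearson residuals

    z_gc = (x_gc - mu_gc) / sqrt(mu_gc + mu_gc^2 / theta_g)

are clipped to `[-sqrt(n_cells), +sqrt(n_cells)]`.

Differential expression between two cell groups is a per-gene two-tailed
Welch t test on these residuals with Benjamini-Hochberg correction, plus an
*empirical effect-size floor*: cells are repartitioned at random into groups
of the same sizes 100 times, and the 99.9th percentile of the pooled
(genes x partitions) absolute mean differences defines a symmetric band
`B`. A gene is significant only if `q < 0.01` *and* `|mean difference| > B`.
The band is pooled globally rather than per gene — a single band is what a
volcano plot's gray region depicts, and per-gene 99.9th percentiles are
unstable at 100 partitions. The number of partitions and the percentile are
exposed as configuration. Volcano-style output reports uncorrected p values
alongside q.

One consequence of depth-constrained normalization worth knowing: when a
large expression program is lost (mutant amnion losing 5-fold elevated
regulon targets), the *relative* abundance of every other gene rises, so a
mutant-versus-wild-type comparison legitimately finds modest positive
shifts in non-target genes. Calibration is therefore asserted under a true
null (random splits of one population), not in the presence of a real
effect.

## Embedding, clustering, annotation, composition

PCA (30 components by default) on centered residuals, with each component's
sign fixed so its largest-magnitude loading is positive, feeds a
symmetrized unit-weight kNN graph (k = 15, Euclidean distances kept as edge
attributes). Clustering is greedy modularity maximization
(`igraph::cluster_fast_greedy`) — deterministic, dependency-light, with a
merge tree. The default uses the modularity-optimal cut; the `resolution`
knob rescales the number of communities along the merge tree (never below
the number of connected components). At the default, the simulated atlas
resolves into about ten clusters (the epiblast's internal naive-to-primed
continuum splits), giving an adjusted Rand index of ~0.95 against the
generated populations; this mirrors how small subclusters without distinct
identity are recombined manually in practice, which `merge_clusters()`
supports while retaining the original labels.

Clusters are annotated by the marker set with the highest mean per-cell
signature score; ties break alphabetically and are flagged.
`composition_by_condition()` tabulates per-condition cell-type fractions —
the quantification behind "mesoderm is depleted and amnion overrepresented
in the mutant" — with a 3-binomial-SE margin used for the headline calls.

## Signature scoring

A cell's score for a gene set is the set's share of the cell's transcripts,
times 100 (the ratio-of-sums score of the Single-Cell Signature Explorer
family). It is computed on raw post-QC counts, is exactly additive over
disjoint sets, exactly scale-invariant per cell, and equals 100 for the
set of all genes. Genes missing from the matrix contribute zero and are
recorded.

## Pseudotime and Moran's I

Rather than learning a principal graph in a low-dimensional embedding, the
package takes the geodesic route: pseudotime is the shortest-path distance
from a root cell along the kNN graph with Euclidean edge lengths, min-max
scaled to [0, 1]. The inference target — ranking genes by how smoothly they
vary along the trajectory — is preserved while avoiding re-implementation
of a published embedding-plus-principal-graph pipeline. The root is user
specified; `select_root()` defaults to the cell with the highest
naive-pluripotency score.

Gene ranking uses Moran's I on the same graph with symmetrized unit
adjacency weights:

    I = n / S0 * sum_ij w_ij (y_i - ybar)(y_j - ybar) / sum_i (y_i - ybar)^2

For a single feature the p value is a seeded one-sided label-permutation
test (999 permutations). For transcriptome-wide ranking the permutation
test would cost permutations x genes sparse multiplications, so the table
uses the closed-form randomization mean and variance of I (normal
approximation) — the ranking itself depends only on I. The top 100 genes
are averaged in 20 equal-width pseudotime bins (empty bins linearly
interpolated), z-scaled, and cut into two dynamics groups (down/up) by
average-linkage hierarchical clustering, labelled by the sign of the
centroid trend.

## Regulon activity and binarization

Regulon *discovery* (co-expression plus motif pruning) requires external
motif databases and is deliberately out of scope; regulons enter as gene
sets (GMT or generator truth). Before scoring, genes are prefiltered by the
1%-of-cells rule: at least three UMI per 1% of cells in total
(`min_counts = 3 * ceiling(0.01 n)`) and presence in at least 1% of cells —
at 1300 cells, exactly the canonical 39 counts / 13 cells.

Activity is the recovery-curve AUC: each cell's genes are ranked by
decreasing count, with ties broken by a seeded shuffle (UMI data is
tie-dominated, so tie policy must be explicit to be reproducible), and

    A = sum_{x=1..k} hits(x) / sum_{x=1..k} min(x, |R|),

with rank cutoff `k = ceiling(0.05 * n_genes)` by default. The TF is
counted among its own regulon's genes (a flag can exclude it).

Binarization follows the distribution of each regulon's AUC values, tested
with Hartigan's dip statistic — the maximum distance between the empirical
CDF and the closest unimodal CDF, computed by the
greatest-convex-minorant / least-concave-majorant algorithm implemented in
the package and validated against a brute-force linear-programming
minimization over piecewise-linear unimodal CDFs. The null distribution of
the dip depends only on sample size, so p values come from 1000 seeded
uniform samples, cached per size. At `alpha = 0.05` (the test's level is
not prescribed anywhere, so it is a parameter): unimodal regulons get
`tau = mean + 2 sd`; bimodal ones get the trough of the Silverman-bandwidth
Gaussian KDE (512-point grid extended 3 bandwidths beyond the range)
between the two highest local maxima, found by grid minimization. Cells are
active strictly above `tau`; regulons active in fewer than 1% of cells are
dropped; the surviving boolean matrix is clustered on both axes with
Jaccard distance and average linkage.

## Numerical and reproducibility choices

* One root seed drives everything; each stage derives a named substream
  (`derive_seed`), all below 2^31, and package functions restore the
  caller's RNG state.
* Degenerate inputs have defined behaviour: zero-variance Welch inputs give
  t = 0, p = 1 (equal means) or the smallest representable p; constant AUC
  vectors take the degenerate `tau = mean` rule with no active cells; a
  bimodal dip call with fewer than two KDE peaks falls back to the unimodal
  rule with a warning; zero-total genes get zero residuals.
* Annotation ties break alphabetically; DE tables order by p then |t|.
* Default problem sizes (2000 genes, 1500 cells per condition) keep a full
  pipeline run around a minute on one CPU; tests use 700-gene /
  300-cell-per-condition versions of the same generator where full scale
  adds nothing.

## What passing tests do and do not show

The generator produces NB counts with a depth-proportional offset structure,
marker-block population identities, and a clean latent pseudotime. It does
not emulate transcriptome-wide co-expression structure, empty droplets or
doublets, batch effects, or per-cluster contamination differences. Results
on it validate the *implementations* — estimator consistency, test
calibration, threshold rules, recovery of planted structure — not the
biological conclusions, and transfer to real data only to the extent that
the NB-with-offset model describes it.
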