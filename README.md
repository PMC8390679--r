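# amniograph

Single-cell analysis of amnion-driven mesoderm formation in primate
embryos, with a fully synthetic test bed.

In peri-gastrulation primate embryos the amnion is not a passive membrane:
it expresses the transcription factor ISL1 and signals (BMP4, WNT6) to the
adjacent epiblast, and loss of ISL1 collapses mesoderm formation. Testing
the computational side of that story requires a chain of bespoke
procedures: estimating ambient RNA through trophoblast-exclusive CG
reporter genes, differential expression on regularized negative-binomial
Pearson residuals against a random-subset null band, ratio-of-sums gene
signature scoring, Moran's-I gene ranking along pseudotime, and
recovery-curve regulon activity with dip-test-driven binarization.
amniograph implements that chain as reusable, tested R functions, plus a
ground-truth synthetic embryo-atlas generator so every stage can be
validated without any external download.

## The statistics in brief

* **Ambient RNA** — with ambient profile `b` (aggregate counts normalized
  to a simplex) and reporter genes exclusive to a producer population, the
  contamination fraction in non-expressing cells is the Poisson MLE ratio
  `rho_hat = sum(x_reporters) / sum(N_c * sum(b_reporters))`, clamped to
  [0, 1]; correction subtracts `round(rho * N_c * b_g)` per entry, clamped
  at zero.
* **DE** — Pearson residuals `z = (x - mu)/sqrt(mu + mu^2/theta)` under an
  NB offset model `mu_gc = N_c p_g` with kernel-regularized `theta_g`,
  clipped at `sqrt(n_cells)`; two-tailed Welch t per gene; significance
  requires BH `q < 0.01` **and** `|mean difference|` above the 99.9th
  percentile of random-split differences.
* **Signatures** — `score = 100 * sum(x[sig]) / N_c` (additive,
  scale-invariant).
* **Pseudotime** — kNN-graph geodesic from a root cell;
  `I = n/S0 * sum w_ij z_i z_j / sum z_i^2` ranks genes; the top 100 are
  binned, z-scaled and cut into down/up dynamics clusters.
* **Regulons** — recovery-curve AUC
  `A = sum_{x<=k} hits(x) / sum_{x<=k} min(x, |R|)` per cell with seeded
  tie-breaks; Hartigan's dip decides unimodal (`tau = mean + 2sd`) versus
  bimodal (`tau` = KDE trough between the two highest peaks); regulons
  active in < 1% of cells are dropped.

## Worked example

```r
library(amniograph)

report <- run_pipeline(pipeline_config(seed = 1))
#> [input] 2000 genes x 3000 cells
#> [qc] 2999/3000 cells and 2000/2000 genes retained
#> [ambient] rho_hat = 0.1008 over 990 reporter cells
#> [normalize] residuals clipped at 54.76
#> [cluster] 10 clusters -> types: Epi, ExE-Mech, Trophoblast, Endo, AM-2, AM-1, meso-1, meso-2
#> [pseudotime] root WT-0225; 2000 genes ranked
#> [regulons] 1/1 regulons retained
#> [de] 172 significant genes

unlist(report$composition_fractions)
#>    meso_wt    meso_mt  amnion_wt  amnion_mt
#> 0.17600000 0.01601067 0.18200000 0.33222148

report$headline
#> $mesoderm_depleted_in_mutant      TRUE
#> $amnion_overrepresented_in_mutant TRUE
#> $bmp4_down_in_mutant_amnion       TRUE
#> $isl1_regulon_amnion_specific     TRUE
```

Reading the output: the simulated ISL1 mutant retains only ~1.6% mesoderm
versus ~18% in wild type while amnion grows to ~33%; the ambient
contamination planted at 0.10 is estimated at 0.101 from CG counts in
epiblast-annotated cells; BMP4 is significantly downregulated in mutant
amnion (it sits among the smallest p values in `report$de`); and the ISL1
regulon's AUC distribution is called bimodal with its active cells nearly
all amnion.

Individual stages are ordinary functions — `simulate_dataset()`,
`apply_qc_filters()`, `estimate_ambient_fraction()`, `run_de()`,
`auc_score()`, `binarize_matrix()`, `graph_pseudotime()`, and so on — see
the help pages and `vignettes/amniograph-methods.Rmd`.

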