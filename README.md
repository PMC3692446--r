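# layernet

Cross-study microarray integration and layered signaling-network analysis
in R.

`layernet` is for researchers who want to pool small case–control
expression cohorts — here ulcerative colitis (UC) versus colorectal
carcinoma (CRC) — into one compendium and extract *robust* differential
signaling modules from it, rather than the unstable gene lists a single
small cohort yields. The pipeline:

1. **Normalize** each study (quantile normalization) and **merge** to the
   common gene universe.
2. **Remove batch effects** with the empirical-Bayes location/scale model
   `Y = α_g + Xβ_g + γ_ig + δ_ig ε`, shrinking per-gene batch effects
   `(γ̂, δ̂)` toward batch-level priors (parametric normal/inverse-gamma
   with the iterative joint posterior, or a nonparametric
   weighted-likelihood variant), with the condition effect protected.
3. **Screen differential genes** with two-class SAM,
   `d_g = (x̄_CRC − x̄_UC)/(s_g + s0)`, permutation-calibrated FDR via the
   delta procedure, plus a two-sided fold-change filter (FDR < 0.05,
   FC > 1.2) — run over 8 resampled virtual cohorts (≥ 12 samples each,
   drawn within condition across studies) so only recurrent drivers
   survive.
4. **Detect dense network modules** in a cleaned cancer signaling map
   (largest component, undirected, deduplicated) with the MCODE
   algorithm; keep complexes with score (density × size) above 2.0 and
   map the recurrent drivers onto them.
5. **Stratify module nodes into four subcellular layers**
   (extracellular, membrane, cytoplasm, nucleus), imputing missing
   localization by iterated neighbor majority vote.
6. **Enrich** every (module × layer) gene set against GMT collections
   with the upper-tail hypergeometric test and BH-FDR (< 0.01), and build
   the clustered −log10(q) heatmap matrix.

A synthetic-data generator with complete ground truth (planted DE genes,
planted network modules, unanimous module layers, planted enriched
terms) makes every stage testable offline.

## Worked example

```r
library(layernet)

dir <- tempfile()
bundle <- simulate_bundle(sim_config(seed = 7), file.path(dir, "inputs"))
cfg <- pipeline_config(
  expression   = bundle$paths$expression,
  metadata     = bundle$paths$metadata,
  network      = bundle$paths$network,
  localization = bundle$paths$localization,
  genesets     = bundle$paths$genesets,
  outdir       = file.path(dir, "out"),
  seed         = 7)
manifest <- run_pipeline(cfg)
str(manifest$counts)
#> List of 6
#>  $ network_nodes      : num 290
#>  $ network_edges      : num 644
#>  $ n_complexes        : int 8
#>  $ n_robust_modules   : int 3
#>  $ n_driver_genes     : int 277
#>  $ n_significant_cells: int 8
```

Reading: the cleaned synthetic interactome's largest component has 290
nodes and 644 edges; MCODE finds 8 complexes scoring above 2.0; the
resampling screen flags 3 of them as robust (at least one member gene
called differential in ≥ 3 of the virtual cohorts) — exactly the three
modules the generator seeded with differential genes; 277 genes are
called in at least one cohort; and 8 (module × layer) enrichment cells
pass BH-FDR < 0.01, so the heatmap stage has signal to cluster. Per-stage
tables (`detable_rds*.tsv`, `complexes.tsv`, `layers.tsv`,
`enrichment.tsv`, `heatmap_matrix.tsv`) and a reproducibility manifest
are written under `outdir`.

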