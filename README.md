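# qtlcompendium

Uniform, cross-dataset cis-eQTL analysis on synthetic cohorts with known
ground truth.

Large eQTL resources harmonize individual-level expression and genotype
data from many studies, map cis-QTLs uniformly, fine-map them to credible
sets, merge independent signals across datasets, quantify effect-size
sharing between cell types and tissues, and colocalize the signals with
GWAS loci. The individual-level inputs of such resources are
controlled-access, so this package re-implements the full analysis as
tested, reusable R functions driven by a synthetic-data generator: every
stage can be validated against planted truth, and the same functions apply
unchanged to real dosage/expression matrices.

**Who it is for:** statistical geneticists who want a transparent,
dependency-light reference implementation of the standard cis-QTL stack
(and a simulation harness to probe its calibration), rather than a wrapper
around external tools.

## What is implemented

| Stage | Core functions |
| --- | --- |
| Synthetic data (LD-structured genotypes, planted cis effects, sharing patterns, coloc region pairs, reference panels) | `simulate_genotypes()`, `simulate_expression_dataset()`, `simulate_effect_matrix()`, `simulate_coloc_pair()`, `simulate_reference_panel()`, `simulate_study()` |
| Genotype QC | `hardy_weinberg_test()`, `filter_variants()`, `ld_prune()`, `compute_pcs()`, `assign_superpopulation()` |
| Expression QC / normalization | `counts_to_tpm()`, `filter_low_expression()`, `median_expression_profile()`, `infer_sex()`, `usage_ratios()`, `inverse_normal_transform()`, `regress_out()` |
| cis-QTL mapping | `cis_scan()`, `permutation_group_best()`, `significant_qtls()` |
| Fine mapping | `wakefield_log_abf()`, `credible_set()`, `finemap_region()` |
| Cross-dataset harmonization | `filter_and_split_credible_sets()`, `connected_components()`, `select_lead_variant()`, `transcript_level_lead_selection()`, `build_effect_matrix()`, `pleiotropy_fraction()` |
| Sharing & MDS | `pair_shared()`, `sharing_matrix()`, `correlation_distance()`, `nonmetric_mds()` |
| Colocalization | `coloc_abf()`, `extract_region()`, `assign_ld_block()`, `summarize_blocks()`, `novelty_score()`, `method_overlap_counts()` |

The statistical core in brief: per-variant OLS with covariates over a
±1 Mb cis window; group-best permutation empirical p-values
`(1 + #{perm min ≤ obs min})/(B + 1)` with BH-FDR across genes; Wakefield
log-ABFs `½log(1−r) + ½z²r`, `r = W²/(se²+W²)`, softmax PIPs and minimal
95% credible sets; per-gene connected components of credible sets that
share variants, with leads chosen by dataset support then largest |β|;
the same-sign-within-twofold sharing criterion on a lead × dataset effect
matrix (missing → 0); Kruskal stress-1 non-metric MDS; and the five-way
ABF colocalization posterior (PP0–PP4) summarized over approximately
independent LD blocks at PP4 ≥ 0.8.

## Worked example

A full synthetic study lives in `analysis/01_simulate.R` …
`analysis/08_coloc_blocks.R` (run them in order from the repository root;
outputs land in `results/`). A minimal end-to-end fragment:

```r
library(qtlcompendium)

g <- simulate_genotypes(n_samples = 500, n_variants = 200, mafs = 0.3,
                        ld_rho = 0.9, seed = 1)
causal <- colnames(g)[100]
y <- sqrt(0.1 / 0.9) / sd(g[, causal]) * g[, causal] + rnorm(500)

perm <- permutation_group_best(y, g, n_perm = 1000, seed = 1)
perm$empirical_p
#> [1] 0.000999001
cs <- finemap_region(y, g)
cs$size; head(cs$members, 3)
#> [1] 3
#>     variant_id       pip        z
#> 1  1_99000_A_G 0.5856958 5.463250
#> 2 1_100000_A_G 0.2866646 5.306265
#> 3 1_101000_A_G 0.1167429 5.090507
```

The empirical p-value is the floor `1/(B+1)` — the observed association
beats all 1000 permutations — and the 95% credible set contains three
variants: the planted causal variant (`1_100000_A_G`) and its two
immediate neighbors, which sit in LD with it at r ≈ 0.9 and cannot be
statistically separated at this sample size. That is exactly the
resolution limit fine mapping is supposed to expose.

Running the eight analysis scripts prints, among other things, the
per-dataset significant-gene counts against the planted effects, the
fine-mapping hit rate (29/30 sets contain the causal variant), the
pairwise sharing matrix with its clear within-group / between-group
contrast, and median PP4 of 0.999 / 0.001 / 0.001 for planted shared /
distinct / null colocalization pairs.

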