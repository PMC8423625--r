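Package: qtlcompendium
Title: Cross-Dataset cis-QTL Mapping, Fine Mapping and Colocalization on
    Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Uniform multi-dataset expression quantitative trait locus
    (eQTL) analysis with known ground truth. Provides a synthetic-data
    generator (LD-structured genotypes, expression with planted cis
    effects, cross-dataset sharing patterns, colocalization region pairs),
    genotype and expression quality control and normalization (TPM, usage
    ratios, rank-based inverse normal transform), nominal cis association
    scans with group-best permutation empirical p-values and FDR,
    single-effect Wakefield approximate-Bayes-factor fine mapping to 95%
    credible sets, cross-dataset harmonization of independent signals via
    connected components of credible sets, effect-size sharing and Kruskal
    non-metric multidimensional scaling, and approximate-Bayes-factor
    colocalization summarized over approximately independent LD blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan,
    cluster,
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
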