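#!/usr/bin/env Rscript
# Simulate the study: four datasets (two cell-type groups of two), each with
# its own genotype panel over a shared variant grid and expression traits
# with planted cis effects that are shared within groups. Everything
# downstream (QC, mapping, fine mapping, harmonization, sharing, coloc) runs
# off the files written here.

library(qtlcompendium)

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_datasets = 4, n_samples_per_dataset = 150, n_genes = 40,
  n_variants_per_region = 20, maf_range = c(0.1, 0.5), ld_rho = 0.8,
  effect_size_sd = 0.6, noise_sd = 1,
  sharing_pattern = c(lcl_a = "lcl", lcl_b = "lcl",
                      tcell_a = "tcell", tcell_b = "tcell"),
  seed = 20260101)

study <- simulate_study(cfg, within_group_shared_fraction = 0.8,
                        n_covariates = 2)

for (d in names(study$datasets)) {
  ds <- study$datasets[[d]]
  write_dosage_tsv(ds$genotypes, sprintf("results/sim/%s_dosage.tsv", d))
  write_trait_matrix(ds$expression, sprintf("results/sim/%s_traits.tsv", d))
  write_trait_matrix(t(ds$covariates), sprintf("results/sim/%s_covariates.tsv", d))
}
# a VCF slice of the first gene's region, as the exchange-format example
g1 <- study$datasets$lcl_a$genotypes[, 1:cfg$n_variants_per_region]
write_genotype_vcf(g1, "results/sim/lcl_a_gene1.vcf")

write.table(study$trait_meta, "results/sim/trait_meta.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- data.frame(gene_id = rownames(study$truth), study$truth,
                    check.names = FALSE)
write.table(truth, "results/sim/truth_beta.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

active <- colSums(!is.na(study$truth))
cat(sprintf("simulated %d genes x %d datasets; active effects per dataset: %s\n",
            cfg$n_genes, cfg$n_datasets,
            paste(names(active), active, sep = "=", collapse = ", ")))
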