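#!/usr/bin/env Rscript
# Expression QC and normalization: TPM, low-expression and median filters,
# sex inference, usage ratios and the inverse normal transform applied to
# the simulated trait matrices used for QTL mapping.

library(qtlcompendium)

## TPM / filter / usage demonstration on a synthetic count matrix ------------
set.seed(33)
n_tr <- 30; n_s <- 24
counts <- matrix(rnbinom(n_tr * n_s, mu = 60, size = 5), n_tr, n_s,
                 dimnames = list(sprintf("tx%02d", 1:n_tr),
                                 sprintf("s%02d", 1:n_s)))
counts[1:3, ] <- rpois(3 * n_s, 0.05)       # near-silent traits
lengths <- sample(500:3000, n_tr)
tpm <- counts_to_tpm(counts, lengths)
keep <- filter_low_expression(tpm)
cat(sprintf("low-expression filter: %d / %d traits retained\n",
            length(keep), n_tr))

groups <- setNames(rep(sprintf("gene%02d", 1:10), each = 3), rownames(tpm))
usage <- usage_ratios(tpm, groups)
cat(sprintf("usage ratios: %.0f%% of group/sample totals equal 1\n",
            100 * mean(abs(rowsum(usage, groups) - 1) < 1e-9, na.rm = TRUE)))

## sex inference on a spiked matrix ------------------------------------------
sex_tpm <- rbind(tpm,
  XIST = c(rep(25, 12), rep(0.1, 12)),
  RPS4Y1 = c(rep(0.1, 12), rep(12, 12)),
  EIF1AY = c(rep(0.2, 12), rep(8, 12)))
sex <- infer_sex(sex_tpm, y_gene_ids = c("RPS4Y1", "EIF1AY"), xist_id = "XIST")
cat(sprintf("sex calls: %s\n",
            paste(names(table(sex$call)), table(sex$call),
                  sep = "=", collapse = ", ")))
write.table(sex, "results/sex_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## INT + covariate regression of the mapping traits --------------------------
for (d in c("lcl_a", "lcl_b", "tcell_a", "tcell_b")) {
  traits <- read_trait_matrix(sprintf("results/sim/%s_traits.tsv", d))
  cov <- t(read_trait_matrix(sprintf("results/sim/%s_covariates.tsv", d)))
  int <- t(apply(traits, 1, inverse_normal_transform))
  colnames(int) <- colnames(traits)
  write_trait_matrix(int, sprintf("results/sim/%s_traits_int.tsv", d))
  resid <- regress_out(int, cov)
  write_trait_matrix(resid, sprintf("results/sim/%s_traits_resid.tsv", d))
}
cat("wrote INT-transformed and covariate-residualized trait matrices\n")
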