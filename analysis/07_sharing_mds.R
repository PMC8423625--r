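#!/usr/bin/env Rscript
# eQTL sharing between datasets (same sign, within twofold) from the
# harmonized effect matrix, plus the non-metric MDS embeddings of both the
# effect-sharing distances and the median expression profiles.

library(qtlcompendium)

eff <- read.table("results/effect_matrix.tsv", header = TRUE, sep = "\t",
                  check.names = FALSE)
beta <- as.matrix(eff[, -1])
rownames(beta) <- eff$signal_id
truthless_missing <- beta == 0          # zeros came from the substitution
em <- list(beta = beta, missing = truthless_missing)

sm <- sharing_matrix(em)
write.table(data.frame(dataset = rownames(sm$values), sm$values,
                       check.names = FALSE),
            "results/sharing_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("pairwise eQTL sharing:\n")
print(round(sm$values, 2))

D <- 1 - sm$values
mds <- nonmetric_mds(D)
coords <- data.frame(dataset = rownames(mds$points),
                     dim1 = mds$points[, 1], dim2 = mds$points[, 2],
                     stress = mds$stress)
write.table(coords, "results/mds_effect_sharing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("effect-sharing MDS stress: %.4f (%d iterations)\n",
            mds$stress, length(mds$stress_trace)))

## expression-profile MDS (Pearson distance on median profiles) --------------
tpm_like <- lapply(c("lcl_a", "lcl_b", "tcell_a", "tcell_b"), function(d)
  2^read_trait_matrix(sprintf("results/sim/%s_traits.tsv", d)))  # positive scale
names(tpm_like) <- c("lcl_a", "lcl_b", "tcell_a", "tcell_b")
prof <- median_expression_profile(tpm_like, median_cut = 0)
De <- correlation_distance(prof, "pearson")
mde <- nonmetric_mds(De)
cat(sprintf("expression-profile MDS stress: %.4f\n", mde$stress))
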