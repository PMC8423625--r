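# Synthetic-study evaluations of the pipeline. Each function regenerates its
# inputs from scratch under the stated study conditions and measures how well
# the corresponding stage recovers the planted truth. Defaults are the
# conditions used throughout the package's validation.

#' Colocalization mode-recovery rates on simulated region pairs
#'
#' For each replicate a pair of cohorts is simulated in one of the three
#' causal configurations and [coloc_abf()] is run on the resulting summary
#' statistics; the rate of confident, correct calls is reported (shared:
#' PP4 > 0.8, distinct: PP3 > 0.8, null: PP0 > 0.9).
#'
#' @param mode `"shared"`, `"distinct"` or `"null"`.
#' @param n_rep Number of replicates.
#' @param n_variants,n,h2,ld_rho Region size, per-cohort sample size,
#'   causal-variant variance explained, and LD of the simulated region.
#' @param seed Integer seed.
#' @return List: `rate`, `pp` (the per-replicate posterior of interest),
#'   `n_rep`.
#' @export
coloc_mode_recovery <- function(mode, n_rep = 50, n_variants = 200, n = 500,
                                h2 = 0.05, ld_rho = 0.9, seed = 1L) {
  pp <- vapply(seq_len(n_rep), function(i) {
    p <- simulate_coloc_pair(mode, n_variants = n_variants, n1 = n, n2 = n,
                             ld_rho = ld_rho, h2_1 = h2, h2_2 = h2,
                             seed = split_seed(seed, 20000L + i))
    cc <- coloc_abf(p$stats1, p$stats2)
    switch(mode, shared = cc$pp[["PP4"]], distinct = cc$pp[["PP3"]],
           null = cc$pp[["PP0"]])
  }, 0)
  cut <- if (mode == "null") 0.9 else 0.8
  list(rate = mean(pp > cut), pp = pp, n_rep = n_rep)
}

#' Coverage of the 95% credible set over planted causal variants
#'
#' Single-causal simulations: the causal variant explains `h2` of the trait
#' variance in an LD-structured region; the replicate counts as covered when
#' the 95% credible set from [finemap_region()] contains it.
#'
#' @param n_rep Replicates.
#' @param n,n_variants,h2,ld_rho Study conditions.
#' @param seed Integer seed.
#' @return List: `coverage`, `mean_cs_size`, `n_rep`.
#' @export
finemap_coverage_rate <- function(n_rep = 200, n = 500, n_variants = 200,
                                  h2 = 0.05, ld_rho = 0.9, seed = 1L) {
  sizes <- integer(n_rep)
  hit <- vapply(seq_len(n_rep), function(i) {
    g <- simulate_genotypes(n, n_variants, 0.3, ld_rho,
                            split_seed(seed, 30000L + i))
    causal <- n_variants %/% 2L
    b <- sqrt(h2 / (1 - h2)) / stats::sd(g[, causal])
    set.seed(split_seed(seed, 40000L + i))
    y <- b * g[, causal] + stats::rnorm(n)
    cs <- finemap_region(y, g)
    sizes[i] <<- cs$size
    colnames(g)[causal] %in% cs$members$variant_id
  }, TRUE)
  list(coverage = mean(hit), mean_cs_size = mean(sizes), n_rep = n_rep)
}

#' Null calibration of group-best permutation p-values
#'
#' Simulates genes with no genetic effect and checks that the empirical
#' p-values are uniform: a Kolmogorov-Smirnov test against U(0, 1) and the
#' fraction below 0.05.
#'
#' @param n_genes Null genes simulated.
#' @param n,n_variants,n_perm Study conditions.
#' @param seed Integer seed.
#' @return List: `ks_p`, `frac_below_05`, `empirical_p`.
#' @export
permutation_null_calibration <- function(n_genes = 1000, n = 200,
                                         n_variants = 50, n_perm = 200,
                                         seed = 1L) {
  emp <- vapply(seq_len(n_genes), function(i) {
    g <- simulate_genotypes(n, n_variants, 0.3, 0.5,
                            split_seed(seed, 50000L + i))
    set.seed(split_seed(seed, 60000L + i))
    y <- stats::rnorm(n)
    permutation_group_best(y, g, n_perm = n_perm,
                           seed = split_seed(seed, 70000L + i))$empirical_p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(emp, "punif"))
  list(ks_p = ks$p.value, frac_below_05 = mean(emp < 0.05), empirical_p = emp)
}

#' Recovery of planted within-group effect sharing
#'
#' Simulates a lead-variant effect matrix with a known within-group sharing
#' fraction over dataset pairs (groups of two, so the pairwise estimator is
#' unbiased for f) and reports the mean within-group entry of the estimated
#' [sharing_matrix()].
#'
#' @param f Planted shared fraction in [0, 1].
#' @param n_signals Signals simulated.
#' @param se_scale Observation noise (0 reproduces f = 1 exactly).
#' @param seed Integer seed.
#' @return List: `estimate`, `error` (estimate - f), `f`.
#' @export
sharing_recovery <- function(f, n_signals = 2000, se_scale = 0.01, seed = 1L) {
  ga <- stats::setNames(rep(c("g1", "g2"), each = 2), paste0("ds", 1:4))
  em <- simulate_effect_matrix(n_signals, ga, f, effect_size_sd = 1,
                               se_scale = se_scale,
                               seed = split_seed(seed, 80000L))
  sm <- sharing_matrix(as_effect_matrix(em$observed_beta, em$observed_se))
  est <- mean(c(sm$values["ds1", "ds2"], sm$values["ds3", "ds4"]))
  list(estimate = est, error = est - f, f = f)
}

#' MDS separation of dataset groups from eQTL-sharing distances
#'
#' Simulates datasets in groups with high within-group sharing, embeds
#' `1 - sharing` with [nonmetric_mds()] and measures the embedding quality:
#' final stress, monotonicity of the stress trace and the silhouette of the
#' true group labels on the 2-D coordinates.
#'
#' @param n_datasets,n_groups Dataset panel layout.
#' @param f Within-group shared fraction.
#' @param n_signals Simulated signals.
#' @param seed Integer seed.
#' @return List: `stress`, `stress_monotone`, `silhouette`, `embedding`.
#' @export
mds_group_separation <- function(n_datasets = 12, n_groups = 3, f = 0.8,
                                 n_signals = 2000, seed = 1L) {
  stopifnot(n_datasets %% n_groups == 0)
  ga <- stats::setNames(rep(LETTERS[seq_len(n_groups)],
                            each = n_datasets / n_groups),
                        sprintf("ds%d", seq_len(n_datasets)))
  em <- simulate_effect_matrix(n_signals, ga, f, se_scale = 0.01,
                               seed = split_seed(seed, 90000L))
  sm <- sharing_matrix(as_effect_matrix(em$observed_beta))
  emb <- nonmetric_mds(1 - sm$values)
  sil <- NA_real_
  if (requireNamespace("cluster", quietly = TRUE)) {
    s <- cluster::silhouette(as.integer(factor(ga)),
                             stats::dist(emb$points))
    sil <- mean(s[, 3])
  }
  list(stress = emb$stress,
       stress_monotone = all(diff(emb$stress_trace) <= 0),
       silhouette = sil, embedding = emb, groups = ga)
}

#' Accuracy of superpopulation assignment on well-separated clusters
#'
#' @param n_test Test samples per population.
#' @param separation Distance between population centers in PC space. The
#'   default (20 cluster standard deviations) is the well-separated regime
#'   where every call is expected to be correct; at separation 10 occasional
#'   samples fall inside the 1.7x ratio margin and are left unassigned.
#' @param spread Within-cluster standard deviation.
#' @param seed Integer seed.
#' @return List: `accuracy` (fraction of correct, non-missing calls over all
#'   test samples), `n_unassigned`.
#' @export
superpopulation_accuracy <- function(n_test = 250, separation = 20,
                                     spread = 1, seed = 1L) {
  centers <- rbind(EUR = c(separation, 0, 0), AFR = c(0, separation, 0),
                   EAS = c(0, 0, separation),
                   SAS = rep(separation / sqrt(3), 3))
  panel <- simulate_reference_panel(centers, spread = spread, n_per_pop = 100,
                                    seed = split_seed(seed, 91000L))
  test <- simulate_reference_panel(centers, spread = spread,
                                   n_per_pop = n_test,
                                   seed = split_seed(seed, 92000L))
  calls <- assign_superpopulation(as.matrix(test[, c("PC1", "PC2", "PC3")]),
                                  panel)
  list(accuracy = mean(!is.na(calls$assigned) &
                         calls$assigned == test$population),
       n_unassigned = sum(is.na(calls$assigned)))
}
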