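test_that("Hardy-Weinberg chi-square test matches hand-derived cases", {
  # exact HWE proportions: chi-square 0
  expect_equal(hardy_weinberg_test(c(25, 50, 25)), 1)
  # total heterozygote deficit: chi-square = n = 100
  p <- hardy_weinberg_test(c(50, 0, 50))
  expect_equal(p, pchisq(100, 1, lower.tail = FALSE))
  expect_lt(p, 1e-20)
  # monomorphic convention
  expect_equal(hardy_weinberg_test(c(100, 0, 0)), 1)
  expect_error(hardy_weinberg_test(c(0, 0, 0)), "positive")
})

test_that("variant filters use strict inequalities and record reasons", {
  pre <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                    n_AA = c(25, 25, 50, 25), n_Aa = c(50, 50, 0, 50),
                    n_aa = c(25, 25, 50, 25),
                    missing_fraction = c(0.05, 0.06, 0, 0),
                    maf = c(0.3, 0.3, 0.5, 0.005))
  res <- filter_variants(pre, "pre_imputation")
  expect_true(res$retained[1])                      # boundary 0.05 retained
  expect_equal(res$reason[2], "missingness")
  expect_equal(res$reason[3], "hwe")
  expect_equal(res$reason[4], "maf")
  # retained + removed partition the input; reasons exhaustive for removed
  expect_setequal(res$variant_id, pre$variant_id)
  expect_true(all(is.na(res$reason) == res$retained))

  post <- data.frame(variant_id = c("w1", "w2", "w3"),
                     maf = c(0.005, 0.3, 0.3),
                     imputation_r2 = c(0.9, 0.4, 0.39))
  resp <- filter_variants(post, "post_imputation")
  expect_equal(resp$reason[1], "maf")
  expect_true(resp$retained[2])                     # R2 = 0.4 exactly retained
  expect_equal(resp$reason[3], "r2")

  # idempotence: filtering the retained variants removes nothing further
  kept <- pre[res$retained, , drop = FALSE]
  expect_true(all(filter_variants(kept, "pre_imputation")$retained))
  expect_error(filter_variants(pre[, -4], "pre_imputation"), "columns")
  expect_error(filter_variants(pre, "post_imputation"), "imputation_r2")
})

test_that("LD pruning drops duplicates, keeps independents, matches oracle", {
  g <- fix_genotypes(n = 200, m = 6, seed = 21)
  dup <- cbind(g, g[, 1])
  colnames(dup) <- c(colnames(g), "1_99000_A_G")
  kept <- ld_prune(dup, window_variants = 50, step = 10, r2_threshold = 0.05)
  expect_true(colnames(g)[1] %in% kept)            # earlier copy retained
  expect_false("1_99000_A_G" %in% kept)

  # independent variants all survive
  g0 <- simulate_genotypes(2000, 8, 0.4, 0, seed = 22)
  expect_equal(ld_prune(g0, 50, 10, 0.05),
               colnames(g0))

  # random LD panels equal the single-window greedy oracle
  for (s in 1:5) {
    gr <- simulate_genotypes(150, 10, 0.3, 0.8, seed = 30 + s)
    expect_equal(ld_prune(gr, window_variants = 10, step = 10,
                          r2_threshold = 0.2),
                 oracle_ld_prune(gr, 0.2), info = paste("seed", 30 + s))
  }

  # no surviving pair within a window exceeds the threshold
  gr <- simulate_genotypes(300, 40, 0.3, 0.9, seed = 41)
  kept <- ld_prune(gr, window_variants = 40, step = 40, r2_threshold = 0.1)
  r2 <- suppressWarnings(cor(gr[, kept]))^2
  expect_lt(max(r2[upper.tri(r2)]), 0.1 + 1e-12)
})

test_that("PCA wrapper is deterministic and reconstructs its input", {
  # collinear 2-D data: one component carries all variance
  x <- cbind(1:20, 2 * (1:20))
  p <- compute_pcs(x, k = 1, scale = FALSE)
  expect_equal(p$var_explained[1], 1)

  # variance-explained spectrum invariant under orthogonal rotation
  set.seed(1)
  y <- matrix(rnorm(100), 20, 5)
  th <- qr.Q(qr(matrix(rnorm(25), 5)))
  expect_equal(compute_pcs(y, 5, scale = FALSE)$var_explained,
               compute_pcs(y %*% th, 5, scale = FALSE)$var_explained,
               tolerance = 1e-10)

  # full-rank reconstruction
  p5 <- compute_pcs(y, 5, scale = FALSE)
  rec <- p5$scores %*% t(p5$loadings)
  rec <- sweep(rec, 2, p5$center, "+")
  expect_lt(max(abs(rec - y)), 1e-10)

  expect_error(compute_pcs(y, 6), "k exceeds")
  expect_warning(compute_pcs(cbind(y, 0), 2), "constant")
})

test_that("superpopulation assignment applies the 1.7x distance-ratio rule", {
  # single-member reference clusters give exact distances
  panel <- data.frame(sample_id = c("e", "a"), population = c("EUR", "AFR"),
                      PC1 = c(0, 0), PC2 = c(0, 0), PC3 = c(1, 2))
  # sample at PC3 = 0: distances 1 and 2, ratio 2 >= 1.7 -> EUR
  r <- assign_superpopulation(matrix(c(0, 0, 0), 1), panel)
  expect_equal(r$assigned, "EUR")
  expect_equal(r$ratio, 2)
  # distances 1 and 1.5: ratio < 1.7 -> NA
  panel2 <- transform(panel, PC3 = c(1, 1.5))
  expect_true(is.na(assign_superpopulation(matrix(c(0, 0, 0), 1), panel2)$assigned))
  # ratio exactly 1.7 assigns (inclusive rule); 1.699 does not
  panel3 <- transform(panel, PC3 = c(1, 1.7))
  expect_equal(assign_superpopulation(matrix(c(0, 0, 0), 1), panel3)$assigned,
               "EUR")
  panel4 <- transform(panel, PC3 = c(1, 1.699))
  expect_true(is.na(assign_superpopulation(matrix(c(0, 0, 0), 1), panel4)$assigned))
  # single population: unconditional assignment, infinite ratio
  r1 <- assign_superpopulation(matrix(c(5, 5, 5), 1), panel[1, ])
  expect_equal(r1$assigned, "EUR")
  expect_equal(r1$ratio, Inf)
  expect_error(assign_superpopulation(matrix(0, 1, 3), panel[0, ]), "empty")
})

test_that("well-separated clusters are assigned correctly at scale", {
  centers <- rbind(EUR = c(10, 0, 0), AFR = c(0, 10, 0), EAS = c(0, 0, 10))
  panel <- simulate_reference_panel(centers, spread = 1, n_per_pop = 50,
                                    seed = 9)
  test_pts <- simulate_reference_panel(centers, spread = 1, n_per_pop = 100,
                                       seed = 10)
  calls <- assign_superpopulation(as.matrix(test_pts[, 3:5]), panel)
  expect_gte(mean(calls$assigned == test_pts$population, na.rm = TRUE), 0.99)
})
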