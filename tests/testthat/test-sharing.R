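test_that("pairwise sharing applies the sign and twofold rules", {
  expect_true(pair_shared(0.5, 0.3))         # ratio 1.67
  expect_false(pair_shared(0.5, 0.2))        # ratio 2.5
  expect_false(pair_shared(0.5, -0.5))       # opposite signs
  expect_true(pair_shared(0.4, 0.2))         # ratio exactly 2, inclusive
  expect_false(pair_shared(0, 0.4))          # zeros never shared
  expect_false(pair_shared(0, 0))
  expect_equal(pair_shared(c(1, 1), c(0.9, -0.9)), c(TRUE, FALSE))
  expect_error(pair_shared(NA, 1), "finite")
})

test_that("sharing matrix matches a direct per-pair count oracle", {
  set.seed(9)
  beta <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  miss <- matrix(runif(600) < 0.2, 200, 3)
  beta[miss] <- NA
  em <- as_effect_matrix(beta)
  sm <- sharing_matrix(em)
  # oracle: loop over pairs, count shared / eligible with zero substitution
  for (i in 1:2) for (j in (i + 1):3) {
    elig <- !(miss[, i] & miss[, j])
    b1 <- ifelse(miss[, i], 0, beta[, i])[elig]
    b2 <- ifelse(miss[, j], 0, beta[, j])[elig]
    shared <- sign(b1) == sign(b2) & b1 != 0 & b2 != 0 &
      pmax(abs(b1), abs(b2)) / pmin(abs(b1), abs(b2)) <= 2
    expect_equal(sm$values[i, j], mean(shared))
  }
  # symmetry, unit diagonal, [0, 1] range
  expect_equal(sm$values, t(sm$values))
  expect_equal(unname(diag(sm$values)), rep(1, 3))
  expect_true(all(sm$values >= 0 & sm$values <= 1))
  # "both" policy restricts the denominator
  smb <- sharing_matrix(em, policy = "both")
  expect_lte(sm$values["a", "b"], smb$values["a", "b"] + 1e-12)
})

test_that("identical effect columns share completely", {
  b <- matrix(rep(rnorm(50), 2), 50, 2, dimnames = list(NULL, c("x", "y")))
  b[b == 0] <- 0.1
  sm <- sharing_matrix(as_effect_matrix(b))
  expect_equal(sm$values["x", "y"], 1)
  expect_error(sharing_matrix(as_effect_matrix(b[, 1, drop = FALSE])),
               "two datasets")
})

test_that("planted within-group sharing is recovered across f values", {
  ga <- setNames(rep(c("g1", "g2"), each = 2), paste0("ds", 1:4))
  for (f in c(0.2, 0.8)) {
    em <- simulate_effect_matrix(2000, ga, f, se_scale = 0.01,
                                 seed = 100 + round(10 * f))
    sm <- sharing_matrix(as_effect_matrix(em$observed_beta, em$observed_se))
    expect_lt(abs(sm$values["ds1", "ds2"] - f), 0.05)
    expect_lt(abs(sm$values["ds3", "ds4"] - f), 0.05)
    # no sharing across groups by construction
    expect_equal(sm$values["ds1", "ds3"], 0)
  }
})

test_that("correlation distances agree with direct computation", {
  set.seed(10)
  prof <- matrix(rnorm(3 * 50), 3, 50,
                 dimnames = list(c("a", "b", "c"), NULL))
  for (meth in c("pearson", "spearman")) {
    D <- correlation_distance(prof, meth)
    direct <- 1 - cor(t(prof), method = meth)
    diag(direct) <- 0
    expect_equal(D, direct, tolerance = 1e-12)
  }
  # identical and anti-correlated profiles hit the bounds
  p2 <- rbind(u = prof[1, ], v = prof[1, ], w = -prof[1, ])
  D2 <- correlation_distance(p2)
  expect_equal(D2["u", "v"], 0)
  expect_equal(D2["u", "w"], 2)
  expect_error(correlation_distance(rbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance")
})

test_that("non-metric MDS embeds exact configurations at ~zero stress", {
  # equilateral triangle is exactly embeddable in 2-D
  D <- matrix(1, 3, 3) - diag(3)
  m <- nonmetric_mds(D)
  expect_lt(m$stress, 1e-3)
  d <- as.vector(dist(m$points))
  expect_lt(max(d) / min(d), 1.01)
  # all-zero dissimilarities: zero embedding by convention
  m0 <- nonmetric_mds(matrix(0, 4, 4))
  expect_equal(m0$points, matrix(0, 4, 2))
  expect_equal(m0$stress, 0)
  expect_error(nonmetric_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("stress is non-increasing and invariant to monotone transforms", {
  set.seed(11)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  m <- nonmetric_mds(D)
  expect_true(all(diff(m$stress_trace) <= 0))
  expect_gte(m$stress, 0)
  expect_lte(m$stress, 1)
  # strictly monotone transform of D: same rank order of embedded distances
  m2 <- nonmetric_mds(sqrt(D))
  r1 <- rank(as.vector(dist(m$points)))
  r2 <- rank(as.vector(dist(m2$points)))
  expect_gt(cor(r1, r2, method = "spearman"), 0.95)
  expect_lt(abs(m$stress - m2$stress), 1e-2)
})

test_that("NMDS stress is comparable to the MASS reference implementation", {
  set.seed(12)
  X <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(X)) + 0.05
  diag(D) <- 0
  ours <- nonmetric_mds(D)
  ref <- MASS::isoMDS(stats::as.dist(D), k = 2, trace = FALSE)
  # MASS reports stress in percent
  expect_lt(ours$stress, ref$stress / 100 + 0.02)
})

test_that("grouped effect structure embeds into separable clusters", {
  ga <- setNames(rep(c("A", "B", "C"), each = 4), paste0("ds", 1:12))
  em <- simulate_effect_matrix(1000, ga, 0.8, se_scale = 0.01, seed = 13)
  sm <- sharing_matrix(as_effect_matrix(em$observed_beta))
  m <- nonmetric_mds(1 - sm$values)
  expect_lt(m$stress, 0.1)
  sil <- cluster::silhouette(as.integer(factor(ga)), dist(m$points))
  expect_gt(mean(sil[, 3]), 0.5)
})
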