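make_stats <- function(beta, se, pos = seq_along(beta) * 1000, chrom = "1",
                       ref = "A", alt = "G", maf = 0.3) {
  data.frame(variant = sprintf("%s_%d_%s_%s", chrom, pos, ref, alt),
             chromosome = chrom, position = pos, ref = ref, alt = alt,
             beta = beta, se = se, maf = maf, n = 500,
             stringsAsFactors = FALSE)
}

test_that("coloc posteriors match closed-form prior arithmetic with no signal", {
  # 100 variants with ABF = 1 each: the five hypothesis weights are
  # 1, 100 p1, 100 p2, 9900 p1 p2, 100 p12
  s <- make_stats(rep(0, 100), rep(1e8, 100))
  cc <- coloc_abf(s, s)
  denom <- 1 + 0.01 + 0.01 + 9900 * 1e-8 + 1e-3
  expect_equal(unname(cc$pp["PP0"]), 1 / denom, tolerance = 1e-6)
  expect_equal(unname(cc$pp["PP1"]), 0.01 / denom, tolerance = 1e-6)
  expect_equal(unname(cc$pp["PP4"]), 1e-3 / denom, tolerance = 1e-6)
  expect_equal(sum(cc$pp), 1, tolerance = 1e-9)
})

test_that("coloc matches the brute-force enumeration oracle", {
  set.seed(14)
  for (i in 1:100) {
    nv <- sample(2:10, 1)
    s1 <- make_stats(rnorm(nv, sd = 0.3), runif(nv, 0.05, 0.2),
                     pos = sort(sample(1:10000, nv)))
    s2 <- make_stats(rnorm(nv, sd = 0.3), runif(nv, 0.05, 0.2),
                     pos = s1$position)
    cc <- coloc_abf(s1, s2)
    l1 <- wakefield_log_abf(s1$beta, s1$se, 0.15)
    l2 <- wakefield_log_abf(s2$beta, s2$se, 0.15)
    expect_lt(max(abs(cc$pp - oracle_coloc_pp(l1, l2))), 1e-10)
  }
})

test_that("a strong shared variant and log-space scaling behave correctly", {
  # single shared variant with z = 8 in both traits
  s1 <- make_stats(0.8, 0.1)
  s2 <- make_stats(0.8, 0.1)
  cc <- coloc_abf(s1, s2)
  expect_gt(cc$pp["PP4"], 0.99)
  # scaling every ABF by e^100 leaves posteriors unchanged: with 5 variants,
  # add a huge common z through tiny ses and compare against the oracle
  z <- c(8, 1, 0.5, -0.3, 2)
  sA <- make_stats(z * 0.05, rep(0.05, 5))
  sB <- make_stats(z * 0.05, rep(0.05, 5))
  cc2 <- coloc_abf(sA, sB)
  l1 <- wakefield_log_abf(sA$beta, sA$se, 0.15)
  pp_direct <- oracle_coloc_pp(l1, l1)
  pp_scaled <- oracle_coloc_pp(l1 + 100, l1 + 100)
  expect_lt(max(abs(pp_direct - pp_scaled)), 1e-10)
  expect_lt(max(abs(cc2$pp - pp_direct)), 1e-10)
})

test_that("allele harmonization flips swapped alleles and drops mismatches", {
  s1 <- make_stats(c(0.5, 0.2, 0.1), rep(0.1, 3))
  s2 <- s1
  # swap ref/alt of the first variant: beta must be flipped back
  s2$ref[1] <- "G"; s2$alt[1] <- "A"; s2$beta[1] <- -0.5
  cc <- coloc_abf(s1, s2)
  expect_equal(cc$n_overlapping_variants, 3)
  expect_gt(cc$pp["PP4"], 0.5)   # flipped effects agree at the lead
  # incompatible alleles are dropped with a warning
  s3 <- s1; s3$ref[2] <- "T"; s3$alt[2] <- "C"
  expect_warning(cc3 <- coloc_abf(s1, s3), "mismatch")
  expect_equal(cc3$n_overlapping_variants, 2)
  # palindromic A/T variant at high MAF is dropped
  s4 <- s1; s4$alt[3] <- "T"; s4$maf[3] <- 0.45
  s5 <- s4
  expect_warning(cc4 <- coloc_abf(s4, s5), "palindromic")
  expect_equal(cc4$n_overlapping_variants, 2)
  # no shared variants at all
  s6 <- make_stats(0.1, 0.1, pos = 99999)
  expect_error(coloc_abf(s1, s6), "no shared variants")
})

test_that("simulated coloc modes are recovered at moderate effect sizes", {
  rates <- vapply(c("shared", "distinct", "null"), function(m) {
    mean(vapply(1:15, function(i) {
      p <- simulate_coloc_pair(m, n_variants = 150, n1 = 800, n2 = 800,
                               h2_1 = 0.08, h2_2 = 0.08, seed = 400 + i)
      cc <- coloc_abf(p$stats1, p$stats2)
      switch(m, shared = cc$pp["PP4"] > 0.8,
             distinct = cc$pp["PP3"] > 0.8,
             null = cc$pp["PP0"] > 0.9)
    }, TRUE))
  }, 0)
  expect_gte(rates["shared"], 0.8)
  expect_gte(rates["distinct"], 0.8)
  expect_gte(rates["null"], 0.9)
})

test_that("region extraction is inclusive at the window bounds", {
  s <- make_stats(rep(0.1, 5), rep(0.1, 5),
                  pos = c(800000, 999999, 1000000, 1200000, 1200001))
  sl <- extract_region(s, "1_1000000_A_G", window = 200000)
  expect_setequal(sl$position, c(800000, 999999, 1000000, 1200000))
  expect_equal(nrow(extract_region(s, "1_1000000_A_G", window = 0)), 1)
  expect_error(extract_region(s, "1_77_A_G"), "absent")
})

test_that("LD-block assignment uses the lead position, 0-based half-open", {
  blocks <- data.frame(block_id = c("b1", "b2"), chrom = "1",
                       start = c(0, 1e6), end = c(1e6, 2e6))
  # lead inside the second block even if the window spans both
  expect_equal(assign_ld_block("1", 1500000, blocks), "b2")
  # 1-based position 1,000,000 is 0-based 999,999 -> first block
  expect_equal(assign_ld_block("1", 1000000, blocks), "b1")
  expect_equal(assign_ld_block("1", 1000001, blocks), "b2")
  expect_true(is.na(assign_ld_block("1", 5e6, blocks)))
  expect_true(is.na(assign_ld_block("2", 5e5, blocks)))
})

test_that("block summaries apply PP4, sample-size and novelty rules", {
  res <- data.frame(
    block_id = c("b1", "b1", "b2", "b3", "b3"),
    gwas_id = "height",
    dataset_id = c("gtex_liver", "blueprint_tcell", "small_ds", "new_ds", "gtex_lung"),
    trait_id = paste0("g", 1:5), method = "gene",
    pp4 = c(0.85, 0.9, 0.95, 0.8, 0.79))
  n <- c(gtex_liver = 500, blueprint_tcell = 169, small_ds = 149,
         new_ds = 200, gtex_lung = 300)
  summ <- summarize_blocks(res, reference_datasets = c("gtex_liver", "gtex_lung"),
                           dataset_n = n)
  s <- setNames(summ$novel, summ$block_id)
  expect_false(s[["b1"]])          # reference dataset colocalizes there
  expect_true(s[["b3"]])           # only the new dataset (PP4 = 0.8, inclusive)
  expect_false("b2" %in% summ$block_id)  # n = 149 dataset excluded
  # PP4 = 0.79 row contributed nothing
  expect_equal(summ$n_results[summ$block_id == "b3"], 1)
})

test_that("novelty score is additional colocalizations per sample", {
  expect_equal(round(novelty_score(18, 169), 4), 0.1065)
  expect_equal(novelty_score(0, 100), 0)
  expect_equal(novelty_score(10, 100), 0.1)
  expect_error(novelty_score(5, 0), "positive")
})

test_that("method overlap counts stratify blocks by detection subset", {
  det <- data.frame(
    block_id = c("b1", "b2", "b2", "b3", "b4", "b4"),
    method = c("gene", "exon", "txrevise", "tx", "gene", "exon"))
  mo <- method_overlap_counts(det)
  expect_equal(unname(mo$counts["gene"]), 1L)
  expect_equal(unname(mo$counts["exon,txrevise"]), 1L)
  expect_equal(mo$transcript_level_only, 2L)  # b2 and b3 lack gene support
  empty <- method_overlap_counts(det[0, ])
  expect_equal(empty$transcript_level_only, 0L)
})

test_that("planted transcript-only fraction is recovered over many blocks", {
  set.seed(15)
  n <- 200
  tx_only <- runif(n) < 0.2
  det <- do.call(rbind, lapply(seq_len(n), function(i) {
    meths <- if (tx_only[i]) sample(c("exon", "tx", "txrevise"), 2)
             else c("gene", sample(c("exon", "tx"), 1))
    data.frame(block_id = sprintf("b%03d", i), method = meths)
  }))
  mo <- method_overlap_counts(det)
  expect_lt(abs(mo$transcript_level_only / n - 0.2), 0.05)
})
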