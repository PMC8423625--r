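test_that("credible-set filter applies strict size and z thresholds", {
  sets <- fix_cs_table(list(
    big   = list(dataset = "d1", variants = "1_10_A_G", size = 30, z = 5),
    weak  = list(dataset = "d1", variants = "1_20_A_G", size = 10, z = 3),
    good  = list(dataset = "d1", variants = "1_30_A_G", size = 29, z = 3.01),
    multi = list(dataset = "d2", variants = "1_40_A_G", size = 5, z = 4,
                 genes = c("gA", "gB"))))
  out <- filter_and_split_credible_sets(sets)
  expect_false("big" %in% out$cs_id)     # size 30 removed (strict < 30)
  expect_false("weak" %in% out$cs_id)    # z = 3 removed (strict > 3)
  expect_true("good" %in% out$cs_id)
  expect_equal(sum(out$cs_id == "multi"), 2)  # one record per linked gene
  expect_error(filter_and_split_credible_sets(data.frame(x = 1)), "columns")
})

test_that("connected components join sets sharing variants, transitively", {
  sets <- fix_cs_table(list(
    s1 = list(dataset = "d1", variants = c("v1", "v2")),
    s2 = list(dataset = "d2", variants = c("v2", "v3")),
    s3 = list(dataset = "d3", variants = "v4")))
  cc <- connected_components(sets)
  comp <- setNames(cc$component, cc$cs_id)
  expect_equal(comp[["s1"]], comp[["s2"]])
  expect_false(comp[["s3"]] == comp[["s1"]])

  chain <- fix_cs_table(list(
    a = list(dataset = "d1", variants = c("v1", "v2")),
    b = list(dataset = "d2", variants = c("v2", "v3")),
    c = list(dataset = "d3", variants = c("v3", "v4"))))
  ccc <- connected_components(chain)
  expect_equal(length(unique(ccc$component)), 1)   # transitivity
})

test_that("connected components equal the transitive-closure oracle", {
  set.seed(7)
  for (rep in 1:30) {
    n_sets <- sample(3:20, 1)
    vsets <- lapply(seq_len(n_sets), function(i)
      sample(sprintf("v%d", 1:30), sample(1:6, 1)))
    names(vsets) <- sprintf("s%02d", seq_len(n_sets))
    tab <- fix_cs_table(lapply(seq_along(vsets), function(i)
      list(dataset = sprintf("d%02d", i), variants = vsets[[i]])) |>
        setNames(names(vsets)))
    cc <- connected_components(tab)
    got <- cc$component[match(names(vsets), cc$cs_id)]
    want <- oracle_components(vsets)
    # same partition: pairwise co-membership must agree
    expect_identical(outer(got, got, "=="), outer(want, want, "=="),
                     info = paste("instance", rep))
    # and the result is a partition covering every set
    expect_setequal(cc$cs_id, names(vsets))
  }
})

test_that("component labels are invariant to record order", {
  sets <- fix_cs_table(list(
    s1 = list(dataset = "d1", variants = c("v1", "v2")),
    s2 = list(dataset = "d2", variants = c("v2", "v3")),
    s3 = list(dataset = "d3", variants = "v9")))
  a <- connected_components(sets)
  b <- connected_components(sets[rev(seq_len(nrow(sets))), ])
  a <- a[order(a$cs_id), ]; b <- b[order(b$cs_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("lead selection maximizes dataset support, then |beta|", {
  recs <- fix_cs_table(list(
    s1 = list(dataset = "d1", variants = c("1_100_A_G", "1_200_A_G")),
    s2 = list(dataset = "d2", variants = c("1_200_A_G", "1_300_A_G"))))
  lookup <- data.frame(
    dataset_id = c("d1", "d2", "d1"),
    variant = c("1_200_A_G", "1_200_A_G", "1_100_A_G"),
    beta = c(0.2, -0.9, 5), se = 0.1)
  # v200 is in both datasets' sets; v100's huge effect is ignored
  lead <- select_lead_variant(recs, lookup)
  expect_equal(lead$lead_variant, "1_200_A_G")
  expect_equal(unname(lead$support["1_200_A_G"]), 2)
  # among equal-support variants the largest |beta| wins
  recs2 <- fix_cs_table(list(
    s1 = list(dataset = "d1", variants = c("1_100_A_G", "1_200_A_G"))))
  lookup2 <- data.frame(dataset_id = "d1",
                        variant = c("1_100_A_G", "1_200_A_G"),
                        beta = c(0.5, -0.8), se = 0.1)
  expect_equal(select_lead_variant(recs2, lookup2)$lead_variant, "1_200_A_G")
  # exact tie on support and |beta|: smaller position
  lookup3 <- transform(lookup2, beta = c(0.8, -0.8))
  expect_equal(select_lead_variant(recs2, lookup3)$lead_variant, "1_100_A_G")
  # no measured effect anywhere: dropped with a reason
  dropped <- select_lead_variant(recs2,
                                 data.frame(dataset_id = "d9", variant = "zz",
                                            beta = 1, se = 1))
  expect_true(dropped$dropped)
  expect_equal(attr(dropped, "drop_reason"), "no_measured_effect")
})

test_that("lead selection is invariant to input record order", {
  recs <- fix_cs_table(list(
    s1 = list(dataset = "d1", variants = c("1_100_A_G", "1_200_A_G", "1_300_A_G")),
    s2 = list(dataset = "d2", variants = c("1_200_A_G", "1_300_A_G"))))
  lookup <- data.frame(dataset_id = rep(c("d1", "d2"), each = 3),
                       variant = rep(c("1_100_A_G", "1_200_A_G", "1_300_A_G"), 2),
                       beta = c(1, 0.4, 0.4, 0.3, 0.4, 0.4), se = 0.1)
  l1 <- select_lead_variant(recs, lookup)
  l2 <- select_lead_variant(recs[sample(nrow(recs)), ], lookup)
  expect_equal(l1$lead_variant, l2$lead_variant)
})

test_that("harmonization yields one signal per filtered set for one dataset", {
  sets <- fix_cs_table(list(
    s1 = list(dataset = "d1", variants = c("1_100_A_G", "1_200_A_G"), z = 5),
    s2 = list(dataset = "d1", variants = "1_900_A_G", z = 4)))
  lookup <- data.frame(dataset_id = "d1",
                       variant = c("1_100_A_G", "1_200_A_G", "1_900_A_G"),
                       beta = c(0.5, 0.2, 0.7), se = 0.1)
  h <- harmonize_signals(sets, lookup)
  expect_equal(nrow(h$signals), 2)
  expect_equal(h$n_dropped, 0L)
})

test_that("transcript-level selection picks smallest set, max PIP, then seed", {
  sets <- rbind(
    fix_cs_table(list(
      small = list(dataset = "d1", variants = c("1_10_A_G", "1_20_A_G", "1_30_A_G"),
                   size = 3, z = 5),
      big = list(dataset = "d1", variants = paste0("1_", 1:5 * 10, "_A_G"),
                 size = 5, z = 5))),
    fix_cs_table(list(
      tie1 = list(dataset = "d2", variants = c("1_10_A_G", "1_20_A_G"),
                  size = 2, pip = c(0.9, 0.05), z = 5),
      tie2 = list(dataset = "d2", variants = c("1_40_A_G", "1_50_A_G"),
                  size = 2, pip = c(0.4, 0.4), z = 5))))
  lookup <- data.frame(dataset_id = "d1",
                       variant = sprintf("1_%d_A_G", 1:5 * 10),
                       beta = c(0.1, 0.9, 0.2, 0.3, 0.2), se = 0.1)
  sel <- transcript_level_lead_selection(sets, lookup, seed = 1)
  expect_equal(nrow(sel), 1)
  # per dataset the smallest set wins; in d2 the higher max PIP breaks the tie
  expect_true(sel$cs_id %in% c("small", "tie1"))
  # deterministic under a fixed seed
  sel2 <- transcript_level_lead_selection(sets, lookup, seed = 1)
  expect_identical(sel, sel2)
})

test_that("effect matrix applies the zero/one substitution with a mask", {
  signals <- data.frame(signal_id = c("g:cc1", "g:cc2"), gene_id = "g",
                        component = c("cc1", "cc2"),
                        lead_variant = c("1_100_A_G", "1_200_A_G"))
  lookup <- data.frame(dataset_id = c("d1", "d2", "d1"),
                       variant = c("1_100_A_G", "1_100_A_G", "1_200_A_G"),
                       beta = c(0.5, 0.6, -0.2), se = c(0.1, 0.1, 0.2))
  em <- build_effect_matrix(signals, lookup, datasets = c("d1", "d2", "d3"))
  expect_equal(em$beta["g:cc1", ], c(d1 = 0.5, d2 = 0.6, d3 = 0))
  expect_equal(em$se["g:cc2", ], c(d1 = 0.2, d2 = 1, d3 = 1))
  expect_equal(unname(rowSums(em$missing)), c(1, 2))
  # fully measured signal has an all-false mask
  expect_false(any(em$missing["g:cc1", c("d1", "d2")]))
})

test_that("pleiotropy fraction counts multi-gene sets", {
  sets <- rbind(
    fix_cs_table(list(a = list(dataset = "d1", variants = "v1", size = 5, z = 4,
                               genes = c("gA", "gB")))),
    fix_cs_table(list(b = list(dataset = "d1", variants = "v2", size = 5, z = 4)),
                 gene_id = "gC"),
    fix_cs_table(list(c = list(dataset = "d2", variants = "v3", size = 5, z = 4)),
                 gene_id = "gD"))
  pf <- pleiotropy_fraction(sets)
  expect_equal(pf$fraction, 1 / 3)
  expect_equal(pf$n_multi_gene, 1L)
  expect_equal(pf$n_sets, 3L)
  expect_error(pleiotropy_fraction(sets[0, ]), "empty")
})

test_that("planted multi-gene rate is recovered from simulated set lists", {
  set.seed(8)
  n <- 1000
  multi <- runif(n) < 0.2
  sets <- do.call(rbind, lapply(seq_len(n), function(i)
    fix_cs_table(setNames(list(list(
      dataset = "d1", variants = sprintf("v%d", i), size = 5, z = 4,
      genes = if (multi[i]) c(sprintf("gA%d", i), sprintf("gB%d", i))
              else sprintf("gA%d", i))), sprintf("cs%d", i)))))
  pf <- pleiotropy_fraction(sets)
  expect_lt(abs(pf$fraction - mean(multi)), 1e-12)
  expect_lt(abs(pf$fraction - 0.2), 0.03)
})
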