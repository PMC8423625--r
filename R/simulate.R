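#' Derive a stream-specific RNG seed from a master seed
#'
#' All stochastic generators in the package draw their randomness from a
#' single integer master seed through this counter-based split, so any stage
#' of a simulated study can be regenerated independently of the others.
#'
#' @param seed Integer master seed.
#' @param counter Integer stream counter (one per operation / replicate).
#' @return A single integer below 2^31 suitable for [set.seed()].
#' @export
split_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(counter), length(counter) == 1L, is.finite(counter))
  as.integer((abs(as.double(seed)) * 48271 + abs(as.double(counter)) * 100003 + 1) %%
               2147483629)
}

#' Simulation configuration
#'
#' Bundles and validates the knobs of a simulated multi-dataset eQTL study:
#' how many datasets and samples, how many genes and cis variants per gene,
#' the minor-allele-frequency range, the strength of local LD, the effect and
#' noise scales, and the dataset-group structure used to plant cross-dataset
#' sharing.
#'
#' @param n_datasets Number of datasets (cell types / tissues / studies).
#' @param n_samples_per_dataset Samples per dataset (recycled if scalar).
#' @param n_genes Number of genes, each with its own cis region.
#' @param n_variants_per_region Variants in each gene's cis region.
#' @param maf_range Length-2 numeric in (0, 0.5], low <= high.
#' @param ld_rho Adjacent-variant haplotype correlation in [0, 1].
#' @param effect_size_sd Standard deviation of planted causal effects.
#' @param noise_sd Residual noise standard deviation of expression traits.
#' @param sharing_pattern Named character vector mapping dataset id to group
#'   label; effects are shared within groups (see
#'   [simulate_effect_matrix()]).
#' @param seed Integer master seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_datasets = 4, n_samples_per_dataset = 200,
                       n_genes = 50, n_variants_per_region = 30,
                       maf_range = c(0.05, 0.5), ld_rho = 0.9,
                       effect_size_sd = 1, noise_sd = 1,
                       sharing_pattern = NULL, seed = 1L) {
  counts <- c(n_datasets = n_datasets,
              n_samples_per_dataset = max(n_samples_per_dataset),
              n_genes = n_genes, n_variants_per_region = n_variants_per_region)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (!is.finite(ld_rho) || ld_rho < 0 || ld_rho > 1)
    stop("ld_rho must lie in [0, 1]")
  if (is.null(sharing_pattern)) {
    sharing_pattern <- stats::setNames(rep("g1", n_datasets),
                                       sprintf("ds%d", seq_len(n_datasets)))
  }
  if (length(sharing_pattern) != n_datasets)
    stop("sharing_pattern must name every dataset")
  structure(list(n_datasets = n_datasets,
                 n_samples_per_dataset = rep_len(n_samples_per_dataset, n_datasets),
                 n_genes = n_genes,
                 n_variants_per_region = n_variants_per_region,
                 maf_range = maf_range, ld_rho = ld_rho,
                 effect_size_sd = effect_size_sd, noise_sd = noise_sd,
                 sharing_pattern = sharing_pattern, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotype dosages with tunable local LD
#'
#' Haplotypes follow a first-order Markov copying process: the allele at
#' variant j copies the allele at variant j-1 with probability `ld_rho` and is
#' otherwise drawn fresh as Bernoulli(maf_j). When adjacent MAFs are equal the
#' adjacent-haplotype correlation equals `ld_rho` in expectation. Dosages are
#' the sum of two independent haplotypes, so values lie in {0, 1, 2}.
#'
#' @param n_samples Number of diploid samples.
#' @param n_variants Number of variants.
#' @param mafs Minor allele frequencies in (0, 0.5]; recycled to
#'   `n_variants`.
#' @param ld_rho Copying probability in [0, 1].
#' @param seed Integer seed; output is deterministic given it.
#' @param chrom Chromosome label used in variant ids.
#' @param pos Optional integer vector of 1-based positions (default: 1 kb
#'   grid).
#' @return An `n_samples x n_variants` integer matrix with variant ids
#'   (`chrom_pos_ref_alt`) as column names and attributes `chrom`, `pos`,
#'   `mafs`.
#' @export
simulate_genotypes <- function(n_samples, n_variants, mafs, ld_rho, seed,
                               chrom = "1", pos = NULL) {
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs > 0.5))
    stop("mafs must be finite and in (0, 0.5]")
  if (!is.finite(ld_rho) || ld_rho < 0 || ld_rho > 1)
    stop("ld_rho must lie in [0, 1]")
  stopifnot(n_samples >= 1, n_variants >= 1)
  mafs <- rep_len(mafs, n_variants)
  set.seed(split_seed(seed, 1L))
  n_hap <- 2L * n_samples
  fresh <- matrix(stats::runif(n_hap * n_variants) <
                    rep(mafs, each = n_hap), n_hap, n_variants)
  copy <- matrix(stats::runif(n_hap * n_variants) < ld_rho, n_hap, n_variants)
  hap <- matrix(FALSE, n_hap, n_variants)
  hap[, 1L] <- fresh[, 1L]
  if (n_variants > 1L) {
    for (j in 2:n_variants) {
      hap[, j] <- ifelse(copy[, j], hap[, j - 1L], fresh[, j])
    }
  }
  dos <- hap[seq_len(n_samples), , drop = FALSE] +
    hap[n_samples + seq_len(n_samples), , drop = FALSE]
  storage.mode(dos) <- "integer"
  if (is.null(pos)) pos <- 1000L * seq_len(n_variants)
  dimnames(dos) <- list(sprintf("sample_%d", seq_len(n_samples)),
                        sprintf("%s_%d_A_G", chrom, pos))
  attr(dos, "chrom") <- chrom
  attr(dos, "pos") <- as.integer(pos)
  attr(dos, "mafs") <- mafs
  dos
}

#' Simulate an expression dataset with planted cis effects
#'
#' Each trait is `beta * dosage(causal variant) + loadings %*% covariates +`
#' Gaussian noise. Genes with `beta = 0` (or `NA` causal variant) are null.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()] (samples x
#'   variants).
#' @param causal_map Data frame with columns `gene_id`, `variant_id`, `beta`;
#'   `variant_id` may be `NA` for null genes.
#' @param n_covariates Number of simulated latent covariates.
#' @param noise_sd Residual standard deviation.
#' @param covariate_sd Standard deviation of per-gene covariate loadings.
#' @param seed Integer seed.
#' @return List with `expression` (traits x samples), `covariates`
#'   (samples x k) and `truth` (the causal map).
#' @export
simulate_expression_dataset <- function(genotypes, causal_map, n_covariates = 0,
                                        noise_sd = 1, covariate_sd = 0.5,
                                        seed = 1L) {
  stopifnot(is.matrix(genotypes))
  v <- causal_map$variant_id
  bad <- !is.na(v) & !(v %in% colnames(genotypes))
  if (any(bad))
    stop("unknown variant id(s) in causal_map: ",
         paste(utils::head(v[bad], 3), collapse = ", "))
  set.seed(split_seed(seed, 2L))
  n <- nrow(genotypes)
  g <- nrow(causal_map)
  covariates <- matrix(stats::rnorm(n * n_covariates), n, n_covariates)
  expr <- matrix(stats::rnorm(g * n, sd = noise_sd), g, n)
  for (i in seq_len(g)) {
    if (!is.na(v[i]) && causal_map$beta[i] != 0)
      expr[i, ] <- expr[i, ] + causal_map$beta[i] * genotypes[, v[i]]
  }
  if (n_covariates > 0) {
    loadings <- matrix(stats::rnorm(g * n_covariates, sd = covariate_sd),
                       g, n_covariates)
    expr <- expr + loadings %*% t(covariates)
  }
  rownames(expr) <- causal_map$gene_id
  colnames(expr) <- rownames(genotypes)
  if (n_covariates > 0) {
    colnames(covariates) <- sprintf("cov%d", seq_len(n_covariates))
    rownames(covariates) <- rownames(genotypes)
  }
  list(expression = expr, covariates = covariates, truth = causal_map)
}

#' Simulate a lead-variant effect matrix with planted cross-dataset sharing
#'
#' Every signal is assigned to one dataset group. With probability
#' `within_group_shared_fraction` it is active with an identical effect size
#' in all group members ("shared"); otherwise it is private to one randomly
#' chosen member. Observed effects add Gaussian noise with standard deviation
#' `se_scale`; entries where a signal is inactive are explicit `NA`s (the
#' zero substitution of the downstream effect-matrix builder is deliberately
#' not applied here).
#'
#' @param n_signals Number of independent signals (rows).
#' @param group_assignment Named character vector: dataset id -> group label.
#' @param within_group_shared_fraction Probability f in [0, 1] of a signal
#'   being group-shared rather than dataset-private.
#' @param effect_size_sd SD of the planted effect sizes.
#' @param se_scale Observation noise SD (also reported as the standard
#'   error).
#' @param seed Integer seed.
#' @return List with matrices `true_beta`, `observed_beta`, `observed_se`
#'   (signals x datasets, `NA` where inactive) and a `truth` data frame
#'   (`signal_id`, `group`, `shared`, `private_dataset`, `beta`).
#' @export
simulate_effect_matrix <- function(n_signals, group_assignment,
                                   within_group_shared_fraction,
                                   effect_size_sd = 1, se_scale = 0.05,
                                   seed = 1L) {
  f <- within_group_shared_fraction
  if (!is.finite(f) || f < 0 || f > 1) stop("sharing fraction must be in [0, 1]")
  if (length(group_assignment) == 0 || is.null(names(group_assignment)) ||
      any(!nzchar(names(group_assignment))))
    stop("group_assignment must be a named vector (dataset -> group)")
  groups <- split(names(group_assignment), group_assignment)
  if (any(lengths(groups) == 0)) stop("empty groups are not allowed")
  datasets <- names(group_assignment)
  set.seed(split_seed(seed, 3L))
  signal_id <- sprintf("signal_%d", seq_len(n_signals))
  true_beta <- matrix(NA_real_, n_signals, length(datasets),
                      dimnames = list(signal_id, datasets))
  grp <- sample(names(groups), n_signals, replace = TRUE)
  shared <- stats::runif(n_signals) < f
  beta <- stats::rnorm(n_signals, sd = effect_size_sd)
  private_ds <- rep(NA_character_, n_signals)
  for (i in seq_len(n_signals)) {
    members <- groups[[grp[i]]]
    if (shared[i]) {
      true_beta[i, members] <- beta[i]
    } else {
      d <- if (length(members) == 1L) members else sample(members, 1L)
      private_ds[i] <- d
      true_beta[i, d] <- beta[i]
    }
  }
  noise <- matrix(stats::rnorm(length(true_beta), sd = se_scale),
                  n_signals, length(datasets))
  observed_beta <- true_beta + noise
  observed_beta[is.na(true_beta)] <- NA_real_
  observed_se <- matrix(se_scale, n_signals, length(datasets),
                        dimnames = dimnames(true_beta))
  observed_se[is.na(true_beta)] <- NA_real_
  list(true_beta = true_beta, observed_beta = observed_beta,
       observed_se = observed_se,
       truth = data.frame(signal_id = signal_id, group = grp, shared = shared,
                          private_dataset = private_ds, beta = beta,
                          stringsAsFactors = FALSE))
}

#' Per-variant marginal OLS scan (no covariates)
#'
#' Regresses a phenotype on each dosage column separately and returns
#' summary statistics in the long format used throughout the package.
#'
#' @param y Phenotype vector.
#' @param genotypes Dosage matrix (samples x variants) with
#'   `chrom_pos_ref_alt` column names.
#' @param dataset_id,trait_id Labels stored in the output.
#' @return Data frame with columns `dataset_id`, `molecular_trait_id`,
#'   `variant`, `chromosome`, `position`, `ref`, `alt`, `beta`, `se`,
#'   `pvalue`, `maf`, `n`. Zero-variance variants get `NA` effect estimates.
#' @export
marginal_scan <- function(y, genotypes, dataset_id = "ds1", trait_id = "trait") {
  stopifnot(is.matrix(genotypes), length(y) == nrow(genotypes))
  n <- length(y)
  yc <- y - mean(y)
  gc <- sweep(genotypes, 2, colMeans(genotypes))
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- sum(yc^2) - beta^2 * sxx
  df <- n - 2L
  sigma2 <- pmax(rss, 0) / df
  se <- ifelse(sxx > 0, sqrt(sigma2 / sxx), NA_real_)
  tstat <- beta / se
  pvalue <- 2 * stats::pt(-abs(tstat), df)
  af <- colMeans(genotypes) / 2
  meta <- parse_variant_id(colnames(genotypes))
  data.frame(dataset_id = dataset_id, molecular_trait_id = trait_id,
             variant = colnames(genotypes),
             chromosome = meta$chrom, position = meta$pos,
             ref = meta$ref, alt = meta$alt,
             beta = beta, se = se, pvalue = pvalue,
             maf = pmin(af, 1 - af), n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a pair of summary-statistic vectors for colocalization tests
#'
#' Generates two cohorts over the same variant grid and plants a causal
#' variant scheme according to `mode`: `"shared"` uses one causal variant for
#' both traits, `"distinct"` uses two causal variants with pairwise r^2 below
#' `max_r2_distinct`, `"null"` plants no effect in either trait. Effect sizes
#' are scaled so the causal variant explains `h2_1` (resp. `h2_2`) of the
#' phenotypic variance.
#'
#' @param mode One of `"shared"`, `"distinct"`, `"null"`.
#' @param n_variants Variants in the region.
#' @param n1,n2 Cohort sample sizes.
#' @param maf Minor allele frequency of the simulated variants.
#' @param ld_rho Adjacent-variant LD (see [simulate_genotypes()]).
#' @param h2_1,h2_2 Variance explained by the causal variant in each trait.
#' @param max_r2_distinct Upper bound on the r^2 between the two causal
#'   variants in `"distinct"` mode.
#' @param seed Integer seed.
#' @return List with `stats1`, `stats2` (per-variant summary statistics) and
#'   `truth` (`mode`, `causal1`, `causal2`).
#' @export
simulate_coloc_pair <- function(mode = c("shared", "distinct", "null"),
                                n_variants = 200, n1 = 500, n2 = 500,
                                maf = 0.3, ld_rho = 0.9,
                                h2_1 = 0.05, h2_2 = 0.05,
                                max_r2_distinct = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  g1 <- simulate_genotypes(n1, n_variants, maf, ld_rho, split_seed(seed, 11L))
  g2 <- simulate_genotypes(n2, n_variants, maf, ld_rho, split_seed(seed, 12L))
  set.seed(split_seed(seed, 13L))
  causal1 <- causal2 <- NA_character_
  y1 <- stats::rnorm(n1)
  y2 <- stats::rnorm(n2)
  effect <- function(g, h2) sqrt(h2 / (1 - h2)) / stats::sd(g)
  if (mode == "shared") {
    idx <- sample(seq(n_variants %/% 4, 3 * n_variants %/% 4), 1L)
    causal1 <- causal2 <- colnames(g1)[idx]
    y1 <- y1 + effect(g1[, idx], h2_1) * g1[, idx]
    y2 <- y2 + effect(g2[, idx], h2_2) * g2[, idx]
  } else if (mode == "distinct") {
    i1 <- max(1L, n_variants %/% 4)
    r2_1 <- suppressWarnings(stats::cor(g1[, i1], g1))^2
    r2_2 <- suppressWarnings(stats::cor(g2[, i1], g2))^2
    ok <- which(r2_1 < max_r2_distinct & r2_2 < max_r2_distinct &
                  seq_len(n_variants) > i1)
    if (length(ok) == 0)
      stop("region too small to place two causal variants with r^2 < ",
           max_r2_distinct)
    i2 <- ok[length(ok) %/% 2 + 1L]
    causal1 <- colnames(g1)[i1]
    causal2 <- colnames(g1)[i2]
    y1 <- y1 + effect(g1[, i1], h2_1) * g1[, i1]
    y2 <- y2 + effect(g2[, i2], h2_2) * g2[, i2]
  }
  list(stats1 = marginal_scan(y1, g1, "cohort1", "trait1"),
       stats2 = marginal_scan(y2, g2, "cohort2", "trait2"),
       truth = list(mode = mode, causal1 = causal1, causal2 = causal2))
}

#' Simulate a labeled reference panel in principal-component space
#'
#' Gaussian clusters around the supplied superpopulation centers, used to
#' exercise PC-distance population assignment.
#'
#' @param pop_centers Matrix (populations x PCs) with unique row names, or a
#'   named list of numeric center vectors.
#' @param spread Within-cluster standard deviation.
#' @param n_per_pop Reference samples per population.
#' @param n_pcs Number of PCs (>= 3); centers are padded with zeros if
#'   shorter.
#' @param seed Integer seed.
#' @return Data frame with `sample_id`, `population` and `PC1..PCk` columns.
#' @export
simulate_reference_panel <- function(pop_centers, spread = 1, n_per_pop = 100,
                                     n_pcs = 3, seed = 1L) {
  if (is.list(pop_centers))
    pop_centers <- do.call(rbind, pop_centers)
  pop_centers <- as.matrix(pop_centers)
  if (is.null(rownames(pop_centers)) || anyDuplicated(rownames(pop_centers)))
    stop("population labels must be unique row names")
  if (n_pcs < 3) stop("n_pcs must be >= 3")
  if (ncol(pop_centers) < n_pcs)
    pop_centers <- cbind(pop_centers,
                         matrix(0, nrow(pop_centers),
                                n_pcs - ncol(pop_centers)))
  set.seed(split_seed(seed, 5L))
  out <- lapply(rownames(pop_centers), function(pop) {
    pts <- matrix(stats::rnorm(n_per_pop * n_pcs, sd = spread),
                  n_per_pop, n_pcs)
    pts <- sweep(pts, 2, pop_centers[pop, seq_len(n_pcs)], "+")
    data.frame(sample_id = sprintf("%s_%d", pop, seq_len(n_per_pop)),
               population = pop, pts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[-(1:2)] <- sprintf("PC%d", seq_len(n_pcs))
  rownames(out) <- NULL
  out
}

#' Simulate a full multi-dataset study
#'
#' Drives the per-dataset generators from one [sim_config()]: a shared
#' variant grid (one cis region per gene), per-dataset genotypes, per-gene
#' causal effects whose activity follows the dataset-group sharing pattern,
#' and expression matrices with covariate structure.
#'
#' @param config A [sim_config()] object.
#' @param within_group_shared_fraction Probability that a gene's effect is
#'   shared by its whole dataset group (vs private to one member).
#' @param n_covariates Latent covariates per dataset.
#' @return List with `datasets` (per dataset: `genotypes`, `expression`,
#'   `covariates`), `trait_meta` (gene metadata with cis anchors) and
#'   `truth` (per gene x dataset planted beta).
#' @export
simulate_study <- function(config, within_group_shared_fraction = 0.8,
                           n_covariates = 2) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants_per_region
  n_genes <- config$n_genes
  datasets <- names(config$sharing_pattern)
  set.seed(split_seed(config$seed, 7L))
  mafs <- stats::runif(m * n_genes, config$maf_range[1], config$maf_range[2])
  gene_id <- sprintf("gene_%d", seq_len(n_genes))
  region_start <- (seq_len(n_genes) - 1L) * 10000000L
  pos <- as.integer(rep(region_start, each = m) + 1000L * seq_len(m))
  causal_idx <- (seq_len(n_genes) - 1L) * m + (m %/% 2L + 1L)

  eff <- simulate_effect_matrix(
    n_genes, config$sharing_pattern, within_group_shared_fraction,
    effect_size_sd = config$effect_size_sd, se_scale = 0,
    seed = split_seed(config$seed, 8L))
  truth_beta <- eff$true_beta
  rownames(truth_beta) <- gene_id

  out <- vector("list", length(datasets))
  names(out) <- datasets
  for (d in seq_along(datasets)) {
    geno <- simulate_genotypes(config$n_samples_per_dataset[d], m * n_genes,
                               mafs, config$ld_rho,
                               split_seed(config$seed, 100L + d), pos = pos)
    colnames(geno) <- sprintf("1_%d_A_G", pos)
    beta_d <- truth_beta[, datasets[d]]
    cm <- data.frame(gene_id = gene_id,
                     variant_id = colnames(geno)[causal_idx],
                     beta = ifelse(is.na(beta_d), 0, beta_d),
                     stringsAsFactors = FALSE)
    ex <- simulate_expression_dataset(geno, cm, n_covariates,
                                      noise_sd = config$noise_sd,
                                      seed = split_seed(config$seed, 200L + d))
    out[[d]] <- list(genotypes = geno, expression = ex$expression,
                     covariates = ex$covariates)
  }
  trait_meta <- data.frame(trait_id = gene_id, gene_id = gene_id,
                           group_id = gene_id, chrom = "1",
                           cis_anchor = pos[causal_idx],
                           causal_variant = sprintf("1_%d_A_G", pos[causal_idx]),
                           trait_type = "gene", stringsAsFactors = FALSE)
  list(datasets = out, trait_meta = trait_meta, truth = truth_beta)
}

#' Parse `chrom_pos_ref_alt` variant identifiers
#'
#' @param ids Character vector of variant ids.
#' @return Data frame with `chrom`, `pos` (integer), `ref`, `alt`.
#' @export
parse_variant_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)_([0-9]+)_([ACGT]+)_([ACGT]+)$", ids))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("malformed variant id(s): ", paste(utils::head(ids[bad], 3), collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             pos = as.integer(vapply(m, `[`, "", 3L)),
             ref = vapply(m, `[`, "", 4L),
             alt = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}
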