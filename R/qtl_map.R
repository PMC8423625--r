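# Residualize a sample-by-anything matrix against [intercept | covariates].
# Returns the matrix of residuals; covariates = NULL just centers columns.
residualize <- function(m, covariates = NULL) {
  m <- as.matrix(m)
  X <- cbind(rep(1, nrow(m)), covariates)
  qr.resid(qr(X), m)
}

#' Nominal cis association scan for one molecular trait
#'
#' Per-variant OLS of trait ~ intercept + dosage + covariates, computed via
#' Frisch-Waugh residualization so all variants in the window are tested in
#' one pass. Traits with fewer than `min_variants` cis variants or zero
#' variance are skipped with a machine-readable reason (mirroring the
#' exclusions applied before QTL mapping).
#'
#' @param trait Phenotype vector (length = samples).
#' @param genotypes Dosage matrix, samples x variants, `chrom_pos_ref_alt`
#'   column names.
#' @param covariates Optional samples x k covariate matrix (e.g. 6 genotype
#'   + 6 phenotype PCs).
#' @param window cis window half-width in bp (inclusive on both ends).
#' @param anchor 1-based cis anchor position (gene start); `NULL` disables
#'   windowing and tests every supplied variant.
#' @param dataset_id,trait_id Labels copied into the output.
#' @param min_variants Minimum number of cis variants required.
#' @return Data frame of per-variant summary statistics (`variant`,
#'   `chromosome`, `position`, `ref`, `alt`, `beta`, `se`, `pvalue`, `maf`,
#'   `n`, ...). When skipped, a zero-row frame with attribute
#'   `skip_reason` set to `"lt5_variants"` or `"zero_variance"`.
#' @export
cis_scan <- function(trait, genotypes, covariates = NULL, window = 1e6,
                     anchor = NULL, dataset_id = "ds1", trait_id = "trait",
                     min_variants = 5) {
  stopifnot(is.matrix(genotypes), length(trait) == nrow(genotypes))
  meta <- parse_variant_id(colnames(genotypes))
  if (!is.null(anchor)) {
    inside <- abs(meta$pos - anchor) <= window
    genotypes <- genotypes[, inside, drop = FALSE]
    meta <- meta[inside, , drop = FALSE]
  }
  skip <- function(reason) {
    out <- data.frame(dataset_id = character(0), molecular_trait_id = character(0),
                      variant = character(0), chromosome = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), beta = numeric(0), se = numeric(0),
                      pvalue = numeric(0), maf = numeric(0), n = integer(0))
    attr(out, "skip_reason") <- reason
    out
  }
  if (ncol(genotypes) < min_variants) return(skip("lt5_variants"))
  if (stats::var(trait) == 0) return(skip("zero_variance"))
  n <- length(trait)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  yr <- residualize(trait, covariates)[, 1]
  gr <- residualize(genotypes, covariates)
  sxx <- colSums(gr^2)
  beta <- ifelse(sxx > 0, as.vector(crossprod(gr, yr)) / sxx, NA_real_)
  df <- n - 2L - k
  rss <- pmax(sum(yr^2) - beta^2 * sxx, 0)
  se <- ifelse(sxx > 0, sqrt(rss / df / sxx), NA_real_)
  pvalue <- 2 * stats::pt(-abs(beta / se), df)
  af <- colMeans(genotypes) / 2
  data.frame(dataset_id = dataset_id, molecular_trait_id = trait_id,
             variant = colnames(genotypes),
             chromosome = meta$chrom, position = meta$pos,
             ref = meta$ref, alt = meta$alt,
             beta = beta, se = se, pvalue = pvalue,
             maf = pmin(af, 1 - af), n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group-best permutation empirical p-value
#'
#' The observed statistic is the minimum nominal p-value over all variants
#' and all molecular traits of the group. Each permutation shuffles the
#' sample labels of the trait matrix jointly across traits (preserving the
#' cross-trait correlation structure) and recomputes the group minimum; the
#' empirical p-value is `(1 + #\{perm min <= observed min\}) / (n_perm + 1)`.
#' Covariates are regressed out of both traits and genotypes once, before
#' permuting, and the degrees of freedom are adjusted accordingly.
#'
#' @param traits Matrix traits x samples (a single vector is accepted).
#' @param genotypes Dosage matrix samples x variants.
#' @param covariates Optional samples x k matrix.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param group_id Group (gene) label for the output.
#' @return One-row data frame: `group_id`, `best_trait_id`,
#'   `best_variant_id`, `nominal_min_p`, `empirical_p`, `n_perm`.
#' @export
permutation_group_best <- function(traits, genotypes, covariates = NULL,
                                   n_perm = 1000, seed = 1L,
                                   group_id = "group") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(dim(traits))) traits <- matrix(traits, nrow = 1)
  stopifnot(ncol(traits) == nrow(genotypes), ncol(genotypes) >= 1)
  n <- ncol(traits)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n - 2L - k
  Y <- residualize(t(traits), covariates)
  G <- residualize(genotypes, covariates)
  norm_cols <- function(m) {
    s <- sqrt(colSums(m^2))
    s[s == 0] <- 1
    sweep(m, 2, s, "/")
  }
  Yn <- norm_cols(Y)
  Gn <- norm_cols(G)
  r_obs <- crossprod(Yn, Gn)                      # traits x variants
  obs <- max(abs(r_obs))
  best <- which(abs(r_obs) == obs, arr.ind = TRUE)[1, ]
  trait_ids <- rownames(traits)
  if (is.null(trait_ids)) trait_ids <- sprintf("trait_%d", seq_len(nrow(traits)))
  set.seed(split_seed(seed, 4L))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    # permuting residualized trait rows jointly across traits; the permuted
    # columns must be re-normalized only if covariates were regressed out,
    # since permutation preserves column norms otherwise
    Yp <- Yn[perm, , drop = FALSE]
    if (max(abs(crossprod(Yp, Gn))) >= obs) exceed <- exceed + 1L
  }
  tstat <- obs * sqrt(df) / sqrt(max(1 - obs^2, .Machine$double.eps))
  data.frame(group_id = group_id,
             best_trait_id = trait_ids[best[1]],
             best_variant_id = colnames(genotypes)[best[2]],
             nominal_min_p = 2 * stats::pt(-tstat, df),
             empirical_p = (1 + exceed) / (n_perm + 1),
             n_perm = n_perm, stringsAsFactors = FALSE)
}

#' Significant QTLs at a given FDR
#'
#' Benjamini-Hochberg correction over group-level empirical p-values;
#' returns the genes whose q-value is at or below `alpha` (the "number of
#' genes with at least one significant QTL" statistic).
#'
#' @param group_results Data frame from [permutation_group_best()] rows.
#' @param alpha FDR level (default 0.05).
#' @return List with `genes` (character), `count` and the annotated `table`
#'   (adds `fdr_q`).
#' @export
significant_qtls <- function(group_results, alpha = 0.05) {
  if (is.null(group_results) || nrow(group_results) == 0)
    return(list(genes = character(0), count = 0L,
                table = cbind(group_results, fdr_q = numeric(0))))
  q <- stats::p.adjust(group_results$empirical_p, method = "BH")
  tab <- cbind(group_results, fdr_q = q)
  sig <- tab$group_id[q <= alpha]
  list(genes = sig, count = length(sig), table = tab)
}
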