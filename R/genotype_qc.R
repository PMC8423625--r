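#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Asymptotic chi-square goodness-of-fit test with one degree of freedom
#' against the genotype proportions expected from the sample allele
#' frequency. Monomorphic variants return p = 1 by convention.
#'
#' @param genotype_counts Numeric triple `(n_AA, n_Aa, n_aa)`.
#' @return p-value in [0, 1].
#' @export
hardy_weinberg_test <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3, all(genotype_counts >= 0))
  n <- sum(genotype_counts)
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * genotype_counts[1] + genotype_counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((genotype_counts - expected)^2 / expected)
  unname(stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Variant filters for the pre- and post-imputation stages
#'
#' Pre-imputation removes variants with Hardy-Weinberg p < 1e-6,
#' missingness > 0.05 or MAF < 0.01; post-imputation removes MAF < 0.01 or
#' imputation R^2 < 0.4. All thresholds are strict inequalities, so boundary
#' values are retained. Failures are recorded as comma-joined reason codes.
#'
#' @param stats Data frame with `variant_id`, and for the pre stage
#'   `n_AA`, `n_Aa`, `n_aa`, `missing_fraction`, `maf`; for the post stage
#'   `maf` and `imputation_r2`.
#' @param stage `"pre_imputation"` or `"post_imputation"`.
#' @param hwe_p,max_missing,min_maf,min_r2 Thresholds.
#' @return Data frame `variant_id`, `retained`, `reason` (`NA` when
#'   retained).
#' @export
filter_variants <- function(stats, stage = c("pre_imputation", "post_imputation"),
                            hwe_p = 1e-6, max_missing = 0.05,
                            min_maf = 0.01, min_r2 = 0.4) {
  stage <- match.arg(stage)
  reasons <- vector("list", nrow(stats))
  if (stage == "pre_imputation") {
    need <- c("variant_id", "n_AA", "n_Aa", "n_aa", "missing_fraction", "maf")
    if (!all(need %in% names(stats)))
      stop("pre-imputation stage needs columns: ", paste(need, collapse = ", "))
    hwe <- vapply(seq_len(nrow(stats)), function(i)
      hardy_weinberg_test(c(stats$n_AA[i], stats$n_Aa[i], stats$n_aa[i])), 0)
    for (i in seq_len(nrow(stats))) {
      r <- character(0)
      if (hwe[i] < hwe_p) r <- c(r, "hwe")
      if (stats$missing_fraction[i] > max_missing) r <- c(r, "missingness")
      if (stats$maf[i] < min_maf) r <- c(r, "maf")
      reasons[[i]] <- r
    }
  } else {
    if (!("imputation_r2" %in% names(stats)) || anyNA(stats$imputation_r2))
      stop("post-imputation stage requires a complete imputation_r2 column")
    for (i in seq_len(nrow(stats))) {
      r <- character(0)
      if (stats$maf[i] < min_maf) r <- c(r, "maf")
      if (stats$imputation_r2[i] < min_r2) r <- c(r, "r2")
      reasons[[i]] <- r
    }
  }
  reason <- vapply(reasons, function(r)
    if (length(r)) paste(r, collapse = ",") else NA_character_, "")
  data.frame(variant_id = stats$variant_id,
             retained = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Greedy windowed LD pruning
#'
#' Scans windows of `window_variants` variants left to right, sliding by
#' `step`; within each window the later variant of any retained pair with
#' squared correlation above `r2_threshold` is dropped. Mirrors PLINK's
#' `--indep-pairwise 50000 200 0.05` and is fully deterministic.
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param window_variants Window size in variants.
#' @param step Window slide in variants.
#' @param r2_threshold Pairwise r^2 above which the later variant is dropped.
#' @return Character vector of retained variant ids (column indices if the
#'   matrix is unnamed).
#' @export
ld_prune <- function(genotypes, window_variants = 50000, step = 200,
                     r2_threshold = 0.05) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (m < 2) return(ids)
  keep <- rep(TRUE, m)
  for (s in seq(1L, m, by = step)) {
    idx <- s:min(s + window_variants - 1L, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(stats::cor(genotypes[, idx, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    for (a in seq_len(length(idx) - 1L)) {
      if (!keep[idx[a]]) next
      for (b in (a + 1L):length(idx)) {
        if (keep[idx[b]] && r2[a, b] > r2_threshold) keep[idx[b]] <- FALSE
      }
    }
    if (s + window_variants - 1L >= m) break
  }
  ids[keep]
}

#' Principal components with a deterministic sign convention
#'
#' Thin wrapper around [stats::prcomp()] that drops constant features when
#' scaling (with a warning) and fixes each component's sign so that its
#' largest-magnitude loading is positive, making outputs reproducible across
#' platforms.
#'
#' @param x Numeric matrix, samples x features.
#' @param k Number of components, `k <= min(dim(x))`.
#' @param center,scale Passed to [stats::prcomp()].
#' @return List with `scores` (samples x k), `loadings` (features x k),
#'   `var_explained` (length k, fractions of total variance) and `center`,
#'   `scale` vectors.
#' @export
compute_pcs <- function(x, k, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (scale) {
    const <- apply(x, 2, stats::var) == 0
    if (any(const)) {
      warning(sum(const), " constant feature(s) dropped before scaling")
      x <- x[, !const, drop = FALSE]
    }
  }
  if (k > min(dim(x))) stop("k exceeds min(n_samples, n_features)")
  p <- stats::prcomp(x, center = center, scale. = scale)
  flip <- vapply(seq_len(k), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(p$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  list(scores = scores, loadings = loadings,
       var_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
       center = p$center, scale = p$scale)
}

#' Assign samples to superpopulations by PC-space distance
#'
#' The distance from a sample to a reference population is the mean Euclidean
#' distance (over the first `n_pcs` PCs) to that population's reference
#' samples. A sample is assigned to its closest population only if the
#' second-closest distance is at least `ratio_threshold` times larger
#' (inclusive); otherwise the call is `NA`. A single-population panel assigns
#' unconditionally (ratio treated as infinite).
#'
#' @param sample_pcs Matrix (samples x PCs) or a single numeric vector.
#' @param panel Data frame from [simulate_reference_panel()] or equivalent:
#'   a `population` column plus `PC1..PCk` columns.
#' @param n_pcs Number of leading PCs used (default 3).
#' @param ratio_threshold Assignment threshold on second-closest / closest.
#' @return Data frame with `sample_id`, one `dist_<pop>` column per
#'   population, `assigned` and `ratio`.
#' @export
assign_superpopulation <- function(sample_pcs, panel, n_pcs = 3,
                                   ratio_threshold = 1.7) {
  if (is.null(dim(sample_pcs)))
    sample_pcs <- matrix(sample_pcs, nrow = 1)
  pc_cols <- grep("^PC[0-9]+$", names(panel), value = TRUE)
  if (nrow(panel) == 0 || length(pc_cols) == 0) stop("empty reference panel")
  if (n_pcs > length(pc_cols) || n_pcs > ncol(sample_pcs))
    stop("n_pcs exceeds the available PCs")
  pops <- sort(unique(panel$population))
  ref <- as.matrix(panel[, pc_cols[seq_len(n_pcs)], drop = FALSE])
  x <- sample_pcs[, seq_len(n_pcs), drop = FALSE]
  dists <- matrix(NA_real_, nrow(x), length(pops),
                  dimnames = list(NULL, pops))
  for (p in seq_along(pops)) {
    rp <- ref[panel$population == pops[p], , drop = FALSE]
    # mean over reference members of the per-member Euclidean distance
    d2 <- outer(rowSums(x^2), rep(1, nrow(rp))) +
      outer(rep(1, nrow(x)), rowSums(rp^2)) - 2 * x %*% t(rp)
    dists[, p] <- rowMeans(sqrt(pmax(d2, 0)))
  }
  assigned <- character(nrow(x))
  ratio <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    o <- order(dists[i, ])
    closest <- dists[i, o[1]]
    ratio[i] <- if (length(pops) == 1L || closest == 0) Inf
                else dists[i, o[2]] / closest
    assigned[i] <- if (ratio[i] >= ratio_threshold) pops[o[1]] else NA_character_
  }
  ids <- rownames(sample_pcs)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_len(nrow(x)))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (p in pops) out[[paste0("dist_", p)]] <- dists[, p]
  out$assigned <- assigned
  out$ratio <- ratio
  out
}
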