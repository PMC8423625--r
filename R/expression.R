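#' Convert read counts to transcripts per million
#'
#' Rates are counts divided by feature length; each sample's rates are
#' rescaled to sum to one million. Columns with zero total rate are returned
#' as all-zero with a warning.
#'
#' @param counts Non-negative matrix, traits x samples.
#' @param lengths Positive per-trait feature lengths in bp.
#' @return TPM matrix of the same dimensions.
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(lengths) != nrow(counts) || any(lengths <= 0))
    stop("lengths must be positive, one per trait")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero sample column(s) left at zero")
    tot[tot == 0] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Drop traits that are unexpressed in almost all samples
#'
#' A trait is excluded when the fraction of samples with TPM below 1 is at
#' least 0.95 (inclusive at the boundary).
#'
#' @param tpm TPM matrix, traits x samples.
#' @param tpm_cut Expression cutoff (TPM).
#' @param max_low_fraction Exclusion boundary on the low-expression fraction.
#' @return Character vector of retained trait ids (row names, or indices).
#' @export
filter_low_expression <- function(tpm, tpm_cut = 1, max_low_fraction = 0.95) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) == 0) stop("at least one sample is required")
  low <- rowMeans(tpm < tpm_cut)
  ids <- rownames(tpm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(tpm)))
  ids[low < max_low_fraction]
}

#' Median expression profiles for dataset-similarity analysis
#'
#' For each dataset, genes with median TPM below 1 are dropped, the median
#' profile is log2(x + 1) transformed, and profiles are restricted to the
#' gene universe shared by all datasets after filtering.
#'
#' @param tpm_list Named list of TPM matrices (genes x samples) with gene row
#'   names.
#' @param median_cut Per-dataset median-TPM inclusion threshold.
#' @return Matrix datasets x genes of log2 median TPM over the shared genes.
#' @export
median_expression_profile <- function(tpm_list, median_cut = 1) {
  stopifnot(is.list(tpm_list), length(tpm_list) >= 1)
  meds <- lapply(tpm_list, function(m) {
    med <- apply(as.matrix(m), 1, stats::median)
    med[med >= median_cut]
  })
  shared <- Reduce(intersect, lapply(meds, names))
  if (length(shared) == 0)
    stop("no genes pass the median filter in every dataset")
  out <- matrix(NA_real_, length(tpm_list), length(shared),
                dimnames = list(names(tpm_list), shared))
  for (i in seq_along(meds)) out[i, ] <- log2(meds[[i]][shared] + 1)
  out
}

#' Infer genetic sex from XIST and Y-chromosome expression
#'
#' Compares log2 XIST expression against the mean TPM of Y-chromosome
#' protein-coding genes. Samples expressing only XIST are called female, only
#' Y genes male; samples with both markers high, or both low, are flagged
#' ambiguous (possible cross-contamination or degradation).
#'
#' @param tpm TPM matrix, traits x samples.
#' @param y_gene_ids Row ids of Y-chromosome protein-coding genes.
#' @param xist_id Row id of XIST.
#' @param xist_cut Cutoff on log2(XIST TPM + 1).
#' @param y_cut Cutoff on mean Y-gene TPM.
#' @return Data frame with `sample_id`, `xist_level`, `y_mean_level`, `call`.
#' @export
infer_sex <- function(tpm, y_gene_ids, xist_id, xist_cut = 1, y_cut = 1) {
  tpm <- as.matrix(tpm)
  if (!(xist_id %in% rownames(tpm)) || !all(y_gene_ids %in% rownames(tpm)))
    stop("XIST and all Y genes must be rows of the TPM matrix")
  if (length(y_gene_ids) < 1) stop("at least one Y gene is required")
  xist <- log2(tpm[xist_id, ] + 1)
  ymean <- colMeans(tpm[y_gene_ids, , drop = FALSE])
  call <- ifelse(xist >= xist_cut & ymean < y_cut, "female",
          ifelse(ymean >= y_cut & xist < xist_cut, "male", "ambiguous"))
  ids <- colnames(tpm)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_len(ncol(tpm)))
  data.frame(sample_id = ids, xist_level = unname(xist),
             y_mean_level = unname(ymean), call = unname(call),
             stringsAsFactors = FALSE)
}

#' Transcript / event usage ratios
#'
#' Divides each trait's TPM by the summed TPM of its gene or event group in
#' the same sample. Samples where the group total is zero get missing usage
#' values for every member of that group.
#'
#' @param tpm TPM matrix, traits x samples.
#' @param group_map Named character vector mapping trait id to group id;
#'   every row of `tpm` must be mapped.
#' @return Usage matrix of the same dimensions (values in [0, 1] or `NA`).
#' @export
usage_ratios <- function(tpm, group_map) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) stop("tpm must have trait row names")
  if (!all(rownames(tpm) %in% names(group_map)))
    stop("every trait must be mapped to a group")
  groups <- group_map[rownames(tpm)]
  out <- tpm
  for (g in unique(groups)) {
    rows <- which(groups == g)
    tot <- colSums(tpm[rows, , drop = FALSE])
    ratio <- sweep(tpm[rows, , drop = FALSE], 2, tot, "/")
    ratio[, tot == 0] <- NA_real_
    out[rows, ] <- ratio
  }
  out
}

#' Rank-based inverse normal transform
#'
#' Ties are averaged; the transformed value is the standard-normal quantile
#' at (rank - 0.5) / n over the non-missing entries, which are the only ones
#' modified. A constant vector maps to all zeros with a warning.
#'
#' @param values Numeric vector, possibly with `NA`s.
#' @return Transformed vector of the same length, `NA`s preserved.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least two non-missing values")
  x <- values[ok]
  if (max(x) == min(x)) {
    warning("constant input; returning zeros")
    values[ok] <- 0
    return(values)
  }
  r <- rank(x, ties.method = "average")
  values[ok] <- stats::qnorm((r - 0.5) / length(x))
  values
}

#' Residualize traits against covariates
#'
#' Per-trait ordinary least squares against an intercept plus the covariate
#' columns; returns the residual matrix. Rank-deficient designs raise an
#' error naming the collinear columns.
#'
#' @param mat Numeric matrix, traits x samples.
#' @param covariates Numeric matrix, samples x k.
#' @return Residual matrix, traits x samples.
#' @export
regress_out <- function(mat, covariates) {
  mat <- as.matrix(mat)
  covariates <- as.matrix(covariates)
  stopifnot(ncol(mat) == nrow(covariates))
  if (is.null(colnames(covariates)))
    colnames(covariates) <- sprintf("cov%d", seq_len(ncol(covariates)))
  X <- cbind(`(intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  t(qr.resid(qx, t(mat)))
}
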