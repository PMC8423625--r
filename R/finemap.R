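#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect `beta` with standard error `se` and a N(0, W^2)
#' effect prior, the log ABF of association versus null is
#' `0.5 * log(1 - r) + 0.5 * z^2 * r` with `r = W^2 / (se^2 + W^2)` and
#' `z = beta / se`. Vectorized over variants.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param W Prior effect standard deviation (default 0.15, appropriate for
#'   inverse-normal-transformed traits).
#' @return Log Bayes factor(s), finite for finite inputs.
#' @export
wakefield_log_abf <- function(beta, se, W = 0.15) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("beta and se must be finite with se > 0")
  if (!is.finite(W) || W <= 0) stop("W must be a positive prior sd")
  r <- W^2 / (se^2 + W^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' 95% credible set from single-effect log Bayes factors
#'
#' Under a single-causal-variant model with a uniform prior over variants,
#' posterior inclusion probabilities are the softmax of the per-variant log
#' ABFs. Variants are sorted by PIP (ties broken by position, then ref/alt
#' alleles) and the smallest prefix with cumulative PIP at or above
#' `coverage` is the credible set.
#'
#' @param log_abf Numeric vector of per-variant log ABFs over the region.
#' @param variant_id Variant ids (default: names of `log_abf`).
#' @param position Optional 1-based positions used for tie-breaking (parsed
#'   from `variant_id` when those follow `chrom_pos_ref_alt`).
#' @param z Optional per-variant z-scores, carried into the output and used
#'   for the `max_abs_z` summary.
#' @param coverage Target posterior mass (default 0.95).
#' @return List of class `"credible_set"` with `members` (data frame
#'   `variant_id`, `pip`, `z`, sorted by descending PIP), `size`,
#'   `coverage`, `max_abs_z` and `pip_all` (full-region PIPs, summing to 1).
#' @export
credible_set <- function(log_abf, variant_id = names(log_abf),
                         position = NULL, z = NULL, coverage = 0.95) {
  if (length(log_abf) == 0) stop("empty region")
  if (is.null(variant_id))
    variant_id <- sprintf("v%d", seq_along(log_abf))
  ref <- alt <- rep("", length(log_abf))
  if (is.null(position)) {
    meta <- tryCatch(parse_variant_id(variant_id), error = function(e) NULL)
    if (!is.null(meta)) {
      position <- meta$pos; ref <- meta$ref; alt <- meta$alt
    } else position <- seq_along(log_abf)
  }
  pip <- exp(log_abf - logsumexp(log_abf))
  ord <- order(-pip, position, ref, alt)
  cum <- cumsum(pip[ord])
  size <- which(cum >= coverage - 1e-12)[1]
  if (is.na(size)) size <- length(pip)
  members <- data.frame(variant_id = variant_id[ord[seq_len(size)]],
                        pip = pip[ord[seq_len(size)]],
                        z = if (is.null(z)) NA_real_ else z[ord[seq_len(size)]],
                        stringsAsFactors = FALSE)
  structure(list(members = members, size = size, coverage = coverage,
                 max_abs_z = if (is.null(z)) NA_real_ else max(abs(z)),
                 pip_all = stats::setNames(pip, variant_id)),
            class = "credible_set")
}

#' Single-effect fine mapping of one cis region
#'
#' Residualizes the trait and the dosage matrix against the covariates
#' (the fine-mapping preprocessing: 6 phenotype + 6 genotype PCs regressed
#' out), computes per-variant marginal effects, converts them to Wakefield
#' log ABFs and extracts the credible set.
#'
#' @param trait Phenotype vector (typically inverse-normal transformed).
#' @param genotypes Dosage matrix samples x variants.
#' @param covariates Optional covariate matrix samples x k.
#' @param W Prior effect sd.
#' @param coverage Credible-set coverage (default 0.95).
#' @return A [credible_set()] object with an extra `stats` element holding
#'   the per-variant marginal summary statistics.
#' @export
finemap_region <- function(trait, genotypes, covariates = NULL, W = 0.15,
                           coverage = 0.95) {
  if (!is.null(covariates)) {
    trait <- residualize(trait, covariates)[, 1]
    genotypes_r <- residualize(genotypes, covariates)
    colnames(genotypes_r) <- colnames(genotypes)
  } else genotypes_r <- genotypes
  st <- marginal_scan(trait, genotypes_r)
  ok <- is.finite(st$beta) & is.finite(st$se) & st$se > 0
  st <- st[ok, , drop = FALSE]
  if (nrow(st) == 0) stop("no testable variants in region")
  labf <- wakefield_log_abf(st$beta, st$se, W)
  cs <- credible_set(labf, variant_id = st$variant, position = st$position,
                     z = st$beta / st$se, coverage = coverage)
  cs$stats <- st
  cs
}

#' Flatten credible sets into the long per-variant table
#'
#' @param cs_list Named list of [credible_set()] objects; names become
#'   `cs_id`s.
#' @param dataset_id,trait_id,gene_id Labels recycled across sets; `gene_id`
#'   may be a list (one vector per set) when a set tags several genes.
#' @return Long data frame with one row per (set, gene, variant):
#'   `dataset_id`, `molecular_trait_id`, `gene_id`, `cs_id`, `variant`,
#'   `pip`, `z`, `cs_size`, `cs_max_z`.
#' @export
credible_sets_table <- function(cs_list, dataset_id, trait_id = NULL,
                                gene_id = NULL) {
  stopifnot(is.list(cs_list), length(cs_list) >= 1)
  ids <- names(cs_list)
  if (is.null(ids)) ids <- sprintf("cs%d", seq_along(cs_list))
  if (is.null(trait_id)) trait_id <- ids
  if (is.null(gene_id)) gene_id <- as.list(trait_id)
  if (!is.list(gene_id)) gene_id <- as.list(gene_id)
  rows <- lapply(seq_along(cs_list), function(i) {
    cs <- cs_list[[i]]
    do.call(rbind, lapply(gene_id[[i]], function(g)
      data.frame(dataset_id = dataset_id, molecular_trait_id = trait_id[i],
                 gene_id = g, cs_id = ids[i],
                 variant = cs$members$variant_id, pip = cs$members$pip,
                 z = cs$members$z, cs_size = cs$size,
                 cs_max_z = cs$max_abs_z, stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}
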