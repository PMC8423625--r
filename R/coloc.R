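#' Approximate-Bayes-factor colocalization of two traits in a region
#'
#' Per-variant Wakefield log ABFs are computed for each trait and combined
#' into the posterior probabilities of the five causal configurations:
#' no association (PP0), trait-1 only (PP1), trait-2 only (PP2), two
#' distinct causal variants (PP3), one shared causal variant (PP4). All
#' sums are taken in log space. Variants are matched on (chromosome,
#' position); effect alleles are harmonized by flipping `beta` of the second
#' trait when ref/alt are swapped, and strand-palindromic variants (A/T,
#' C/G) with MAF above `palindromic_maf` are dropped with a warning.
#'
#' @param stats1,stats2 Summary-statistic data frames with columns
#'   `variant`, `chromosome`, `position`, `ref`, `alt`, `beta`, `se`,
#'   `maf`; `stats2` may carry a `trait_type` column (`"cc"`/`"binary"`
#'   selects the log-odds prior sd).
#' @param p1,p2,p12 Prior probabilities that a variant is associated with
#'   trait 1, trait 2, or both (coloc defaults).
#' @param W1,W2 Prior effect sds; `W2 = NULL` picks 0.15 for quantitative
#'   and 0.2 for binary GWAS traits.
#' @param palindromic_maf MAF above which A/T and C/G variants are dropped.
#' @return List of class `"coloc_result"`: `pp` (named numeric, sums to 1),
#'   `n_overlapping_variants`, `lead_variant` (top trait-1 ABF among shared
#'   variants), `lead_position`, `lead_chrom`.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W1 = 0.15, W2 = NULL, palindromic_maf = 0.4) {
  key1 <- paste(stats1$chromosome, stats1$position)
  key2 <- paste(stats2$chromosome, stats2$position)
  i2 <- match(key1, key2)
  keep <- !is.na(i2)
  s1 <- stats1[keep, , drop = FALSE]
  s2 <- stats2[i2[keep], , drop = FALSE]
  same <- s1$ref == s2$ref & s1$alt == s2$alt
  swapped <- s1$ref == s2$alt & s1$alt == s2$ref
  mismatched <- !(same | swapped)
  if (any(mismatched)) {
    warning(sum(mismatched), " variant(s) dropped: allele mismatch")
    s1 <- s1[!mismatched, , drop = FALSE]
    s2 <- s2[!mismatched, , drop = FALSE]
    same <- same[!mismatched]; swapped <- swapped[!mismatched]
  }
  pal <- paste0(s1$ref, s1$alt) %in% c("AT", "TA", "CG", "GC")
  drop_pal <- pal & (s1$maf > palindromic_maf | s2$maf > palindromic_maf)
  if (any(drop_pal)) {
    warning(sum(drop_pal), " palindromic high-MAF variant(s) dropped")
    s1 <- s1[!drop_pal, , drop = FALSE]
    s2 <- s2[!drop_pal, , drop = FALSE]
    swapped <- swapped[!drop_pal]
  }
  ok <- is.finite(s1$beta) & is.finite(s1$se) & s1$se > 0 &
        is.finite(s2$beta) & is.finite(s2$se) & s2$se > 0
  s1 <- s1[ok, , drop = FALSE]; s2 <- s2[ok, , drop = FALSE]
  swapped <- swapped[ok]
  if (nrow(s1) == 0) stop("no shared variants between the two traits")
  beta2 <- ifelse(swapped, -s2$beta, s2$beta)
  if (is.null(W2)) {
    W2 <- 0.15
    if ("trait_type" %in% names(s2) &&
        any(s2$trait_type %in% c("cc", "binary"))) W2 <- 0.2
  }
  l1 <- wakefield_log_abf(s1$beta, s1$se, W1)
  l2 <- wakefield_log_abf(beta2, s2$se, W2)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  # H3: all ordered pairs (i, j), i != j — full matrix minus its diagonal,
  # evaluated exactly in log space to survive a dominant shared variant
  M <- outer(l1, l2, "+")
  diag(M) <- -Inf
  lH <- c(h0 = 0,
          h1 = log(p1) + lsum1,
          h2 = log(p2) + lsum2,
          h3 = log(p1) + log(p2) + logsumexp(as.vector(M)),
          h4 = log(p12) + lsum12)
  pp <- exp(lH - logsumexp(lH))
  names(pp) <- paste0("PP", 0:4)
  lead <- which.max(l1)
  structure(list(pp = pp, n_overlapping_variants = nrow(s1),
                 lead_variant = s1$variant[lead],
                 lead_position = s1$position[lead],
                 lead_chrom = s1$chromosome[lead]),
            class = "coloc_result")
}

#' Slice summary statistics to a window around a lead variant
#'
#' @param stats Summary-statistic data frame with `variant`, `position`.
#' @param lead_variant Variant id that must be present in `stats`.
#' @param window Half-width in bp, inclusive at both bounds (default
#'   200,000).
#' @return The rows of `stats` with `|position - lead position| <= window`.
#' @export
extract_region <- function(stats, lead_variant, window = 200000) {
  i <- match(lead_variant, stats$variant)
  if (is.na(i)) stop("lead variant ", lead_variant, " absent from stats")
  lead_pos <- stats$position[i]
  stats[abs(stats$position - lead_pos) <= window, , drop = FALSE]
}

#' Assign a colocalization result to an approximately independent LD block
#'
#' When the cis window overlaps several blocks, the result belongs to the
#' block containing the QTL lead variant. Blocks follow the BED convention
#' (0-based, half-open); lead positions are 1-based and converted
#' explicitly.
#'
#' @param lead_chrom,lead_pos Lead variant chromosome and 1-based position.
#' @param blocks Data frame `block_id`, `chrom`, `start` (0-based), `end`
#'   (exclusive); non-overlapping within chromosome.
#' @return The containing `block_id`, or `NA_character_` if none.
#' @export
assign_ld_block <- function(lead_chrom, lead_pos, blocks) {
  pos0 <- lead_pos - 1L
  hit <- blocks$chrom == lead_chrom & blocks$start <= pos0 & pos0 < blocks$end
  if (!any(hit)) return(NA_character_)
  blocks$block_id[which(hit)[1]]
}

#' Summarize strong colocalizations over LD blocks
#'
#' Keeps results with PP4 at or above `threshold`, removes non-reference
#' datasets below the sample-size floor, groups by (block, GWAS) and flags a
#' block as novel when none of the kept results in it come from the
#' reference dataset set.
#'
#' @param results Data frame with columns `block_id`, `gwas_id`,
#'   `dataset_id`, `trait_id`, `method`, `pp4`.
#' @param threshold PP4 inclusion bound (inclusive, default 0.8).
#' @param reference_datasets Character vector of reference (e.g. GTEx)
#'   dataset ids.
#' @param min_n Sample-size floor for non-reference datasets (default 150).
#' @param dataset_n Named integer vector of per-dataset sample sizes.
#' @return Data frame per (block, GWAS): `block_id`, `gwas_id`, `n_results`,
#'   `novel`, `methods` (comma-joined sorted methods detecting the block),
#'   `datasets`.
#' @export
summarize_blocks <- function(results, threshold = 0.8,
                             reference_datasets = character(0),
                             min_n = 150, dataset_n = integer(0)) {
  res <- results[!is.na(results$block_id) & results$pp4 >= threshold, ,
                 drop = FALSE]
  if (nrow(res) > 0 && length(dataset_n) > 0) {
    n <- dataset_n[res$dataset_id]
    small <- !(res$dataset_id %in% reference_datasets) &
      !is.na(n) & n < min_n
    res <- res[!small, , drop = FALSE]
  }
  if (nrow(res) == 0)
    return(data.frame(block_id = character(0), gwas_id = character(0),
                      n_results = integer(0), novel = logical(0),
                      methods = character(0), datasets = character(0),
                      stringsAsFactors = FALSE))
  res <- res[order(res$block_id, res$gwas_id, res$dataset_id), , drop = FALSE]
  out <- lapply(split(res, paste(res$block_id, res$gwas_id, sep = "\r")),
                function(g)
    data.frame(block_id = g$block_id[1], gwas_id = g$gwas_id[1],
               n_results = nrow(g),
               novel = !any(g$dataset_id %in% reference_datasets),
               methods = paste(sort(unique(g$method)), collapse = ","),
               datasets = paste(sort(unique(g$dataset_id)), collapse = ","),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$block_id, out$gwas_id), , drop = FALSE]
}

#' Novelty score of a dataset
#'
#' Number of additional (reference-missed) colocalizing LD blocks divided by
#' the dataset's sample size.
#'
#' @param n_new_blocks Count of novel colocalizations.
#' @param sample_size Dataset sample size, > 0.
#' @return The ratio.
#' @export
novelty_score <- function(n_new_blocks, sample_size) {
  if (!is.finite(sample_size) || sample_size <= 0)
    stop("sample_size must be positive")
  n_new_blocks / sample_size
}

#' Count LD blocks by the set of quantification methods detecting them
#'
#' @param detections Data frame `block_id`, `method` (one row per block x
#'   method detection, methods from \{gene, exon, tx, txrevise\}).
#' @return List with `counts` (named by the sorted comma-joined method
#'   subset) and `transcript_level_only` (blocks detected by at least one
#'   transcript-level method but not at the gene level).
#' @export
method_overlap_counts <- function(detections) {
  if (nrow(detections) == 0)
    return(list(counts = integer(0), transcript_level_only = 0L))
  methods_by_block <- tapply(detections$method, detections$block_id,
                             function(m) paste(sort(unique(m)), collapse = ","))
  counts <- table(methods_by_block)
  # a block is transcript-level-only when "gene" is not among its methods
  tx_only <- sum(!grepl("(^|,)gene(,|$)", methods_by_block))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       transcript_level_only = as.integer(tx_only))
}
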