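#' Write summary statistics in the tabix-friendly TSV layout of public
#' eQTL resources
#'
#' Columns: molecular_trait_id, chromosome, position, ref, alt, variant,
#' maf, pvalue, beta, se, an, ac, r2 (r2 left empty when unknown), sorted by
#' chromosome then position so the file can be bgzip/tabix indexed.
#'
#' @param stats Data frame from [cis_scan()] / [marginal_scan()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  an <- 2L * stats$n
  out <- data.frame(molecular_trait_id = stats$molecular_trait_id,
                    chromosome = stats$chromosome,
                    position = stats$position,
                    ref = stats$ref, alt = stats$alt,
                    variant = stats$variant,
                    maf = stats$maf, pvalue = stats$pvalue,
                    beta = stats$beta, se = stats$se,
                    an = an, ac = round(stats$maf * an),
                    r2 = if ("r2" %in% names(stats)) stats$r2 else NA,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a summary-statistics TSV written by [write_summary_stats()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_summary_stats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chromosome = "character"))
}

#' Write genotype dosages as a minimal VCF with GT and DS fields
#'
#' Hard-call genotypes (0/0, 0/1, 1/1) are derived from the integer dosages
#' produced by [simulate_genotypes()].
#'
#' @param genotypes Dosage matrix, samples x variants, `chrom_pos_ref_alt`
#'   column names.
#' @param path Output path (uncompressed VCF).
#' @return The path, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  meta <- parse_variant_id(colnames(genotypes))
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")), con)
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    ds <- genotypes[, j]
    paste(c(meta$chrom[j], meta$pos[j], colnames(genotypes)[j],
            meta$ref[j], meta$alt[j], ".", "PASS", ".", "GT:DS",
            paste0(gt_codes[ds + 1L], ":", ds)), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Write / read a dosage matrix as TSV (variants x samples)
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param path File path.
#' @return The path (writer, invisibly) or the samples x variants matrix
#'   (reader).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(variant = colnames(genotypes),
                   t(genotypes), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$variant
  m
}

#' Write / read a trait matrix as TSV (rows traits, columns samples)
#'
#' @param mat Traits x samples numeric matrix with row names.
#' @param path File path.
#' @export
write_trait_matrix <- function(mat, path) {
  df <- data.frame(trait_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$trait_id
  m
}

#' Write a credible-set table as TSV
#'
#' Columns: dataset_id, molecular_trait_id, gene_id, cs_id, variant, pip, z,
#' cs_size, cs_min_r2 (left empty; purity is not computed by the
#' single-effect model).
#'
#' @param sets Long credible-set table (see [credible_sets_table()]).
#' @param path File path.
#' @export
write_credible_sets <- function(sets, path) {
  out <- sets
  if (!("cs_min_r2" %in% names(out))) out$cs_min_r2 <- NA
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_credible_sets
#' @export
read_credible_sets <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
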