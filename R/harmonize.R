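#' Filter credible sets and split multi-gene sets into per-gene records
#'
#' Keeps sets with fewer than 30 variants and a maximal univariate |z| above
#' 3 (both strict). A credible set linked to k genes contributes k records,
#' each treated downstream as an independent signal.
#'
#' @param sets Long credible-set table (see [credible_sets_table()]):
#'   one row per (dataset, cs, gene, variant) with `cs_size` and `cs_max_z`.
#' @param max_size Exclusive upper bound on set size (default 30).
#' @param min_z Exclusive lower bound on the maximal |z| (default 3).
#' @return The filtered long table (same columns).
#' @export
filter_and_split_credible_sets <- function(sets, max_size = 30, min_z = 3) {
  need <- c("dataset_id", "gene_id", "cs_id", "variant", "cs_size", "cs_max_z")
  if (!all(need %in% names(sets)))
    stop("sets must carry columns: ", paste(need, collapse = ", "))
  keep <- sets$cs_size < max_size & sets$cs_max_z > min_z
  sets[keep, , drop = FALSE]
}

#' Connected components of credible sets sharing variants
#'
#' Two credible sets (from any pair of datasets) belong to the same
#' independent signal if they share at least one variant; components are the
#' transitive closure of that relation, computed by union-find over the sets
#' keyed on `(dataset_id, cs_id)`. Component labels are deterministic and
#' independent of row order.
#'
#' @param records Long table for a single gene (rows: set x variant).
#' @return Data frame `dataset_id`, `cs_id`, `component` (labels `cc1`,
#'   `cc2`, ... ordered by each component's first set key, sorted).
#' @export
connected_components <- function(records) {
  if (length(unique(records$gene_id)) > 1)
    stop("records must belong to a single gene")
  key <- paste(records$dataset_id, records$cs_id, sep = "\r")
  sets <- sort(unique(key))
  idx <- match(key, sets)
  parent <- seq_along(sets)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (members in split(idx, records$variant)) {
    u <- unique(members)
    if (length(u) > 1)
      for (j in 2:length(u)) union_(u[1], u[j])
  }
  root <- vapply(seq_along(sets), find, 0L)
  comp_label <- stats::setNames(sprintf("cc%d", seq_along(unique(sort(root)))),
                                as.character(unique(sort(root))))
  parts <- do.call(rbind, strsplit(sets, "\r", fixed = TRUE))
  data.frame(dataset_id = parts[, 1], cs_id = parts[, 2],
             component = unname(comp_label[as.character(root)]),
             stringsAsFactors = FALSE)
}

#' Choose the lead variant of an independent signal
#'
#' Restricts the component's variants to those contained in the member
#' credible sets of the largest number of datasets, then picks the variant
#' with the largest absolute effect size across datasets. Remaining ties are
#' broken by genomic position, then ref/alt alleles, making the choice
#' deterministic and order-independent.
#'
#' @param component_records Long table rows of one connected component.
#' @param effect_lookup Data frame `(dataset_id, variant, beta, se)` of
#'   nominal per-dataset effects at candidate variants.
#' @param datasets Optional character vector of all dataset ids for the
#'   per-dataset effect slots (defaults to those present in
#'   `effect_lookup`).
#' @return List: `gene_id`, `lead_variant`, `support` (named count of
#'   datasets per retained variant), `member_sets` data frame,
#'   `lead_effects` (`dataset_id`, `beta`, `se`, `missing`); when no retained
#'   variant has a measured effect, `list(dropped = TRUE)` with attribute
#'   `drop_reason`.
#' @export
select_lead_variant <- function(component_records, effect_lookup,
                                datasets = NULL) {
  support <- tapply(component_records$dataset_id, component_records$variant,
                    function(d) length(unique(d)))
  retained <- names(support)[support == max(support)]
  lk <- effect_lookup[effect_lookup$variant %in% retained &
                        is.finite(effect_lookup$beta), , drop = FALSE]
  if (nrow(lk) == 0)
    return(structure(list(dropped = TRUE),
                     drop_reason = "no_measured_effect"))
  max_abs <- tapply(abs(lk$beta), lk$variant, max)
  best <- max(max_abs)
  cand <- names(max_abs)[max_abs == best]
  if (length(cand) > 1) {
    meta <- parse_variant_id(cand)
    cand <- cand[order(meta$pos, meta$ref, meta$alt)]
  }
  lead <- cand[1]
  if (is.null(datasets)) datasets <- sort(unique(effect_lookup$dataset_id))
  at_lead <- effect_lookup[effect_lookup$variant == lead, , drop = FALSE]
  i <- match(datasets, at_lead$dataset_id)
  lead_effects <- data.frame(dataset_id = datasets,
                             beta = at_lead$beta[i], se = at_lead$se[i],
                             stringsAsFactors = FALSE)
  lead_effects$missing <- !is.finite(lead_effects$beta)
  list(gene_id = component_records$gene_id[1], lead_variant = lead,
       support = support[retained],
       member_sets = unique(component_records[, c("dataset_id", "cs_id")]),
       lead_effects = lead_effects)
}

#' Harmonize credible sets into independent cross-dataset signals
#'
#' The full gene-level pipeline: filter/split the credible sets, build
#' per-gene connected components, and choose a lead variant for each
#' component. Components whose retained variants have no measured effect in
#' any dataset are dropped and counted.
#'
#' @param sets Long credible-set table across datasets.
#' @param effect_lookup Data frame `(dataset_id, variant, beta, se)`.
#' @param datasets Optional dataset universe for the effect slots.
#' @return List with `signals` (data frame: `gene_id`, `component`,
#'   `lead_variant`, `n_sets`, `n_datasets`, `max_support`), `lead_effects`
#'   (long data frame signal x dataset) and `n_dropped`.
#' @export
harmonize_signals <- function(sets, effect_lookup, datasets = NULL) {
  filtered <- filter_and_split_credible_sets(sets)
  if (nrow(filtered) == 0)
    return(list(signals = NULL, lead_effects = NULL, n_dropped = 0L))
  if (is.null(datasets)) datasets <- sort(unique(effect_lookup$dataset_id))
  sig_rows <- list()
  eff_rows <- list()
  dropped <- 0L
  for (g in sort(unique(filtered$gene_id))) {
    recs <- filtered[filtered$gene_id == g, , drop = FALSE]
    comp <- connected_components(recs)
    recs$component <- comp$component[match(
      paste(recs$dataset_id, recs$cs_id),
      paste(comp$dataset_id, comp$cs_id))]
    for (cc in sort(unique(recs$component))) {
      cr <- recs[recs$component == cc, , drop = FALSE]
      lead <- select_lead_variant(cr, effect_lookup, datasets)
      if (isTRUE(lead$dropped)) {
        dropped <- dropped + 1L
        next
      }
      signal_id <- paste(g, cc, sep = ":")
      sig_rows[[signal_id]] <- data.frame(
        signal_id = signal_id, gene_id = g, component = cc,
        lead_variant = lead$lead_variant,
        n_sets = nrow(lead$member_sets),
        n_datasets = length(unique(lead$member_sets$dataset_id)),
        max_support = max(lead$support), stringsAsFactors = FALSE)
      le <- lead$lead_effects
      le$signal_id <- signal_id
      eff_rows[[signal_id]] <- le
    }
  }
  list(signals = do.call(rbind, c(sig_rows, list(make.row.names = FALSE))),
       lead_effects = do.call(rbind, c(eff_rows, list(make.row.names = FALSE))),
       n_dropped = dropped)
}

#' Lead selection for transcript-level quantification methods
#'
#' Exon, transcript and splicing-event traits of one gene are highly
#' correlated, so instead of connected components the procedure takes, per
#' dataset, the smallest credible set (ties resolved by the largest member
#' PIP, then by set id), then picks one of the per-dataset selections per
#' gene uniformly at random, and finally chooses that set's lead variant by
#' dataset support and largest |beta| as in [select_lead_variant()].
#'
#' @param sets Long credible-set table with a `pip` column.
#' @param effect_lookup Data frame `(dataset_id, variant, beta, se)`.
#' @param seed Integer seed for the random per-gene draw.
#' @return Data frame per gene: `gene_id`, `dataset_id`, `cs_id`,
#'   `lead_variant`.
#' @export
transcript_level_lead_selection <- function(sets, effect_lookup, seed = 1L) {
  set.seed(split_seed(seed, 6L))
  out <- list()
  for (g in sort(unique(sets$gene_id))) {
    gs <- sets[sets$gene_id == g, , drop = FALSE]
    per_ds <- list()
    for (d in sort(unique(gs$dataset_id))) {
      ds <- gs[gs$dataset_id == d, , drop = FALSE]
      info <- do.call(rbind, lapply(split(ds, ds$cs_id), function(s)
        data.frame(cs_id = s$cs_id[1], size = s$cs_size[1],
                   max_pip = max(s$pip), stringsAsFactors = FALSE)))
      info <- info[order(info$size, -info$max_pip, info$cs_id), , drop = FALSE]
      per_ds[[d]] <- data.frame(dataset_id = d, cs_id = info$cs_id[1],
                                stringsAsFactors = FALSE)
    }
    per_ds <- do.call(rbind, per_ds)
    pick <- per_ds[sample.int(nrow(per_ds), 1L), , drop = FALSE]
    chosen <- gs[gs$dataset_id == pick$dataset_id & gs$cs_id == pick$cs_id, ,
                 drop = FALSE]
    lead <- select_lead_variant(chosen, effect_lookup)
    out[[g]] <- data.frame(gene_id = g, dataset_id = pick$dataset_id,
                           cs_id = pick$cs_id,
                           lead_variant = if (isTRUE(lead$dropped)) NA_character_
                                          else lead$lead_variant,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Build the lead-variant x dataset effect matrix
#'
#' Looks up each signal's lead variant in every dataset's nominal summary
#' statistics. Entries missing there (gene not expressed, variant filtered
#' out) are substituted with beta 0 and standard error 1 for the sharing
#' analyses; the missingness mask is retained alongside.
#'
#' @param signals Signals data frame from [harmonize_signals()].
#' @param effect_lookup Data frame `(dataset_id, variant, beta, se)`.
#' @param datasets Dataset universe (columns); default: those in the lookup.
#' @return List of class `"effect_matrix"`: `beta`, `se`, `missing`
#'   (signals x datasets matrices) and `policy`.
#' @export
build_effect_matrix <- function(signals, effect_lookup, datasets = NULL) {
  stopifnot(!is.null(signals), nrow(signals) >= 1)
  if (is.null(datasets)) datasets <- sort(unique(effect_lookup$dataset_id))
  nm <- list(signals$signal_id, datasets)
  beta <- se <- matrix(NA_real_, nrow(signals), length(datasets), dimnames = nm)
  key <- paste(effect_lookup$dataset_id, effect_lookup$variant)
  for (d in seq_along(datasets)) {
    i <- match(paste(datasets[d], signals$lead_variant), key)
    beta[, d] <- effect_lookup$beta[i]
    se[, d] <- effect_lookup$se[i]
  }
  missing <- !is.finite(beta)
  beta[missing] <- 0
  se[missing] <- 1
  structure(list(beta = beta, se = se, missing = missing,
                 policy = "missing_beta_to_0_se_to_1"),
            class = "effect_matrix")
}

#' Effect matrix from observed beta/se matrices
#'
#' Applies the missing-value policy of [build_effect_matrix()] (beta -> 0,
#' se -> 1, mask retained) to matrices that already have signals as rows and
#' datasets as columns, e.g. the observations of
#' [simulate_effect_matrix()].
#'
#' @param beta,se Numeric matrices with `NA` for unmeasured entries.
#' @return An `"effect_matrix"` list.
#' @export
as_effect_matrix <- function(beta, se = NULL) {
  beta <- as.matrix(beta)
  missing <- !is.finite(beta)
  beta[missing] <- 0
  if (is.null(se)) se <- matrix(1, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  se <- as.matrix(se)
  se[missing] <- 1
  structure(list(beta = beta, se = se, missing = missing,
                 policy = "missing_beta_to_0_se_to_1"),
            class = "effect_matrix")
}

#' Fraction of confidently fine-mapped sets linked to two or more genes
#'
#' @param filtered_sets Output of [filter_and_split_credible_sets()] (the
#'   size < 30 universe).
#' @return List `fraction`, `n_multi_gene`, `n_sets`.
#' @export
pleiotropy_fraction <- function(filtered_sets) {
  if (is.null(filtered_sets) || nrow(filtered_sets) == 0)
    stop("pleiotropy fraction is undefined for an empty set collection")
  key <- paste(filtered_sets$dataset_id, filtered_sets$cs_id)
  genes_per_set <- tapply(filtered_sets$gene_id, key,
                          function(g) length(unique(g)))
  list(fraction = mean(genes_per_set >= 2),
       n_multi_gene = sum(genes_per_set >= 2),
       n_sets = length(genes_per_set))
}
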