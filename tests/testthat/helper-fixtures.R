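# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# small LD-free genotype panel with fixed seed
fix_genotypes <- function(n = 100, m = 10, maf = 0.3, rho = 0, seed = 101) {
  simulate_genotypes(n, m, maf, rho, seed)
}

# long credible-set table from explicit variant lists
fix_cs_table <- function(spec_list, gene_id = "geneA") {
  # spec_list: named list cs_key -> list(dataset, variants, genes, size, z, pip)
  rows <- lapply(names(spec_list), function(k) {
    s <- spec_list[[k]]
    genes <- if (is.null(s$genes)) gene_id else s$genes
    do.call(rbind, lapply(genes, function(g)
      data.frame(dataset_id = s$dataset, molecular_trait_id = k, gene_id = g,
                 cs_id = k, variant = s$variants,
                 pip = if (is.null(s$pip)) rep(1 / length(s$variants), length(s$variants)) else s$pip,
                 z = if (is.null(s$z)) 5 else s$z,
                 cs_size = if (is.null(s$size)) length(s$variants) else s$size,
                 cs_max_z = if (is.null(s$z)) 5 else max(abs(s$z)),
                 stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}

# brute-force transitive-closure oracle for connected components:
# repeatedly merge any two groups that share a variant until stable
oracle_components <- function(variant_sets) {
  n <- length(variant_sets)
  memb <- seq_len(n)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        if (memb[a] != memb[b] &&
            length(intersect(variant_sets[[a]], variant_sets[[b]])) > 0) {
          memb[memb == memb[b]] <- memb[a]
          changed <- TRUE
        }
      }
    }
  }
  match(memb, unique(memb))   # relabel by first occurrence
}

# brute-force coloc enumeration oracle: explicit sum over causal
# configurations in linear space after rescaling by the largest ABF
oracle_coloc_pp <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- max(c(l1, l2, l1 + max(l2)))
  b1 <- exp(l1 - m / 2)
  b2 <- exp(l2 - m / 2)
  s0 <- exp(-m)
  s1 <- sum(b1) * exp(-m / 2) * p1
  s2 <- sum(b2) * exp(-m / 2) * p2
  s3 <- 0
  for (i in seq_along(l1)) for (j in seq_along(l2))
    if (i != j) s3 <- s3 + b1[i] * b2[j] * p1 * p2
  s4 <- sum(b1 * b2) * p12
  pp <- c(s0, s1, s2, s3, s4) / (s0 + s1 + s2 + s3 + s4)
  names(pp) <- paste0("PP", 0:4)
  pp
}

# brute-force greedy LD-pruning oracle for a single window
oracle_ld_prune <- function(genotypes, r2_threshold) {
  m <- ncol(genotypes)
  r2 <- suppressWarnings(cor(genotypes))^2
  r2[is.na(r2)] <- 0
  keep <- rep(TRUE, m)
  for (a in 1:(m - 1)) {
    if (!keep[a]) next
    for (b in (a + 1):m)
      if (keep[b] && r2[a, b] > r2_threshold) keep[b] <- FALSE
  }
  colnames(genotypes)[keep]
}
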