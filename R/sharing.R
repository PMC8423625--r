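#' Is a pair of effect sizes "shared"?
#'
#' Two effects count as the same eQTL signal when they have the same
#' (non-zero) sign and their magnitudes differ by at most a factor of two
#' (inclusive). Zero effects — including the zeros substituted for missing
#' entries — are never shared. Vectorized.
#'
#' @param beta_a,beta_b Finite numeric vectors.
#' @param fold Maximum allowed magnitude ratio (default 2).
#' @return Logical vector.
#' @export
pair_shared <- function(beta_a, beta_b, fold = 2) {
  if (any(!is.finite(beta_a)) || any(!is.finite(beta_b)))
    stop("effect sizes must be finite")
  same_sign <- sign(beta_a) == sign(beta_b) & beta_a != 0 & beta_b != 0
  ratio <- pmax(abs(beta_a), abs(beta_b)) / pmin(abs(beta_a), abs(beta_b))
  same_sign & ratio <= fold
}

#' Pairwise eQTL-sharing matrix between datasets
#'
#' Entry (i, j) is the fraction of eligible signals whose effects in the two
#' datasets satisfy the sign-and-twofold criterion of [pair_shared()]. Under
#' the default `"either"` policy a signal is eligible when its
#' (pre-substitution) effect is non-missing in at least one of the two
#' datasets, with the substituted zeros then counting as non-shared; the
#' `"both"` policy restricts to signals measured in both.
#'
#' @param effects An `"effect_matrix"` from [build_effect_matrix()], or a
#'   list with `beta` and logical `missing` matrices (signals x datasets).
#' @param policy `"either"` (default) or `"both"`.
#' @param fold Magnitude ratio bound passed to [pair_shared()].
#' @return List of class `"sharing_matrix"`: `values` (symmetric, diagonal
#'   1, `NA` where no signal was eligible), `n_eligible` and
#'   `denominator_policy`.
#' @export
sharing_matrix <- function(effects, policy = c("either", "both"), fold = 2) {
  policy <- match.arg(policy)
  beta <- effects$beta
  missing <- effects$missing
  if (is.null(missing)) missing <- matrix(FALSE, nrow(beta), ncol(beta))
  if (ncol(beta) < 2) stop("need at least two datasets")
  datasets <- colnames(beta)
  nd <- ncol(beta)
  vals <- matrix(NA_real_, nd, nd, dimnames = list(datasets, datasets))
  nelig <- matrix(0L, nd, nd, dimnames = list(datasets, datasets))
  diag(vals) <- 1
  for (i in seq_len(nd - 1)) {
    for (j in (i + 1):nd) {
      eligible <- if (policy == "either") !(missing[, i] & missing[, j])
                  else !missing[, i] & !missing[, j]
      nelig[i, j] <- nelig[j, i] <- sum(eligible)
      if (!any(eligible)) {
        warning("no eligible signals for pair ", datasets[i], " / ", datasets[j])
        next
      }
      shared <- pair_shared(beta[eligible, i], beta[eligible, j], fold)
      vals[i, j] <- vals[j, i] <- mean(shared)
    }
  }
  structure(list(values = vals, n_eligible = nelig,
                 denominator_policy = policy),
            class = "sharing_matrix")
}

#' Correlation distance between dataset profiles
#'
#' `1 - r` on the rows of a dataset x feature matrix, with Pearson's r for
#' expression profiles and Spearman's for effect-size columns.
#'
#' @param profiles Numeric matrix, datasets x features (>= 2 features).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric distance matrix with zero diagonal, values in [0, 2].
#' @export
correlation_distance <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("need at least two features")
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance profile(s): ",
         paste(rownames(profiles)[v == 0], collapse = ", "))
  D <- 1 - stats::cor(t(profiles), method = method)
  diag(D) <- 0
  D
}

#' Kruskal non-metric multidimensional scaling
#'
#' Minimizes Kruskal's stress-1 by alternating isotonic regression of the
#' embedded distances onto the dissimilarity ranks (pool-adjacent-violators
#' via [stats::isoreg()], primary tie treatment: tied blocks unconstrained
#' among themselves) with Guttman-transform configuration updates.
#' Initialized from classical (Torgerson) scaling by default. Iterations are
#' accepted only while stress decreases, so the reported trace is
#' non-increasing.
#'
#' @param D Symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param k Embedding dimension (default 2).
#' @param init Optional starting configuration (n x k matrix); default
#'   classical MDS.
#' @param max_iter,tol Iteration cap and minimum stress improvement.
#' @return List of class `"mds_embedding"`: `points` (n x k), `stress`
#'   (final stress-1), `stress_trace` (per accepted iteration), `k`.
#' @export
nonmetric_mds <- function(D, k = 2, init = NULL, max_iter = 500, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("D must be non-negative with a zero diagonal")
  labels <- rownames(D)
  if (all(D == 0)) {
    pts <- matrix(0, n, k)
    if (!is.null(labels)) rownames(pts) <- labels
    return(structure(list(points = pts, stress = 0, stress_trace = 0, k = k),
                     class = "mds_embedding"))
  }
  if (is.null(init)) {
    X <- suppressWarnings(stats::cmdscale(D, k = k))
    if (ncol(X) < k) X <- cbind(X, matrix(0, n, k - ncol(X)))
  } else {
    X <- as.matrix(init)
    stopifnot(nrow(X) == n, ncol(X) == k)
  }
  ut <- which(upper.tri(D))
  ij <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  edist <- function(X)
    sqrt(rowSums((X[ij[, 1], , drop = FALSE] - X[ij[, 2], , drop = FALSE])^2))
  fit_dhat <- function(e) {
    o <- order(d, e)     # primary approach: ties ordered by embedded distance
    dhat <- numeric(length(e))
    dhat[o] <- stats::isoreg(e[o])$yf
    dhat
  }
  stress1 <- function(e, dhat) {
    denom <- sum(e^2)
    if (denom == 0) return(0)
    sqrt(sum((e - dhat)^2) / denom)
  }
  e <- edist(X)
  dhat <- fit_dhat(e)
  best_stress <- stress1(e, dhat)
  trace <- best_stress
  for (iter in seq_len(max_iter)) {
    # Guttman transform with unit weights
    ratio <- ifelse(e > 0, dhat / e, 0)
    B <- matrix(0, n, n)
    B[upper.tri(B)] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    en <- edist(Xn)
    dh <- fit_dhat(en)
    s <- stress1(en, dh)
    if (!is.finite(s) || s > best_stress - tol) break
    X <- Xn; e <- en; dhat <- dh; best_stress <- s
    trace <- c(trace, s)
  }
  if (!is.null(labels)) rownames(X) <- labels
  structure(list(points = X, stress = best_stress, stress_trace = trace,
                 k = k), class = "mds_embedding")
}
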