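#' Relationship matrix container
#'
#' @param matrix symmetric numeric n x n matrix.
#' @param ids individual identifiers.
#' @param kind one of `"grm_vr1"`, `"grm_vr2"`, `"grm_alpha"`,
#'   `"pedigree_A"`, `"custom"`.
#' @param meta named list of construction metadata (frequencies used, alpha,
#'   denominator, variant count).
#' @return a `relationship_matrix` list.
#' @export
relationship_matrix <- function(matrix, ids, kind = "custom", meta = list()) {
  matrix <- as.matrix(matrix)
  ids <- as.character(ids)
  stopifnot(nrow(matrix) == ncol(matrix), nrow(matrix) == length(ids))
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix)))) {
    stop("relationship matrix is not symmetric")
  }
  matrix <- (matrix + t(matrix)) / 2
  dimnames(matrix) <- list(ids, ids)
  structure(list(matrix = matrix, ids = ids, kind = kind, meta = meta),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix (%s): %d individuals; mean diag %.4f\n",
              x$kind, length(x$ids), mean(diag(x$matrix))))
  invisible(x)
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' `G = (X - 2p1')(X - 2p1')' / (2 sum p_j (1 - p_j))` where `X` is the
#' dosage matrix and `p` the alt-allele frequencies. This scaling makes `G`
#' comparable to the pedigree numerator relationship matrix. Missing dosages
#' are mean-imputed per variant before centering.
#'
#' @param g a `genotype_matrix`.
#' @param freqs alt-allele frequencies for centering; defaults to the
#'   frequencies observed in the analyzed sample.
#' @return a `relationship_matrix` of kind `"grm_vr1"`.
#' @export
grm_vanraden1 <- function(g, freqs = NULL) {
  if (is.null(freqs)) freqs <- alt_freq(g)
  if (length(freqs) != n_variants(g)) stop("freqs length mismatch")
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all variants monomorphic: zero VanRaden denominator")
  X <- impute_mean(g$dosages)
  W <- sweep(X, 2, 2 * freqs)
  G <- tcrossprod(W) / denom
  relationship_matrix(G, g$individual_ids, kind = "grm_vr1",
                      meta = list(freqs = freqs, denominator = denom,
                                  n_variants = n_variants(g)))
}

#' Alpha-scaled genomic relationship matrix
#'
#' Columns of the working matrix are
#' `W_j = (S_j - 2 f_j) * (2 f_j (1 - f_j))^(alpha/2)` and
#' `G = W W' / m`. `alpha = -1` standardizes every variant (VanRaden method
#' 2, weighting rare variants more); `alpha = 0` reproduces VanRaden method
#' 1 up to the global scale `m` versus `2 sum f (1 - f)`.
#'
#' @param g a `genotype_matrix`.
#' @param freqs alt-allele frequencies (defaults to observed).
#' @param alpha scaling exponent (0 = animal/plant convention, -1 = human
#'   convention; intermediate values such as -0.25 are allowed).
#' @return a `relationship_matrix` of kind `"grm_vr2"` (`alpha = -1`) or
#'   `"grm_alpha"`.
#' @export
grm_alpha <- function(g, freqs = NULL, alpha = -1) {
  if (is.null(freqs)) freqs <- alt_freq(g)
  if (length(freqs) != n_variants(g)) stop("freqs length mismatch")
  if (alpha < 0 && any(freqs <= 0 | freqs >= 1)) {
    stop("monomorphic variant with negative alpha: infinite weight")
  }
  m <- n_variants(g)
  X <- impute_mean(g$dosages)
  w <- (2 * freqs * (1 - freqs))^(alpha / 2)
  W <- sweep(X, 2, 2 * freqs) %*% diag(w, m)
  G <- tcrossprod(W) / m
  relationship_matrix(G, g$individual_ids,
                      kind = if (alpha == -1) "grm_vr2" else "grm_alpha",
                      meta = list(freqs = freqs, alpha = alpha, n_variants = m))
}

#' VanRaden method 2 GRM
#'
#' Convenience wrapper: [grm_alpha()] with `alpha = -1` (each standardized
#' variant weighted equally, i.e. rare variants contribute relatively more).
#'
#' @inheritParams grm_alpha
#' @return a `relationship_matrix` of kind `"grm_vr2"`.
#' @export
grm_vanraden2 <- function(g, freqs = NULL) grm_alpha(g, freqs, alpha = -1)

#' Pedigree numerator relationship matrix (tabular method)
#'
#' `a_ii = 1 + a(sire, dam)/2`; `a_ij = (a(j, sire_i) + a(j, dam_i))/2` for
#' `j` preceding `i`; an unknown parent contributes zero.
#'
#' @param ped a `pedigree` (topologically ordered; see [as_pedigree()]).
#' @return a `relationship_matrix` of kind `"pedigree_A"`.
#' @export
a_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      js <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[js, s] else rep(0, i - 1)
      ad_ <- if (!is.na(d)) A[js, d] else rep(0, i - 1)
      A[js, i] <- A[i, js] <- 0.5 * (as_ + ad_)
    }
  }
  relationship_matrix(A, ped$id, kind = "pedigree_A")
}

#' Align a relationship matrix to a set of individuals
#'
#' @param K a `relationship_matrix`.
#' @param ids individual ids to keep, in order.
#' @return the restricted `relationship_matrix`.
#' @export
align_relmat <- function(K, ids) {
  m <- match(ids, K$ids)
  if (anyNA(m)) stop("individual(s) missing from relationship matrix: ",
                     paste(ids[is.na(m)][1:min(3, sum(is.na(m)))], collapse = ", "))
  relationship_matrix(K$matrix[m, m, drop = FALSE], ids, K$kind, K$meta)
}

#' Correlation of GRM off-diagonals
#'
#' Pearson correlation over the strict lower triangles of two relationship
#' matrices built on the same individuals in the same order.
#'
#' @param K1,K2 `relationship_matrix` objects.
#' @return correlation in `[-1, 1]`.
#' @export
grm_offdiag_correlation <- function(K1, K2) {
  if (!identical(K1$ids, K2$ids)) {
    stop("relationship matrices are over different (or reordered) individuals")
  }
  n <- length(K1$ids)
  if (n < 3) stop("need at least 3 individuals for an off-diagonal correlation")
  lt <- lower.tri(K1$matrix)
  as.numeric(stats::cor(K1$matrix[lt], K2$matrix[lt]))
}

#' Rescale a variance estimate to the analyzed population's base
#'
#' Variances estimated under different relationship matrices (pedigree A
#' versus a sample-centered GRM) refer to different base populations. The
#' comparison rule used here multiplies the estimate by
#' `mean(diag(K)) - mean(K)`, expressing it as genetic variance within the
#' analyzed sample. A VanRaden-1 GRM centered at sample frequencies already
#' has a factor near one.
#'
#' @param sigma2 nonnegative variance estimate obtained under `K`.
#' @param K the `relationship_matrix` the variance was estimated with,
#'   aligned to the phenotyped sample.
#' @return the rescaled variance.
#' @export
rescale_to_base <- function(sigma2, K) {
  stopifnot(sigma2 >= 0)
  f <- mean(diag(K$matrix)) - mean(K$matrix)
  if (f <= 0) stop("degenerate relationship structure: mean(diag) - mean <= 0")
  sigma2 * f
}
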