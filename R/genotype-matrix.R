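#' Genotype matrix container
#'
#' Holds an individuals-by-variants dosage matrix (alt-allele counts in
#' `[0, 2]`, possibly fractional for imputed data, `NA` for missing) together
#' with a variant table carrying coordinates and alleles.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#'   Positions are 1-based and must be nondecreasing within chromosome.
#' @param individual_ids character vector of unique individual identifiers.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` and `individual_ids`.
#' @export
genotype_matrix <- function(dosages, variants, individual_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind", seq_len(nrow(dosages)))
  }
  individual_ids <- as.character(individual_ids)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(variants) != ncol(dosages)) {
    stop("variant table has ", nrow(variants), " rows but dosage matrix has ",
         ncol(dosages), " columns")
  }
  if (length(individual_ids) != nrow(dosages)) {
    stop("individual_ids length does not match dosage rows")
  }
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  if (anyDuplicated(variants$id)) stop("duplicated variant ids")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) {
      stop("positions not nondecreasing within chromosome ", ch)
    }
  }
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]")
  }
  rownames(dosages) <- individual_ids
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants, individual_ids = individual_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants on %d chromosome(s)\n",
              n_individuals(x), n_variants(x), length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosages: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of individuals / variants
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(g) nrow(g$dosages)

#' @rdname n_individuals
#' @export
n_variants <- function(g) ncol(g$dosages)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param individuals index vector over individuals (logical, integer or ids).
#' @param variants index vector over variants (logical, integer or ids).
#' @return a new `genotype_matrix`.
#' @export
subset_genotypes <- function(g, individuals = NULL, variants = NULL) {
  ii <- resolve_index(individuals, g$individual_ids, "individual")
  vi <- resolve_index(variants, g$variants$id, "variant")
  genotype_matrix(g$dosages[ii, vi, drop = FALSE],
                  g$variants[vi, , drop = FALSE],
                  g$individual_ids[ii])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    m <- match(idx, ids)
    if (anyNA(m)) stop("unknown ", what, " id(s): ",
                       paste(idx[is.na(m)][1:min(3, sum(is.na(m)))], collapse = ", "))
    return(m)
  }
  if (is.logical(idx)) {
    if (length(idx) != length(ids)) stop(what, " logical index has wrong length")
    return(which(idx))
  }
  as.integer(idx)
}

#' Alternate-allele frequency per variant
#'
#' The (unfolded) frequency of the alternate allele, `mean(dosage) / 2` over
#' non-missing entries.
#'
#' @param g a `genotype_matrix`.
#' @return numeric vector of frequencies in `[0, 1]`, named by variant id.
#' @export
alt_freq <- function(g) {
  f <- colMeans(g$dosages, na.rm = TRUE) / 2
  all_missing <- colSums(!is.na(g$dosages)) == 0
  if (any(all_missing)) {
    stop("variant(s) with all dosages missing: ",
         paste(g$variants$id[all_missing][1:min(3, sum(all_missing))], collapse = ", "))
  }
  f
}

#' Minor-allele frequency per variant
#'
#' MAF is the folded allele frequency `min(f, 1 - f)` where `f` is the mean
#' dosage over non-missing entries divided by two.
#'
#' @param g a `genotype_matrix`.
#' @return numeric vector of MAF values in `[0, 0.5]`, named by variant id.
#' @export
compute_maf <- function(g) {
  f <- alt_freq(g)
  pmin(f, 1 - f)
}

# Mean-impute missing dosages per variant (used inside GRM/LD computations
# only; never persisted back into the container).
impute_mean <- function(dos) {
  if (!anyNA(dos)) return(dos)
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2]]
  dos
}
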