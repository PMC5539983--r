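#' Chi-square test for Hardy-Weinberg proportions
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the proportions (p^2, 2pq, q^2) expected at the sample allele
#' frequency, without continuity correction.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote).
#' @return list with `chi_square` and `p_value`. Monomorphic input returns
#'   `chi_square = 0`, `p_value = 1` and `monomorphic = TRUE`.
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE: chi-square 0, p = 1
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) {
    return(list(chi_square = 0, p_value = 1, monomorphic = TRUE))
  }
  expected <- n * c(p^2, 2 * p * q, q^2)
  observed <- c(n_AA, n_Aa, n_aa)
  chi <- sum((observed - expected)^2 / expected)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies the standard array-QC filters in a fixed order: individual call
#' rate, locus call rate, monomorphic loci, Hardy-Weinberg deviation, and
#' minimum MAF. Locus statistics (call rate, HWE, MAF) are computed on the
#' individuals retained by the first step. For the HWE count step only,
#' fractional dosages are rounded to the nearest integer genotype; retained
#' dosages stay fractional.
#'
#' @param g a `genotype_matrix`.
#' @param min_individual_call_rate drop individuals with a lower fraction of
#'   non-missing genotypes (default 0.85).
#' @param min_locus_call_rate drop variants with a lower fraction of
#'   non-missing genotypes among retained individuals (default 0.95).
#' @param hwe_p_min drop variants whose HWE test p-value is below this
#'   (default 1e-5).
#' @param maf_min drop variants with MAF below this (default 0.001).
#' @return list with the filtered `genotypes` and a `report` (class
#'   `qc_report`) itemizing removals per step and the thresholds used.
#' @export
qc_filter <- function(g,
                      min_individual_call_rate = 0.85,
                      min_locus_call_rate = 0.95,
                      hwe_p_min = 1e-5,
                      maf_min = 0.001) {
  n0 <- n_individuals(g)
  m0 <- n_variants(g)

  ind_cr <- rowMeans(!is.na(g$dosages))
  keep_ind <- ind_cr >= min_individual_call_rate
  if (!any(keep_ind)) stop("all individuals removed by the call-rate filter")
  n_ind_removed <- sum(!keep_ind)
  g <- subset_genotypes(g, individuals = keep_ind)

  loc_cr <- colMeans(!is.na(g$dosages))
  keep_cr <- loc_cr >= min_locus_call_rate
  n_cr_removed <- sum(!keep_cr)
  g <- subset_genotypes(g, variants = keep_cr)

  f <- alt_freq(g)
  keep_poly <- f > 0 & f < 1
  n_mono_removed <- sum(!keep_poly)
  g <- subset_genotypes(g, variants = keep_poly)

  hwe_p <- hwe_pvalues(g)
  keep_hwe <- hwe_p >= hwe_p_min
  n_hwe_removed <- sum(!keep_hwe)
  g <- subset_genotypes(g, variants = keep_hwe)

  maf <- compute_maf(g)
  keep_maf <- maf >= maf_min
  n_maf_removed <- sum(!keep_maf)
  g <- subset_genotypes(g, variants = keep_maf)

  report <- structure(list(
    thresholds = list(min_individual_call_rate = min_individual_call_rate,
                      min_locus_call_rate = min_locus_call_rate,
                      hwe_p_min = hwe_p_min,
                      maf_min = maf_min),
    input = c(individuals = n0, variants = m0),
    removed = c(individual_call_rate = n_ind_removed,
                locus_call_rate = n_cr_removed,
                monomorphic = n_mono_removed,
                hwe = n_hwe_removed,
                maf = n_maf_removed),
    retained = c(individuals = n_individuals(g), variants = n_variants(g))
  ), class = "qc_report")

  list(genotypes = g, report = report)
}

hwe_pvalues <- function(g) {
  rounded <- round(g$dosages)
  vapply(seq_len(n_variants(g)), function(j) {
    d <- rounded[, j]
    d <- d[!is.na(d)]
    hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))$p_value
  }, numeric(1))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input:    %d individuals, %d variants\n",
              x$input["individuals"], x$input["variants"]))
  for (step in names(x$removed)) {
    cat(sprintf("  removed (%s): %d\n", step, x$removed[step]))
  }
  cat(sprintf("  retained: %d individuals, %d variants\n",
              x$retained["individuals"], x$retained["variants"]))
  invisible(x)
}

#' Write a QC report as tab-separated text
#' @param report a `qc_report`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(step = names(report$removed),
                   removed = as.integer(report$removed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thresholds: %s",
                     paste(names(report$thresholds),
                           unlist(report$thresholds), sep = "=", collapse = " ")), con)
  writeLines(sprintf("# input: individuals=%d variants=%d",
                     report$input["individuals"], report$input["variants"]), con)
  writeLines(sprintf("# retained: individuals=%d variants=%d",
                     report$retained["individuals"], report$retained["variants"]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
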