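#' MAF class boundaries
#'
#' Default: the seven classes 0.001-0.01, 0.01-0.05, 0.05-0.1, 0.1-0.2,
#' 0.2-0.3, 0.3-0.4 and 0.4-0.5. Intervals are lower-inclusive and
#' upper-exclusive except the last, which is closed at 0.5.
#'
#' @param boundaries strictly increasing numeric vector; first >= 0, last
#'   must be 0.5.
#' @return a `maf_class_spec` with `boundaries` and `labels`.
#' @export
maf_class_spec <- function(boundaries = c(0.001, 0.01, 0.05, 0.1, 0.2, 0.3,
                                          0.4, 0.5)) {
  stopifnot(length(boundaries) >= 2, !is.unsorted(boundaries, strictly = TRUE),
            boundaries[1] >= 0, boundaries[length(boundaries)] == 0.5)
  k <- length(boundaries) - 1
  labels <- paste0(boundaries[-length(boundaries)], "-", boundaries[-1])
  structure(list(boundaries = boundaries, labels = labels, n_classes = k),
            class = "maf_class_spec")
}

maf_class_labels <- function(mafs, spec, clamp = FALSE) {
  if (clamp) mafs <- pmax(mafs, spec$boundaries[1])
  if (any(mafs < spec$boundaries[1])) {
    stop("MAF below the first class boundary (", spec$boundaries[1],
         "); such variants should have been removed by QC")
  }
  k <- findInterval(mafs, spec$boundaries, rightmost.closed = TRUE)
  factor(spec$labels[k], levels = spec$labels)
}

#' Assign variants to MAF classes
#'
#' @param mafs numeric vector of minor allele frequencies.
#' @param spec a `maf_class_spec`.
#' @return a `variant_partition` data.frame with columns `maf` and
#'   `maf_class` (factor over all class labels).
#' @export
assign_maf_classes <- function(mafs, spec = maf_class_spec()) {
  part <- data.frame(maf = as.numeric(mafs),
                     maf_class = maf_class_labels(mafs, spec))
  if (!is.null(names(mafs))) part$id <- names(mafs)
  class(part) <- c("variant_partition", "data.frame")
  attr(part, "spec") <- spec
  part
}

#' Squared-correlation LD between two dosage columns
#'
#' `r^2` is the squared Pearson correlation of dosages over individuals
#' non-missing in both columns.
#'
#' @param x_j,x_k numeric dosage vectors of equal length.
#' @return `r^2` in `[0, 1]`.
#' @export
ld_r2 <- function(x_j, x_k) {
  ok <- !is.na(x_j) & !is.na(x_k)
  x <- x_j[ok]; y <- x_k[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("monomorphic column in ld_r2")
  }
  r <- as.numeric(stats::cor(x, y))
  r * r
}

#' Windowed LD scores
#'
#' The LD score of variant `j` is the sum of `r^2` between `j` and every
#' other variant on the same chromosome within `window_bp / 2` base pairs of
#' it (a `window_bp`-wide region centered on the variant; the variant itself
#' is excluded). Missing dosages are mean-imputed before correlation;
#' monomorphic variants receive an LD score of 0 and contribute 0.
#'
#' @param g a `genotype_matrix`, variants sorted by position within
#'   chromosome.
#' @param window_bp window width in base pairs (default 20 Mb).
#' @return an `ld_score_table` data.frame: `id`, `chrom`, `pos`, `ld_score`.
#' @export
ld_scores <- function(g, window_bp = 2e7) {
  dos <- impute_mean(g$dosages)
  n <- nrow(dos)
  sds <- apply(dos, 2, stats::sd)
  Z <- dos
  poly <- sds > 0
  Z[, poly] <- scale(dos[, poly, drop = FALSE])
  Z[, !poly] <- 0
  half <- window_bp / 2
  score <- numeric(ncol(dos))
  for (ch in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == ch)
    pos <- g$variants$pos[idx]
    Zc <- Z[, idx, drop = FALSE]
    for (a in seq_along(idx)) {
      if (!poly[idx[a]]) next
      w <- which(abs(pos - pos[a]) <= half)
      w <- w[w != a]
      if (!length(w)) next
      r <- crossprod(Zc[, w, drop = FALSE], Zc[, a]) / (n - 1)
      score[idx[a]] <- sum(r * r)
    }
  }
  out <- data.frame(id = g$variants$id, chrom = g$variants$chrom,
                    pos = g$variants$pos, ld_score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("ld_score_table", "data.frame")
  out
}

#' Segment-mean LD scores
#'
#' Splits each chromosome into consecutive position-ordered segments of
#' `s = round(2 * m_chr / n_windows)` variants, where `n_windows` is the
#' chromosome span in 100-kb windows (span = max - min position, at least
#' one window) — i.e. each segment holds about twice the average number of
#' variants per 100-kb window. Each variant is annotated with the mean raw
#' LD score of its segment.
#'
#' @param table an `ld_score_table` from [ld_scores()].
#' @return the table with added columns `segment` and `segment_mean_ld`.
#' @export
segment_mean_ld <- function(table) {
  table$segment <- NA_character_
  table$segment_mean_ld <- NA_real_
  for (ch in unique(table$chrom)) {
    idx <- which(table$chrom == ch)
    m_chr <- length(idx)
    span <- max(table$pos[idx]) - min(table$pos[idx])
    n_windows <- max(1, span / 1e5)
    s <- round(2 * m_chr / n_windows)
    if (s < 1) {
      stop("segment size below 1 on chromosome ", ch,
           " (too few variants for the 100-kb rule)")
    }
    ord <- idx[order(table$pos[idx])]
    seg_no <- ceiling(seq_along(ord) / s)
    for (sg in unique(seg_no)) {
      members <- ord[seg_no == sg]
      table$segment[members] <- paste0(ch, "_seg", sg)
      table$segment_mean_ld[members] <- mean(table$ld_score[members])
    }
  }
  table
}

#' Stratify variants into LD groups within MAF classes
#'
#' Within each MAF class, variants are ordered by segment-mean LD score
#' (position as tie-breaker) and split into `n_groups` contiguous groups
#' whose sizes differ by at most one; when the class size is not divisible,
#' the extra variants go to the lowest-LD groups. A class with fewer
#' variants than `n_groups` keeps a single group (with a warning).
#'
#' @param partition a `variant_partition` from [assign_maf_classes()].
#' @param table an `ld_score_table` with segment means
#'   (see [segment_mean_ld()]), rows aligned with `partition`.
#' @param n_groups number of LD groups per MAF class (3 or 4).
#' @return the partition with added columns `ld_group` (integer, 1 =
#'   lowest LD) and `group` (`"<maf_class>:LD<k>"` label).
#' @export
stratify_ld_groups <- function(partition, table, n_groups = 4) {
  stopifnot(n_groups %in% c(3, 4))
  if (nrow(partition) != nrow(table)) {
    stop("partition and LD table have different numbers of variants")
  }
  if (is.null(table$segment_mean_ld)) {
    stop("LD table lacks segment means; run segment_mean_ld() first")
  }
  partition$ld_group <- NA_integer_
  for (cl in levels(partition$maf_class)) {
    members <- which(partition$maf_class == cl)
    sz <- length(members)
    if (sz == 0) next
    if (sz < n_groups) {
      warning("MAF class ", cl, " has fewer variants (", sz, ") than LD groups; ",
              "keeping a single group")
      partition$ld_group[members] <- 1L
      next
    }
    ord <- members[order(table$segment_mean_ld[members], table$pos[members])]
    base <- sz %/% n_groups
    extra <- sz %% n_groups
    sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
    partition$ld_group[ord] <- rep(seq_len(n_groups), sizes)
  }
  partition$group <- ifelse(is.na(partition$ld_group),
                            NA_character_,
                            paste0(as.character(partition$maf_class), ":LD",
                                   partition$ld_group))
  partition
}

#' Write a variant partition / LD table as tab-separated text
#' @param partition a `variant_partition` (optionally LD-stratified).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(as.data.frame(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
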