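#' Simulation configuration for cattle-like genotypes
#'
#' The generator induces long-range LD by haplotype copying from a small
#' founder pool: every sampled haplotype is a mosaic of founder-pool
#' haplotypes with Poisson-distributed switch points. A small pool yields the
#' long-range LD typical of intensively selected cattle populations (LD
#' scores well above human levels); a large pool with a high switch rate
#' approaches linkage equilibrium.
#'
#' @param n_individuals number of individuals to sample.
#' @param n_variants total number of variants across all chromosomes.
#' @param n_chromosomes number of chromosomes (variants split evenly).
#' @param chromosome_length_bp length of each chromosome in base pairs.
#' @param maf_spectrum target allele-frequency spectrum: `spectrum_uniform()`,
#'   `spectrum_neutral()` or `spectrum_beta()`.
#' @param founder_pool_size number of founder-pool diploid members (>= 2);
#'   2 x this many haplotypes are generated.
#' @param switch_rate haplotype-copying switch rate per base pair (>= 0).
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals, n_variants, n_chromosomes = 1,
                       chromosome_length_bp = 1e8,
                       maf_spectrum = spectrum_neutral(),
                       founder_pool_size = 20,
                       switch_rate = 1e-8,
                       seed = 1L) {
  stopifnot(n_individuals >= 1, n_variants >= 1, n_chromosomes >= 1,
            chromosome_length_bp >= n_variants / n_chromosomes,
            founder_pool_size >= 2, switch_rate >= 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = as.integer(chromosome_length_bp),
                 maf_spectrum = maf_spectrum,
                 founder_pool_size = as.integer(founder_pool_size),
                 switch_rate = switch_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Allele-frequency spectra
#'
#' `spectrum_uniform(lo, hi)` draws target MAF uniformly on `[lo, hi]`;
#' `spectrum_neutral()` draws from the density proportional to `1/x`
#' truncated to `[0.001, 0.5]` (the neutral site-frequency-spectrum shape,
#' strongly enriched for rare alleles); `spectrum_beta(a, b)` draws from a
#' Beta and folds to `[0.001, 0.5]`.
#'
#' @param lo,hi bounds in `(0, 0.5]`.
#' @param a,b Beta shape parameters.
#' @return a spectrum specification list.
#' @export
spectrum_uniform <- function(lo = 0.001, hi = 0.5) {
  stopifnot(lo > 0, lo <= hi, hi <= 0.5)
  list(kind = "uniform", lo = lo, hi = hi)
}

#' @rdname spectrum_uniform
#' @export
spectrum_neutral <- function(lo = 0.001, hi = 0.5) {
  stopifnot(lo > 0, lo < hi, hi <= 0.5)
  list(kind = "neutral", lo = lo, hi = hi)
}

#' @rdname spectrum_uniform
#' @export
spectrum_beta <- function(a = 0.5, b = 0.5) {
  stopifnot(a > 0, b > 0)
  list(kind = "beta", a = a, b = b)
}

draw_target_freqs <- function(spectrum, m) {
  switch(spectrum$kind,
    uniform = stats::runif(m, spectrum$lo, spectrum$hi),
    neutral = {
      # inverse-CDF sample from density 1/x on [lo, hi]
      u <- stats::runif(m)
      spectrum$lo * (spectrum$hi / spectrum$lo)^u
    },
    beta = {
      f <- stats::rbeta(m, spectrum$a, spectrum$b)
      f <- pmin(f, 1 - f)
      pmin(pmax(f, 0.001), 0.5)
    },
    stop("unknown spectrum kind: ", spectrum$kind)
  )
}

#' Simulate founder-pool haplotypes
#'
#' Draws variant positions (sorted uniform per chromosome) and target minor
#' allele frequencies from the configured spectrum, then samples
#' `2 * founder_pool_size` binary haplotypes with independent Bernoulli
#' alleles at the target frequency. Columns whose realized alt frequency
#' exceeds 0.5 are folded (allele labels swapped) so realized frequencies lie
#' in `[0, 0.5]`.
#'
#' @param config a `sim_config`.
#' @return list with `haplotypes` (2*pool x m binary matrix), `variants`
#'   (coordinate table) and `target_maf`.
#' @export
simulate_founder_haplotypes <- function(config) {
  set.seed(config$seed)
  m <- config$n_variants
  per_chr <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k) {
    sort(sample.int(config$chromosome_length_bp, k, replace = FALSE))
  }))
  target <- draw_target_freqs(config$maf_spectrum, m)
  h <- 2L * config$founder_pool_size
  hap <- matrix(stats::rbinom(h * m, 1L, rep(target, each = h)), nrow = h)
  realized <- colMeans(hap)
  flip <- realized > 0.5
  hap[, flip] <- 1L - hap[, flip]
  variants <- data.frame(id = paste0("var", seq_len(m)), chrom = chrom,
                         pos = pos,
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  list(haplotypes = hap, variants = variants, target_maf = target)
}

# Sample one mosaic haplotype by copying from the founder pool with Poisson
# switch points along each chromosome. Returns a vector over all variants.
copy_haplotype <- function(founders, variants, switch_rate) {
  m <- ncol(founders$haplotypes)
  out <- integer(m)
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    pos <- variants$pos[idx]
    span <- max(pos) - min(pos)
    n_switch <- stats::rpois(1, switch_rate * span)
    breaks <- sort(stats::runif(n_switch, min(pos), max(pos)))
    seg <- findInterval(pos, breaks) + 1L
    donors <- sample.int(nrow(founders$haplotypes), n_switch + 1L, replace = TRUE)
    out[idx] <- founders$haplotypes[cbind(donors[seg], idx)]
  }
  out
}

#' Simulate unrelated individuals by haplotype copying
#'
#' Each individual receives two mosaic haplotypes copied from the founder
#' pool; dosage is their sum.
#'
#' @param config a `sim_config`.
#' @return list with the `genotype_matrix` (`genotypes`) and the founder set
#'   (`founders`).
#' @export
simulate_genotypes <- function(config) {
  founders <- simulate_founder_haplotypes(config)
  # simulate_founder_haplotypes leaves the RNG seeded; keep drawing from it
  n <- config$n_individuals
  m <- config$n_variants
  dos <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    dos[i, ] <- copy_haplotype(founders, founders$variants, config$switch_rate) +
      copy_haplotype(founders, founders$variants, config$switch_rate)
  }
  g <- genotype_matrix(dos, founders$variants,
                       sprintf("ind%04d", seq_len(n)))
  list(genotypes = g, founders = founders)
}

#' Simulate a multi-generation pedigree
#'
#' Founders are unrelated; each later generation is produced by sampling
#' sire/dam pairs (without self-mating) from the previous generation, each
#' pair leaving `offspring_per_mating` offspring. Records are topologically
#' ordered: parents always precede offspring.
#'
#' @param n_founders number of founder individuals (>= 2).
#' @param n_generations number of descendant generations (0 = founders only).
#' @param offspring_per_mating offspring per sampled pair.
#' @param n_matings_per_generation number of pairs sampled per generation
#'   (default: enough to keep the generation size near `n_founders`).
#' @param seed integer seed.
#' @return a `pedigree` data.frame with columns `id`, `sire`, `dam`,
#'   `generation` (`NA` parent = unknown).
#' @export
simulate_pedigree <- function(n_founders, n_generations = 0,
                              offspring_per_mating = 1,
                              n_matings_per_generation = NULL,
                              seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 0, offspring_per_mating >= 1)
  set.seed(seed)
  if (is.null(n_matings_per_generation)) {
    n_matings_per_generation <- max(1L, round(n_founders / offspring_per_mating))
  }
  id <- sprintf("F%04d", seq_len(n_founders))
  ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    generation = 0L, stringsAsFactors = FALSE)
  prev <- id
  counter <- 0L
  for (gen in seq_len(n_generations)) {
    kids <- character(0); sires <- character(0); dams <- character(0)
    for (k in seq_len(n_matings_per_generation)) {
      pair <- sample(prev, 2, replace = FALSE)
      for (o in seq_len(offspring_per_mating)) {
        counter <- counter + 1L
        kids <- c(kids, sprintf("G%d_%04d", gen, counter))
        sires <- c(sires, pair[1]); dams <- c(dams, pair[2])
      }
    }
    ped <- rbind(ped, data.frame(id = kids, sire = sires, dam = dams,
                                 generation = gen, stringsAsFactors = FALSE))
    prev <- kids
  }
  as_pedigree(ped)
}

#' Validate and class a pedigree table
#'
#' @param df data.frame with columns `id`, `sire`, `dam` (NA = unknown),
#'   topologically ordered.
#' @return the validated data.frame with class `pedigree`.
#' @export
as_pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  if (anyDuplicated(df$id)) stop("duplicated pedigree id")
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    for (p in c(df$sire[i], df$dam[i])) {
      if (!is.na(p)) {
        if (p == df$id[i]) stop("individual ", p, " is its own parent")
        if (!(p %in% seen)) {
          stop("pedigree not topologically ordered (or cyclic): parent ", p,
               " of ", df$id[i], " does not precede it")
        }
      }
    }
    seen <- c(seen, df$id[i])
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Drop genes down a pedigree
#'
#' Pedigree founders receive two mosaic haplotypes copied from the founder
#' pool; every non-founder receives one recombinant gamete from each parent
#' (Poisson crossovers at `recombination_rate_per_bp`, random starting
#' phase, per chromosome). Offspring genotypes are Mendelian-consistent with
#' their parents at every locus by construction.
#'
#' @param pedigree a `pedigree`.
#' @param founder_haplotypes output of [simulate_founder_haplotypes()].
#' @param recombination_rate_per_bp crossover rate per base pair (cattle-like
#'   default 1e-8, ~1 cM/Mb).
#' @param switch_rate haplotype-copying switch rate used to build pedigree
#'   founder haplotypes from the pool.
#' @param seed integer seed.
#' @return a `genotype_matrix` over all pedigree members, plus the phased
#'   haplotypes as an attribute `haplotypes` (list of 2-row matrices).
#' @export
gene_drop <- function(pedigree, founder_haplotypes,
                      recombination_rate_per_bp = 1e-8,
                      switch_rate = 1e-8, seed = 1L) {
  set.seed(seed)
  variants <- founder_haplotypes$variants
  m <- nrow(variants)
  n <- nrow(pedigree)
  haps <- vector("list", n)
  names(haps) <- pedigree$id
  for (i in seq_len(n)) {
    sire <- pedigree$sire[i]; dam <- pedigree$dam[i]
    if (is.na(sire) && is.na(dam)) {
      haps[[i]] <- rbind(
        copy_haplotype(founder_haplotypes, variants, switch_rate),
        copy_haplotype(founder_haplotypes, variants, switch_rate))
    } else if (!is.na(sire) && !is.na(dam)) {
      haps[[i]] <- rbind(make_gamete(haps[[sire]], variants,
                                     recombination_rate_per_bp),
                         make_gamete(haps[[dam]], variants,
                                     recombination_rate_per_bp))
    } else {
      stop("individual ", pedigree$id[i], " has exactly one known parent; ",
           "both or neither required")
    }
  }
  dos <- t(vapply(haps, colSums, numeric(m)))
  g <- genotype_matrix(dos, variants, pedigree$id)
  attr(g, "haplotypes") <- haps
  g
}

make_gamete <- function(parent_haps, variants, rate) {
  m <- ncol(parent_haps)
  gam <- integer(m)
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    pos <- variants$pos[idx]
    span <- max(pos) - min(pos)
    n_x <- stats::rpois(1, rate * span)
    breaks <- sort(stats::runif(n_x, min(pos), max(pos)))
    seg <- findInterval(pos, breaks)
    phase <- (seg + sample.int(2, 1)) %% 2L + 1L
    gam[idx] <- parent_haps[cbind(phase, idx)]
  }
  gam
}

#' Genetic-architecture configuration
#'
#' @param n_causal number of causal variants.
#' @param alpha effect-size scaling exponent: causal effect variance is
#'   proportional to `(2p(1-p))^alpha`. `alpha = 0` (the animal/plant
#'   genetics convention) gives every causal variant the same expected
#'   per-allele effect; `alpha = -1` (the human-genetics convention) gives
#'   every standardized causal variant the same expected variance
#'   contribution.
#' @param target_h2 total genetic variance of the true breeding values, in
#'   DRP-variance units (see Details of [simulate_phenotypes()]).
#' @param per_class_variance_fractions optional named numeric vector of
#'   per-MAF-class genetic variances (same units); overrides `target_h2`.
#'   Names are MAF-class labels from [maf_class_spec()].
#' @param large_qtl optional `list(maf =, fraction_of_variance =)`: plant one
#'   large QTL at the variant whose MAF is nearest `maf`, explaining the
#'   given fraction of the total genetic variance.
#' @param reliability_lo,reliability_hi reliabilities drawn uniformly from
#'   `[lo, hi]`, within (0, 1].
#' @param seed integer seed.
#' @return an `arch_config` list.
#' @export
arch_config <- function(n_causal, alpha = 0, target_h2 = 0.5,
                        per_class_variance_fractions = NULL,
                        large_qtl = NULL,
                        reliability_lo = 0.9, reliability_hi = 0.99,
                        seed = 1L) {
  stopifnot(n_causal >= 0, target_h2 >= 0, target_h2 <= 1,
            reliability_lo > 0, reliability_lo <= reliability_hi,
            reliability_hi <= 1)
  if (!is.null(per_class_variance_fractions)) {
    if (any(per_class_variance_fractions < 0)) {
      stop("per-class variance fractions must be nonnegative")
    }
    if (sum(per_class_variance_fractions) > 1) {
      stop("per-class variance fractions sum to more than 1")
    }
  }
  if (!is.null(large_qtl)) {
    stopifnot(is.list(large_qtl), large_qtl$maf > 0, large_qtl$maf <= 0.5,
              large_qtl$fraction_of_variance > 0,
              large_qtl$fraction_of_variance < 1)
  }
  structure(list(n_causal = as.integer(n_causal), alpha = alpha,
                 target_h2 = target_h2,
                 per_class_variance_fractions = per_class_variance_fractions,
                 large_qtl = large_qtl,
                 reliability_lo = reliability_lo,
                 reliability_hi = reliability_hi,
                 seed = as.integer(seed)),
            class = "arch_config")
}

#' Simulate DRP phenotypes with known genetic architecture
#'
#' Causal variants are sampled at random; effect `beta_j` is drawn with
#' variance proportional to `(2 p_j (1-p_j))^alpha` at the realized MAF
#' `p_j`. True breeding values are `TBV_i = sum_j x_ij beta_j`. Effects are
#' rescaled so the realized (sample) genetic variance matches the request:
#' either `target_h2` overall, or, when `per_class_variance_fractions` is
#' given, each MAF class's component variance equals its requested fraction
#' exactly. The deregressed proof adds deregression noise,
#' `DRP_i = TBV_i + e_i` with `var(e_i) = var(TBV) (1 - r_i) / r_i` for
#' reliability `r_i` — the standard deregression-error variance — so with
#' constant reliability `r` the expected DRP variance is `var(TBV)/r` and the
#' genetic fraction of the DRP variance is `r`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param arch an `arch_config`.
#' @param class_spec MAF-class boundaries used when per-class fractions are
#'   requested (default [maf_class_spec()]).
#' @return list with `phenotypes` (data.frame `id`, `trait`, `drp`,
#'   `reliability`, `tbv`) and `truth` (a `truth_record`: causal ids,
#'   effects, realized per-class and total genetic variances, residual
#'   variance).
#' @export
simulate_phenotypes <- function(genotypes, arch, class_spec = maf_class_spec()) {
  set.seed(arch$seed)
  n <- n_individuals(genotypes)
  m <- n_variants(genotypes)
  if (arch$n_causal > m) stop("n_causal exceeds the number of variants")
  maf <- compute_maf(genotypes)

  if (arch$n_causal == 0) {
    tbv <- rep(0, n)
    causal <- integer(0)
    beta <- numeric(0)
    class_var <- stats::setNames(rep(0, length(class_spec$labels)),
                                 class_spec$labels)
  } else {
    poly_ok <- which(maf > 0)
    if (length(poly_ok) < arch$n_causal) {
      stop("not enough polymorphic variants for the requested n_causal")
    }
    causal <- sort(sample(poly_ok, arch$n_causal))
    qtl_idx <- NULL
    if (!is.null(arch$large_qtl)) {
      qtl_idx <- poly_ok[which.min(abs(maf[poly_ok] - arch$large_qtl$maf))]
      causal <- sort(union(causal, qtl_idx))
    }
    p <- maf[causal]
    het <- 2 * p * (1 - p)
    beta <- stats::rnorm(length(causal), 0, sqrt(het^arch$alpha))
    X <- impute_mean(genotypes$dosages[, causal, drop = FALSE])

    if (!is.null(arch$per_class_variance_fractions)) {
      fr <- arch$per_class_variance_fractions
      labels <- maf_class_labels(p, class_spec, clamp = TRUE)
      for (cl in names(fr)) {
        in_cl <- labels == cl
        if (!any(in_cl)) {
          if (fr[[cl]] > 0) stop("no causal variants in MAF class ", cl)
          next
        }
        comp <- X[, in_cl, drop = FALSE] %*% beta[in_cl]
        v <- stats::var(as.vector(comp))
        beta[in_cl] <- if (v > 0) beta[in_cl] * sqrt(fr[[cl]] / v) else 0
      }
      # zero out classes not requested
      beta[!(labels %in% names(fr))] <- 0
    } else {
      tbv0 <- as.vector(X %*% beta)
      v0 <- stats::var(tbv0)
      if (v0 > 0) beta <- beta * sqrt(arch$target_h2 / v0)
    }

    if (!is.null(arch$large_qtl)) {
      # carve the QTL share out of the polygenic background: project the
      # background out of the QTL column (folding the projection into the
      # QTL's own effect slot) so the QTL's marginal share of the genetic
      # variance is exactly the requested fraction
      tot <- if (!is.null(arch$per_class_variance_fractions)) {
        sum(arch$per_class_variance_fractions)
      } else arch$target_h2
      q <- arch$large_qtl$fraction_of_variance
      qpos <- match(qtl_idx, causal)
      beta[qpos] <- 0
      xq <- X[, qpos]
      poly_tbv <- as.vector(X %*% beta)
      b <- stats::cov(xq, poly_tbv) / stats::var(xq)
      beta[qpos] <- -b                      # residualize background on the QTL
      res_tbv <- poly_tbv - b * xq
      vr <- stats::var(res_tbv)
      if (vr > 0) beta <- beta * sqrt(tot * (1 - q) / vr)
      beta[qpos] <- beta[qpos] + sqrt(tot * q / stats::var(xq))
    }

    tbv <- as.vector(X %*% beta)
    labels_all <- maf_class_labels(p, class_spec, clamp = TRUE)
    class_var <- vapply(class_spec$labels, function(cl) {
      in_cl <- labels_all == cl
      if (!any(in_cl)) return(0)
      stats::var(as.vector(X[, in_cl, drop = FALSE] %*% beta[in_cl]))
    }, numeric(1))
  }

  v_tbv <- if (length(causal)) stats::var(tbv) else 0
  r <- stats::runif(n, arch$reliability_lo, arch$reliability_hi)
  noise_var <- if (v_tbv > 0) v_tbv * (1 - r) / r else rep(1, n)
  e <- stats::rnorm(n, 0, sqrt(noise_var))
  drp <- tbv + e

  phenotypes <- data.frame(id = genotypes$individual_ids, trait = "sim",
                           drp = drp, reliability = r, tbv = tbv,
                           stringsAsFactors = FALSE)
  truth <- structure(list(
    causal_variant_ids = genotypes$variants$id[causal],
    effects = beta,
    true_variance_per_class = class_var,
    true_total_genetic_variance = v_tbv,
    true_residual_variance = stats::var(e)
  ), class = "truth_record")
  list(phenotypes = phenotypes, truth = truth)
}

#' Write a truth record as tab-separated text
#' @param truth a `truth_record`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# true_total_genetic_variance\t%s",
                     format_num(truth$true_total_genetic_variance)), con)
  writeLines(sprintf("# true_residual_variance\t%s",
                     format_num(truth$true_residual_variance)), con)
  for (cl in names(truth$true_variance_per_class)) {
    writeLines(sprintf("# class_variance\t%s\t%s", cl,
                       format_num(truth$true_variance_per_class[[cl]])), con)
  }
  df <- data.frame(variant = truth$causal_variant_ids, effect = truth$effects)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
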