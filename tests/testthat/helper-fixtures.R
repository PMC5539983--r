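# Small in-code fixtures shared across the suite.

# A tiny hand-built genotype matrix (no simulation, fully deterministic).
toy_genotypes <- function() {
  dos <- rbind(c(0, 1, 2, 0),
               c(1, 1, 0, 0),
               c(2, 0, 1, 1),
               c(0, 2, 2, 0),
               c(1, 1, 1, 2))
  variants <- data.frame(id = paste0("v", 1:4),
                         chrom = c("chr1", "chr1", "chr1", "chr2"),
                         pos = c(100L, 5000L, 90000L, 1000L),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, paste0("ind", 1:5))
}

# Simulated genotypes at a given size, cached per test file run.
sim_fixture <- function(n = 200, m = 500, pool = 25, seed = 11,
                        spectrum = spectrum_uniform(0.01, 0.5),
                        n_chromosomes = 1, chromosome_length_bp = 5e7) {
  cfg <- sim_config(n_individuals = n, n_variants = m,
                    n_chromosomes = n_chromosomes,
                    chromosome_length_bp = chromosome_length_bp,
                    maf_spectrum = spectrum, founder_pool_size = pool,
                    switch_rate = 1e-8, seed = seed)
  simulate_genotypes(cfg)$genotypes
}

# Brute-force pedigree relationship oracle: the recursive definition of the
# additive relationship, memoized, independent of the tabular code path.
recursive_a <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  memo <- new.env()
  a <- function(i, j) {
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + if (!is.na(si[i]) && !is.na(di[i])) 0.5 * a(si[i], di[i]) else 0
    } else {
      # i is the later-born individual (topological order)
      s <- si[i]; d <- di[i]
      0.5 * ((if (!is.na(s)) a(j, s) else 0) + (if (!is.na(d)) a(j, d) else 0))
    }
    memo[[key]] <- val
    val
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) out[i, j] <- out[j, i] <- a(i, j)
  out
}

# Brute-force O(m^2) windowed LD-score oracle: all-pairs double loop with a
# plain distance filter, summing r^2 in ascending variant order.
brute_ld_scores <- function(g, window_bp = 2e7) {
  m <- n_variants(g)
  score <- numeric(m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (k == j) next
      if (g$variants$chrom[k] != g$variants$chrom[j]) next
      if (abs(g$variants$pos[k] - g$variants$pos[j]) > window_bp / 2) next
      xj <- g$dosages[, j]; xk <- g$dosages[, k]
      if (sd(xj) == 0 || sd(xk) == 0) next
      score[j] <- score[j] + ld_r2(xj, xk)
    }
  }
  score
}
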