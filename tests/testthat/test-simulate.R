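test_that("degenerate spectra behave as expected", {
  # uniform(0.5, 0.5): every variant at frequency 0.5 in expectation
  cfg <- sim_config(n_individuals = 10, n_variants = 200, founder_pool_size = 50,
                    maf_spectrum = spectrum_uniform(0.5, 0.5), seed = 2)
  f <- simulate_founder_haplotypes(cfg)
  realized <- colMeans(f$haplotypes)
  expect_true(all(realized >= 0 & realized <= 0.5))  # folded
  # binomial sampling bound: 100 haplotypes at p = 0.5, folded mean ~ 0.46
  expect_gt(mean(realized), 0.40)

  # positions strictly increasing within chromosome
  cfg2 <- sim_config(n_individuals = 5, n_variants = 300, n_chromosomes = 3,
                     chromosome_length_bp = 1e6, seed = 4)
  f2 <- simulate_founder_haplotypes(cfg2)
  for (ch in unique(f2$variants$chrom)) {
    expect_true(!is.unsorted(f2$variants$pos[f2$variants$chrom == ch],
                             strictly = TRUE))
  }
})

test_that("neutral spectrum is enriched for rare variants", {
  # density 1/x on [0.001, 0.5]: mass below 0.01 is log(10)/log(500) ~ 0.37,
  # mass in [0.4, 0.5] is log(1.25)/log(500) ~ 0.036 -- rare dominates
  cfg <- sim_config(n_individuals = 10, n_variants = 10000,
                    founder_pool_size = 2000,
                    maf_spectrum = spectrum_neutral(), seed = 9)
  f <- simulate_founder_haplotypes(cfg)
  maf <- colMeans(f$haplotypes)
  frac_rare <- mean(maf < 0.01)
  frac_common <- mean(maf >= 0.4 & maf <= 0.5)
  expect_gt(frac_rare, frac_common)
})

test_that("zero switch rate copies founder haplotypes end-to-end", {
  cfg <- sim_config(n_individuals = 20, n_variants = 300, founder_pool_size = 5,
                    switch_rate = 0, maf_spectrum = spectrum_uniform(0.2, 0.5),
                    seed = 12)
  founders <- simulate_founder_haplotypes(cfg)
  ped <- simulate_pedigree(n_founders = 6, seed = 1)
  g <- gene_drop(ped, founders, recombination_rate_per_bp = 0,
                 switch_rate = 0, seed = 3)
  haps <- attr(g, "haplotypes")
  pool <- founders$haplotypes
  for (h in haps) {
    for (row in 1:2) {
      match_any <- any(apply(pool, 1, function(p) all(p == h[row, ])))
      expect_true(match_any)
    }
  }
})

test_that("pedigree simulation is topologically ordered", {
  p0 <- simulate_pedigree(5, n_generations = 0, seed = 1)
  expect_equal(nrow(p0), 5)
  expect_true(all(is.na(p0$sire)) && all(is.na(p0$dam)))

  p1 <- simulate_pedigree(2, n_generations = 1, offspring_per_mating = 2,
                          n_matings_per_generation = 1, seed = 1)
  expect_equal(nrow(p1), 4)
  expect_equal(p1$sire[3], p1$sire[4])
  expect_equal(p1$dam[3], p1$dam[4])

  p3 <- simulate_pedigree(10, n_generations = 3, offspring_per_mating = 2,
                          seed = 42)
  for (i in seq_len(nrow(p3))) {
    for (par in c(p3$sire[i], p3$dam[i])) {
      if (!is.na(par)) expect_lt(match(par, p3$id), i)
    }
  }
})

test_that("as_pedigree rejects disorder and self-parentage", {
  bad <- data.frame(id = c("a", "b"), sire = c("b", NA), dam = c(NA, NA))
  expect_error(as_pedigree(bad), "topologically")
  selfp <- data.frame(id = "a", sire = "a", dam = NA)
  expect_error(as_pedigree(selfp), "own parent")
})

test_that("gene_drop output is Mendelian-consistent at every locus", {
  cfg <- sim_config(n_individuals = 1, n_variants = 400, n_chromosomes = 2,
                    chromosome_length_bp = 5e7, founder_pool_size = 8,
                    maf_spectrum = spectrum_uniform(0.05, 0.5), seed = 21)
  founders <- simulate_founder_haplotypes(cfg)
  ped <- simulate_pedigree(8, n_generations = 3, offspring_per_mating = 2,
                          seed = 5)
  g <- gene_drop(ped, founders, recombination_rate_per_bp = 1e-8, seed = 6)

  # brute-force per-locus trio check: offspring dosage must be attainable
  # from one allele of each parent
  inconsistencies <- 0L
  dos <- g$dosages
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$sire[i])) next
    s <- dos[ped$sire[i], ]; d <- dos[ped$dam[i], ]; o <- dos[ped$id[i], ]
    s_min <- ifelse(s == 2, 1, 0); s_max <- ifelse(s == 0, 0, 1)
    d_min <- ifelse(d == 2, 1, 0); d_max <- ifelse(d == 0, 0, 1)
    bad <- o < s_min + d_min | o > s_max + d_max
    inconsistencies <- inconsistencies + sum(bad)
  }
  expect_identical(inconsistencies, 0L)
})

test_that("phenotype simulation honours reliability and null architectures", {
  g <- sim_fixture(n = 150, m = 300, seed = 31)

  # reliability 1: DRP equals TBV exactly
  arch1 <- arch_config(n_causal = 50, target_h2 = 0.5, reliability_lo = 1,
                       reliability_hi = 1, seed = 1)
  sim1 <- simulate_phenotypes(g, arch1)
  expect_equal(sim1$phenotypes$drp, sim1$phenotypes$tbv)
  expect_equal(var(sim1$phenotypes$tbv), 0.5, tolerance = 1e-10)

  # no causal variants: TBV identically zero
  arch0 <- arch_config(n_causal = 0, seed = 2)
  sim0 <- simulate_phenotypes(g, arch0)
  expect_true(all(sim0$phenotypes$tbv == 0))
  expect_equal(sim0$truth$true_total_genetic_variance, 0)
  expect_gt(var(sim0$phenotypes$drp), 0)
})

test_that("constant reliability r gives var(DRP) ~ var(TBV)/r", {
  g <- sim_fixture(n = 2000, m = 400, seed = 32)
  arch <- arch_config(n_causal = 200, target_h2 = 0.5, reliability_lo = 0.5,
                      reliability_hi = 0.5, seed = 3)
  sim <- simulate_phenotypes(g, arch)
  v_tbv <- var(sim$phenotypes$tbv)
  v_drp <- var(sim$phenotypes$drp)
  expect_equal(v_drp, v_tbv / 0.5, tolerance = 0.1)
})

test_that("per-class variance fractions are realized exactly", {
  g <- sim_fixture(n = 300, m = 1000, pool = 200,
                   spectrum = spectrum_uniform(0.01, 0.5), seed = 33)
  maf <- compute_maf(g)
  fr <- c("0.05-0.1" = 0.2, "0.2-0.3" = 0.3)
  arch <- arch_config(n_causal = 600, per_class_variance_fractions = fr,
                      reliability_lo = 0.9, reliability_hi = 0.9, seed = 4)
  sim <- simulate_phenotypes(g, arch)
  tv <- sim$truth$true_variance_per_class
  expect_equal(unname(tv["0.05-0.1"]), 0.2, tolerance = 1e-9)
  expect_equal(unname(tv["0.2-0.3"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(tv["0.4-0.5"]), 0)
  expect_error(
    arch_config(n_causal = 10,
                per_class_variance_fractions = c("0.05-0.1" = 0.9,
                                                 "0.2-0.3" = 0.3)),
    "sum to more than 1")
})

test_that("a planted large QTL explains its share of TBV variance", {
  g <- sim_fixture(n = 2000, m = 800, pool = 60,
                   spectrum = spectrum_uniform(0.05, 0.5), seed = 34)
  arch <- arch_config(n_causal = 300, target_h2 = 0.5,
                      large_qtl = list(maf = 0.29, fraction_of_variance = 0.15),
                      reliability_lo = 0.95, reliability_hi = 0.99, seed = 5)
  sim <- simulate_phenotypes(g, arch)
  maf <- compute_maf(g)
  qtl_id <- sim$truth$causal_variant_ids[
    which.max(abs(sim$truth$effects) *
                sqrt(2 * maf[sim$truth$causal_variant_ids] *
                       (1 - maf[sim$truth$causal_variant_ids])))]
  r2 <- single_variant_r2(g$dosages[, qtl_id], sim$phenotypes$tbv)
  expect_equal(r2, 0.15, tolerance = 0.03)
})

test_that("same seed gives bit-identical simulation output", {
  cfg <- sim_config(n_individuals = 40, n_variants = 100, seed = 77)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  arch <- arch_config(n_causal = 20, seed = 9)
  pa <- simulate_phenotypes(a$genotypes, arch)
  pb <- simulate_phenotypes(b$genotypes, arch)
  expect_identical(pa$phenotypes$drp, pb$phenotypes$drp)
})

test_that("effect-size scaling follows the alpha convention", {
  # alpha = 0: per-variant variance contribution ~ 2p(1-p) (common variants
  # contribute more); alpha = -1: contribution flat in MAF.
  g <- sim_fixture(n = 500, m = 600, pool = 500,
                   spectrum = spectrum_uniform(0.02, 0.5), seed = 35)
  maf <- compute_maf(g)
  slope_for <- function(alpha, seeds) {
    num <- 0; den <- 0
    for (s in seeds) {
      arch <- arch_config(n_causal = 600, alpha = alpha, target_h2 = 0.5,
                          reliability_lo = 1, reliability_hi = 1, seed = s)
      sim <- simulate_phenotypes(g, arch)
      ids <- sim$truth$causal_variant_ids
      het <- 2 * maf[ids] * (1 - maf[ids])
      pv <- sim$truth$effects^2 * het   # per-variant variance contribution
      fitc <- coef(lm(pv ~ het))
      num <- num + fitc[2]; den <- den + fitc[1]
    }
    num / abs(den)   # slope relative to intercept magnitude
  }
  seeds <- 101:130
  expect_gt(slope_for(0, seeds), 0.5)          # strongly increasing in het
  expect_lt(abs(slope_for(-1, seeds)), 0.5)    # near-flat
})
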