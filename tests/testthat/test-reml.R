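test_that("restricted log-likelihood matches the 2x2 closed form", {
  # n = 2, residual only, y = (0, 0), sigma2_e = 1:
  # V = I, log|V| = 0, 1'V^-1 1 = 2, y'Py = 0  ->  ll = -0.5 log 2
  ll <- restricted_loglik(c(0, 0), list(), 1)
  expect_equal(ll, -0.5 * log(2))

  # general 2-point case, still closed form: y = (1, 3), sigma2_e = 2
  # y'Py = sum((y - mean(y))^2) / sigma2 = 2 / 2 = 1
  ll2 <- restricted_loglik(c(1, 3), list(), 2)
  expect_equal(ll2, -0.5 * (2 * log(2) + log(2 / 2) + 1))
})

test_that("restricted log-likelihood is invariant to adding a constant", {
  g <- sim_fixture(n = 40, m = 200, seed = 61)
  K <- grm_vanraden1(g)
  y <- rnorm(40)
  a <- restricted_loglik(y, list(K), c(0.4, 0.6))
  b <- restricted_loglik(y + 17.3, list(K), c(0.4, 0.6))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("restricted log-likelihood agrees with a naive dense evaluation", {
  set.seed(62)
  n <- 50
  g <- sim_fixture(n = n, m = 300, seed = 62)
  f <- alt_freq(g)
  g <- subset_genotypes(g, variants = f > 0 & f < 1)
  K1 <- grm_vanraden1(g)$matrix
  K2 <- grm_vanraden2(g)$matrix
  y <- rnorm(n)
  s2 <- c(0.3, 0.25, 0.5)
  # independent oracle: explicit inverses, no Cholesky shortcuts
  V <- s2[1] * K1 + s2[2] * K2 + s2[3] * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  P <- Vi - Vi %*% one %*% solve(t(one) %*% Vi %*% one) %*% t(one) %*% Vi
  oracle <- -0.5 * (determinant(V)$modulus[1] +
                      log(drop(t(one) %*% Vi %*% one)) +
                      drop(t(y) %*% P %*% y))
  expect_equal(restricted_loglik(y, list(K1, K2), s2), oracle,
               tolerance = 1e-8)
})

test_that("ai_reml matches the 2-D grid-refinement oracle", {
  g <- sim_fixture(n = 200, m = 800, pool = 15,
                   spectrum = spectrum_uniform(0.05, 0.5), seed = 63)
  K <- grm_vanraden1(g)
  y <- simulate_from_K(K$matrix, h2 = 0.5, seed = 101)
  fit <- ai_reml(y, list(grm = K))
  expect_true(fit$converged)
  oracle <- grid_reml_2d(y, K$matrix)
  expect_equal(fit$estimates[["grm"]], oracle$sigma2[1], tolerance = 1e-3)
  expect_equal(fit$estimates[["residual"]], oracle$sigma2[2], tolerance = 1e-3)
  expect_gte(fit$loglik + 1e-8, oracle$loglik)
  # estimate within 2 SE of the simulated truth
  expect_lt(abs(fit$estimates[["grm"]] - 0.5), 2 * fit$se[["grm"]])
})

test_that("pure-noise data drives the genetic variance to the boundary", {
  g <- sim_fixture(n = 150, m = 400, pool = 15, seed = 64)
  K <- grm_vanraden1(g)
  set.seed(5)
  y <- rnorm(150)
  fit <- ai_reml(y, list(grm = K))
  expect_lt(fit$proportions[1], 0.05)
})

test_that("accepted iterations never decrease the log-likelihood", {
  g <- sim_fixture(n = 100, m = 300, pool = 12, seed = 65)
  K <- grm_vanraden1(g)
  y <- simulate_from_K(K$matrix, h2 = 0.4, seed = 7)
  path <- capture.output(fit <- ai_reml(y, list(K), verbose = TRUE))
  lls <- as.numeric(sub(".*logL ([-0-9.]+).*", "\\1", path))
  expect_true(all(diff(lls) >= -1e-7))
  # and the fit improves on the equal-split start
  start_ll <- restricted_loglik(y, list(K), rep(var(y) / 2, 2))
  expect_gte(fit$loglik, start_ll)
})

test_that("estimates are invariant to component reordering", {
  g <- sim_fixture(n = 120, m = 600, pool = 15, seed = 66)
  K1 <- grm_vanraden1(subset_genotypes(g, variants = 1:300))
  K2 <- grm_vanraden1(subset_genotypes(g, variants = 301:600))
  y <- simulate_from_K(0.5 * (K1$matrix + K2$matrix), h2 = 0.5, seed = 8)
  f12 <- ai_reml(y, list(a = K1, b = K2))
  f21 <- ai_reml(y, list(b = K2, a = K1))
  expect_equal(f12$estimates[["a"]], f21$estimates[["a"]], tolerance = 1e-5)
  expect_equal(f12$estimates[["b"]], f21$estimates[["b"]], tolerance = 1e-5)
  expect_equal(f12$loglik, f21$loglik, tolerance = 1e-7)
})

test_that("proportions: arithmetic, boundaries, and sum to one", {
  fit <- structure(list(
    estimates = c(a = 1, b = 1, c = 2, residual = 4),
    cov = diag(4) * 0.01,
    labels = c("a", "b", "c", "residual")), class = "vc_fit")
  pr <- proportion_explained(fit)
  expect_equal(pr$proportion, c(0.125, 0.125, 0.25, 0.5))
  expect_equal(sum(pr$proportion), 1)

  fit$estimates <- c(a = 0, b = 0, c = 0, residual = 4)
  pr0 <- proportion_explained(fit)
  expect_equal(pr0$proportion[1:3], rep(0, 3))
})

test_that("delta-method proportion SE tracks the parametric bootstrap", {
  g <- sim_fixture(n = 120, m = 500, pool = 10,
                   spectrum = spectrum_uniform(0.05, 0.5), seed = 67)
  K <- grm_vanraden1(g)
  y <- simulate_from_K(K$matrix, h2 = 0.5, seed = 11)
  fit <- ai_reml(y, list(grm = K))
  delta_se <- fit$proportion_se[1]

  set.seed(12)
  sg <- fit$estimates[[1]]; se_ <- fit$estimates[[2]]
  L <- t(chol(sg * K$matrix + se_ * diag(120)))
  props <- replicate(200, {
    yb <- drop(L %*% rnorm(120))
    fb <- ai_reml(yb, list(K), tol = 1e-6)
    fb$proportions[1]
  })
  expect_equal(delta_se, sd(props), tolerance = 0.25)
})

test_that("AIC arithmetic and model-addition behaviour", {
  fake <- structure(list(loglik = -100, converged = TRUE,
                         at_boundary = c(a = FALSE, residual = FALSE)),
                    class = "vc_fit")
  expect_equal(aic(fake), 204)
  fake$converged <- FALSE
  expect_error(aic(fake), "unconverged")

  # adding a component never decreases the restricted log-likelihood
  g <- sim_fixture(n = 100, m = 400, pool = 12, seed = 68)
  K1 <- grm_vanraden1(subset_genotypes(g, variants = 1:200))
  K2 <- grm_vanraden1(subset_genotypes(g, variants = 201:400))
  y <- simulate_from_K(K1$matrix, h2 = 0.4, seed = 13)
  f1 <- ai_reml(y, list(K1))
  f2 <- ai_reml(y, list(K1, K2))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("fit_model builds the advertised component structure", {
  g <- sim_fixture(n = 100, m = 1400, pool = 400,
                   spectrum = spectrum_uniform(0.001, 0.5),
                   chromosome_length_bp = 2e7, seed = 69)
  g <- qc_filter(g)$genotypes
  maf <- compute_maf(g)
  part <- assign_maf_classes(maf)
  phen <- data.frame(id = g$individual_ids,
                     drp = rnorm(n_individuals(g)))

  fit_ms <- fit_model(phen, "greml-ms", genotypes = g, partition = part,
                      max_iter = 10)
  expect_equal(length(fit_ms$estimates), 8)  # 7 classes + residual

  tab <- segment_mean_ld(ld_scores(g))
  part4 <- stratify_ld_groups(part, tab, n_groups = 4)
  fit_ldms <- fit_model(phen, "greml-ldms", genotypes = g, partition = part4,
                        max_iter = 3)
  expect_equal(length(fit_ldms$estimates), 29)  # 28 groups + residual

  ped <- simulate_pedigree(20, n_generations = 2, offspring_per_mating = 2,
                           n_matings_per_generation = 20, seed = 3)
  expect_error(fit_model(phen, "reml-ped"), "pedigree")
  expect_error(fit_model(phen, "greml-ms", genotypes = g), "partition")
})
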