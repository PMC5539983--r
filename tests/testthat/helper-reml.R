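# Independent grid-refinement maximizer of the restricted log-likelihood
# over (sigma2_g, sigma2_e) for a single genetic component. Pure grid /
# interval-shrinking search; shares no code with the AI-REML path.
grid_reml_2d <- function(y, K, passes = 8, grid_n = 15) {
  vy <- var(y)
  lo <- c(1e-6 * vy, 1e-6 * vy)
  hi <- c(2 * vy, 2 * vy)
  best <- c(NA, NA)
  for (p in seq_len(passes)) {
    gs <- seq(lo[1], hi[1], length.out = grid_n)
    es <- seq(lo[2], hi[2], length.out = grid_n)
    ll <- matrix(-Inf, grid_n, grid_n)
    for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
      ll[i, j] <- tryCatch(restricted_loglik(y, list(K), c(gs[i], es[j])),
                           error = function(e) -Inf)
    }
    w <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(gs[w[1]], es[w[2]])
    step_g <- gs[2] - gs[1]
    step_e <- es[2] - es[1]
    lo <- pmax(c(best[1] - step_g, best[2] - step_e), 1e-9 * vy)
    hi <- c(best[1] + step_g, best[2] + step_e)
  }
  list(sigma2 = best, loglik = max(ll))
}

# Simulate phenotypes with a given true covariance structure:
# y ~ N(0, h2 * K + (1 - h2) * I), exact via Cholesky.
simulate_from_K <- function(K, h2, seed, sigma_tot = 1) {
  set.seed(seed)
  n <- nrow(K)
  V <- sigma_tot * (h2 * K + (1 - h2) * diag(n))
  drop(t(chol(V)) %*% rnorm(n))
}
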