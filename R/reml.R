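#' Restricted log-likelihood of a variance-component model
#'
#' For the model `y = 1 mu + sum_k u_k + e` with `u_k ~ N(0, K_k sigma2_k)`
#' and `e ~ N(0, I sigma2_e)`, returns
#' `-0.5 * (log|V| + log|1' V^-1 1| + y' P y)` where
#' `V = sum_k sigma2_k K_k + sigma2_e I` and
#' `P = V^-1 - V^-1 1 (1' V^-1 1)^-1 1' V^-1` (the constant term is
#' dropped). The intercept is the only fixed effect.
#'
#' @param y numeric phenotype vector.
#' @param components list of n x n genetic covariance-structure matrices
#'   (plain matrices or `relationship_matrix` objects); the residual
#'   identity is appended internally.
#' @param sigma2 parameter vector, one genetic variance per component plus
#'   the residual variance last.
#' @return the restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(y, components, sigma2) {
  K <- component_matrices(components, length(y))
  if (length(sigma2) != length(K)) {
    stop("sigma2 must have one entry per component plus the residual")
  }
  V <- Reduce(`+`, Map(`*`, K, sigma2))
  ch <- tryCatch(chol(V), error = function(e) stop("V is singular or not positive definite"))
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  one <- rep(1, length(y))
  Vinv1 <- Vinv %*% one
  s11 <- sum(Vinv1)
  if (s11 <= 0) stop("V is singular or not positive definite")
  Vinvy <- Vinv %*% y
  yPy <- sum(y * Vinvy) - (sum(y * Vinv1))^2 / s11
  -0.5 * (logdetV + log(s11) + yPy)
}

component_matrices <- function(components, n) {
  K <- lapply(components, function(k) {
    if (inherits(k, "relationship_matrix")) k$matrix else as.matrix(k)
  })
  for (k in K) {
    if (!all(dim(k) == c(n, n))) stop("component matrix not conformable with y")
  }
  c(K, list(diag(n)))
}

#' Average-information REML
#'
#' Maximizes the restricted log-likelihood over nonnegative variance
#' components by average-information (AI) updates with an
#' expectation-maximization fallback and step-halving. The first two
#' iterations use EM (which cannot decrease the likelihood); afterwards an
#' AI step is attempted and halved until it does not decrease the
#' likelihood, falling back to EM if halving fails. Components that fall to
#' the lower bound (`min_variance_fraction * var(y)`) are clamped there and
#' flagged. Standard errors come from the inverse AI matrix at the optimum.
#'
#' @param y numeric phenotype vector.
#' @param components list of genetic covariance matrices (the residual
#'   identity is added internally); names become component labels.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-8).
#' @param min_variance_fraction lower bound for each variance, as a fraction
#'   of `var(y)` (default 1e-8).
#' @param start optional starting values (genetic variances then residual);
#'   default splits `var(y)` equally.
#' @param verbose print the likelihood path.
#' @return a `vc_fit`: estimates, SEs, the inverse-AI sampling covariance,
#'   restricted log-likelihood, iteration count, `converged` flag, boundary
#'   flags, and per-component proportions of phenotypic variance with
#'   delta-method SEs.
#' @export
ai_reml <- function(y, components, max_iter = 200, tol = 1e-8,
                    min_variance_fraction = 1e-8, start = NULL,
                    verbose = FALSE) {
  n <- length(y)
  K <- component_matrices(components, n)
  nk <- length(K)
  if (n <= nk) stop("more variance components than informative observations")
  labels <- names(components)
  if (is.null(labels)) labels <- paste0("g", seq_len(nk - 1))
  labels <- c(labels, "residual")
  vy <- stats::var(y)
  bound <- min_variance_fraction * vy
  theta <- if (is.null(start)) rep(vy / nk, nk) else as.numeric(start)
  if (length(theta) != nk) stop("start has wrong length")
  theta <- pmax(theta, bound)

  state <- reml_state(y, K, theta)
  ll <- state$ll
  converged <- FALSE
  iter <- 0
  AI <- NULL
  repeat {
    iter <- iter + 1
    em_theta <- pmax(em_update(state, theta, n), bound)
    if (iter <= 2) {
      new_theta <- em_theta
      new_state <- reml_state(y, K, new_theta)
    } else {
      AI <- ai_matrix(state)
      # active-set AI step: components pinned at the bound with a negative
      # gradient stay fixed there; solve the AI system over the free set
      free <- !(theta <= bound * (1 + 1e-6) & state$grad < 0)
      delta <- rep(0, nk)
      if (any(free)) {
        d_free <- tryCatch(
          solve(AI[free, free, drop = FALSE], state$grad[free]),
          error = function(e) NULL)
        if (!is.null(d_free)) delta[free] <- d_free else delta <- NULL
      }
      new_theta <- NULL
      if (!is.null(delta)) {
        step <- 1
        for (h in 1:20) {
          cand <- pmax(theta + step * delta, bound)
          cand_state <- tryCatch(reml_state(y, K, cand), error = function(e) NULL)
          if (!is.null(cand_state) && cand_state$ll >= ll - 1e-12) {
            new_theta <- cand
            new_state <- cand_state
            break
          }
          step <- step / 2
        }
      }
      if (is.null(new_theta)) {
        new_theta <- em_theta
        new_state <- reml_state(y, K, new_theta)
      }
    }
    dll <- new_state$ll - ll
    theta <- new_theta
    state <- new_state
    ll <- state$ll
    if (verbose) cat(sprintf("iter %d  logL %.8f  dll %.2e\n", iter, ll, dll))
    if (iter > 2 && abs(dll) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  AI <- ai_matrix(state)
  covmat <- tryCatch(solve(AI), error = function(e) {
    solve(AI + diag(1e-8 * max(diag(AI)), nk))
  })
  se <- sqrt(pmax(diag(covmat), 0))
  at_boundary <- theta <= bound * (1 + 1e-6)

  fit <- structure(list(
    estimates = stats::setNames(theta, labels),
    se = stats::setNames(se, labels),
    cov = covmat,
    loglik = ll,
    iterations = iter,
    converged = converged,
    at_boundary = stats::setNames(at_boundary, labels),
    n = n,
    var_y = vy,
    labels = labels
  ), class = "vc_fit")
  pr <- proportion_explained(fit)
  fit$proportions <- pr$proportion
  fit$proportion_se <- pr$se
  fit
}

# One evaluation of the REML quantities at theta: V, P-projected vectors,
# gradient pieces, and the restricted log-likelihood.
reml_state <- function(y, K, theta) {
  n <- length(y)
  V <- Reduce(`+`, Map(`*`, K, theta))
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  one <- rep(1, n)
  Vinv1 <- drop(Vinv %*% one)
  s11 <- sum(Vinv1)
  P <- Vinv - tcrossprod(Vinv1) / s11
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  ll <- -0.5 * (logdetV + log(s11) + yPy)
  nk <- length(K)
  KPy <- vapply(K, function(k) drop(k %*% Py), numeric(n))   # n x nk
  trPK <- vapply(K, function(k) sum(P * k), numeric(1))       # K symmetric
  yPKPy <- colSums(Py * KPy)
  grad <- -0.5 * (trPK - yPKPy)
  list(ll = ll, P = P, Py = Py, KPy = KPy, trPK = trPK, yPKPy = yPKPy,
       grad = grad)
}

ai_matrix <- function(state) {
  PKPy <- state$P %*% state$KPy     # n x nk
  0.5 * crossprod(state$KPy, PKPy)
}

em_update <- function(state, theta, n) {
  theta + theta^2 * (state$yPKPy - state$trPK) / n
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("variance-component fit: %d components + residual, n = %d\n",
              length(x$estimates) - 1, x$n))
  cat(sprintf("  logL = %.4f after %d iterations (%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  df <- data.frame(component = x$labels,
                   sigma2 = x$estimates, se = x$se,
                   proportion = x$proportions, prop_se = x$proportion_se,
                   boundary = x$at_boundary)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Proportion of phenotypic variance per component
#'
#' `p_i = sigma2_i / (sum_k sigma2_k + sigma2_e)`, with standard errors by
#' the delta method using the full sampling covariance of the estimates.
#'
#' @param fit a `vc_fit`.
#' @return data.frame with `component`, `proportion`, `se`. The residual row
#'   is included; proportions sum to one.
#' @export
proportion_explained <- function(fit) {
  th <- fit$estimates
  total <- sum(th)
  if (total <= 0) stop("total variance is not positive")
  p <- th / total
  nk <- length(th)
  se <- vapply(seq_len(nk), function(i) {
    grad <- -th[i] / total^2
    g <- rep(grad, nk)
    g[i] <- g[i] + 1 / total
    sqrt(max(0, drop(t(g) %*% fit$cov %*% g)))
  }, numeric(1))
  data.frame(component = fit$labels, proportion = as.numeric(p),
             se = se, row.names = NULL)
}

#' Akaike information criterion of a REML fit
#'
#' `AIC = 2k - 2 logL` where `logL` is the restricted log-likelihood and `k`
#' counts the free variance components (boundary-clamped components are not
#' counted; the intercept is profiled out by REML).
#'
#' @param fit a converged `vc_fit`.
#' @return the AIC value.
#' @export
aic <- function(fit) {
  if (!fit$converged) stop("AIC undefined for an unconverged fit")
  k <- sum(!fit$at_boundary)
  2 * k - 2 * fit$loglik
}

#' Fit one of the standard variance-partitioning models
#'
#' * `greml-ms`: one GRM per MAF class (7 with the default class
#'   specification), GCTA-style per-class GRMs (`alpha = -1`).
#' * `greml-ldms`: one GRM per MAF class x LD group (21 or 28).
#' * `reml-grm`: a single VanRaden-1 GRM over all variants.
#' * `reml-ped`: the pedigree A-matrix only.
#' * `reml-pedgrm`: VanRaden-1 GRM and A-matrix fitted jointly.
#'
#' Phenotype records are matched to genotype/pedigree individuals by id
#' (one record per individual; identity incidence).
#'
#' @param phenotypes data.frame with `id` and `drp` columns (reliabilities,
#'   if present, are carried along but never used as weights).
#' @param model model label (see above).
#' @param genotypes `genotype_matrix` (required for the GRM-based models).
#' @param partition `variant_partition` aligned with the genotype variants
#'   (required for `greml-ms`/`greml-ldms`; the latter needs the `group`
#'   column from [stratify_ld_groups()]).
#' @param pedigree `pedigree` covering all phenotyped individuals (required
#'   for `reml-ped`/`reml-pedgrm`).
#' @param grm_alpha_class alpha used for the per-class GRMs (default -1).
#' @param ... passed to [ai_reml()].
#' @return a `vc_fit` with an added `model` label and per-component
#'   base-scaling factors (`base_factor`, the mean-diagonal minus mean of
#'   each component matrix) for Legarra-style rescaling.
#' @export
fit_model <- function(phenotypes, model = c("greml-ms", "greml-ldms",
                                            "reml-grm", "reml-ped",
                                            "reml-pedgrm"),
                      genotypes = NULL, partition = NULL, pedigree = NULL,
                      grm_alpha_class = -1, ...) {
  model <- match.arg(model)
  ids <- as.character(phenotypes$id)
  y <- phenotypes$drp
  comps <- list()

  need_geno <- model %in% c("greml-ms", "greml-ldms", "reml-grm", "reml-pedgrm")
  if (need_geno && is.null(genotypes)) stop(model, " requires genotypes")
  if (model %in% c("reml-ped", "reml-pedgrm") && is.null(pedigree)) {
    stop(model, " requires a pedigree")
  }

  if (model %in% c("greml-ms", "greml-ldms")) {
    if (is.null(partition)) stop(model, " requires a variant partition")
    if (nrow(partition) != n_variants(genotypes)) {
      stop("partition rows do not match genotype variants")
    }
    group_col <- if (model == "greml-ms") as.character(partition$maf_class)
                 else partition$group
    if (model == "greml-ldms" && is.null(partition$ld_group)) {
      stop("greml-ldms needs LD groups; run stratify_ld_groups() first")
    }
    for (grp in unique(group_col[!is.na(group_col)])) {
      vi <- which(group_col == grp)
      sub <- subset_genotypes(genotypes, individuals = ids, variants = vi)
      f <- alt_freq(sub)
      poly <- f > 0 & f < 1
      if (!any(poly)) {
        warning("group ", grp, " has no polymorphic variants; dropped")
        next
      }
      sub <- subset_genotypes(sub, variants = poly)
      comps[[grp]] <- grm_alpha(sub, alpha = grm_alpha_class)
    }
    # order components by MAF class (then LD group) rather than genome order
    lvl <- levels(partition$maf_class)
    if (model == "greml-ms") {
      comps <- comps[order(match(names(comps), lvl))]
    } else {
      cls <- sub(":LD.*$", "", names(comps))
      grp <- as.integer(sub("^.*:LD", "", names(comps)))
      comps <- comps[order(match(cls, lvl), grp)]
    }
  }
  if (model %in% c("reml-grm", "reml-pedgrm")) {
    sub <- subset_genotypes(genotypes, individuals = ids)
    f <- alt_freq(sub)
    sub <- subset_genotypes(sub, variants = f > 0 & f < 1)
    comps[["grm"]] <- grm_vanraden1(sub)
  }
  if (model %in% c("reml-ped", "reml-pedgrm")) {
    A <- a_matrix(pedigree)
    comps[["pedigree"]] <- align_relmat(A, ids)
  }
  if (!length(comps)) stop("no genetic components could be built")

  fit <- ai_reml(y, comps, ...)
  fit$model <- model
  fit$base_factor <- c(vapply(comps, function(K) {
    mean(diag(K$matrix)) - mean(K$matrix)
  }, numeric(1)), residual = 1)
  fit
}

#' Write a variance-component fit as tab-separated text
#' @param fit a `vc_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model\t%s", if (is.null(fit$model)) "custom" else fit$model), con)
  writeLines(sprintf("# logL\t%s", format_num(fit$loglik)), con)
  writeLines(sprintf("# iterations\t%d", fit$iterations), con)
  writeLines(sprintf("# converged\t%s", fit$converged), con)
  if (fit$converged) writeLines(sprintf("# AIC\t%s", format_num(aic(fit))), con)
  df <- data.frame(component = fit$labels,
                   sigma2 = fit$estimates, se = fit$se,
                   proportion = fit$proportions,
                   proportion_se = fit$proportion_se,
                   boundary = fit$at_boundary)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
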