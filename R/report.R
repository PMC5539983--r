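#' Expected variance partition under VanRaden method 1
#'
#' With method-1 scaling, a variant's expected contribution to genetic
#' variance is proportional to its heterozygosity `2 p (1 - p)`; the
#' expected share of a MAF class is the class sum of `2 p (1 - p)` over the
#' total.
#'
#' @param mafs per-variant minor allele frequencies.
#' @param partition a `variant_partition` aligned with `mafs`.
#' @return named numeric vector of per-class expected proportions (sums
#'   to 1).
#' @export
expected_partition_vr1 <- function(mafs, partition) {
  het <- 2 * mafs * (1 - mafs)
  total <- sum(het)
  if (total <= 0) stop("zero total heterozygosity")
  out <- tapply(het, partition$maf_class, sum, default = 0) / total
  labels <- levels(partition$maf_class)
  stats::setNames(as.numeric(out[labels]), labels)
}

#' Expected variance partition under VanRaden method 2
#'
#' With method-2 scaling every standardized variant contributes equally in
#' expectation, so a class's expected share is simply its variant count over
#' the total — giving rare variants relatively more weight than method 1.
#'
#' @param partition a `variant_partition`.
#' @return named numeric vector of per-class expected proportions (sums
#'   to 1).
#' @export
expected_partition_vr2 <- function(partition) {
  counts <- table(partition$maf_class)
  n <- sum(counts)
  if (n == 0) stop("empty partition")
  stats::setNames(as.numeric(counts) / n, names(counts))
}

#' Variance share of a single variant
#'
#' Squared Pearson correlation between one dosage column and the phenotype
#' (the usual single-marker R^2, e.g. for a large known QTL).
#'
#' @param x_j numeric dosage vector.
#' @param y phenotype (DRP) vector.
#' @return squared correlation in `[0, 1]`.
#' @export
single_variant_r2 <- function(x_j, y) {
  ok <- !is.na(x_j) & !is.na(y)
  if (stats::sd(x_j[ok]) == 0) stop("monomorphic variant")
  as.numeric(stats::cor(x_j[ok], y[ok]))^2
}

#' Aggregate MAF-class proportions into rare / low-frequency / common
#'
#' Sums the fitted per-class proportions of DRP variance into three
#' aggregates — rare (MAF < 0.01), low-frequency (0.01 <= MAF < 0.05) and
#' common (MAF >= 0.05) — and divides each by the total explained
#' proportion, giving relative contributions that sum to one. Also tabulates
#' per-class counts, estimates, SEs and the expected shares under VanRaden
#' methods 1 and 2, flagging estimates larger than one standard error.
#'
#' @param fit a `vc_fit` from a `greml-ms` model (component labels must be
#'   MAF-class labels).
#' @param partition the `variant_partition` the fit was built from.
#' @param rare_max upper bound of the rare aggregate (default 0.01).
#' @param low_max upper bound of the low-frequency aggregate (default 0.05).
#' @return a `partition_report` list with elements `per_class` (data.frame),
#'   `aggregates` (data.frame with `relative_contribution`),
#'   `total_explained`.
#' @export
aggregate_contributions <- function(fit, partition, rare_max = 0.01,
                                    low_max = 0.05) {
  spec <- attr(partition, "spec")
  if (is.null(spec)) spec <- maf_class_spec()
  labels <- levels(partition$maf_class)
  est <- stats::setNames(rep(0, length(labels)), labels)
  se <- est
  present <- intersect(labels, fit$labels)
  est[present] <- fit$proportions[match(present, fit$labels)]
  se[present] <- fit$proportion_se[match(present, fit$labels)]
  counts <- as.numeric(table(partition$maf_class))
  evr1 <- expected_partition_vr1(partition$maf, partition)
  evr2 <- expected_partition_vr2(partition)
  per_class <- data.frame(
    maf_class = labels,
    n_variants = counts,
    proportion = as.numeric(est),
    se = as.numeric(se),
    exceeds_se = as.numeric(est) > as.numeric(se),
    expected_vr1 = as.numeric(evr1[labels]),
    expected_vr2 = as.numeric(evr2[labels]),
    row.names = NULL
  )
  lower <- spec$boundaries[-length(spec$boundaries)]
  agg_of <- ifelse(lower < rare_max, "rare",
                   ifelse(lower < low_max, "low_frequency", "common"))
  total <- sum(est)
  agg_prop <- tapply(est, agg_of, sum, default = 0)
  agg_levels <- c("rare", "low_frequency", "common")
  agg_prop <- stats::setNames(as.numeric(agg_prop[agg_levels]), agg_levels)
  agg_prop[is.na(agg_prop)] <- 0
  rel <- if (total > 0) agg_prop / total else rep(NA_real_, 3)
  aggregates <- data.frame(aggregate = agg_levels,
                           proportion = agg_prop,
                           relative_contribution = as.numeric(rel),
                           row.names = NULL)
  structure(list(per_class = per_class, aggregates = aggregates,
                 total_explained = total),
            class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat("Partition of DRP variance by MAF class\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat(sprintf("total proportion explained: %.3f\n", x$total_explained))
  print(x$aggregates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' AIC comparison table
#'
#' AIC per model expressed as the difference from a reference model
#' (conventionally the pedigree-only fit, scaled to zero).
#'
#' @param fits named list of converged `vc_fit`s.
#' @param reference name of the reference model (default `"reml-ped"` when
#'   present, else the first).
#' @return data.frame with `model`, `aic`, `delta_aic`, `converged`.
#' @export
aic_table <- function(fits, reference = NULL) {
  vals <- vapply(fits, function(f) if (f$converged) aic(f) else NA_real_,
                 numeric(1))
  if (is.null(reference)) {
    reference <- if ("reml-ped" %in% names(fits)) "reml-ped" else names(fits)[1]
  }
  data.frame(model = names(fits), aic = as.numeric(vals),
             delta_aic = as.numeric(vals - vals[reference]),
             converged = vapply(fits, `[[`, logical(1), "converged"),
             row.names = NULL)
}

#' Run the full variance-partitioning pipeline
#'
#' Executes simulate (or load) -> QC -> stratify -> relationship matrices ->
#' REML -> report, writing every table to `output_dir`. The configuration is
#' a YAML file (or an equivalent list); see the packaged example under
#' `inst/extdata/pipeline-config.yaml` and the vignette for the schema.
#'
#' @param config path to a YAML config file, or a list with the same
#'   structure.
#' @param output_dir directory for the report tables (created if absent).
#' @return invisibly, a list with the genotypes, partition, fits, partition
#'   report and AIC table.
#' @export
run_pipeline <- function(config, output_dir = "grmpart-report") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    say("stage simulate: n=%d m=%d seed=%d", sc$n_individuals, sc$n_variants,
        sc$seed)
    config_obj <- sim_config(
      n_individuals = sc$n_individuals, n_variants = sc$n_variants,
      n_chromosomes = sc$n_chromosomes %||% 1L,
      chromosome_length_bp = sc$chromosome_length_bp %||% 1e8,
      maf_spectrum = spectrum_from_config(sc$maf_spectrum),
      founder_pool_size = sc$founder_pool_size %||% 20L,
      switch_rate = sc$switch_rate %||% 1e-8,
      seed = sc$seed)
    ped <- simulate_pedigree(
      n_founders = sc$pedigree$n_founders %||% sc$n_individuals,
      n_generations = sc$pedigree$n_generations %||% 0L,
      offspring_per_mating = sc$pedigree$offspring_per_mating %||% 1L,
      seed = sc$seed + 1L)
    founders <- simulate_founder_haplotypes(config_obj)
    g <- gene_drop(ped, founders,
                   recombination_rate_per_bp = sc$recombination_rate %||% 1e-8,
                   switch_rate = config_obj$switch_rate, seed = sc$seed + 2L)
    arch <- arch_config(
      n_causal = sc$architecture$n_causal,
      alpha = sc$architecture$alpha %||% 0,
      target_h2 = sc$architecture$target_h2 %||% 0.5,
      per_class_variance_fractions =
        unlist(sc$architecture$per_class_variance_fractions) %||% NULL,
      reliability_lo = sc$architecture$reliability_lo %||% 0.9,
      reliability_hi = sc$architecture$reliability_hi %||% 0.99,
      seed = sc$seed + 3L)
    sim <- simulate_phenotypes(g, arch)
    phen <- sim$phenotypes
    write_truth(sim$truth, file.path(output_dir, "truth.tsv"))
    write_pedigree(ped, file.path(output_dir, "pedigree.csv"))
  } else {
    g <- read_genotypes(cfg$input$genotypes)
    phen <- read_phenotypes(cfg$input$phenotypes)
    ped <- if (!is.null(cfg$input$pedigree)) read_pedigree(cfg$input$pedigree)
           else NULL
  }

  # --- qc -----------------------------------------------------------------
  qc <- qc_filter(g,
                  min_individual_call_rate = cfg$qc$min_individual_call_rate,
                  min_locus_call_rate = cfg$qc$min_locus_call_rate,
                  hwe_p_min = cfg$qc$hwe_p_min,
                  maf_min = cfg$qc$maf_min)
  g <- qc$genotypes
  say("stage qc: retained %d individuals, %d variants",
      n_individuals(g), n_variants(g))
  write_qc_report(qc$report, file.path(output_dir, "qc_report.tsv"))
  phen <- phen[phen$id %in% g$individual_ids, , drop = FALSE]

  # --- stratify -----------------------------------------------------------
  spec <- maf_class_spec(cfg$stratify$maf_boundaries)
  maf <- compute_maf(g)
  partition <- assign_maf_classes(maf, spec)
  n_ld <- cfg$stratify$n_ld_groups
  if (n_ld > 0) {
    lst <- ld_scores(g, window_bp = cfg$stratify$ld_window_bp)
    lst <- segment_mean_ld(lst)
    partition <- stratify_ld_groups(partition, lst, n_groups = n_ld)
    utils::write.table(lst, file.path(output_dir, "ld_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_partition(partition, file.path(output_dir, "partition.tsv"))
  say("stage stratify: %d MAF classes, %d LD groups", spec$n_classes, n_ld)

  # --- reml ---------------------------------------------------------------
  fits <- list()
  for (model in cfg$models) {
    if (model %in% c("reml-ped", "reml-pedgrm") && is.null(ped)) {
      say("stage reml: skipping %s (no pedigree)", model)
      next
    }
    part_for_model <- if (model == "greml-ldms") partition else partition
    f <- tryCatch(
      fit_model(phen, model, genotypes = g, partition = part_for_model,
                pedigree = ped),
      error = function(e) stop("stage reml (", model, "): ",
                               conditionMessage(e), call. = FALSE))
    fits[[model]] <- f
    say("stage reml: %s logL=%.3f converged=%s", model, f$loglik, f$converged)
    write_fit(f, file.path(output_dir, paste0("fit_", model, ".tsv")))
  }

  # --- report -------------------------------------------------------------
  report <- NULL
  if (!is.null(fits[["greml-ms"]])) {
    report <- aggregate_contributions(fits[["greml-ms"]], partition)
    utils::write.table(report$per_class,
                       file.path(output_dir, "partition_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$aggregates,
                       file.path(output_dir, "aggregates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  conv <- fits[vapply(fits, `[[`, logical(1), "converged")]
  model_table <- data.frame(
    model = names(fits),
    total_proportion_explained = vapply(fits, function(f) {
      sum(f$proportions[-length(f$proportions)])
    }, numeric(1)),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  utils::write.table(model_table, file.path(output_dir, "model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  aics <- NULL
  if (length(conv) > 1) {
    aics <- aic_table(conv)
    utils::write.table(aics, file.path(output_dir, "aic_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c(sprintf("# grmpart pipeline log"),
               sprintf("# config: %s", yaml::as.yaml(cfg)), log_lines),
             file.path(output_dir, "pipeline.log"))
  invisible(list(genotypes = g, phenotypes = phen, partition = partition,
                 fits = fits, report = report, aic_table = aics,
                 model_table = model_table))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spectrum_from_config <- function(s) {
  if (is.null(s)) return(spectrum_neutral())
  switch(s$kind,
         uniform = spectrum_uniform(s$lo %||% 0.001, s$hi %||% 0.5),
         neutral = spectrum_neutral(s$lo %||% 0.001, s$hi %||% 0.5),
         beta = spectrum_beta(s$a %||% 0.5, s$b %||% 0.5),
         stop("unknown maf_spectrum kind: ", s$kind))
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stop("config needs either a 'simulate' or an 'input' block")
  }
  if (!is.null(cfg$simulate)) {
    for (f in c("n_individuals", "n_variants", "seed")) {
      if (is.null(cfg$simulate[[f]])) stop("simulate block needs '", f, "'")
    }
    if (is.null(cfg$simulate$architecture$n_causal)) {
      stop("simulate block needs architecture: n_causal")
    }
  }
  cfg$qc <- cfg$qc %||% list()
  cfg$qc$min_individual_call_rate <- cfg$qc$min_individual_call_rate %||% 0.85
  cfg$qc$min_locus_call_rate <- cfg$qc$min_locus_call_rate %||% 0.95
  cfg$qc$hwe_p_min <- cfg$qc$hwe_p_min %||% 1e-5
  cfg$qc$maf_min <- cfg$qc$maf_min %||% 0.001
  cfg$stratify <- cfg$stratify %||% list()
  cfg$stratify$maf_boundaries <- cfg$stratify$maf_boundaries %||%
    c(0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  cfg$stratify$n_ld_groups <- cfg$stratify$n_ld_groups %||% 0L
  if (!cfg$stratify$n_ld_groups %in% c(0, 3, 4)) {
    stop("n_ld_groups must be 0 (MAF-only), 3 or 4")
  }
  cfg$stratify$ld_window_bp <- cfg$stratify$ld_window_bp %||% 2e7
  cfg$models <- cfg$models %||% "greml-ms"
  allowed <- c("greml-ms", "greml-ldms", "reml-grm", "reml-ped", "reml-pedgrm")
  bad <- setdiff(cfg$models, allowed)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  cfg
}
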