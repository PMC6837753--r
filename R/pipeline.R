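#' Benchmark configuration
#'
#' Describes one synthetic-scale benchmark run: the cohort simulation, the
#' reconstruction methods (the ground truth plus baseline grid reconstructors
#' at one or more grid widths), the mutation views, the agreement metrics,
#' the survival feature sets, and the cross-validation setup.
#'
#' @param sim A [sim_config()] for the cohort.
#' @param views Mutation views to analyse: subset of
#'   `c("protected", "public")`.
#' @param baseline_grid_widths Grid widths of the baseline reconstructor; each
#'   width x view combination is one clone-resolving method.
#' @param metrics Agreement metrics to tabulate: subset of
#'   `c("1B", "1C", "2A")`.
#' @param min_snvs Clone post-filter threshold (default 5).
#' @param folds Cross-validation folds (default 5).
#' @param min_level_count Clinical categorical-level threshold (default 50).
#' @param seed Seed for fold assignment (the cohort uses `sim$seed`).
#' @return Object of class `"benchmark_config"`.
#' @export
benchmark_config <- function(sim = sim_config(),
                             views = c("protected", "public"),
                             baseline_grid_widths = 0.1,
                             metrics = c("1B", "1C", "2A"),
                             min_snvs = 5L,
                             folds = 5L,
                             min_level_count = 50L,
                             seed = 1L) {
  views <- match.arg(views, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(length(baseline_grid_widths) >= 1L, all(baseline_grid_widths > 0),
            folds >= 2L)
  structure(list(sim = sim, views = views,
                 baseline_grid_widths = baseline_grid_widths,
                 metrics = metrics, min_snvs = as.integer(min_snvs),
                 folds = as.integer(folds),
                 min_level_count = as.integer(min_level_count),
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# small deterministic content hash for provenance rows (no external deps)
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

observed_vaf <- function(variants) {
  v <- variants$tumor_alt / variants$tumor_depth
  names(v) <- variants$mutation_id
  v
}

# one baseline reconstruction: observed VAFs -> CCF estimates -> grid bins
baseline_from_sample <- function(smp, view, grid_width, min_snvs) {
  variants <- smp$views[[view]]
  vaf <- observed_vaf(variants)
  ccf <- ccf_from_vaf(vaf, smp$purity, variants$cn_total,
                      variants$multiplicity)
  ccf <- pmax(ccf, 1e-6)
  names(ccf) <- variants$mutation_id
  postfilter_clones(baseline_reconstruct(ccf, grid_width = grid_width,
                                         min_snvs = min_snvs),
                    min_snvs = min_snvs)
}

#' Run the full synthetic-scale benchmark
#'
#' Orchestrates the study design end to end: simulates a cohort, derives the
#' protected/public mutation views, builds reconstructions (ground truth plus
#' a baseline grid reconstructor per configured width and view), post-filters
#' clones, extracts ITH features and MATH scores, tabulates pairwise
#' method-agreement medians for the configured metrics, runs the correlation
#' analysis of ITH measures against confounders (purity, mutation load, CNA
#' fraction), and evaluates survival prediction by cross-validated ranking
#' SVM for each feature set, with Fisher-aggregated fold p-values,
#' Benjamini-Hochberg correction and significance stars (`***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05). Deterministic given the configured seeds.
#'
#' @param config A [benchmark_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSVs plus a `provenance.json`.
#' @return List with `cohort`, `recons`, `features` (long data frame),
#'   `math` (per sample x view), `comparisons` (named list of median
#'   matrices), `correlations`, `survival` (summary data frame with stars),
#'   `cv` (per-fold CI long table), `feature_matrices`, and `provenance`.
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  cohort <- simulate_cohort(config$sim)
  sample_ids <- names(cohort$samples)

  ## reconstructions per method
  recons <- list()
  recons[["truth"]] <- lapply(cohort$samples, function(s) {
    postfilter_clones(as_reconstruction(s$truth, purity = s$purity),
                      min_snvs = config$min_snvs)
  })
  for (w in config$baseline_grid_widths) for (view in config$views) {
    mname <- sprintf("baseline%g.%s", w, view)
    recons[[mname]] <- lapply(cohort$samples, baseline_from_sample,
                              view = view, grid_width = w,
                              min_snvs = config$min_snvs)
  }

  ## per-method features and MATH
  feature_matrices <- lapply(recons, function(per_sample) {
    rows <- lapply(per_sample, function(r) unlist(extract_ith_features(r)))
    m <- do.call(rbind, rows)
    rownames(m) <- names(per_sample)
    m
  })
  features_long <- do.call(rbind, lapply(names(feature_matrices), function(m) {
    data.frame(sample_id = rownames(feature_matrices[[m]]), method = m,
               feature_matrices[[m]], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  math <- sapply(config$views, function(view) {
    vapply(cohort$samples, function(s) {
      math_score(observed_vaf(s$views[[view]]))
    }, numeric(1))
  })
  math <- matrix(math, nrow = length(sample_ids),
                 dimnames = list(sample_ids, config$views))

  ## pairwise agreement tables
  comparisons <- lapply(config$metrics, function(metric) {
    suppressWarnings(pairwise_comparison_table(recons, metric))
  })
  names(comparisons) <- paste0("score", config$metrics)

  ## correlations of ITH measures and confounders
  measures <- data.frame(
    row.names = sample_ids,
    purity = vapply(cohort$samples, `[[`, numeric(1), "purity"),
    mutation_load = vapply(cohort$samples,
                           function(s) nrow(s$views$protected), numeric(1)),
    cna_fraction = vapply(cohort$samples, `[[`, numeric(1), "cna_fraction"),
    math_score = math[, 1]
  )
  for (m in names(feature_matrices)) {
    measures[[paste0("n_clones.", m)]] <- feature_matrices[[m]][, "n_clones"]
  }
  correlations <- suppressWarnings(correlation_analysis(measures))

  ## survival feature sets
  time <- cohort$survival$time
  event <- cohort$survival$event
  sets <- list()
  for (m in names(feature_matrices)) {
    sets[[m]] <- feature_matrices[[m]]
    sets[[paste0(m, ".n_clones")]] <-
      feature_matrices[[m]][, "n_clones", drop = FALSE]
    sets[[paste0(m, ".squared")]] <- augment_squared(feature_matrices[[m]])
  }
  sets[["math"]] <- math[, 1, drop = FALSE]
  sets[["combined"]] <- combine_features(feature_matrices, math = math[, 1])
  clin <- suppressWarnings(select_clinical_variables(
    cohort$clinical[setdiff(names(cohort$clinical), "sample_id")],
    time, event, min_level_count = config$min_level_count))
  if (ncol(clin$features) > 0) {
    sets[["clinical"]] <- clin$features
    sets[["clinical_ith"]] <- cbind(clin$features, sets[["combined"]])
  }

  cv_rows <- list(); fisher_p <- numeric(0)
  for (nm in names(sets)) {
    cv <- suppressWarnings(cross_validated_ci(sets[[nm]], time, event,
                                              k = config$folds,
                                              seed = config$seed))
    cis <- vapply(cv$results, `[[`, numeric(1), "ci")
    ps <- vapply(cv$results, function(r) {
      tryCatch(noether_ci_test(r), error = function(e) NA_real_)
    }, numeric(1))
    cv_rows[[nm]] <- data.frame(feature_set = nm,
                                fold = seq_along(cis), ci = cis, p = ps,
                                stringsAsFactors = FALSE)
    ok <- !is.na(ps)
    fisher_p[nm] <- if (any(ok)) fisher_aggregate(ps[ok]) else NA_real_
  }
  cv_table <- do.call(rbind, c(cv_rows, list(make.row.names = FALSE)))
  bh <- bh_correct(fisher_p[!is.na(fisher_p)])
  p_adj <- rep(NA_real_, length(fisher_p)); names(p_adj) <- names(fisher_p)
  p_adj[names(fisher_p)[!is.na(fisher_p)]] <- bh$adjusted
  stars <- ifelse(is.na(p_adj), "",
           ifelse(p_adj < 0.001, "***",
           ifelse(p_adj < 0.01, "**",
           ifelse(p_adj < 0.05, "*", ""))))
  surv_summary <- data.frame(
    feature_set = names(fisher_p),
    n_features = vapply(sets[names(fisher_p)], ncol, integer(1)),
    median_ci = vapply(names(fisher_p), function(nm) {
      stats::median(cv_rows[[nm]]$ci)
    }, numeric(1)),
    fisher_p = unname(fisher_p),
    p_adj = unname(p_adj),
    stars = unname(stars),
    row.names = NULL, stringsAsFactors = FALSE
  )

  provenance <- list(seed = config$seed, sim_seed = config$sim$seed,
                     config_hash = config_hash(config),
                     n_samples = length(sample_ids))
  out <- list(cohort = cohort, recons = recons, features = features_long,
              math = math, comparisons = comparisons,
              correlations = correlations, survival = surv_summary,
              cv = cv_table, feature_matrices = feature_matrices,
              clinical_screening = clin$screening, provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      df$seed <- config$seed
      df$config_hash <- provenance$config_hash
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(features_long, "features.tsv")
    wt(data.frame(sample_id = rownames(math), math, row.names = NULL),
       "math.tsv")
    for (metric in names(comparisons)) {
      cm <- comparisons[[metric]]
      long <- data.frame(method_a = rownames(cm)[row(cm)],
                         method_b = colnames(cm)[col(cm)],
                         metric = metric, median_score = as.vector(cm))
      wt(long, paste0("comparison_", metric, ".tsv"))
    }
    rmat <- correlations$r
    wt(data.frame(measure_a = rownames(rmat)[row(rmat)],
                  measure_b = colnames(rmat)[col(rmat)],
                  r = as.vector(rmat),
                  p_adj = as.vector(correlations$p_adj),
                  significant = as.vector(correlations$significant)),
       "correlations.tsv")
    wt(cv_table, "survival_cv.tsv")
    wt(surv_summary, "survival_summary.tsv")
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
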