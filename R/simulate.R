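#' Simulation configuration for a synthetic tumor cohort
#'
#' Bundles the knobs of the synthetic-cohort generator: cohort size, clone
#' architecture, sequencing depth, purity and copy-number confounders, and the
#' survival model linking latent ITH features to outcome.
#'
#' @param n_samples Number of tumor samples in the cohort.
#' @param clone_count_range Integer interval (length 2, min >= 1) from which the
#'   number of clones per sample is drawn uniformly.
#' @param mutations_per_sample_range Integer interval for the number of somatic
#'   SNVs per sample.
#' @param mean_coverage Mean sequencing depth (reads); per-locus depth is
#'   Poisson with this mean, truncated at 1.
#' @param purity_range Interval in (0, 1] for tumor purity, drawn uniformly.
#' @param cna_fraction_range Interval in [0, 1] for the fraction of mutations
#'   placed on copy-number-altered segments.
#' @param min_ccf_separation Minimum gap between any two clone cancer cell
#'   fractions (CCFs), in (0, 0.5].
#' @param survival_coeffs Numeric vector of log-hazard coefficients applied to
#'   the (standardized) latent ITH features; `NULL` means no ITH effect.
#' @param baseline_hazard Baseline exponential hazard rate (> 0).
#' @param censoring_horizon Upper bound of the uniform censoring distribution.
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_samples = 100,
                       clone_count_range = c(1L, 5L),
                       mutations_per_sample_range = c(50L, 300L),
                       mean_coverage = 100,
                       purity_range = c(0.3, 0.95),
                       cna_fraction_range = c(0, 0.4),
                       min_ccf_separation = 0.1,
                       survival_coeffs = NULL,
                       baseline_hazard = 0.1,
                       censoring_horizon = 20,
                       seed = 1L) {
  stopifnot(
    length(n_samples) == 1L, n_samples >= 1,
    length(clone_count_range) == 2L, clone_count_range[1] >= 1,
    clone_count_range[1] <= clone_count_range[2],
    length(mutations_per_sample_range) == 2L,
    mutations_per_sample_range[1] >= 1,
    mutations_per_sample_range[1] <= mutations_per_sample_range[2],
    mean_coverage > 0,
    length(purity_range) == 2L, purity_range[1] > 0, purity_range[2] <= 1,
    purity_range[1] <= purity_range[2],
    length(cna_fraction_range) == 2L, cna_fraction_range[1] >= 0,
    cna_fraction_range[2] <= 1, cna_fraction_range[1] <= cna_fraction_range[2],
    min_ccf_separation > 0, min_ccf_separation <= 0.5,
    baseline_hazard > 0, censoring_horizon > 0
  )
  structure(list(
    n_samples = as.integer(n_samples),
    clone_count_range = as.integer(clone_count_range),
    mutations_per_sample_range = as.integer(mutations_per_sample_range),
    mean_coverage = mean_coverage,
    purity_range = purity_range,
    cna_fraction_range = cna_fraction_range,
    min_ccf_separation = min_ccf_separation,
    survival_coeffs = survival_coeffs,
    baseline_hazard = baseline_hazard,
    censoring_horizon = censoring_horizon,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d, clones: %d-%d, SNVs/sample: %d-%d\n",
              x$n_samples, x$clone_count_range[1], x$clone_count_range[2],
              x$mutations_per_sample_range[1], x$mutations_per_sample_range[2]))
  cat(sprintf("  coverage: %gx, purity: [%g, %g], CNA fraction: [%g, %g]\n",
              x$mean_coverage, x$purity_range[1], x$purity_range[2],
              x$cna_fraction_range[1], x$cna_fraction_range[2]))
  cat(sprintf("  min CCF separation: %g, h0: %g, censoring horizon: %g, seed: %d\n",
              x$min_ccf_separation, x$baseline_hazard, x$censoring_horizon, x$seed))
  invisible(x)
}

#' Simulate a ground-truth clone structure
#'
#' Draws clone cancer cell fractions and a mutation-to-clone assignment. The
#' truncal clone sits at CCF 1; subclone CCFs are drawn uniformly and resampled
#' until all pairwise gaps (including the gap to the truncal clone) are at
#' least `config$min_ccf_separation`. Mutation counts per clone follow a
#' symmetric Dirichlet-multinomial with every clone receiving at least one
#' mutation. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config A [sim_config()] object.
#' @param n_clones Optional clone count; drawn from `clone_count_range` if `NULL`.
#' @param n_mutations Optional mutation count; drawn from
#'   `mutations_per_sample_range` if `NULL`.
#'
#' @return An object of class `"clone_structure"`: list with `clone_ids`,
#'   `ccfs` (named, sorted decreasing, first element 1), and `assignment`
#'   (named character vector, mutation_id -> clone_id).
#' @export
simulate_clone_structure <- function(config, n_clones = NULL, n_mutations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_clones)) {
    n_clones <- sample(seq(config$clone_count_range[1],
                           config$clone_count_range[2]), 1L)
  }
  if (is.null(n_mutations)) {
    n_mutations <- sample(seq(config$mutations_per_sample_range[1],
                              config$mutations_per_sample_range[2]), 1L)
  }
  n_clones <- as.integer(n_clones)
  n_mutations <- as.integer(n_mutations)
  if (n_mutations < n_clones) {
    stop("need at least one mutation per clone")
  }
  sep <- config$min_ccf_separation
  ccf_floor <- 0.02  # keep subclones detectably above zero prevalence
  # K-1 subclones must fit below 1 - sep with pairwise gaps >= sep
  if (n_clones > 1 && ccf_floor + (n_clones - 1) * sep > 1) {
    stop(sprintf("cannot place %d clones with CCF separation %g", n_clones, sep))
  }
  ccfs <- 1
  if (n_clones > 1) {
    ok <- FALSE
    for (attempt in seq_len(10000L)) {
      sub <- sort(stats::runif(n_clones - 1L, ccf_floor, 1 - sep),
                  decreasing = TRUE)
      if (all(diff(c(1, sub)) <= -sep)) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to sample separated subclone CCFs; loosen min_ccf_separation")
    ccfs <- c(1, sub)
  }
  clone_ids <- sprintf("clone%02d", seq_len(n_clones))
  names(ccfs) <- clone_ids
  # symmetric Dirichlet(1) weights, multinomial split of the non-guaranteed mass
  w <- stats::rgamma(n_clones, shape = 1)
  w <- w / sum(w)
  extra <- stats::rmultinom(1L, n_mutations - n_clones, prob = w)[, 1L]
  sizes <- extra + 1L
  mutation_ids <- sprintf("mut%05d", seq_len(n_mutations))
  assignment <- rep(clone_ids, times = sizes)
  names(assignment) <- mutation_ids
  structure(list(clone_ids = clone_ids, ccfs = ccfs, assignment = assignment),
            class = "clone_structure")
}

#' @export
print.clone_structure <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$clone_ids))
  cat(sprintf("Clone structure: %d clones, %d mutations\n",
              length(x$clone_ids), length(x$assignment)))
  print(data.frame(clone_id = x$clone_ids, ccf = unname(x$ccfs),
                   n_mut = as.integer(sizes)), row.names = FALSE)
  invisible(x)
}

#' Expected variant allele fraction under the CCF/purity/copy-number model
#'
#' The standard allele-fraction model: a mutation present in a fraction `ccf`
#' of tumor cells, on `multiplicity` of the `cn_total` tumor copies, in a
#' sample of purity `purity` with diploid (by default) normal contamination,
#' is expected at
#' \deqn{VAF = \rho m \cdot ccf / (\rho CN_t + (1-\rho) CN_n).}
#'
#' @param ccf Cancer cell fraction in (0, 1]. Vectorized.
#' @param purity Tumor purity in (0, 1].
#' @param cn_total Total tumor copy number at the locus (>= 1).
#' @param multiplicity Number of mutated copies (1 <= m <= cn_total).
#' @param cn_normal Normal-cell copy number (default 2, diploid).
#'
#' @return Expected VAF in [0, 1].
#' @export
expected_vaf <- function(ccf, purity, cn_total, multiplicity, cn_normal = 2) {
  if (any(ccf <= 0 | ccf > 1)) stop("ccf must be in (0, 1]")
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(cn_total < 1)) stop("cn_total must be >= 1")
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  if (any(multiplicity > cn_total)) stop("multiplicity cannot exceed cn_total")
  purity * multiplicity * ccf / (purity * cn_total + (1 - purity) * cn_normal)
}

#' Invert the expected-VAF model to a CCF estimate
#'
#' @inheritParams expected_vaf
#' @param vaf Observed variant allele fraction.
#' @return CCF estimate, capped at 1.
#' @export
ccf_from_vaf <- function(vaf, purity, cn_total, multiplicity, cn_normal = 2) {
  ccf <- vaf * (purity * cn_total + (1 - purity) * cn_normal) /
    (purity * multiplicity)
  pmin(pmax(ccf, 0), 1)
}

# Poisson depth truncated at >= 1 (zero-depth loci have no defined VAF)
rpois_trunc1 <- function(n, lambda) {
  d <- stats::rpois(n, lambda)
  while (any(d == 0L)) {
    z <- d == 0L
    d[z] <- stats::rpois(sum(z), lambda)
  }
  d
}

#' Simulate tumor/normal read counts for a clone structure
#'
#' Per mutation, tumor depth is Poisson(`mean_coverage`) truncated at 1 and
#' the alt count is Binomial(depth, [expected_vaf()]); the matched normal gets
#' an independent truncated-Poisson depth with alt reads at a fixed
#' sequencing-error rate.
#'
#' @param structure A `"clone_structure"`.
#' @param purity Sample purity in (0, 1].
#' @param cn_total Per-mutation total copy number (scalar or vector).
#' @param multiplicity Per-mutation multiplicity (scalar or vector).
#' @param mean_coverage Mean depth.
#' @param error_rate Normal-sample alt-read error rate (default 0.001).
#'
#' @return A `data.frame` of variant records: `mutation_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `is_indel`, `caller`, `filter_status`, `af_1000g`,
#'   `af_exac`, `in_cosmic`, `normal_depth`, `normal_alt`, `tumor_depth`,
#'   `tumor_alt`, plus ground-truth columns `clone_id`, `true_ccf`,
#'   `cn_total`, `multiplicity`, `true_vaf`.
#' @export
simulate_read_counts <- function(structure, purity, cn_total = 2L,
                                 multiplicity = 1L, mean_coverage = 100,
                                 error_rate = 0.001) {
  stopifnot(inherits(structure, "clone_structure"))
  n <- length(structure$assignment)
  cn_total <- rep_len(as.integer(cn_total), n)
  multiplicity <- rep_len(as.integer(multiplicity), n)
  ccf <- unname(structure$ccfs[structure$assignment])
  vaf <- expected_vaf(ccf, purity, cn_total, multiplicity)
  tumor_depth <- rpois_trunc1(n, mean_coverage)
  tumor_alt <- stats::rbinom(n, tumor_depth, vaf)
  normal_depth <- rpois_trunc1(n, mean_coverage)
  normal_alt <- stats::rbinom(n, normal_depth, error_rate)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(
    mutation_id = names(structure$assignment),
    chrom = "chr1",
    pos = seq_len(n) * 1000L,
    ref = ref,
    alt = unname(alt),
    is_indel = FALSE,
    caller = "Mutect2",
    filter_status = "PASS",
    af_1000g = NA_real_,
    af_exac = NA_real_,
    in_cosmic = FALSE,
    normal_depth = normal_depth,
    normal_alt = normal_alt,
    tumor_depth = tumor_depth,
    tumor_alt = tumor_alt,
    clone_id = unname(structure$assignment),
    true_ccf = ccf,
    cn_total = cn_total,
    multiplicity = multiplicity,
    true_vaf = vaf,
    stringsAsFactors = FALSE
  )
}

#' Derive nested protected/public mutation views
#'
#' The protected view is the full record set; the public view keeps variants
#' with strong evidence (alt reads >= `public_min_alt` or VAF >=
#' `public_min_vaf`) and then retains each survivor independently with
#' probability `retention_prob`, emulating the stricter release filtering of
#' public call sets. The public view is always a subset of the protected one.
#'
#' @param variants Variant record `data.frame` (see [simulate_read_counts()]).
#' @param public_min_alt Minimum tumor alt reads for the evidence rule (default 8).
#' @param public_min_vaf Minimum tumor VAF for the evidence rule (default 0.1).
#' @param retention_prob Independent retention probability (default 0.9).
#'
#' @return `list(protected = ..., public = ...)` of variant data frames.
#' @export
derive_views <- function(variants, public_min_alt = 8, public_min_vaf = 0.1,
                         retention_prob = 0.9) {
  stopifnot(is.data.frame(variants))
  vaf <- ifelse(variants$tumor_depth > 0,
                variants$tumor_alt / variants$tumor_depth, 0)
  evidence <- variants$tumor_alt >= public_min_alt | vaf >= public_min_vaf
  keep <- evidence & stats::runif(nrow(variants)) <= retention_prob
  list(protected = variants, public = variants[keep, , drop = FALSE])
}

#' Simulate censored survival labels from features
#'
#' Event times are exponential with rate `h0 * exp(x %*% beta)` (a
#' proportional-hazards generator); censoring times are uniform on
#' `(0, censoring_horizon)`; the observed time is the minimum and the event
#' indicator records whether the event preceded censoring.
#'
#' @param features Numeric matrix (samples x features).
#' @param beta Coefficient vector, one per feature column.
#' @param baseline_hazard Baseline rate h0 > 0.
#' @param censoring_horizon Upper bound of the censoring distribution; `Inf`
#'   disables censoring.
#'
#' @return A `data.frame` with `time` and `event` (1 = observed death).
#' @export
simulate_survival_labels <- function(features, beta, baseline_hazard,
                                     censoring_horizon) {
  features <- as.matrix(features)
  if (length(beta) != ncol(features)) {
    stop("length(beta) must equal ncol(features)")
  }
  n <- nrow(features)
  rate <- baseline_hazard * exp(drop(features %*% beta))
  t_event <- stats::rexp(n, rate = rate)
  if (is.finite(censoring_horizon)) {
    t_cens <- stats::runif(n, 0, censoring_horizon)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Simulate a full synthetic cohort
#'
#' Generates `config$n_samples` tumors: clone structure, purity, per-mutation
#' copy number and multiplicity, tumor/normal read counts, protected/public
#' mutation views, latent ITH features (clone count, major-clone SNV fraction,
#' minimum clone prevalence, Shannon index, largest-clone prevalence), simple
#' clinical covariates (age, stage), and censored survival driven by the
#' standardized latent features through `config$survival_coeffs`.
#'
#' Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `"ith_cohort"`: list with `samples` (per-sample
#'   lists: `variants`, `views`, `purity`, `truth`, `features_latent`),
#'   `features` (matrix of latent features), `clinical` (data.frame),
#'   `survival` (data.frame `sample_id`, `time`, `event`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  samples <- vector("list", n)
  names(samples) <- sample_ids
  feats <- matrix(NA_real_, n, 5,
                  dimnames = list(sample_ids,
                                  c("n_clones", "major_clone_snv_fraction",
                                    "min_clone_prevalence", "shannon_index",
                                    "largest_clone_prevalence")))
  for (s in seq_len(n)) {
    truth <- simulate_clone_structure(config)
    purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
    nm <- length(truth$assignment)
    cna_frac <- stats::runif(1, config$cna_fraction_range[1],
                             config$cna_fraction_range[2])
    cn_total <- rep(2L, nm)
    multiplicity <- rep(1L, nm)
    on_cna <- stats::runif(nm) < cna_frac
    if (any(on_cna)) {
      cn_total[on_cna] <- sample(c(1L, 3L, 4L), sum(on_cna), replace = TRUE,
                                 prob = c(0.3, 0.5, 0.2))
      major <- pmax(1L, cn_total[on_cna] - 1L)
      multiplicity[on_cna] <- vapply(major, function(mj) sample.int(mj, 1L),
                                     integer(1))
    }
    variants <- simulate_read_counts(truth, purity, cn_total, multiplicity,
                                     config$mean_coverage)
    views <- derive_views(variants)
    fl <- extract_ith_features(as_reconstruction(truth, purity = purity))
    feats[s, ] <- unlist(fl[colnames(feats)])
    samples[[s]] <- list(sample_id = sample_ids[s], variants = variants,
                         views = views, purity = purity,
                         cna_fraction = cna_frac, truth = truth,
                         features_latent = feats[s, ])
  }
  clinical <- data.frame(
    sample_id = sample_ids,
    age = round(stats::rnorm(n, 62, 10), 1),
    stage = sample(c("I", "II", "III"), n, replace = TRUE,
                   prob = c(0.35, 0.4, 0.25)),
    stringsAsFactors = FALSE
  )
  # standardize latent features so survival_coeffs are per-SD log hazards
  z <- scale(feats)
  z[, apply(feats, 2, stats::sd) == 0] <- 0
  beta <- config$survival_coeffs
  if (is.null(beta)) beta <- rep(0, ncol(feats))
  if (length(beta) != ncol(feats)) {
    stop("survival_coeffs must have one entry per latent feature (5)")
  }
  clin_lp <- 0.02 * (clinical$age - 62) +
    ifelse(clinical$stage == "II", 0.3, ifelse(clinical$stage == "III", 0.6, 0))
  surv <- simulate_survival_labels(cbind(z, clin_lp),
                                   c(beta, 1),
                                   config$baseline_hazard,
                                   config$censoring_horizon)
  survival <- data.frame(sample_id = sample_ids, time = surv$time,
                         event = surv$event, stringsAsFactors = FALSE)
  structure(list(samples = samples, features = feats, clinical = clinical,
                 survival = survival, config = config),
            class = "ith_cohort")
}

#' @export
print.ith_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ITH cohort: %d samples (seed %d)\n",
              length(x$samples), x$config$seed))
  cat(sprintf("  clones/sample: %s; events: %d/%d\n",
              paste(range(x$features[, "n_clones"]), collapse = "-"),
              sum(x$survival$event), nrow(x$survival)))
  invisible(x)
}

#' Write a cohort to disk as plain-text tables and VCFs
#'
#' Emits, per sample, a tumor/normal pair VCF (`<id>.vcf.gz`, AD/DP-style
#' counts) and a TSV mirror of the variant table, plus cohort-level
#' ground-truth tables `clones.tsv` (`sample_id`, `clone_id`, `ccf`, `n_mut`),
#' `assignment.tsv` (`sample_id`, `mutation_id`, `clone_id`), `survival.tsv`
#' and `clinical.tsv`.
#'
#' @param cohort An `"ith_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ith_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clones <- list(); assign_rows <- list()
  for (s in cohort$samples) {
    v <- s$variants
    utils::write.table(v, file.path(dir, paste0(s$sample_id, "_variants.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_variants_vcf(v, file.path(dir, paste0(s$sample_id, ".vcf.gz")))
    tab <- table(factor(s$truth$assignment, levels = s$truth$clone_ids))
    clones[[s$sample_id]] <- data.frame(
      sample_id = s$sample_id, clone_id = s$truth$clone_ids,
      ccf = unname(s$truth$ccfs), n_mut = as.integer(tab))
    assign_rows[[s$sample_id]] <- data.frame(
      sample_id = s$sample_id, mutation_id = names(s$truth$assignment),
      clone_id = unname(s$truth$assignment))
  }
  utils::write.table(do.call(rbind, clones), file.path(dir, "clones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, assign_rows),
                     file.path(dir, "assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
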