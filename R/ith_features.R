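#' Shannon index of a clonal distribution
#'
#' \eqn{-\sum_k p_k \ln p_k} with \eqn{p_k} the fraction of mutations in
#' clone k. Natural logarithm; a single clone gives 0.
#'
#' @param clone_sizes Non-negative mutation counts per clone.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(clone_sizes) {
  if (all(clone_sizes == 0)) stop("all clone sizes are zero")
  p <- clone_sizes / sum(clone_sizes)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Extract per-sample ITH summary features from a reconstruction
#'
#' The five clone-level features: number of clones, proportion of SNVs in the
#' major clone (the clone with most SNVs; ties broken by higher prevalence,
#' then clone id), minimal cellular prevalence over clones, Shannon index of
#' the clonal distribution, and the cellular prevalence of the largest clone.
#'
#' @param recon A (typically post-filtered) `"subclonal_recon"`.
#' @param subclones_only If `TRUE`, the minimum-prevalence feature is taken
#'   over non-truncal clones only (clones with CCF < max CCF); default `FALSE`
#'   takes the minimum over all retained clones.
#' @return Named list: `n_clones`, `major_clone_snv_fraction`,
#'   `min_clone_prevalence`, `shannon_index`, `largest_clone_prevalence`.
#' @export
extract_ith_features <- function(recon, subclones_only = FALSE) {
  stopifnot(inherits(recon, "subclonal_recon"))
  cl <- recon$clones
  if (nrow(cl) == 0L || sum(cl$n_mut) == 0L) stop("empty reconstruction")
  ord <- order(-cl$n_mut, -cl$ccf, cl$clone_id)
  major <- cl[ord[1L], ]
  min_pool <- cl$ccf
  if (subclones_only && nrow(cl) > 1L) {
    min_pool <- cl$ccf[cl$ccf < max(cl$ccf)]
    if (!length(min_pool)) min_pool <- cl$ccf
  }
  list(
    n_clones = nrow(cl),
    major_clone_snv_fraction = major$n_mut / sum(cl$n_mut),
    min_clone_prevalence = min(min_pool),
    shannon_index = shannon_index(cl$n_mut),
    largest_clone_prevalence = major$ccf
  )
}

#' MATH score (mutant-allele tumor heterogeneity)
#'
#' \eqn{100 \cdot MAD / median} of the VAF distribution, where MAD is the
#' median absolute deviation scaled by the consistency constant 1.4826.
#' Scale-invariant in the VAFs.
#'
#' @param vafs Variant allele fractions (at least one, median > 0).
#' @return Non-negative MATH score.
#' @export
math_score <- function(vafs) {
  if (length(vafs) < 1L) stop("need at least one VAF")
  med <- stats::median(vafs)
  if (med == 0) stop("median VAF is zero; MATH undefined")
  100 * stats::mad(vafs, constant = 1.4826) / med
}

#' Cohort-inverted signature scores
#'
#' For each sample, the complement to the cohort maximum:
#' \eqn{inv_i = \max_j raw_j - raw_i}, so the inverted score varies in the
#' same direction as tumor purity and stays non-negative.
#'
#' @param raw_scores Named or unnamed numeric vector of per-sample signature
#'   scores over the cohort.
#' @return List with `raw` and `inverted` vectors.
#' @export
signature_inverse <- function(raw_scores) {
  if (length(raw_scores) == 0L) stop("empty cohort")
  list(raw = raw_scores, inverted = max(raw_scores) - raw_scores)
}

#' Augment a feature vector or matrix with elementwise squares
#'
#' @param features Numeric vector or matrix.
#' @return Vector of doubled length, or matrix with doubled columns
#'   (squared columns suffixed `"_sq"`).
#' @export
augment_squared <- function(features) {
  if (is.matrix(features) || is.data.frame(features)) {
    m <- as.matrix(features)
    sq <- m^2
    colnames(sq) <- paste0(colnames(m), "_sq")
    return(cbind(m, sq))
  }
  c(features, features^2)
}

#' Combine per-method ITH features and MATH into one matrix
#'
#' Column-binds each method's feature block (columns prefixed by the method
#' name) and appends the MATH column; with five clone-resolving methods this
#' is the 26-feature combined model (5 methods x 5 features + MATH).
#'
#' @param feature_tables Named list of per-method feature matrices or data
#'   frames (same rows: samples).
#' @param math Optional numeric vector of per-sample MATH scores.
#' @return Numeric matrix.
#' @export
combine_features <- function(feature_tables, math = NULL) {
  stopifnot(length(feature_tables) >= 1L)
  blocks <- lapply(names(feature_tables), function(m) {
    b <- as.matrix(feature_tables[[m]])
    colnames(b) <- paste(m, colnames(b), sep = ".")
    b
  })
  out <- do.call(cbind, blocks)
  if (!is.null(math)) out <- cbind(out, math_score = math)
  out
}
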