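#' Clone-number adequacy score (score1B)
#'
#' \eqn{(J_1 + 1 - \min(J_1 + 1, |J_2 - J_1|)) / (J_1 + 1)}: 1 when the two
#' clone counts agree, decaying with their absolute difference relative to
#' the reference count. Asymmetric in (J1, J2).
#'
#' @param J1 Reference clone count (>= 1).
#' @param J2 Compared clone count (>= 1).
#' @return Score in [0, 1].
#' @export
score1B <- function(J1, J2) {
  if (any(J1 < 1) || any(J2 < 1)) stop("clone counts must be >= 1")
  (J1 + 1 - pmin(J1 + 1, abs(J2 - J1))) / (J1 + 1)
}

# exact 1-Wasserstein distance between weighted point-mass distributions:
# integral of |F1 - F2| over the merged support
wasserstein1_weighted <- function(x1, w1, x2, w2) {
  w1 <- w1 / sum(w1); w2 <- w2 / sum(w2)
  grid <- sort(unique(c(x1, x2)))
  if (length(grid) == 1L) return(0)
  F1 <- vapply(grid, function(g) sum(w1[x1 <= g]), numeric(1))
  F2 <- vapply(grid, function(g) sum(w2[x2 <= g]), numeric(1))
  k <- length(grid)
  sum(abs(F1[-k] - F2[-k]) * diff(grid))
}

#' Wasserstein distance between clone CCF distributions (score1C)
#'
#' Represents each reconstruction as a distribution putting, at every clone's
#' CCF, mass proportional to the clone's number of mutations, and returns the
#' exact 1-Wasserstein distance between the two distributions. Symmetric;
#' 0 iff the distributions coincide.
#'
#' @param recon1,recon2 `"subclonal_recon"` objects with CCFs (reconstructions
#'   without prevalence estimates, e.g. pure consensus clusterings, are
#'   rejected).
#' @return Non-negative distance.
#' @export
score1C <- function(recon1, recon2) {
  stopifnot(inherits(recon1, "subclonal_recon"),
            inherits(recon2, "subclonal_recon"))
  if (any(is.na(recon1$clones$ccf)) || any(is.na(recon2$clones$ccf))) {
    stop("score1C requires clone CCFs in both reconstructions")
  }
  wasserstein1_weighted(recon1$clones$ccf, recon1$clones$n_mut,
                        recon2$clones$ccf, recon2$clones$n_mut)
}

#' Binary co-clustering matrix of a reconstruction
#'
#' N x N binary matrix over `mutation_order` with entry 1 iff the two
#' mutations are assigned to the same clone (diagonal 1). Valid partitions
#' give symmetric, transitive matrices.
#'
#' @param recon A `"subclonal_recon"`.
#' @param mutation_order Ordered character vector of mutation ids (must all
#'   be present in `recon`); defaults to the sorted mutation ids of `recon`.
#' @return Integer matrix with dimnames; the partition labels are attached as
#'   attribute `"labels"`.
#' @export
cocluster_matrix <- function(recon, mutation_order = NULL) {
  stopifnot(inherits(recon, "subclonal_recon"))
  if (is.null(mutation_order)) mutation_order <- sort(names(recon$assignment))
  missing <- setdiff(mutation_order, names(recon$assignment))
  if (length(missing)) {
    stop("mutation(s) not in reconstruction: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  labels <- recon$assignment[mutation_order]
  M <- outer(labels, labels, `==`) + 0L
  dimnames(M) <- list(mutation_order, mutation_order)
  attr(M, "labels") <- unname(labels)
  M
}

# partition labels from a (partition-valid) co-clustering matrix
labels_from_matrix <- function(M) {
  match(apply(M, 1L, paste, collapse = ""), unique(apply(M, 1L, paste, collapse = "")))
}

# V-measure of a predicted partition against reference classes.
# Natural-log conditional entropies; a component whose reference entropy is
# zero is set to 1; V = harmonic mean of homogeneity and completeness.
v_measure_labels <- function(labels_true, labels_pred) {
  n <- length(labels_true)
  tab <- table(labels_true, labels_pred)
  joint <- tab / n
  pc <- rowSums(joint); pk <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_c <- ent(pc); h_k <- ent(pk)
  cond <- function(joint, marg_other) {
    # H(A|B) = -sum joint * log(joint / p(B))
    s <- 0
    for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
      p <- joint[i, j]
      if (p > 0) s <- s - p * log(p / marg_other[j])
    }
    s
  }
  h_c_given_k <- cond(joint, pk)
  h_k_given_c <- cond(t(joint), pc)
  homogeneity <- if (h_c == 0) 1 else unname(1 - h_c_given_k / h_c)
  completeness <- if (h_k == 0) 1 else unname(1 - h_k_given_c / h_k)
  if (homogeneity + completeness == 0) return(0)
  unname(2 * homogeneity * completeness / (homogeneity + completeness))
}

#' Raw agreement between two co-clustering matrices
#'
#' Pearson and Matthews correlation coefficients over the vectorized N^2
#' entries (diagonal included), and the V-measure of the second partition
#' scored against the first as reference classes. Degenerate cases (zero
#' variance or zero MCC denominator) return 0 by convention.
#'
#' @param M1 Reference co-clustering matrix (see [cocluster_matrix()]).
#' @param M2 Compared co-clustering matrix over the same mutation order.
#' @return List with `pcc`, `mcc`, `v_measure`.
#' @export
raw_coclustering_agreement <- function(M1, M2) {
  if (!all(dim(M1) == dim(M2))) stop("matrix dimensions differ")
  if (nrow(M1) < 2L) stop("need at least 2 mutations")
  if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
      !identical(rownames(M1), rownames(M2))) {
    stop("mutation orders differ")
  }
  v1 <- as.numeric(M1); v2 <- as.numeric(M2)
  pcc <- if (stats::sd(v1) == 0 || stats::sd(v2) == 0) 0 else
    stats::cor(v1, v2)
  tp <- sum(v1 == 1 & v2 == 1); tn <- sum(v1 == 0 & v2 == 0)
  fp <- sum(v1 == 0 & v2 == 1); fn <- sum(v1 == 1 & v2 == 0)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  l1 <- attr(M1, "labels"); l2 <- attr(M2, "labels")
  if (is.null(l1)) l1 <- labels_from_matrix(M1)
  if (is.null(l2)) l2 <- labels_from_matrix(M2)
  list(pcc = pcc, mcc = mcc, v_measure = v_measure_labels(l1, l2))
}

#' Rescale a raw agreement score against the worse bad scenario
#'
#' Bad scenarios are the all-ones prediction (all mutations in one cluster)
#' and the identity prediction (every mutation its own cluster). The raw
#' score is mapped to `clip((raw - worst) / (1 - worst), 0, 1)` where
#' `worst = min(raw_allones, raw_identity)`; a degenerate scale
#' (`1 - worst < 1e-12`) returns 1 if `raw >= worst`, else 0.
#'
#' @param raw Raw score of the compared prediction.
#' @param raw_allones Raw score of the all-ones prediction.
#' @param raw_identity Raw score of the identity prediction.
#' @return Rescaled score in [0, 1].
#' @export
rescale_against_bad <- function(raw, raw_allones, raw_identity) {
  worst <- min(raw_allones, raw_identity)
  if (1 - worst < 1e-12) return(if (raw >= worst) 1 else 0)
  min(max((raw - worst) / (1 - worst), 0), 1)
}

#' Co-clustering agreement score (score2A)
#'
#' Restricted to the mutations present in both reconstructions, builds the
#' two co-clustering matrices (first reconstruction as reference), computes
#' Pearson, Matthews and V-measure agreement, rescales each against the worse
#' of the two bad scenarios, and averages. Asymmetric in its arguments.
#'
#' @param recon1 Reference `"subclonal_recon"`.
#' @param recon2 Compared `"subclonal_recon"`.
#' @return Score in [0, 1].
#' @export
score2A <- function(recon1, recon2) {
  stopifnot(inherits(recon1, "subclonal_recon"),
            inherits(recon2, "subclonal_recon"))
  common <- intersect(names(recon1$assignment), names(recon2$assignment))
  if (length(common) < 2L) {
    stop("fewer than 2 common mutations; reconstructions not comparable")
  }
  ord <- sort(common)
  M1 <- cocluster_matrix(recon1, ord)
  M2 <- cocluster_matrix(recon2, ord)
  n <- length(ord)
  ones <- matrix(1L, n, n); attr(ones, "labels") <- rep(1L, n)
  eye <- diag(1L, n); attr(eye, "labels") <- seq_len(n)
  raw <- raw_coclustering_agreement(M1, M2)
  raw_ones <- raw_coclustering_agreement(M1, ones)
  raw_eye <- raw_coclustering_agreement(M1, eye)
  comps <- vapply(c("pcc", "mcc", "v_measure"), function(k) {
    rescale_against_bad(raw[[k]], raw_ones[[k]], raw_eye[[k]])
  }, numeric(1))
  mean(comps)
}

#' Pairwise method-agreement table of per-sample medians
#'
#' For every ordered pair of methods, computes the chosen metric on each
#' sample present for both (metric failures on a sample are warned about and
#' excluded) and reports the median. All metrics are treated as asymmetric:
#' entry [a, b] uses method a as first (reference) argument.
#'
#' @param recons Named list of methods, each a named list of per-sample
#'   `"subclonal_recon"` objects.
#' @param metric One of `"1B"`, `"1C"`, `"2A"`.
#' @return Square numeric matrix of median scores (methods x methods).
#' @export
pairwise_comparison_table <- function(recons, metric = c("1B", "1C", "2A")) {
  metric <- match.arg(metric)
  fun <- switch(metric,
    "1B" = function(a, b) score1B(n_clones(a), n_clones(b)),
    "1C" = score1C,
    "2A" = score2A)
  methods <- names(recons)
  out <- matrix(NA_real_, length(methods), length(methods),
                dimnames = list(methods, methods))
  for (a in methods) for (b in methods) {
    common <- intersect(names(recons[[a]]), names(recons[[b]]))
    vals <- vapply(common, function(s) {
      tryCatch(fun(recons[[a]][[s]], recons[[b]][[s]]),
               error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(vals)) {
      warning(sprintf("%s vs %s: %d sample(s) not comparable, excluded",
                      a, b, sum(is.na(vals))))
    }
    out[a, b] <- stats::median(vals, na.rm = TRUE)
  }
  out
}

#' Pairwise Pearson correlations with BH-controlled significance
#'
#' Computes Pearson's r for every pair of columns, two-sided p-values for the
#' null r = 0 (t transform), and a Benjamini-Hochberg mask at the given FDR
#' across all tested (off-diagonal) pairs. Pairs with fewer than 3 complete
#' observations or a constant column are excluded with a warning.
#'
#' @param measures Numeric `data.frame` or matrix (samples x measures).
#' @param fdr FDR level for the BH mask (default 0.05).
#' @return List with matrices `r`, `p`, `p_adj` and logical `significant`.
#' @export
correlation_analysis <- function(measures, fdr = 0.05) {
  m <- as.matrix(measures)
  p_names <- colnames(m)
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(p_names, p_names))
  diag(r) <- 1; diag(p) <- 0
  skipped <- character(0)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) < 3 || stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
      skipped <- c(skipped, paste(p_names[i], p_names[j], sep = "~"))
      next
    }
    ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (length(skipped)) {
    warning("excluded pair(s): ", paste(skipped, collapse = ", "))
  }
  ut <- upper.tri(p)
  p_adj <- matrix(NA_real_, k, k, dimnames = dimnames(p))
  p_adj[ut] <- stats::p.adjust(p[ut], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  diag(p_adj) <- 0
  significant <- !is.na(p_adj) & p_adj <= fdr
  list(r = r, p = p, p_adj = p_adj, significant = significant)
}
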