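# Independent brute-force oracles, deliberately written with plain loops and
# textbook formulas so they share no code path with the package internals.

# all partitions of n items into at most max_blocks blocks, as canonical
# label vectors (restricted growth strings)
enum_partitions <- function(n, max_blocks) {
  out <- list()
  recurse <- function(labels, used) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(min(used + 1L, max_blocks))) {
      recurse(c(labels, lab), max(used, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

brute_cocluster <- function(labels) {
  n <- length(labels)
  M <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) if (labels[i] == labels[j]) M[i, j] <- 1L
  M
}

brute_pcc <- function(v1, v2) {
  n <- length(v1)
  m1 <- sum(v1) / n; m2 <- sum(v2) / n
  num <- 0; d1 <- 0; d2 <- 0
  for (k in 1:n) {
    num <- num + (v1[k] - m1) * (v2[k] - m2)
    d1 <- d1 + (v1[k] - m1)^2
    d2 <- d2 + (v2[k] - m2)^2
  }
  if (d1 == 0 || d2 == 0) return(0)
  num / sqrt(d1 * d2)
}

brute_mcc <- function(v1, v2) {
  tp <- tn <- fp <- fn <- 0
  for (k in seq_along(v1)) {
    if (v1[k] == 1 && v2[k] == 1) tp <- tp + 1
    if (v1[k] == 0 && v2[k] == 0) tn <- tn + 1
    if (v1[k] == 0 && v2[k] == 1) fp <- fp + 1
    if (v1[k] == 1 && v2[k] == 0) fn <- fn + 1
  }
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

brute_entropy <- function(labels) {
  n <- length(labels)
  h <- 0
  for (lev in unique(labels)) {
    p <- sum(labels == lev) / n
    h <- h - p * log(p)
  }
  h
}

brute_vmeasure <- function(true_labels, pred_labels) {
  n <- length(true_labels)
  h_c <- brute_entropy(true_labels)
  h_k <- brute_entropy(pred_labels)
  h_c_given_k <- 0
  for (k in unique(pred_labels)) {
    idx <- pred_labels == k
    h_c_given_k <- h_c_given_k + sum(idx) / n * brute_entropy(true_labels[idx])
  }
  h_k_given_c <- 0
  for (c in unique(true_labels)) {
    idx <- true_labels == c
    h_k_given_c <- h_k_given_c + sum(idx) / n * brute_entropy(pred_labels[idx])
  }
  hom <- if (h_c == 0) 1 else 1 - h_c_given_k / h_c
  com <- if (h_k == 0) 1 else 1 - h_k_given_c / h_k
  if (hom + com == 0) return(0)
  2 * hom * com / (hom + com)
}

brute_raw_scores <- function(true_labels, pred_labels) {
  v1 <- as.vector(brute_cocluster(true_labels))
  v2 <- as.vector(brute_cocluster(pred_labels))
  c(pcc = brute_pcc(v1, v2), mcc = brute_mcc(v1, v2),
    v_measure = brute_vmeasure(true_labels, pred_labels))
}

brute_rescale <- function(raw, bad1, bad2) {
  worst <- min(bad1, bad2)
  if (1 - worst < 1e-12) return(if (raw >= worst) 1 else 0)
  max(min((raw - worst) / (1 - worst), 1), 0)
}

brute_score2A <- function(true_labels, pred_labels) {
  n <- length(true_labels)
  raw <- brute_raw_scores(true_labels, pred_labels)
  bad_ones <- brute_raw_scores(true_labels, rep(1L, n))
  bad_eye <- brute_raw_scores(true_labels, seq_len(n))
  mean(sapply(names(raw), function(k) {
    brute_rescale(raw[[k]], bad_ones[[k]], bad_eye[[k]])
  }))
}

# concordance index by direct pair enumeration
brute_ci <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && time[i] >= time[j] && event[j] == 1) {
      den <- den + 1
      if (scores[j] > scores[i]) num <- num + 1
      else if (scores[j] == scores[i]) num <- num + 0.5
    }
  }
  num / den
}

# build a reconstruction from integer labels (and optional per-clone CCFs)
recon_from_labels <- function(labels, ccfs = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%02d", seq_along(labels))
  clone_ids <- sort(unique(as.character(labels)))
  if (is.null(ccfs)) {
    ccfs <- seq(1, 0.2, length.out = length(clone_ids))
  }
  assignment <- as.character(labels)
  names(assignment) <- ids
  subclonal_reconstruction(clone_ids, ccfs, assignment)
}
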