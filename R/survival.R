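#' Comparable patient pairs under right censoring
#'
#' The ordered pairs (i, j) for which patient i is known to have lived at
#' least as long as patient j: `y_i >= y_j`, patient j had an observed event
#' (`delta_j = 1`), and i != j.
#'
#' @param time Observed times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Two-column integer matrix of (i, j) indices (possibly 0 rows).
#' @export
comparable_pairs <- function(time, event) {
  n <- length(time)
  stopifnot(length(event) == n)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  keep <- idx$i != idx$j & time[idx$i] >= time[idx$j] & event[idx$j] == 1
  as.matrix(idx[keep, c("i", "j"), drop = FALSE])
}

# squared-hinge ranking objective and gradient over comparable pairs,
# on standardized features Z: f(w) = w'w + alpha * sum max(0, 1 - (s_i - s_j))^2
ranksvm_objective <- function(w, Z, pairs, alpha) {
  s <- drop(Z %*% w)
  m <- 1 - (s[pairs[, 1]] - s[pairs[, 2]])
  act <- m > 0
  sum(w^2) + alpha * sum(m[act]^2)
}

ranksvm_gradient <- function(w, Z, pairs, alpha) {
  s <- drop(Z %*% w)
  m <- 1 - (s[pairs[, 1]] - s[pairs[, 2]])
  act <- m > 0
  d <- numeric(nrow(Z))
  if (any(act)) {
    ci <- m[act]
    ii <- pairs[act, 1]; jj <- pairs[act, 2]
    di <- rowsum(ci, ii); d[as.integer(rownames(di))] <- di
    dj <- rowsum(ci, jj)
    d[as.integer(rownames(dj))] <- d[as.integer(rownames(dj))] - dj
  }
  2 * w - 2 * alpha * drop(crossprod(Z, d))
}

#' Ranking support vector machine for censored survival
#'
#' Fits a linear survival ranking SVM: the weight vector minimizes the
#' strictly convex objective
#' \deqn{w^\top w + \alpha \sum_{(i,j) \in P} \max(0, 1 - (w^\top x_i - w^\top x_j))^2}
#' over the comparable pairs P (see [comparable_pairs()]), i.e. a squared
#' hinge penalizing pairs whose predicted ranking contradicts the observed
#' survival ordering, with a Euclidean-norm penalty. Features are z-scored
#' internally; optimization uses BFGS with an analytic gradient to a gradient
#' tolerance of 1e-6.
#'
#' @param x Numeric feature matrix (patients x features), or a formula.
#' @param ... Passed to methods.
#' @return Object of class `"rank_svm"` with elements `w` (weights on the
#'   standardized scale), `center`, `scale`, `alpha`, `objective`,
#'   `gradient_norm`, `converged`, `train_ci` and `feature_names`.
#' @export
rank_svm <- function(x, ...) UseMethod("rank_svm")

#' @rdname rank_svm
#' @param time Observed survival times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param alpha Regularization trade-off (> 0); default 1.
#' @param maxit Maximum BFGS iterations per restart.
#' @export
rank_svm.default <- function(x, time, event, alpha = 1, maxit = 500L, ...) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  stopifnot(nrow(x) == length(time), length(time) == length(event),
            alpha > 0)
  pairs <- comparable_pairs(time, event)
  if (nrow(pairs) == 0L) stop("no comparable pairs; cannot fit")
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Z <- sweep(sweep(x, 2, center), 2, scale_, "/")
  w <- numeric(ncol(Z))
  for (restart in 1:5) {
    opt <- stats::optim(w, ranksvm_objective, ranksvm_gradient,
                        Z = Z, pairs = pairs, alpha = alpha,
                        method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    w <- opt$par
    gnorm <- max(abs(ranksvm_gradient(w, Z, pairs, alpha)))
    if (gnorm <= 1e-6) break
  }
  names(w) <- colnames(x)
  fit <- structure(list(
    w = w, center = center, scale = scale_, alpha = alpha,
    objective = ranksvm_objective(w, Z, pairs, alpha),
    gradient_norm = gnorm, converged = gnorm <= 1e-6,
    n = nrow(x), n_pairs = nrow(pairs),
    feature_names = colnames(x)
  ), class = "rank_svm")
  fit$train_ci <- concordance_index(predict(fit, x), time, event)$ci
  fit
}

#' @rdname rank_svm
#' @param formula A formula with a [survival::Surv()] response, e.g.
#'   `Surv(time, event) ~ .`.
#' @param data Data frame holding the variables.
#' @export
rank_svm.formula <- function(x, data, alpha = 1, ...) {
  formula <- x
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stop("response must be a survival::Surv object")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- rank_svm.default(X, time = y[, "time"], event = y[, "status"],
                          alpha = alpha, ...)
  fit$call <- match.call()
  fit
}

#' @export
print.rank_svm <- function(x, ...) {
  cat(sprintf("Survival ranking SVM (alpha = %g)\n", x$alpha))
  cat(sprintf("  n = %d, comparable pairs = %d, training CI = %.3f\n",
              x$n, x$n_pairs, x$train_ci))
  cat("  weights (standardized features):\n")
  print(round(x$w, 4))
  invisible(x)
}

#' @export
coef.rank_svm <- function(object, ...) object$w

#' @export
summary.rank_svm <- function(object, ...) {
  cat(sprintf(
    "Survival ranking SVM: %d features, alpha = %g\n n = %d, |P| = %d\n",
    length(object$w), object$alpha, object$n, object$n_pairs))
  cat(sprintf(" objective = %.6g, max |gradient| = %.2e (converged: %s)\n",
              object$objective, object$gradient_norm, object$converged))
  cat(sprintf(" training concordance index = %.4f\n", object$train_ci))
  invisible(object)
}

#' Predict risk scores from a fitted ranking SVM
#'
#' Returns `-w' x` on the standardized feature scale, so that a higher score
#' means predicted shorter survival (a risk), matching the concordance-index
#' convention that rewards higher scores for shorter-lived patients.
#'
#' @param object A `"rank_svm"` fit.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param ... Ignored.
#' @return Numeric risk scores.
#' @export
predict.rank_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$w)) stop("feature dimension mismatch")
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  -drop(Z %*% object$w)
}

#' Concordance index of risk scores against censored survival
#'
#' Over the comparable pairs P, the fraction of pairs whose risk ordering
#' matches the survival ordering: \eqn{CI = |P|^{-1} \sum_{(i,j) \in P}
#' I(s_j - s_i)} with I(u) = 1 if u > 0, 1/2 if u = 0, 0 otherwise (the
#' shorter-lived patient j should have the larger risk). The standard error
#' is the leave-one-patient-out jackknife estimate of the U-statistic
#' sampling variance, computed exactly from per-patient concordant and
#' discordant pair tallies; it is consistent for the asymptotic (Noether)
#' variance and close to unbiased at cohort sizes in the hundreds.
#'
#' @param scores Predicted risk scores (higher = shorter predicted survival).
#' @param time Observed times.
#' @param event Event indicators.
#' @return Object of class `"concordance_result"`: list with `ci`, `n_pairs`,
#'   `se`.
#' @export
concordance_index <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  pairs <- comparable_pairs(time, event)
  if (nrow(pairs) == 0L) stop("no comparable pairs")
  u <- scores[pairs[, 2]] - scores[pairs[, 1]]
  conc <- ifelse(u > 0, 1, ifelse(u == 0, 0.5, 0))
  ci <- mean(conc)
  # per-patient concordant/discordant tallies (each pair credited to both)
  ch <- dh <- numeric(n)
  for (col in 1:2) {
    cs <- rowsum(conc, pairs[, col])
    ds <- rowsum(1 - conc, pairs[, col])
    at <- as.integer(rownames(cs))
    ch[at] <- ch[at] + cs
    dh[at] <- dh[at] + ds
  }
  # exact leave-one-patient-out CI values: dropping patient k removes the
  # ch[k] + dh[k] pairs involving k and their sum(conc) contribution ch[k]
  se <- NA_real_
  involved <- ch + dh
  remaining <- nrow(pairs) - involved
  if (n > 2 && all(remaining > 0)) {
    loo <- (sum(conc) - ch) / remaining
    se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  }
  structure(list(ci = ci, n_pairs = nrow(pairs), se = se),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance index: %.4f (|P| = %d, se = %.4f)\n",
              x$ci, x$n_pairs, x$se))
  invisible(x)
}

#' One-sided Noether test of CI against 0.5
#'
#' Asymptotic z-test `z = (CI - 0.5) / se` with the U-statistic standard
#' error, upper-tailed: small p means the score ranks survival better than
#' chance.
#'
#' @param result A `"concordance_result"`.
#' @return One-sided p-value.
#' @export
noether_ci_test <- function(result) {
  stopifnot(inherits(result, "concordance_result"))
  if (is.na(result$se) || result$se == 0) {
    stop("standard error is zero or undefined; test not applicable")
  }
  stats::pnorm((result$ci - 0.5) / result$se, lower.tail = FALSE)
}

#' Cross-validated concordance of the ranking SVM
#'
#' Splits patients into k folds (seeded shuffle, no stratification), fits the
#' ranking SVM on each training set and evaluates the concordance index on
#' the held-out fold. Folds whose test set has no comparable pairs are
#' skipped with a warning.
#'
#' @param x Feature matrix.
#' @param time,event Survival outcome.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param alpha Ranking-SVM regularization trade-off.
#' @return List with `folds` (assignment vector) and `results` (per-fold
#'   `"concordance_result"` objects, fold p-values accessible via
#'   [noether_ci_test()]).
#' @export
cross_validated_ci <- function(x, time, event, k = 5L, seed = 1L, alpha = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("more folds than samples")
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  results <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- rank_svm(x[!test, , drop = FALSE], time[!test], event[!test],
                    alpha = alpha)
    res <- tryCatch(
      concordance_index(predict(fit, x[test, , drop = FALSE]),
                        time[test], event[test]),
      error = function(e) {
        warning(sprintf("fold %d skipped: %s", f, conditionMessage(e)))
        NULL
      })
    results[[f]] <- res
  }
  list(folds = folds, results = Filter(Negate(is.null), results))
}

#' Fisher aggregation of p-values
#'
#' \eqn{\chi^2 = -2 \sum \ln p_i} on 2k degrees of freedom, upper tail.
#'
#' @param pvals p-values in (0, 1].
#' @return Aggregated p-value.
#' @export
fisher_aggregate <- function(pvals) {
  if (length(pvals) == 0L || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' @param pvals p-values.
#' @param fdr Target false discovery rate (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical mask at the given FDR).
#' @export
bh_correct <- function(pvals, fdr = 0.05) {
  if (length(pvals) == 0L) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= fdr)
}

#' Paired comparison of per-fold concordance indices
#'
#' Two-sided paired Student t-test across folds. Identical vectors give p = 1;
#' a zero-variance nonzero difference is an error (degenerate t statistic).
#'
#' @param ci_a,ci_b Per-fold CI values of the two models (same folds).
#' @return Two-sided p-value.
#' @export
compare_ci_paired <- function(ci_a, ci_b) {
  stopifnot(length(ci_a) == length(ci_b))
  if (length(ci_a) < 2L) stop("need at least 2 folds")
  d <- ci_a - ci_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(1)
    stop("zero-variance nonzero difference; t-test undefined")
  }
  stats::t.test(ci_a, ci_b, paired = TRUE)$p.value
}

#' Select clinical variables for survival modelling
#'
#' Three screening rules: (i) categorical variables are one-hot encoded and a
#' level is kept only if it covers at least `min_level_count` patients and at
#' least `min_level_count` patients take another level; (ii) numeric
#' variables are kept only if observed for every patient; (iii) survivors are
#' kept only if the Wald p-value of a univariate Cox proportional-hazards
#' model (Breslow ties) passes Benjamini-Hochberg at the given FDR.
#'
#' @param clinical Data frame of clinical variables (no outcome columns).
#' @param time,event Survival outcome, aligned with `clinical` rows.
#' @param min_level_count Minimum patients per kept categorical level and its
#'   complement (default 50).
#' @param fdr FDR level of the Cox screening (default 0.05).
#' @return List with `features` (numeric matrix of selected columns, possibly
#'   0 columns) and `screening` (data frame of candidates with `p`, `p_adj`,
#'   `kept`).
#' @export
select_clinical_variables <- function(clinical, time, event,
                                      min_level_count = 50L, fdr = 0.05) {
  stopifnot(nrow(clinical) == length(time), length(time) == length(event))
  n <- nrow(clinical)
  candidates <- list()
  for (nm in names(clinical)) {
    col <- clinical[[nm]]
    if (is.numeric(col)) {
      if (!anyNA(col)) candidates[[nm]] <- col
    } else {
      col <- as.character(col)
      for (lev in unique(col[!is.na(col)])) {
        x <- as.numeric(!is.na(col) & col == lev)
        if (sum(x) >= min_level_count && (n - sum(x)) >= min_level_count) {
          candidates[[paste(nm, lev, sep = "_")]] <- x
        }
      }
    }
  }
  if (length(candidates) == 0L) {
    warning("no clinical variables survive the availability/level rules")
    return(list(features = matrix(numeric(0), n, 0),
                screening = data.frame()))
  }
  pvals <- vapply(candidates, function(x) {
    fit <- survival::coxph(survival::Surv(time, event) ~ x,
                           ties = "breslow")
    summary(fit)$coefficients[1, "Pr(>|z|)"]
  }, numeric(1))
  bh <- bh_correct(pvals, fdr)
  screening <- data.frame(variable = names(candidates), p = unname(pvals),
                          p_adj = unname(bh$adjusted),
                          kept = unname(bh$reject),
                          stringsAsFactors = FALSE)
  kept <- names(candidates)[bh$reject]
  if (length(kept) == 0L) {
    warning("no clinical variables significantly associated with survival")
    return(list(features = matrix(numeric(0), n, 0), screening = screening))
  }
  features <- do.call(cbind, candidates[kept])
  colnames(features) <- kept
  list(features = features, screening = screening)
}
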