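test_that("comparable pairs enumerate certain survival orderings", {
  p <- comparable_pairs(c(5, 3, 1), c(1, 1, 1))
  expect_setequal(paste(p[, 1], p[, 2]), c("1 2", "1 3", "2 3"))
  p2 <- comparable_pairs(c(5, 3, 1), c(1, 0, 1))
  expect_setequal(paste(p2[, 1], p2[, 2]), c("1 3", "2 3"))
  expect_identical(nrow(comparable_pairs(c(5, 3, 1), c(0, 0, 0))), 0L)
  # tied event times are comparable in both directions
  p3 <- comparable_pairs(c(2, 2), c(1, 1))
  expect_identical(nrow(p3), 2L)
})

test_that("concordance index matches pair enumeration and its identities", {
  r <- concordance_index(c(1, 4, 2), c(5, 3, 1), c(1, 1, 1))
  expect_equal(r$ci, 2 / 3)
  expect_identical(r$n_pairs, 3L)
  set.seed(71)
  y <- rexp(60); d <- rbinom(60, 1, 0.7)
  expect_equal(concordance_index(-y, y, d)$ci, 1)
  expect_equal(concordance_index(rep(2, 60), y, d)$ci, 0.5)
  s <- rnorm(60)
  expect_equal(concordance_index(s, y, d)$ci +
                 concordance_index(-s, y, d)$ci, 1)
  # invariant under strictly increasing transforms
  expect_equal(concordance_index(exp(s), y, d)$ci,
               concordance_index(s, y, d)$ci)
  # agrees with the brute-force oracle on random data with ties
  s_tied <- round(rnorm(60), 1)
  expect_equal(concordance_index(s_tied, y, d)$ci, brute_ci(s_tied, y, d))
})

test_that("Noether test is centered at 0.5 and matches a permutation null", {
  set.seed(72)
  y <- rexp(50); d <- rbinom(50, 1, 0.8); s <- rnorm(50)
  res <- concordance_index(s, y, d)
  p_analytic <- noether_ci_test(res)
  perm <- replicate(1000, concordance_index(sample(s), y, d)$ci)
  p_perm <- mean(perm >= res$ci)
  expect_lt(abs(p_analytic - p_perm), 0.05)
  # CI exactly 0.5 gives p = 0.5 (z = 0)
  res_null <- res; res_null$ci <- 0.5
  expect_equal(noether_ci_test(res_null), 0.5)
  res_zero <- res; res_zero$se <- 0
  expect_error(noether_ci_test(res_zero), "zero")
})

test_that("Noether test has power against a true concordance of 0.7", {
  set.seed(73)
  rho <- sin(0.2 * pi)  # bivariate-normal corr giving concordance 0.7
  hits <- 0
  for (rep in 1:100) {
    u <- rnorm(200); v <- rho * u + sqrt(1 - rho^2) * rnorm(200)
    y <- exp(u)
    p <- noether_ci_test(concordance_index(-v, y, rep(1, 200)))
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("ranking SVM recovers a perfect risk feature and rejects bad input", {
  set.seed(74)
  y <- rexp(100)
  fit <- rank_svm(matrix(-y, ncol = 1), y, rep(1, 100))
  expect_equal(fit$train_ci, 1)
  expect_lte(fit$gradient_norm, 1e-6)
  # all-zero features: strictly convex penalty keeps w at the origin
  fit0 <- rank_svm(matrix(0, 50, 2), rexp(50), rep(1, 50))
  expect_equal(unname(fit0$w), c(0, 0))
  expect_equal(concordance_index(predict(fit0, matrix(0, 50, 2)),
                                 rexp(50), rep(1, 50))$ci, 0.5)
  expect_error(rank_svm(matrix(NA_real_, 5, 1), rexp(5), rep(1, 5)),
               "non-finite")
  expect_error(rank_svm(matrix(1, 5, 1), rexp(5), rep(0, 5)),
               "comparable")
})

test_that("the squared-hinge objective is convex in alpha's favor", {
  set.seed(75)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3)
  y <- rexp(n, exp(0.8 * x[, 1])); d <- rbinom(n, 1, 0.8)
  f1 <- rank_svm(x, y, d, alpha = 1)
  f10 <- rank_svm(x, y, d, alpha = 10)
  hinge <- function(fit, alpha) (fit$objective - sum(fit$w^2)) / alpha
  expect_lte(hinge(f10, 10), hinge(f1, 1) + 1e-8)
  # doubling data scale leaves standardized fit identical
  f_scaled <- rank_svm(2 * x, y, d, alpha = 1)
  expect_equal(f_scaled$w, f1$w, tolerance = 1e-4)
})

test_that("formula interface accepts a Surv response", {
  set.seed(76)
  df <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.8),
                   a = rnorm(60), b = rnorm(60))
  fit <- rank_svm(survival::Surv(time, event) ~ a + b, data = df)
  expect_s3_class(fit, "rank_svm")
  expect_identical(names(coef(fit)), c("a", "b"))
  expect_length(predict(fit, df[, c("a", "b")]), 60)
  expect_error(rank_svm(time ~ a, data = df), "Surv")
})

test_that("risk predictions flip the ranking direction consistently", {
  set.seed(77)
  n <- 80
  x <- matrix(rnorm(n), ncol = 1)
  y <- rexp(n, exp(1.2 * x[, 1]))
  fit <- rank_svm(x, y, rep(1, n))
  s <- predict(fit, x)
  expect_equal(concordance_index(s, y, rep(1, n))$ci +
                 concordance_index(-s, y, rep(1, n))$ci, 1)
  # higher risk for the high-hazard direction
  expect_gt(cor(s, x[, 1]), 0)
  expect_error(predict(fit, matrix(0, 2, 3)), "dimension")
})

test_that("cross-validation is seeded, sized and near 0.5 under the null", {
  set.seed(78)
  n <- 500
  x <- matrix(rnorm(n * 3), n, 3)
  y <- rexp(n, 0.1); d <- as.integer(y <= runif(n, 0, 20))
  y <- pmin(y, runif(n, 0, 20))
  cv1 <- cross_validated_ci(x, y, d, k = 5, seed = 11)
  cv2 <- cross_validated_ci(x, y, d, k = 5, seed = 11)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(vapply(cv1$results, `[[`, numeric(1), "ci"),
               vapply(cv2$results, `[[`, numeric(1), "ci"))
  expect_length(cv1$results, 5)
  mean_ci <- mean(vapply(cv1$results, `[[`, numeric(1), "ci"))
  expect_lt(abs(mean_ci - 0.5), 0.05)
  expect_error(cross_validated_ci(x[1:4, ], y[1:4], d[1:4], k = 10), "folds")
})

test_that("Fisher aggregation matches the chi-square closed form", {
  expect_equal(fisher_aggregate(rep(1, 5)), 1)
  expect_equal(fisher_aggregate(rep(0.5, 5)),
               pchisq(-2 * 5 * log(0.5), df = 10, lower.tail = FALSE))
  expect_equal(fisher_aggregate(0.37), 0.37, tolerance = 1e-12)
  expect_error(fisher_aggregate(c(0.5, 0)), "0, 1")
})

test_that("BH step-up matches hand arithmetic on the two derived vectors", {
  r1 <- bh_correct(c(0.01, 0.02, 0.03, 0.04), fdr = 0.05)
  expect_true(all(r1$reject))
  expect_equal(r1$adjusted, c(0.04, 0.04, 0.04, 0.04))
  r2 <- bh_correct(c(0.5, 0.9), fdr = 0.05)
  expect_false(any(r2$reject))
  expect_equal(r2$adjusted, c(0.9, 0.9))
  expect_true(bh_correct(0.05)$reject)
  expect_false(bh_correct(0.051)$reject)
  empty <- bh_correct(numeric(0))
  expect_length(empty$adjusted, 0)
})

test_that("paired fold comparison matches the t formula and handles degeneracy", {
  expect_equal(compare_ci_paired(c(0.6, 0.7, 0.65), c(0.6, 0.7, 0.65)), 1)
  expect_error(compare_ci_paired(c(0.7, 0.7), c(0.6, 0.6)), "zero-variance")
  set.seed(79)
  a <- runif(5, 0.5, 0.8); b <- a + 0.1 + rnorm(5, 0, 1e-4)
  expect_lt(compare_ci_paired(a, b), 0.01)
  # formula oracle
  a <- runif(6); b <- runif(6)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(6))
  p_hand <- 2 * pt(abs(tstat), df = 5, lower.tail = FALSE)
  expect_equal(compare_ci_paired(a, b), p_hand, tolerance = 1e-10)
})

test_that("clinical screening applies level, availability and Cox rules", {
  set.seed(80)
  n <- 110
  age <- rnorm(n, 60, 8)
  y <- rexp(n, 0.05 * exp(0.08 * (age - 60))); d <- rep(1L, n)
  clin <- data.frame(
    age = age,
    with_na = c(NA, rnorm(n - 1)),
    unbalanced = rep(c("big", "small"), c(70, 40)),
    balanced = rep(c("x", "y"), c(60, 50)),
    noise = rnorm(n))
  res <- select_clinical_variables(clin, y, d, min_level_count = 50)
  vars <- res$screening$variable
  expect_false("with_na" %in% vars)            # missing value -> dropped
  expect_false("unbalanced_small" %in% vars)   # level below 50
  expect_false("unbalanced_big" %in% vars)     # complement below 50
  expect_true(all(c("balanced_x", "balanced_y") %in% vars))
  expect_true("age" %in% colnames(res$features))  # drives the hazard
  # a cohort with nothing informative yields an empty matrix with warning
  expect_warning(
    res0 <- select_clinical_variables(
      data.frame(k = rep("only", n)), y, d, min_level_count = 50),
    "no clinical variables")
  expect_identical(ncol(res0$features), 0L)
})
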