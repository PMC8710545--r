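test_that("SMOTE balances classes with convex synthetic points", {
  set.seed(3)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(c(0, 1), each = 6)
  out <- smote_oversample(X, y, k = 3, seed = 1)
  expect_identical(out$X, X)
  expect_equal(out$n_synthetic, 0L)

  # 4 majority / 2 minority -> 4 / 4
  X2 <- matrix(rnorm(12), 6, 2)
  y2 <- c(0, 0, 0, 0, 1, 1)
  out2 <- smote_oversample(X2, y2, k = 5, seed = 2)
  expect_equal(sum(out2$y == 1), 4)
  expect_equal(sum(out2$y == 0), 4)
  # with 2 minority points every synthetic point lies on their segment
  x1 <- X2[5, ]; x2 <- X2[6, ]
  syn <- out2$X[7:8, , drop = FALSE]
  for (i in 1:2) {
    t1 <- (syn[i, 1] - x1[1]) / (x2[1] - x1[1])
    t2 <- (syn[i, 2] - x1[2]) / (x2[2] - x1[2])
    expect_equal(t1, t2, tolerance = 1e-12)
    expect_true(t1 >= 0 && t1 <= 1)
  }

  # synthetic coordinates never leave the minority bounding box
  X3 <- matrix(rnorm(60), 20, 3)
  y3 <- c(rep(0, 14), rep(1, 6))
  out3 <- smote_oversample(X3, y3, k = 3, seed = 4)
  syn3 <- out3$X[-(1:20), , drop = FALSE]
  mins <- apply(X3[15:20, ], 2, min); maxs <- apply(X3[15:20, ], 2, max)
  expect_true(all(sweep(syn3, 2, mins, `>=`)))
  expect_true(all(sweep(syn3, 2, maxs, `<=`)))

  expect_error(smote_oversample(X3[1:15, ], c(rep(0, 14), 1)), "at least 2")
})

test_that("ridge logistic fit matches an independent gradient-descent oracle", {
  set.seed(21)
  X <- scale(matrix(rnorm(40), 20, 2))
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(20, sd = 0.3) > 0)
  for (lam in c(1, 0.1)) {
    fit <- ridge_logistic_fit(X, y, lam)
    oracle <- ridge_gd_oracle(X, y, lam)
    expect_equal(unname(fit$coefficients[, 1]), oracle$w, tolerance = 1e-6)
    expect_equal(fit$intercept[1], oracle$b, tolerance = 1e-6)
  }
})

test_that("ridge fit agrees with glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  X <- scale(matrix(rnorm(120), 30, 4))
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  y <- as.integer(X[, 1] - X[, 3] + rnorm(30, sd = 0.5) > 0)
  lam <- 0.05
  fit <- ridge_logistic_fit(X, y, lam)
  # glmnet penalizes lambda/2 * ||w||^2 on the mean log-likelihood scale
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = 2 * lam,
                      standardize = FALSE, thresh = 1e-14, maxit = 1e6)
  expect_equal(unname(fit$coefficients[, 1]), as.numeric(g$beta),
               tolerance = 1e-4)
  expect_equal(fit$intercept[1], as.numeric(g$a0), tolerance = 1e-4)
})

test_that("heavy regularization shrinks weights to zero and the intercept to the base-rate log-odds", {
  set.seed(5)
  X <- matrix(rnorm(60), 30, 2)
  y <- c(rep(1, 10), rep(0, 20))
  fit <- ridge_logistic_fit(X, y, 1e8)
  expect_lt(max(abs(fit$coefficients)), 1e-5)
  expect_equal(fit$intercept[1], log((10 / 30) / (20 / 30)), tolerance = 1e-2)
})

test_that("duplicating every sample leaves the ridge solution unchanged", {
  set.seed(13)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  f1 <- ridge_logistic_fit(X, y, 0.5)
  f2 <- ridge_logistic_fit(rbind(X, X), c(y, y), 0.5)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-7)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-7)
})

test_that("p > n fits agree with the reduced-rank route and stay deterministic", {
  set.seed(17)
  X <- matrix(rnorm(15 * 40), 15, 40)
  y <- rep(c(0, 1), length.out = 15)
  f1 <- ridge_logistic_fit(X, y, 0.3)
  f2 <- ridge_logistic_fit(X, y, 0.3)
  expect_identical(f1$coefficients, f2$coefficients)
  oracle <- ridge_gd_oracle(X, y, 0.3, step = 0.05, iters = 400000)
  expect_equal(unname(f1$coefficients[, 1]), oracle$w, tolerance = 1e-5)
})

test_that("classification metrics match hand-computed confusion counts", {
  expect_equal(auc_mw(c(0.9, 0.3, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_bf(c(0.9, 0.3, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  # perfect ranking
  expect_equal(auc_mw(1:10 / 10, c(rep(0, 5), rep(1, 5))), 1)
  # random small instances against the pair-counting oracle
  set.seed(2)
  for (rep in 1:10) {
    s <- round(runif(12), 2)  # induces ties
    l <- rbinom(12, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc_mw(s, l), auc_bf(s, l), tolerance = 1e-12)
  }
  # TP=3 FP=1 FN=2 TN=4 at threshold 0.5
  scores <- c(.9, .8, .7, .2, .1, .6, .4, .3, .2, .1)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  met <- classification_metrics(scores, labels)
  expect_equal(met$sensitivity, 0.6)
  expect_equal(met$specificity, 0.8)
  expect_equal(met$balanced_accuracy, 0.7)
  expect_equal(met$f1, 3 / 4.5)
  expect_error(auc_mw(c(.1, .2), c(1, 1)), "both classes")
})

test_that("nested CV produces k x repeats hold-out rows, reproducibly", {
  set.seed(30)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0, 1), each = 20)
  cfg <- cv_config(k_folds = 3, n_outer_repeats = 2, n_inner_repeats = 2,
                   lambda_grid = c(0.01, 1), seed = 44)
  cv1 <- nested_cv(X, y, cfg)
  expect_equal(nrow(cv1$metrics), 6L)
  expect_equal(dim(cv1$coefficients), c(6L, 4L))
  expect_true(all(cv1$metrics$auc >= 0 & cv1$metrics$auc <= 1))
  cv2 <- nested_cv(X, y, cfg)
  expect_identical(cv1$metrics, cv2$metrics)
  cfg2 <- cv_config(k_folds = 3, n_outer_repeats = 2, n_inner_repeats = 2,
                    lambda_grid = c(0.01, 1), seed = 45)
  cv3 <- nested_cv(X, y, cfg2)
  expect_false(identical(cv1$metrics$auc, cv3$metrics$auc))
})

test_that("nested CV separates a strongly informative feature", {
  set.seed(61)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(signal = y * 3 + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 3), n, 3))
  colnames(X) <- paste0("f", 1:4)
  cfg <- cv_config(k_folds = 5, n_outer_repeats = 4, n_inner_repeats = 2,
                   lambda_grid = 10^seq(-2, 1, length.out = 4), seed = 9)
  cv <- nested_cv(X, y, cfg)
  expect_gte(median(cv$metrics$auc), 0.95)
  # the informative feature carries the largest mean weight
  expect_equal(which.max(abs(aggregate_weights(cv))), c(f1 = 1L))
})

test_that("permutation comparison is exact at the extremes", {
  a <- runif(100)
  res <- compare_models_permutation(a, a, n_perm = 500, seed = 2)
  expect_equal(res$p_value, 1)
  # constant positive difference over many pairs: minimal attainable p
  b <- a - 0.2
  res2 <- compare_models_permutation(a, b, n_perm = 500, seed = 2)
  expect_equal(res2$p_value, 1 / 501)
  expect_error(compare_models_permutation(a, a[-1]), "equal length")
})
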