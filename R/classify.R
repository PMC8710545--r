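# Ridge-regularized logistic classification under repeated nested stratified
# cross-validation with SMOTE oversampling, plus permutation model comparison.

#' Cross-validation configuration
#'
#' @param k_folds folds for both outer and inner loops.
#' @param n_outer_repeats outer random partitions (default 100, giving
#'   `k_folds * n_outer_repeats` hold-out test sets).
#' @param n_inner_repeats inner-loop partitions of the training data only.
#' @param lambda_grid ridge penalties to search (default 13 values log-spaced
#'   over 10^-3..10^3).
#' @param smote_k SMOTE nearest-neighbor count (capped at minority size - 1).
#' @param seed master seed; all partitions, SMOTE draws and tie-breaks flow
#'   from it.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(k_folds = 5L, n_outer_repeats = 100L,
                      n_inner_repeats = 5L,
                      lambda_grid = 10^seq(-3, 3, length.out = 13L),
                      smote_k = 5L, seed = 1L) {
  stopifnot(k_folds >= 2, n_outer_repeats >= 1, n_inner_repeats >= 1,
            length(lambda_grid) >= 1, all(lambda_grid > 0))
  structure(list(k_folds = as.integer(k_folds),
                 n_outer_repeats = as.integer(n_outer_repeats),
                 n_inner_repeats = as.integer(n_inner_repeats),
                 lambda_grid = sort(as.numeric(lambda_grid)),
                 smote_k = as.integer(smote_k),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Binary labels as 0/1 with 1 = case (second factor level).  Numeric 0/1
# input passes through, even when only one class is present (callers that
# need both classes check for themselves).
.binary_labels <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1)))
    return(list(y = as.integer(labels), levels = c("0", "1")))
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two levels")
  list(y = as.integer(f) - 1L, levels = levels(f))
}

#' Stratified fold assignment
#'
#' Subjects of each class are shuffled and dealt round-robin into `k` folds,
#' so every fold holds (as nearly as possible) the class proportions of the
#' whole sample.  Uses the current RNG state.
#'
#' @param labels two-level grouping vector.
#' @param k number of folds.
#' @return integer fold id (1..k) per subject.
#' @export
stratified_folds <- function(labels, k) {
  y <- .binary_labels(labels)$y
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    if (length(idx) < k && length(idx) > 0 && cls >= 0) {
      # still deal what we have; caller validates minimum class sizes
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic point is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`
#' and `x_nn` one of the `k` Euclidean nearest minority neighbors of a
#' randomly chosen minority point `x_i`; points are generated until the two
#' classes have equal counts.  Originals are retained; an already balanced
#' input is returned unchanged.
#'
#' @param X feature matrix (rows = samples).
#' @param y binary labels (0/1 or two-level factor).
#' @param k nearest-neighbor count, capped at minority size - 1.
#' @param seed optional RNG seed; when `NULL` the ambient RNG state is used
#'   (as inside the cross-validation loops).
#' @return list with `X`, `y` (0/1 integer), and `n_synthetic`.
#' @export
smote_oversample <- function(X, y, k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  y <- .binary_labels(y)$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0) return(list(X = X, y = y, n_synthetic = 0L))
  minority <- if (n1 < n0) 1L else 0L
  Xmin <- X[y == minority, , drop = FALSE]
  nmin <- nrow(Xmin)
  if (nmin < 2L) stop("minority class must have at least 2 samples for SMOTE")
  k <- min(k, nmin - 1L)
  need <- abs(n0 - n1)
  d <- as.matrix(dist(Xmin))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  base_i <- sample.int(nmin, need, replace = TRUE)
  pick <- sample.int(k, need, replace = TRUE)
  u <- runif(need)
  syn <- Xmin[base_i, , drop = FALSE] +
    u * (Xmin[nn[cbind(base_i, pick)], , drop = FALSE] - Xmin[base_i, , drop = FALSE])
  list(X = rbind(X, syn), y = c(y, rep(minority, need)), n_synthetic = need)
}

#' Ridge-penalized logistic regression
#'
#' Minimizes the mean negative log-likelihood plus `lambda * ||w||^2` with an
#' unpenalized intercept, by damped Newton iteration to gradient tolerance
#' 1e-8 (the problem is strictly convex, so the fit is deterministic).  When
#' p > n the problem is first reduced to the row space of `X` via thin SVD
#' (the optimal coefficient vector lies there), which leaves the solution
#' unchanged.
#'
#' `X` is expected to be standardized by the caller (training-fold mean/SD);
#' zero-variance columns should be dropped before calling.
#'
#' @param X feature matrix.
#' @param y binary labels (0/1 or two-level factor; second level = case).
#' @param lambda ridge penalty (scalar) or increasing vector; a vector is
#'   fitted with warm starts and returns one column per penalty.
#' @param tol gradient infinity-norm tolerance.
#' @param max_iter Newton iteration cap.
#' @return list with `coefficients` (p x n_lambda matrix), `intercept`
#'   (length n_lambda), `lambda`.
#' @export
ridge_logistic_fit <- function(X, y, lambda, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  y <- .binary_labels(y)$y
  stopifnot(nrow(X) == length(y), all(lambda > 0))
  lambda <- as.numeric(lambda)
  n <- nrow(X); p <- ncol(X)
  V <- NULL
  Z <- X
  if (p > n) {
    sv <- svd(X)
    keep <- sv$d > max(sv$d[1L], 1) * 1e-12
    Z <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = sum(keep))
    V <- sv$v[, keep, drop = FALSE]
  }
  q <- ncol(Z)
  coef_out <- matrix(0, p, length(lambda))
  int_out <- numeric(length(lambda))
  beta <- rep(0, q); b0 <- 0
  ord <- order(lambda, decreasing = TRUE)  # warm start from most penalized
  for (li in ord) {
    lam <- lambda[li]
    for (iter in seq_len(max_iter)) {
      eta <- drop(Z %*% beta) + b0
      mu <- plogis(eta)
      g_beta <- drop(crossprod(Z, mu - y)) / n + 2 * lam * beta
      g_b0 <- mean(mu - y)
      if (max(abs(c(g_beta, g_b0))) < tol) break
      s <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(Z * s, Z) / n
      diag(H) <- diag(H) + 2 * lam
      h_cross <- colSums(Z * s) / n
      h_b0 <- mean(s)
      Hfull <- rbind(cbind(H, h_cross), c(h_cross, h_b0))
      step <- tryCatch(solve(Hfull, c(g_beta, g_b0)),
                       error = function(e) c(g_beta, g_b0))
      obj <- function(be, b) {
        e <- drop(Z %*% be) + b
        mean(log1p(exp(-abs(e))) + pmax(e, 0) - y * e) + lam * sum(be^2)
      }
      f0 <- obj(beta, b0)
      t_step <- 1
      repeat {
        beta_new <- beta - t_step * step[seq_len(q)]
        b0_new <- b0 - t_step * step[q + 1L]
        if (obj(beta_new, b0_new) <= f0 + 1e-12 || t_step < 1e-8) break
        t_step <- t_step / 2
      }
      beta <- beta_new; b0 <- b0_new
    }
    coef_out[, li] <- if (is.null(V)) beta else drop(V %*% beta)
    int_out[li] <- b0
  }
  rownames(coef_out) <- colnames(X)
  list(coefficients = coef_out, intercept = int_out, lambda = lambda)
}

#' Predicted case probabilities from a ridge logistic fit
#' @param fit result of [ridge_logistic_fit()].
#' @param X feature matrix on the same (standardized) scale as the training
#'   data.
#' @param which_lambda column index of the penalty to use.
#' @return numeric vector of probabilities.
#' @export
predict_ridge <- function(fit, X, which_lambda = 1L) {
  plogis(drop(as.matrix(X) %*% fit$coefficients[, which_lambda]) +
           fit$intercept[which_lambda])
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random case outranks a random control, with ties
#' counted one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels (second level / 1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  y <- .binary_labels(labels)$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: both classes required")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics at a probability threshold
#'
#' @param scores predicted case probabilities in \[0, 1\].
#' @param labels binary labels (second level / 1 = case).
#' @param threshold decision threshold on the scores.
#' @return one-row data.frame: `auc`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `f1`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  y <- .binary_labels(labels)$y
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (tp + 0.5 * (fp + fn) > 0) tp / (tp + 0.5 * (fp + fn)) else NA_real_
  data.frame(auc = auc_mw(scores, y), sensitivity = sens, specificity = spec,
             balanced_accuracy = mean(c(sens, spec)), f1 = f1)
}

# Standardize train columns; return transform for test.  Zero-variance
# columns are dropped (recorded) so ridge sees full-rank scaled data.
.standardizer <- function(Xtr) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, sd)
  keep <- which(sdv > 0)
  list(mu = mu, sd = sdv, keep = keep,
       apply = function(X)
         scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep]))
}

# Fit-and-score pipeline for one training/validation split and a lambda grid:
# standardize on train, SMOTE to balance, fit all lambdas, validation AUC per
# lambda.  Consumes RNG (SMOTE).
.fit_score_grid <- function(X, y, tr, va, cfg) {
  st <- .standardizer(X[tr, , drop = FALSE])
  if (!length(st$keep)) return(rep(NA_real_, length(cfg$lambda_grid)))
  Xtr <- st$apply(X[tr, , drop = FALSE])
  sm <- smote_oversample(Xtr, y[tr], k = cfg$smote_k)
  fit <- ridge_logistic_fit(sm$X, sm$y, cfg$lambda_grid)
  Xva <- st$apply(X[va, , drop = FALSE])
  vapply(seq_along(cfg$lambda_grid), function(li)
    auc_mw(predict_ridge(fit, Xva, li), y[va]), numeric(1))
}

#' Run one outer cross-validation fold
#'
#' The inner loop (`n_inner_repeats` stratified `k_folds`-fold partitions of
#' the outer-training set only) selects the ridge penalty maximizing mean
#' validation AUC (ties broken toward the larger penalty, i.e. more
#' regularization); the model is then refit on the full outer-training set
#' (standardize, SMOTE, fit) and evaluated once on the untouched test fold.
#' The test fold is never seen by standardization, SMOTE or penalty
#' selection.
#'
#' @param X full feature matrix.
#' @param y binary labels.
#' @param train_idx,test_idx disjoint row indices.
#' @param cfg a [cv_config()].
#' @return list with `metrics` (one-row data.frame incl. `lambda`),
#'   `coefficients` (length p, zeros for dropped columns, standardized
#'   scale), `intercept`.
#' @export
run_cv_fold <- function(X, y, train_idx, test_idx, cfg = cv_config()) {
  X <- as.matrix(X)
  y <- .binary_labels(y)$y
  ytr <- y[train_idx]
  inner_auc <- matrix(NA_real_, cfg$n_inner_repeats * cfg$k_folds,
                      length(cfg$lambda_grid))
  row <- 0L
  for (ir in seq_len(cfg$n_inner_repeats)) {
    fold <- stratified_folds(ytr, cfg$k_folds)
    for (f in seq_len(cfg$k_folds)) {
      row <- row + 1L
      va_local <- which(fold == f)
      tr_local <- which(fold != f)
      if (length(unique(ytr[va_local])) < 2L) next  # AUC undefined; skip cell
      inner_auc[row, ] <- .fit_score_grid(X[train_idx, , drop = FALSE], ytr,
                                          tr_local, va_local, cfg)
    }
  }
  mean_auc <- colMeans(inner_auc, na.rm = TRUE)
  best <- max(which(mean_auc == max(mean_auc, na.rm = TRUE)))  # tie -> larger lambda
  lam <- cfg$lambda_grid[best]
  st <- .standardizer(X[train_idx, , drop = FALSE])
  Xtr <- st$apply(X[train_idx, , drop = FALSE])
  sm <- smote_oversample(Xtr, ytr, k = cfg$smote_k)
  fit <- ridge_logistic_fit(sm$X, sm$y, lam)
  scores <- predict_ridge(fit, st$apply(X[test_idx, , drop = FALSE]))
  met <- classification_metrics(scores, y[test_idx])
  met$lambda <- lam
  coefs <- numeric(ncol(X))
  names(coefs) <- colnames(X)
  coefs[st$keep] <- fit$coefficients[, 1L]
  list(metrics = met, coefficients = coefs, intercept = fit$intercept[1L])
}

#' Repeated nested stratified cross-validation
#'
#' For each of `n_outer_repeats` seeded partitions, a stratified
#' `k_folds`-fold outer split is drawn; every outer fold is evaluated with
#' [run_cv_fold()] (inner penalty selection, SMOTE, standardization all
#' confined to the outer-training set).  With the defaults this yields
#' 5 x 100 = 500 hold-out test sets.
#'
#' @param features a `feature_table` or plain feature matrix.
#' @param labels two-level grouping vector (second level = case).
#' @param cfg a [cv_config()].
#' @return object of class `cv_result`: `metrics` (data.frame with one row
#'   per hold-out fold: `repeat_id`, `fold`, `auc`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `f1`, `lambda`), `coefficients`
#'   (n_rows x p matrix, standardized scale), `model_tag`, `label_levels`,
#'   `cfg`.
#' @export
nested_cv <- function(features, labels, cfg = cv_config()) {
  X <- if (inherits(features, "feature_table")) features$values else as.matrix(features)
  tag <- if (inherits(features, "feature_table")) features$model_tag else "MATRIX"
  bl <- .binary_labels(labels)
  y <- bl$y
  if (min(table(y)) < cfg$k_folds)
    stop("each class needs at least k_folds members")
  rows <- vector("list", cfg$n_outer_repeats * cfg$k_folds)
  coefs <- matrix(NA_real_, length(rows), ncol(X),
                  dimnames = list(NULL, colnames(X)))
  i <- 0L
  for (r in seq_len(cfg$n_outer_repeats)) {
    set.seed(child_seed(cfg$seed, r))
    fold <- stratified_folds(y, cfg$k_folds)
    for (f in seq_len(cfg$k_folds)) {
      i <- i + 1L
      res <- run_cv_fold(X, y, which(fold != f), which(fold == f), cfg)
      res$metrics <- cbind(data.frame(repeat_id = r, fold = f), res$metrics)
      rows[[i]] <- res$metrics
      coefs[i, ] <- res$coefficients
    }
  }
  structure(list(metrics = do.call(rbind, rows), coefficients = coefs,
                 model_tag = tag, label_levels = bl$levels, cfg = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): %d hold-out folds, median AUC = %.3f\n",
              x$model_tag, nrow(x$metrics), median(x$metrics$auc)))
  invisible(x)
}

#' Paired permutation test comparing two models' AUC distributions
#'
#' The models must share fold partitions (same outer seeds), giving paired
#' per-fold AUCs.  The observed statistic is the mean paired difference; the
#' null is built by independently sign-flipping each paired difference, and
#' the two-sided p-value is `(1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' @param aucs_a,aucs_b paired AUC vectors of equal length.
#' @param n_perm number of sign-flip permutations.
#' @param seed RNG seed.
#' @return list with `p_value`, `observed` (mean difference), `n_perm`.
#' @export
compare_models_permutation <- function(aucs_a, aucs_b, n_perm = 10000L,
                                       seed = 1L) {
  if (length(aucs_a) != length(aucs_b)) stop("AUC vectors must have equal length")
  d <- aucs_a - aucs_b
  obs <- mean(d)
  set.seed(seed)
  n <- length(d)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    mean(s * d)
  }, numeric(1))
  p <- (1 + sum(abs(null_stats) >= abs(obs))) / (n_perm + 1)
  list(p_value = p, observed = obs, n_perm = n_perm)
}
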