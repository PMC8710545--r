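# Dynamic functional connectivity: tapered sliding-window correlation,
# pooled L1 k-means brain-state clustering with elbow selection, and
# per-subject state metrics and centroids.

#' Sliding-window specification
#'
#' Defaults follow the common tapered-window convention for resting-state
#' scans with TR = 2.3 s: 22-TR (50.6 s) rectangular windows advanced in
#' steps of 1 TR, tapered by convolution with a Gaussian of 3 TR.
#'
#' @param length_tr window length in TR (>= 2).
#' @param step_tr step between window starts in TR (>= 1).
#' @param gauss_sigma_tr standard deviation of the tapering Gaussian in TR
#'   (0 gives a rectangular window).
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length_tr = 22L, step_tr = 1L, gauss_sigma_tr = 3,
                        tr_seconds = 2.3) {
  stopifnot(length_tr >= 2, step_tr >= 1, gauss_sigma_tr >= 0, tr_seconds > 0)
  structure(list(length_tr = as.integer(length_tr),
                 step_tr = as.integer(step_tr),
                 gauss_sigma_tr = as.numeric(gauss_sigma_tr),
                 tr_seconds = as.numeric(tr_seconds)),
            class = "window_spec")
}

#' Window duration in seconds
#' @param spec a [window_spec()].
#' @return `length_tr * tr_seconds`.
#' @export
window_duration_seconds <- function(spec) spec$length_tr * spec$tr_seconds

#' Build the tapered window weights
#'
#' A rectangle of ones of the window length is convolved (full convolution)
#' with a discrete Gaussian kernel of standard deviation `gauss_sigma_tr`
#' samples truncated at +/- ceiling(3 sigma); the central `length_tr` samples
#' are retained and renormalized to sum to one.  With sigma = 0 the kernel is
#' a delta and the weights are uniform.
#'
#' @param spec a [window_spec()].
#' @return numeric weight vector of length `spec$length_tr`, nonnegative,
#'   symmetric, summing to 1.
#' @export
build_taper <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  L <- spec$length_tr
  s <- spec$gauss_sigma_tr
  if (s == 0) return(rep(1 / L, L))
  half <- ceiling(3 * s)
  t <- seq(-half, half)
  kern <- exp(-t^2 / (2 * s^2))
  kern <- kern / sum(kern)
  full <- convolve(rep(1, L), rev(kern), type = "open")  # length L + 2*half
  start <- floor((length(full) - L) / 2) + 1L
  w <- full[start:(start + L - 1L)]
  w / sum(w)
}

#' Tapered sliding-window dynamic FC
#'
#' Window w (1-based) covers time points
#' `[(w-1)*step + 1, (w-1)*step + length]`; the number of windows is
#' `floor((T - length)/step) + 1`.  Within each window, every matrix entry is
#' the weighted Pearson correlation of the two regional time courses under
#' the taper weights (weighted means, weighted covariance, weighted
#' variances).  An entry with zero weighted variance is set to 0 with a
#' warning.
#'
#' @param ts a [regional_timeseries()].
#' @param spec a [window_spec()].
#' @return an object of class `dfc_windows`: list with `vectors` (n_windows x
#'   R(R-1)/2 matrix of vectorized windows, row-major upper triangle),
#'   `n_windows`, `R`, `region_names`, `spec`, `subject_id`.
#' @export
windowed_dfc <- function(ts, spec = window_spec(tr_seconds = ts$tr_seconds)) {
  stopifnot(inherits(ts, "regional_timeseries"), inherits(spec, "window_spec"))
  X <- ts$data
  Tn <- nrow(X); R <- ncol(X)
  L <- spec$length_tr; st <- spec$step_tr
  if (Tn < L) stop(sprintf("T = %d shorter than window length %d", Tn, L))
  W <- (Tn - L) %/% st + 1L
  w <- build_taper(spec)
  P <- R * (R - 1L) / 2L
  # row-major upper-triangle linear indices, computed once
  pr <- which(upper.tri(matrix(0, R, R)))
  ri <- ((pr - 1L) %% R) + 1L
  ci <- ((pr - 1L) %/% R) + 1L
  ord <- order(ri, ci)
  iu <- pr[ord]
  rn <- colnames(X)
  out <- matrix(NA_real_, W, P)
  zeroed <- FALSE
  for (i in seq_len(W)) {
    sl <- X[((i - 1L) * st + 1L):((i - 1L) * st + L), , drop = FALSE]
    cc <- cov.wt(sl, wt = w, cor = TRUE)$cor
    if (anyNA(cc) || any(!is.finite(cc))) {
      cc[!is.finite(cc)] <- 0
      zeroed <- TRUE
    }
    out[i, ] <- pmin(pmax(cc[iu], -1), 1)
  }
  if (zeroed)
    warning("zero weighted variance in at least one window; entries set to 0")
  colnames(out) <- paste(rn[ri[ord]], rn[ci[ord]], sep = "|")
  structure(list(vectors = out, n_windows = W, R = R,
                 region_names = colnames(X), spec = spec,
                 subject_id = ts$subject_id),
            class = "dfc_windows")
}

#' Extract one window as a connectivity matrix
#' @param dw a `dfc_windows` object.
#' @param w window index.
#' @return a [conn_matrix()] of kind `"DFC_WINDOW"`.
#' @export
dfc_window_matrix <- function(dw, w) {
  stopifnot(inherits(dw, "dfc_windows"), w >= 1, w <= dw$n_windows)
  devectorize_pairwise(dw$vectors[w, ], dw$R, kind = "DFC_WINDOW",
                       region_names = dw$region_names)
}

# Pool per-subject window matrices into one matrix plus a subject index.
.pool_windows <- function(window_list) {
  vecs <- lapply(window_list, function(dw) {
    if (inherits(dw, "dfc_windows")) dw$vectors else as.matrix(dw)
  })
  X <- do.call(rbind, vecs)
  sizes <- vapply(vecs, nrow, integer(1))
  subj <- rep(seq_along(vecs), sizes)
  list(X = X, subject = subj, sizes = sizes)
}

#' Pooled k-means brain-state clustering under the L1 distance
#'
#' All subjects' windowed dFC matrices are pooled and clustered with k-means
#' under the Manhattan (L1) distance: assignment to the nearest centroid in
#' L1, centroid update by coordinate-wise median, k-means++ initialization,
#' best of `n_init` replicates by total L1 inertia.  An empty cluster is
#' re-seeded at the point farthest (L1) from its current centroid.  Final
#' states are relabeled in descending order of occupancy, so state 1 is the
#' most occupied.
#'
#' @param window_list named list (one element per subject) of `dfc_windows`
#'   objects or plain window-by-feature matrices, all with the same feature
#'   dimension.
#' @param K number of states.
#' @param seed RNG seed.
#' @param n_init number of k-means++ replicates.
#' @param max_iter iteration cap per replicate.
#' @return an object of class `state_model`: list with `K`, `centroids`
#'   (K x P), `assignments` (named list of per-subject integer sequences in
#'   1..K), `inertia`, `occupancy`, `seed`.
#' @export
cluster_states <- function(window_list, K, seed = 1L, n_init = 10L,
                           max_iter = 200L) {
  pool <- .pool_windows(window_list)
  if (nrow(pool$X) < K) stop("fewer windows than states")
  set.seed(seed)
  fit <- .kmeans_l1_cpp(t(pool$X), as.integer(K), as.integer(n_init),
                        as.integer(max_iter))
  assign <- fit$assignments
  # relabel by descending occupancy (ties broken by original label)
  occ <- tabulate(assign, nbins = K)
  ord <- order(-occ, seq_len(K))
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  assign <- relabel[assign]
  centroids <- fit$centroids[ord, , drop = FALSE]
  colnames(centroids) <- colnames(pool$X)
  per_subject <- split(assign, pool$subject)
  names(per_subject) <- names(window_list)
  structure(list(K = as.integer(K), centroids = centroids,
                 assignments = per_subject, inertia = fit$inertia,
                 occupancy = tabulate(assign, nbins = K), seed = seed),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: K = %d, %d windows over %d subjects, inertia = %.4g\n",
              x$K, sum(x$occupancy), length(x$assignments), x$inertia))
  invisible(x)
}

#' Elbow selection of the number of states
#'
#' For each candidate K the clustering ratio
#' r(K) = (mean L1 distance of windows to their own centroid) /
#' (mean L1 distance of windows to the centroids of the other clusters) is
#' computed — the within- to between-cluster distance ratio in the
#' convention of the GIFT toolbox.  The optimal K maximizes the discrete
#' second difference r(K-1) - 2 r(K) + r(K+1) over interior candidates (the
#' point of maximum curvature of the elbow curve), with ties broken toward
#' the smallest K.
#'
#' @param window_list as in [cluster_states()].
#' @param k_range increasing integer vector of candidate K (min >= 2, at
#'   least 3 values).
#' @param seed RNG seed (each K uses a derived child seed).
#' @param n_init replicates per K.
#' @return list with `K` (selected), `elbow_curve` (named numeric over
#'   `k_range`), and `models` (the fitted `state_model` per K).
#' @export
select_k_elbow <- function(window_list, k_range = 2:8, seed = 1L,
                           n_init = 10L) {
  k_range <- as.integer(k_range)
  stopifnot(all(diff(k_range) > 0), min(k_range) >= 2)
  if (length(k_range) < 3L) stop("need at least 3 candidate K (no interior point)")
  pool <- .pool_windows(window_list)
  models <- list(); ratio <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    m <- cluster_states(window_list, K, seed = child_seed(seed, K),
                        n_init = n_init)
    assign <- unlist(m$assignments)
    D <- vapply(seq_len(K), function(k)
      .l1_rowdist_cpp(pool$X, m$centroids[k, ]), numeric(nrow(pool$X)))
    within <- mean(D[cbind(seq_len(nrow(pool$X)), assign)])
    between <- mean(vapply(seq_len(K), function(k)
      mean(D[assign != k, k]), numeric(1)))
    ratio[i] <- within / between
    models[[as.character(K)]] <- m
  }
  names(ratio) <- k_range
  list(K = k_range[.elbow_pick(ratio)], elbow_curve = ratio, models = models)
}

# Maximum-curvature pick on an elbow curve: index (into ratio) of the
# interior point maximizing the discrete second difference, ties toward the
# smallest K (which.max returns the first maximum).
.elbow_pick <- function(ratio) {
  if (length(ratio) < 3L) stop("need at least 3 candidate K (no interior point)")
  interior <- 2:(length(ratio) - 1L)
  curv <- ratio[interior - 1L] - 2 * ratio[interior] + ratio[interior + 1L]
  interior[which.max(curv)]
}

#' Per-subject state metrics from an assignment sequence
#'
#' @param sequence integer state sequence over a subject's windows (values in
#'   1..K, length >= 2).
#' @param K number of states.
#' @return an object of class `state_metrics`: `mean_dwell` (length K, mean
#'   length in windows of maximal runs of each state, 0 when unvisited),
#'   `transition_prob` (K x K, row i = empirical distribution of the next
#'   state given state i, self-transitions included; rows with no outgoing
#'   observations are the identity row), `n_transitions` (count of
#'   consecutive-window state changes), `visited` (logical length K).
#' @export
state_metrics <- function(sequence, K) {
  sequence <- as.integer(sequence)
  if (length(sequence) < 2L) stop("sequence must have length >= 2")
  if (any(sequence < 1L | sequence > K)) stop("state values must lie in 1..K")
  runs <- rle(sequence)
  mean_dwell <- numeric(K)
  for (k in seq_len(K)) {
    len <- runs$lengths[runs$values == k]
    if (length(len)) mean_dwell[k] <- mean(len)
  }
  visited <- tabulate(sequence, nbins = K) > 0L
  from <- sequence[-length(sequence)]
  to <- sequence[-1L]
  counts <- matrix(0, K, K)
  for (t in seq_along(from)) counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
  denom <- rowSums(counts)
  P <- diag(K)  # identity rows where no outgoing observations
  nz <- denom > 0
  P[nz, ] <- counts[nz, , drop = FALSE] / denom[nz]
  structure(list(mean_dwell = mean_dwell, transition_prob = P,
                 n_transitions = sum(from != to), visited = visited,
                 K = as.integer(K)),
            class = "state_metrics")
}

#' Per-subject state centroids and regional dFC
#'
#' The subject's centroid for state k is the elementwise mean of the
#' subject's windows assigned to k (a symmetric R x R matrix with zero
#' diagonal); regional dFC is the node strength of each centroid after
#' removing negative entries.  Unvisited states yield `NULL` centroids and
#' `NA` regional rows (imputed with the cohort mean, and flagged, at
#' feature-table assembly).
#'
#' @param dw a `dfc_windows` object (or window-by-feature matrix).
#' @param sequence the subject's state assignment over the same windows.
#' @param K number of states.
#' @param R number of regions (taken from `dw` when available).
#' @param region_names optional region names.
#' @return list with `centroids` (length-K list of [conn_matrix()] or
#'   `NULL`) and `regional_dfc` (K x R matrix, `NA` rows for unvisited
#'   states).
#' @export
subject_centroids <- function(dw, sequence, K, R = NULL, region_names = NULL) {
  if (inherits(dw, "dfc_windows")) {
    vec <- dw$vectors; R <- dw$R
    if (is.null(region_names)) region_names <- dw$region_names
  } else vec <- as.matrix(dw)
  stopifnot(!is.null(R), nrow(vec) == length(sequence))
  cents <- vector("list", K)
  reg <- matrix(NA_real_, K, R)
  if (!is.null(region_names)) colnames(reg) <- region_names
  rownames(reg) <- paste0("state", seq_len(K))
  for (k in seq_len(K)) {
    rows <- which(sequence == k)
    if (!length(rows)) next
    v <- colMeans(vec[rows, , drop = FALSE])
    cm <- devectorize_pairwise(v, R, kind = "DFC_CENTROID",
                               region_names = region_names)
    cents[[k]] <- cm
    reg[k, ] <- node_strength(cm, drop_negatives = TRUE)
  }
  list(centroids = cents, regional_dfc = reg)
}

#' All per-subject state metrics and centroids for a fitted state model
#'
#' Convenience wrapper applying [state_metrics()] and [subject_centroids()]
#' to every subject in a [cluster_states()] result.
#'
#' @param window_list the window list the model was fitted on.
#' @param model a `state_model`.
#' @return named list per subject with elements `metrics` (a
#'   `state_metrics`) and `centroids`/`regional_dfc` from
#'   [subject_centroids()].
#' @export
subject_state_summaries <- function(window_list, model) {
  stopifnot(inherits(model, "state_model"))
  out <- vector("list", length(window_list))
  names(out) <- names(window_list)
  for (s in seq_along(window_list)) {
    seq_s <- model$assignments[[s]]
    sc <- subject_centroids(window_list[[s]], seq_s, model$K)
    out[[s]] <- list(metrics = state_metrics(seq_s, model$K),
                     centroids = sc$centroids,
                     regional_dfc = sc$regional_dfc)
  }
  out
}
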