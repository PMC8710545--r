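# Feature-weight aggregation, scaling, network-level summaries, and the
# dual-criterion importance rule.

#' Average feature weights over all cross-validation fits
#'
#' Elementwise mean of the per-fit coefficient vectors (standardized-feature
#' scale).  Positive means a higher feature value pushes toward the second
#' (case) class.
#'
#' @param cv a `cv_result` from [nested_cv()].
#' @return named numeric vector of mean weights.
#' @export
aggregate_weights <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  colMeans(cv$coefficients)
}

#' Scale weights by the maximum magnitude
#'
#' @param mean_weights numeric weight vector.
#' @return `w / max(|w|)`, so the largest-magnitude weight is +/- 1; an
#'   all-zero vector is returned unchanged with a warning.
#' @export
scale_weights <- function(mean_weights) {
  m <- max(abs(mean_weights))
  if (m == 0) {
    warning("all weights are zero; returning the zero vector")
    return(mean_weights)
  }
  mean_weights / m
}

# Map feature names to their region token(s): names are "|"-separated with
# region names as the trailing one (regional) or two (pairwise) tokens.
.feature_regions <- function(feature_names, atlas, n_regions) {
  rn <- atlas$region_name
  lapply(strsplit(feature_names, "|", fixed = TRUE), function(tok) {
    reg <- tok[tok %in% rn]
    if (length(reg) != n_regions)
      stop("cannot map feature to ", n_regions, " region(s): ",
           paste(tok, collapse = "|"))
    reg
  })
}

#' Network-level summary of feature values
#'
#' Averages positive and negative values separately over the network (pair)
#' each feature's region(s) belong to.  Pairwise mode returns symmetric
#' network-by-network matrices; regional mode returns per-network vectors.
#' Cells with no contributing feature are 0, with the count recorded.
#'
#' @param values numeric vector of per-feature values (e.g. relative
#'   weights), named or accompanied by `feature_names`.
#' @param atlas an `atlas_networks` data.frame.
#' @param mode `"pairwise"` or `"regional"`.
#' @param feature_names feature names (default `names(values)`); each must
#'   contain its region name(s) as `|`-separated tokens.
#' @return list with `positive`, `negative`, `count` — matrices
#'   (network x network) in pairwise mode, named vectors in regional mode.
#'   Negative means are reported as (non-positive) means of the negative
#'   values only.
#' @export
network_summary <- function(values, atlas, mode = c("pairwise", "regional"),
                            feature_names = names(values)) {
  mode <- match.arg(mode)
  if (is.null(feature_names)) stop("feature names required")
  stopifnot(length(feature_names) == length(values))
  nets <- atlas_network_levels(atlas)
  net_of <- setNames(as.character(atlas$network), atlas$region_name)
  nreg <- if (mode == "pairwise") 2L else 1L
  regs <- .feature_regions(feature_names, atlas, nreg)
  if (mode == "pairwise") {
    pos_sum <- neg_sum <- pos_n <- neg_n <- cnt <-
      matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
    for (i in seq_along(values)) {
      a <- net_of[[regs[[i]][1L]]]; b <- net_of[[regs[[i]][2L]]]
      v <- values[i]
      cnt[a, b] <- cnt[a, b] + 1
      if (a != b) cnt[b, a] <- cnt[b, a] + 1
      if (v > 0) {
        pos_sum[a, b] <- pos_sum[a, b] + v; pos_n[a, b] <- pos_n[a, b] + 1
        if (a != b) { pos_sum[b, a] <- pos_sum[b, a] + v; pos_n[b, a] <- pos_n[b, a] + 1 }
      } else if (v < 0) {
        neg_sum[a, b] <- neg_sum[a, b] + v; neg_n[a, b] <- neg_n[a, b] + 1
        if (a != b) { neg_sum[b, a] <- neg_sum[b, a] + v; neg_n[b, a] <- neg_n[b, a] + 1 }
      }
    }
    positive <- ifelse(pos_n > 0, pos_sum / pmax(pos_n, 1), 0)
    negative <- ifelse(neg_n > 0, neg_sum / pmax(neg_n, 1), 0)
    list(positive = positive, negative = negative, count = cnt,
         positive_count = pos_n, negative_count = neg_n)
  } else {
    pos_sum <- neg_sum <- pos_n <- neg_n <- cnt <-
      setNames(numeric(length(nets)), nets)
    for (i in seq_along(values)) {
      a <- net_of[[regs[[i]][1L]]]
      v <- values[i]
      cnt[a] <- cnt[a] + 1
      if (v > 0) { pos_sum[a] <- pos_sum[a] + v; pos_n[a] <- pos_n[a] + 1 }
      else if (v < 0) { neg_sum[a] <- neg_sum[a] + v; neg_n[a] <- neg_n[a] + 1 }
    }
    positive <- ifelse(pos_n > 0, pos_sum / pmax(pos_n, 1), 0)
    negative <- ifelse(neg_n > 0, neg_sum / pmax(neg_n, 1), 0)
    list(positive = positive, negative = negative, count = cnt,
         positive_count = pos_n, negative_count = neg_n)
  }
}

#' Dual-criterion importance flags
#'
#' A feature is flagged important iff its absolute relative weight is in the
#' top `q` fraction of all features AND its absolute univariate statistic is
#' in the top `q` fraction — the operational form of requiring both a large
#' group difference and a large classifier weight.
#'
#' @param rel_weights numeric vector of relative weights.
#' @param univariate_stats numeric vector of univariate test statistics,
#'   aligned with `rel_weights`.
#' @param q top fraction for each criterion.
#' @return logical flags, same length.
#' @export
flag_important <- function(rel_weights, univariate_stats, q = 0.10) {
  if (length(rel_weights) != length(univariate_stats))
    stop("rel_weights and univariate_stats must be aligned")
  stopifnot(q > 0, q <= 1)
  n <- length(rel_weights)
  m <- ceiling(q * n)
  top_of <- function(v) {
    thr <- sort(abs(v), decreasing = TRUE)[m]
    abs(v) >= thr
  }
  top_of(rel_weights) & top_of(univariate_stats)
}

#' Build an importance table for one model
#'
#' @param cv a `cv_result`.
#' @param univariate data.frame from [univariate_screen()] (matched on
#'   `feature_name`; features without a univariate row get statistic 0).
#' @param q top fraction for [flag_important()].
#' @return data.frame: `feature_name`, `mean_weight`, `rel_weight`,
#'   `univariate_stat`, `important`.
#' @export
importance_table <- function(cv, univariate, q = 0.10) {
  mw <- aggregate_weights(cv)
  rw <- scale_weights(mw)
  us <- setNames(rep(0, length(mw)), names(mw))
  hit <- intersect(names(us), univariate$feature_name)
  us[hit] <- univariate$statistic[match(hit, univariate$feature_name)]
  data.frame(feature_name = names(mw), mean_weight = unname(mw),
             rel_weight = unname(rw), univariate_stat = unname(us),
             important = flag_important(rw, us, q))
}
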