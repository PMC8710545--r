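# Mass univariate group comparisons with Benjamini-Hochberg control.

#' Compare one feature between two groups
#'
#' `TTEST` is the Welch two-sample t-test; `WILCOXON` is the rank-sum test
#' with normal approximation and tie correction (no continuity correction);
#' `CHISQ` is the Pearson chi-squared test without continuity correction (for
#' categorical features, `values` may be a character/factor vector or a
#' pre-tabulated contingency matrix with groups in columns).
#'
#' @param values numeric (TTEST/WILCOXON) or categorical (CHISQ) feature
#'   values per subject; alternatively a contingency matrix for CHISQ.
#' @param labels two-level grouping vector aligned with `values` (ignored
#'   when `values` is already a contingency matrix).
#' @param test one of `"TTEST"`, `"WILCOXON"`, `"CHISQ"`.
#' @return a one-row data.frame: `test`, `statistic`, `p_raw`, `direction`
#'   (sign of the second-group minus first-group location difference; 0 for
#'   CHISQ).
#' @export
compare_feature <- function(values, labels = NULL, test = c("TTEST", "WILCOXON", "CHISQ")) {
  test <- match.arg(test)
  if (test == "CHISQ") {
    tab <- if (is.matrix(values)) values else {
      if (is.null(labels)) stop("labels required")
      table(values, labels)
    }
    ht <- chisq.test(tab, correct = FALSE)
    return(data.frame(test = test, statistic = unname(ht$statistic),
                      p_raw = ht$p.value, direction = 0))
  }
  if (is.null(labels)) stop("labels required")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  g1 <- values[labels == levels(labels)[1L]]
  g2 <- values[labels == levels(labels)[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 observations")
  if (test == "TTEST") {
    ht <- t.test(g2, g1, var.equal = FALSE)
    data.frame(test = test, statistic = unname(ht$statistic),
               p_raw = ht$p.value, direction = sign(mean(g2) - mean(g1)))
  } else {
    ht <- suppressWarnings(wilcox.test(g2, g1, exact = FALSE, correct = FALSE))
    data.frame(test = test, statistic = unname(ht$statistic),
               p_raw = ht$p.value,
               direction = sign(median(g2) - median(g1)))
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorted ascending, q(i) = min over j >= i of m * p(j) / j, clipped at 1,
#' returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Mass univariate screen of a feature table
#'
#' Applies the family's test to every connectome feature, adjusts within the
#' screened family by Benjamini-Hochberg, and flags significance at the
#' corrected level.  For pairwise SC features, edges failing the control
#' prevalence filter (nonzero in more than half the controls) are excluded
#' before testing and never appear in the output.
#'
#' @param features a `feature_table` (see [build_feature_table()]).
#' @param labels two-level grouping vector aligned with the table's subjects.
#' @param test the test for this family; defaults by model tag (SC families
#'   use WILCOXON, FC/dFC families use TTEST).
#' @param alpha significance level on corrected p-values.
#' @param prevalence_mask optional logical R x R matrix from
#'   [sc_prevalence_filter()], applied when `features$model_tag == "PAIR_SC"`.
#' @param atlas atlas used to map mask entries to feature names (required
#'   with `prevalence_mask`).
#' @return data.frame with one row per tested feature: `feature_name`,
#'   `test`, `statistic`, `p_raw`, `p_bh`, `direction`, `significant`.
#' @export
univariate_screen <- function(features, labels, test = NULL, alpha = 0.05,
                              prevalence_mask = NULL, atlas = NULL) {
  stopifnot(inherits(features, "feature_table"))
  if (is.null(test)) {
    test <- switch(features$model_tag,
                   PAIR_SC = , REG_SC = "WILCOXON",
                   "TTEST")
  }
  cols <- features$connectome_cols
  if (!is.null(prevalence_mask) && features$model_tag == "PAIR_SC") {
    if (is.null(atlas)) stop("atlas required to apply the prevalence mask")
    keep_pairs <- vectorize_pairwise(conn_matrix(prevalence_mask * 1,
                                                 kind = "SC",
                                                 region_names = atlas$region_name))
    keep <- names(keep_pairs)[keep_pairs > 0]
    cols <- cols[sub("^SC\\|", "", cols) %in% keep]
  }
  if (!length(cols)) stop("no features to test")
  rows <- lapply(cols, function(cn)
    cbind(feature_name = cn,
          compare_feature(features$values[, cn], labels, test)))
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p_raw)
  out$significant <- out$p_bh < alpha
  out
}
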