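#!/usr/bin/env Rscript

# Stage 5 — classification.
#
# Ridge-regularized logistic regression under repeated nested stratified
# 5-fold cross-validation with SMOTE on the training folds, for two tasks:
# HC vs MS, and MS by disability status.  Per-model hold-out metrics and
# fitted coefficients are written per fold; models are then compared with
# the paired sign-flip permutation test, BH-corrected.
#
# The outer loop here runs 20 random partitions (100 hold-out folds per
# model) to keep the demonstration cohort quick; the package default is 100
# partitions (500 folds).

suppressPackageStartupMessages(library(dynconn))

indir <- "results/cohort"
outdir <- "results/classify"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260923L

subjects <- read_subjects(file.path(indir, "subjects.csv"))
atlas <- read_atlas(file.path(indir, "atlas.csv"))

ts <- lapply(subjects$subject_id, function(id)
  read_timeseries(file.path(indir, paste0("ts_", id, ".tsv")), 2.3, id))
names(ts) <- subjects$subject_id
sc <- lapply(subjects$subject_id, function(id)
  read_conn_matrix(file.path(indir, paste0("sc_", id, ".tsv")), "SC"))
names(sc) <- subjects$subject_id
fc <- lapply(ts, compute_fc)

metrics_df <- as.data.frame(data.table::fread("results/dfc/state_metrics.csv"))
regional <- as.data.frame(data.table::fread("results/dfc/regional_dfc.csv"))
K <- max(regional$state)
reg_dfc <- lapply(subjects$subject_id, function(id) {
  m <- as.matrix(regional[regional$subject_id == id, -(1:2)])
  rownames(m) <- paste0("state", 1:K)
  m
})
names(reg_dfc) <- subjects$subject_id
met_list <- lapply(subjects$subject_id, function(id) {
  row <- metrics_df[metrics_df$subject_id == id, ]
  list(mean_dwell = as.numeric(row[paste0("dwell_state", 1:K)]),
       transition_prob = matrix(as.numeric(row[as.vector(t(outer(1:K, 1:K,
         function(i, j) paste0("trans_", i, "_", j))))]), K, K, byrow = TRUE),
       n_transitions = row$n_transitions)
})
names(met_list) <- subjects$subject_id

cfg <- cv_config(n_outer_repeats = 20L,
                 lambda_grid = 10^seq(-3, 3, length.out = 7), seed = seed)

run_task <- function(task, keep, labels) {
  models <- list(REG_SC = sc, REG_FC = fc, REG_DFC = reg_dfc,
                 DFC_METRICS = met_list)
  out <- list()
  for (tag in names(models)) {
    ft <- build_feature_table(subjects[keep, ], models[[tag]][keep], tag,
                              atlas, task = task, K = K)
    cv <- nested_cv(ft, labels[keep], cfg)
    data.table::fwrite(cv$metrics,
                       file.path(outdir, sprintf("%s_%s_metrics.csv", task, tolower(tag))))
    data.table::fwrite(as.data.frame(cv$coefficients),
                       file.path(outdir, sprintf("%s_%s_coefs.csv", task, tolower(tag))))
    cat(sprintf("[%s] %s: median AUC %.3f, median balanced accuracy %.3f\n",
                task, tag, median(cv$metrics$auc),
                median(cv$metrics$balanced_accuracy)))
    out[[tag]] <- cv
  }
  # pairwise model comparison via paired sign-flip permutation, BH-corrected
  tags <- names(out)
  pairs <- t(combn(tags, 2))
  cmp <- data.frame(model_a = pairs[, 1], model_b = pairs[, 2],
                    p_raw = NA_real_, delta_auc = NA_real_)
  for (i in seq_len(nrow(pairs))) {
    pc <- compare_models_permutation(out[[pairs[i, 1]]]$metrics$auc,
                                     out[[pairs[i, 2]]]$metrics$auc,
                                     n_perm = 5000, seed = seed + i)
    cmp$p_raw[i] <- pc$p_value; cmp$delta_auc[i] <- pc$observed
  }
  cmp$p_bh <- bh_adjust(cmp$p_raw)
  data.table::fwrite(cmp, file.path(outdir, sprintf("%s_model_comparison.csv", task)))
  out
}

cat("== task 1: HC vs MS ==\n")
cv_group <- run_task("group", rep(TRUE, nrow(subjects)),
                     factor(subjects$group, levels = c("HC", "MS")))

cat("== task 2: MS, no disability vs evidence of disability ==\n")
ms <- subjects$group == "MS"
cv_dis <- run_task("disability", ms,
                   factor(subjects$disability, levels = c("NONE", "EVIDENCE")))
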