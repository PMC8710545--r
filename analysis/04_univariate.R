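#!/usr/bin/env Rscript

# Stage 4 — mass univariate group comparisons.
#
# Compares demographics between groups (chi-squared for categoricals,
# rank-sum for quantitative), then screens the connectome features family by
# family: Wilcoxon rank-sum for SC (after the control prevalence filter),
# Welch t-tests for FC/dFC, Benjamini-Hochberg correction within each
# family, significance at corrected p < 0.05.

suppressPackageStartupMessages(library(dynconn))

indir <- "results/cohort"
outdir <- "results/univariate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

subjects <- read_subjects(file.path(indir, "subjects.csv"))
atlas <- read_atlas(file.path(indir, "atlas.csv"))

## demographics, HC vs MS
cat("demographics (HC vs MS):\n")
demo <- rbind(
  cbind(variable = "sex",
        suppressWarnings(
          compare_feature(table(subjects$sex, subjects$group), test = "CHISQ"))),
  cbind(variable = "age",
        compare_feature(subjects$age, subjects$group, "WILCOXON")))
print(demo, row.names = FALSE)
data.table::fwrite(demo, file.path(outdir, "demographics.csv"))

## connectome screens, HC vs MS
sc <- lapply(subjects$subject_id, function(id)
  read_conn_matrix(file.path(indir, paste0("sc_", id, ".tsv")), "SC"))
names(sc) <- subjects$subject_id
ts <- lapply(subjects$subject_id, function(id)
  read_timeseries(file.path(indir, paste0("ts_", id, ".tsv")), 2.3, id))
names(ts) <- subjects$subject_id
fc <- lapply(ts, compute_fc)
mask <- sc_prevalence_filter(sc[subjects$group == "HC"])

labels <- subjects$group
for (fam in list(list("PAIR_SC", sc, "WILCOXON", mask),
                 list("REG_SC", sc, "WILCOXON", NULL),
                 list("PAIR_FC", fc, "TTEST", NULL),
                 list("REG_FC", fc, "TTEST", NULL))) {
  ft <- build_feature_table(subjects, fam[[2]], fam[[1]], atlas)
  res <- univariate_screen(ft, labels, test = fam[[3]],
                           prevalence_mask = fam[[4]], atlas = atlas)
  data.table::fwrite(res, file.path(outdir, paste0(tolower(fam[[1]]), "_hc_ms.csv")))
  cat(sprintf("%s: %d features tested, %d significant after BH\n",
              fam[[1]], nrow(res), sum(res$significant)))
}

## dFC metrics, disability subgroups (needs stage 3 output)
mfile <- "results/dfc/state_metrics.csv"
if (file.exists(mfile)) {
  metrics <- as.data.frame(data.table::fread(mfile))
  ms <- subjects$group == "MS"
  lab <- subjects$disability[ms]
  testable <- Filter(function(cn) {
    v <- metrics[[cn]][ms]
    all(tapply(v, lab, function(x) var(x) > 0))  # both groups vary
  }, setdiff(names(metrics), "subject_id"))
  rows <- lapply(testable, function(cn)
    cbind(feature_name = cn,
          compare_feature(metrics[[cn]][ms], lab, "TTEST")))
  res <- do.call(rbind, rows)
  res$p_bh <- bh_adjust(res$p_raw)
  res$significant <- res$p_bh < 0.05
  data.table::fwrite(res, file.path(outdir, "dfc_metrics_disability.csv"))
  top <- res[order(res$p_raw), ][1:3, ]
  cat("top dFC-metric group differences (MS by disability):\n")
  print(top[, c("feature_name", "statistic", "p_raw", "p_bh")], row.names = FALSE)
}
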