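#!/usr/bin/env Rscript

# Stage 6 — feature importance.
#
# Averages the ridge coefficients over all cross-validation fits, scales by
# the maximum magnitude, summarizes regional weights at the network level
# (positive and negative parts separately), and flags features that rank in
# the top decile on both the relative weight and the univariate statistic.

suppressPackageStartupMessages(library(dynconn))

indir <- "results/cohort"
outdir <- "results/importance"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

subjects <- read_subjects(file.path(indir, "subjects.csv"))
atlas <- read_atlas(file.path(indir, "atlas.csv"))

coefs <- as.matrix(data.table::fread("results/classify/disability_reg_dfc_coefs.csv"))
cv <- structure(list(coefficients = coefs), class = "cv_result")
mw <- aggregate_weights(cv)
rw <- scale_weights(mw)

## univariate statistics for the same features (regional dFC, MS subgroups)
regional <- as.data.frame(data.table::fread("results/dfc/regional_dfc.csv"))
K <- max(regional$state)
ms_ids <- subjects$subject_id[subjects$group == "MS"]
lab <- subjects$disability[subjects$group == "MS"]
us <- setNames(rep(0, length(rw)), names(rw))
for (k in 1:K) for (rn in atlas$region_name) {
  cn <- paste0("dFCstr|state", k, "|", rn)
  if (!cn %in% names(us)) next
  v <- regional[regional$state == k & regional$subject_id %in% ms_ids, rn]
  if (length(unique(v)) < 3) next
  us[cn] <- compare_feature(v, lab, "TTEST")$statistic
}

imp <- data.frame(feature_name = names(rw), mean_weight = unname(mw),
                  rel_weight = unname(rw), univariate_stat = unname(us),
                  important = flag_important(rw, us, q = 0.10))
data.table::fwrite(imp, file.path(outdir, "regional_dfc_importance.csv"))
cat(sprintf("%d of %d features flagged important (top-decile weight AND statistic)\n",
            sum(imp$important), nrow(imp)))
print(head(imp[order(-abs(imp$rel_weight)), ], 10), row.names = FALSE)

## network-level summary of the connectome block's relative weights
conn <- grepl("^dFCstr\\|", names(rw))
for (k in 1:K) {
  sel <- conn & grepl(paste0("\\|state", k, "\\|"), names(rw))
  if (!any(sel)) next
  vals <- rw[sel]
  names(vals) <- names(rw)[sel]
  ns <- network_summary(vals, atlas, "regional")
  out <- data.frame(network = names(ns$positive),
                    positive = as.numeric(ns$positive),
                    negative = as.numeric(ns$negative),
                    count = as.numeric(ns$count))
  data.table::fwrite(out, file.path(outdir, sprintf("network_weights_state%d.csv", k)))
}
cat(sprintf("network summaries written to %s\n", outdir))
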