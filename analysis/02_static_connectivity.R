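#!/usr/bin/env Rscript

# Stage 2 — static connectivity features.
#
# Reads the simulated cohort, computes static FC (full-scan Pearson
# correlation) per subject, node strengths for FC (negative entries
# removed) and SC, and the SC edge-prevalence filter over controls, then
# writes the four static feature tables (pairwise/regional x SC/FC).

suppressPackageStartupMessages(library(dynconn))

indir <- "results/cohort"
outdir <- "results/features"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

subjects <- read_subjects(file.path(indir, "subjects.csv"))
atlas <- read_atlas(file.path(indir, "atlas.csv"))

ts <- lapply(subjects$subject_id, function(id)
  read_timeseries(file.path(indir, paste0("ts_", id, ".tsv")), 2.3, id))
sc <- lapply(subjects$subject_id, function(id)
  read_conn_matrix(file.path(indir, paste0("sc_", id, ".tsv")), "SC"))
names(ts) <- names(sc) <- subjects$subject_id

fc <- lapply(ts, compute_fc)

mask <- sc_prevalence_filter(sc[subjects$group == "HC"])
cat(sprintf("SC prevalence filter keeps %d of %d edges\n",
            sum(mask[upper.tri(mask)]), sum(upper.tri(mask))))
data.table::fwrite(data.table::as.data.table(mask * 1),
                   file.path(outdir, "sc_prevalence_mask.tsv"), sep = "\t")

for (spec in list(list("PAIR_SC", sc), list("PAIR_FC", fc),
                  list("REG_SC", sc), list("REG_FC", fc))) {
  ft <- build_feature_table(subjects, spec[[2]], spec[[1]], atlas)
  write_feature_table(ft, file.path(outdir, paste0(tolower(spec[[1]]), ".csv")))
  cat(sprintf("%s: %d covariate + %d connectome columns\n", spec[[1]],
              length(ft$covariate_cols), length(ft$connectome_cols)))
}
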