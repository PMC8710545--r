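#!/usr/bin/env Rscript

# Stage 1 — simulate a cohort.
#
# Generates a synthetic cohort with the pipeline's default study conditions
# scaled to desk size (50 subjects, 20 regions, 174 time points at
# TR = 2.3 s, four latent connectivity states) and writes it to
# results/cohort/ in the same delimited-text formats the pipeline reads for
# real data.  The ground truth (per-subject state paths, transition
# matrices) goes to truth.json for the recovery checks in later stages.

suppressPackageStartupMessages(library(dynconn))

seed <- 20260921L
outdir <- "results/cohort"

cfg <- synth_config(n_hc = 17, n_ms_nodis = 17, n_ms_dis = 16,
                    R = 20, T_len = 174, seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, outdir)

cat(sprintf("wrote %d subjects to %s\n", nrow(cohort$subjects), outdir))
print(table(cohort$subjects$group, useNA = "ifany"))
print(table(cohort$subjects$disability, useNA = "ifany"))
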