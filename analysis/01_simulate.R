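#!/usr/bin/env Rscript
# Stage 1 — generate the study's two synthetic datasets.
#
# (a) A pooled five-arm preclinical trial (159 subjects) with graded injury
#     severity, correlated behavioral + histological outcome batteries, and
#     an inverted-U dose effect on the behavioral outcomes of the sTNFR1 arm.
# (b) An RNA-seq-like count matrix (3 groups x 5 samples) with 10 planted
#     co-expression modules, 300 injury-shifted genes, and 225 genes whose
#     injury response is reversed by treatment.
#
# Writes: results/analysis/outcomes.csv, counts.tsv, groups.tsv,
#         simulation_truth.json

library(scimint)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

trial <- simulate_trial(trial_sim_config(seed = 1))
write_outcome_table(trial$data, file.path(out, "outcomes.csv"))
message(sprintf("trial: %d subjects, %d outcomes, %.1f%% missing",
                nrow(trial$data$outcomes), ncol(trial$data$outcomes),
                100 * mean(is.na(trial$data$outcomes))))

sim <- simulate_expression(expr_sim_config(seed = 2))
write_counts(sim$counts, file.path(out, "counts.tsv"))
write_groups(sim$groups, file.path(out, "groups.tsv"))
jsonlite::write_json(
  list(module = as.list(sim$truth$module),
       injury = as.list(sim$truth$injury),
       reversal = as.list(sim$truth$reversal)),
  file.path(out, "simulation_truth.json"), auto_unbox = TRUE)
message(sprintf("expression: %d genes x %d samples, %d injury / %d reversal genes planted",
                nrow(sim$counts), ncol(sim$counts),
                sum(sim$truth$injury), sum(sim$truth$reversal)))
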