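#!/usr/bin/env Rscript
# Stage 3 — syndromic PCA of the outcome battery, component retention audit,
# subject scoring, and the dose-response test on the first retained
# component within the treated arm.
#
# Reads:  results/analysis/outcomes.csv
# Writes: results/analysis/pca_*.tsv, dose_response.tsv

library(scimint)

out <- "results/analysis"
outcomes <- read_outcome_table(file.path(out, "outcomes.csv"))

model <- correlation_pca(outcomes)
model <- retain_components(model)
model <- score_subjects(model, outcomes)

write.table(data.frame(variable = rownames(model$loadings), model$loadings,
                       check.names = FALSE),
            file.path(out, "pca_loadings.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(model$audit, file.path(out, "pca_retention_audit.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(subject_id = rownames(model$scores), model$scores,
                       check.names = FALSE),
            file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("PC1 explains %.1f%% of total variance; retained: %s",
                100 * model$variance_explained[1],
                paste(names(model$eigenvalues)[model$retained], collapse = ", ")))

treated <- outcomes$meta$arm == "sTNFR1"
dr <- test_dose_response(model$scores[treated, 1],
                         outcomes$meta$dose[treated])
write.table(dr$contrasts, file.path(out, "dose_response.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(dr)
message(sprintf("inverted-U dose response detected: %s", dr$inverted_u))
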