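#!/usr/bin/env Rscript
# Stage 5 — differential expression between the three groups, treatment-
# reversal classification of injury genes, and hypergeometric
# over-representation of the planted gene programs among treatment DEGs.
#
# Reads:  results/analysis/counts.tsv, groups.tsv, simulation_truth.json
# Writes: results/analysis/de_*.tsv, reversal.tsv, enrichment.tsv

library(scimint)

out <- "results/analysis"
counts <- read_counts(file.path(out, "counts.tsv"))
groups <- read_groups(file.path(out, "groups.tsv"), counts)
expr <- normalize_counts(counts)

degs <- deg_table(expr, groups, reference = "sham", vehicle = "vehicle",
                  treated = "treated")
for (nm in names(degs)[1:3])
  write.table(degs[[nm]], file.path(out, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
write.table(degs$reversal, file.path(out, "reversal.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_injury <- sum(degs$vehicle_vs_reference$significant)
n_trt <- sum(degs$treated_vs_vehicle$significant)
cls <- degs$reversal$reversal_class
message(sprintf("%d genes altered by injury; %d altered by treatment", n_injury, n_trt))
message(sprintf("%d injury genes reversed by treatment (%d fully, %d partially)",
                sum(cls %in% c("partial", "full"), na.rm = TRUE),
                sum(cls == "full", na.rm = TRUE),
                sum(cls == "partial", na.rm = TRUE)))

truth <- jsonlite::read_json(file.path(out, "simulation_truth.json"),
                             simplifyVector = TRUE)
sens <- mean(cls[unlist(truth$reversal)] %in% c("partial", "full"))
message(sprintf("sensitivity for planted reversal genes: %.3f", sens))

sets <- split(names(truth$module), unlist(truth$module))
sets <- sets[names(sets) != "none"]
sets$injury_response <- names(truth$injury)[unlist(truth$injury)]
coll <- gene_set_collection(sets, rownames(expr))
sig <- degs$treated_vs_vehicle$gene[degs$treated_vs_vehicle$significant]
enr <- geneset_enrichment(sig, coll)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top enriched sets among treatment DEGs:")
print(head(enr, 4), row.names = FALSE)
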