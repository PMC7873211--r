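#!/usr/bin/env Rscript
# Stage 4 — four-step co-expression analysis: sample-outlier screen, bicor
# network, complete-linkage modules at the top-decile cut, eigengene
# merging, kME, and module-level reversion tests across the three groups.
#
# Reads:  results/analysis/counts.tsv, groups.tsv
# Writes: results/analysis/module_*.tsv

library(scimint)

out <- "results/analysis"
counts <- read_counts(file.path(out, "counts.tsv"))
groups <- read_groups(file.path(out, "groups.tsv"), counts)
expr <- normalize_counts(counts)

dropped <- flag_outlier_samples(expr)
if (length(dropped)) message("excluded outlier samples: ",
                             paste(dropped, collapse = ", "))
keep <- setdiff(colnames(expr), dropped)
expr <- expr[, keep, drop = FALSE]

ms <- detect_modules(expr)
message(sprintf("static cut height %.3f; %d pre-merge modules",
                ms$cut_height,
                length(setdiff(unique(ms$labels), "unassigned"))))
ms <- merge_modules(ms, expr)
print(ms)

own_kme <- vapply(seq_along(ms$labels), function(i) {
  m <- ms$labels[i]
  if (m == "unassigned" || !ncol(ms$kme)) NA_real_ else ms$kme[i, m]
}, numeric(1))
write.table(data.frame(gene = names(ms$labels), module = unname(ms$labels),
                       kme_own = own_kme),
            file.path(out, "module_assignment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_counts(round(ms$eigengenes, 8), file.path(out, "module_eigengenes.tsv"),
             id_label = "module")
write.table(ms$merge_log, file.path(out, "module_merge_log.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tt <- module_trait_test(ms, groups[keep],
                        levels = c("sham", "vehicle", "treated"))
write.table(tt, file.path(out, "module_trait.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "%d of %d modules show a treatment reversion of the injury phenotype: %s",
  sum(tt$reversion), nrow(tt),
  paste(tt$module[tt$reversion], collapse = ", ")))
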