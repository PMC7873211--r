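#!/usr/bin/env Rscript
# Stage 2 — map the multivariate outcome space with bootstrap-consensus
# Mapper and overlay severity, recovery, and arm membership on the nodes.
#
# Reads:  results/analysis/outcomes.csv
# Writes: results/analysis/mapper.graphml, mapper.json, cooccurrence.tsv

library(scimint)

out <- "results/analysis"
outcomes <- read_outcome_table(file.path(out, "outcomes.csv"))

cons <- bootstrap_consensus(outcomes, mapper_config(seed = 3))
g <- cons$graph
g <- add_overlay(g, outcomes, "severity")
g <- add_overlay(g, outcomes, "paw_preference")
g <- add_overlay(g, outcomes, "pct_sparing")
for (a in unique(outcomes$meta$arm))
  g <- add_overlay(g, outcomes, "arm", level = a)
write_mapper_graph(g, file.path(out, "mapper"))
write_counts(round(cons$cooccurrence, 6), file.path(out, "cooccurrence.tsv"),
             id_label = "subject")

message(sprintf("consensus graph: %d nodes, %d edges (full graph had %d edges)",
                nrow(g$nodes), nrow(g$edges), nrow(cons$full_graph$edges)))

# do nodes enriched for behavioral recovery coincide with treated-arm nodes?
rec <- overlay(g, outcomes, "paw_preference")
trt <- overlay(g, outcomes, "arm", level = "sTNFR1")
message(sprintf(
  "rank correlation between recovery overlay and sTNFR1 membership overlay: %.2f",
  cor(rec, trt, method = "spearman", use = "complete.obs")))
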