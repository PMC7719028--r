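#!/usr/bin/env Rscript
# Simulate the study cohort: three groups of weighted structural
# connectomes (controls, PD without hallucinations, PD with
# hallucinations) with a planted set of edges whose weights are reduced
# only in the hallucinating group, plus age and intracranial-volume
# effects on every edge.  Writes the adjacency matrices, the metadata
# table and the ground truth for the downstream scripts.

library(vhconnect)

seed <- 1L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
coh <- generate_cohort(cfg)

message(sprintf("simulated %d subjects (%d nodes each); %d planted edges over %d nodes, effect size %.2f",
                length(coh$connectomes), cfg$n_nodes,
                nrow(coh$truth$planted_edges),
                length(coh$truth$planted_nodes), cfg$effect_size))

for (x in coh$connectomes)
  write_connectome(x, file.path(out_dir, paste0(x$subject_id, ".tsv")))
write.csv(coh$meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       planted_edges = coh$truth$planted_edge_labels,
       planted_nodes = coh$truth$planted_nodes,
       effect_size = coh$truth$effect_size),
  file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)

message("wrote ", out_dir)
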