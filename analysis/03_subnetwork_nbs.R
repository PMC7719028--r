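#!/usr/bin/env Rscript
# Network-based statistic: edge-wise GLM (group + age + intracranial
# volume), suprathreshold components at t = 3.1, and family-wise error
# control by Freedman-Lane permutation of the maximum component size,
# 5000 permutations.  The significant component is the "VH subnetwork"
# of reduced connectivity in the hallucinating group; the test is also
# run in the opposite direction, where nothing should survive.

library(vhconnect)

in_dir <- "results/cohort"
out_dir <- "results/nbs"
if (!file.exists(file.path(in_dir, "metadata.csv")))
  stop("run analysis/01_simulate_cohort.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read.csv(file.path(in_dir, "metadata.csv"))
cons <- lapply(seq_len(nrow(meta)), function(i) {
  read_connectome(file.path(in_dir, paste0(meta$subject_id[i], ".tsv")),
                  meta[i, ])
})
stack <- assemble_cohort(cons, contrast = c("pd_nonvh", "pd_vh"))

res <- nbs_test(stack, threshold = 3.1, direction = "less",
                n_perm = 5000, seed = 2L)
print(res)
res_opp <- nbs_test(stack, threshold = 3.1, direction = "greater",
                    n_perm = 5000, seed = 2L)
message(sprintf("opposite direction: %d significant component(s)",
                length(subnetwork_nodes(res_opp))))

sig_nodes <- subnetwork_nodes(res)
truth <- jsonlite::read_json(file.path(in_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
message(sprintf("planted nodes recovered: %d / %d",
                sum(truth$planted_nodes %in% sig_nodes),
                length(truth$planted_nodes)))

# edge list of the significant components, with t-statistics
edges <- do.call(rbind, lapply(
  Filter(function(c_k) c_k$fwe_p < 0.05, res$components),
  function(c_k) {
    data.frame(node_a = c_k$edges[, 1], node_b = c_k$edges[, 2],
               t = res$edge_stats$t_stat[cbind(c_k$edges[, 1],
                                               c_k$edges[, 2])],
               fwe_p = c_k$fwe_p)
  }))
write.table(edges, file.path(out_dir, "subnetwork_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(node = sig_nodes),
            file.path(out_dir, "subnetwork_nodes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(threshold = res$threshold, n_perm = res$n_perm, seed = res$seed,
       components = lapply(res$components, function(c_k) {
         list(size_edges = c_k$size_edges, n_nodes = length(c_k$nodes),
              fwe_p = c_k$fwe_p)
       })),
  file.path(out_dir, "nbs_summary.json"), auto_unbox = TRUE)
message("wrote ", out_dir)
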