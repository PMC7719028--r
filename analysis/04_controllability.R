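#!/usr/bin/env Rscript
# Average controllability of the stabilized linear dynamics per node and
# subject; rank maps; the strength-controllability association; and group
# comparisons of mean controllability over the whole network and within
# the NBS-derived subnetwork (where the planted reduction should surface
# as lower controllability in the hallucinating group).

library(vhconnect)

in_dir <- "results/cohort"
nbs_dir <- "results/nbs"
out_dir <- "results/controllability"
if (!file.exists(file.path(nbs_dir, "subnetwork_nodes.tsv")))
  stop("run analysis/03_subnetwork_nbs.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read.csv(file.path(in_dir, "metadata.csv"))
cons <- lapply(seq_len(nrow(meta)), function(i) {
  read_connectome(file.path(in_dir, paste0(meta$subject_id[i], ".tsv")),
                  meta[i, ])
})
sub_nodes <- read.delim(file.path(nbs_dir, "subnetwork_nodes.tsv"))$node

profiles <- lapply(cons, controllability_profile)
avg <- t(sapply(profiles, `[[`, "avg_ctrb"))
rownames(avg) <- meta$subject_id
write.csv(avg, file.path(out_dir, "avg_controllability.csv"))

# controllability rank map in controls (the healthy reference)
ctl <- colMeans(avg[meta$group == "control", , drop = FALSE])
write.csv(data.frame(node = names(ctl), avg_ctrb = ctl,
                     rank = rank_nodes(ctl)),
          file.path(out_dir, "control_rank_map.csv"), row.names = FALSE)

# strength-controllability association in controls
rho <- mean(sapply(which(meta$group == "control"), function(i) {
  cor(node_strength(cons[[i]]), profiles[[i]]$avg_ctrb,
      method = "spearman")
}))
message(sprintf("strength-controllability Spearman rho (controls): %.3f",
                rho))

groups <- meta$group
whole <- sapply(profiles, function(p) mean(p$avg_ctrb))
sub <- sapply(profiles, subnetwork_summary, node_subset = sub_nodes)
tests <- list(
  whole_threegroup = compare_groups(split(whole, groups),
                                    test = "kruskal_wallis"),
  whole_vh_vs_nonvh = compare_groups(
    list(pd_nonvh = whole[groups == "pd_nonvh"],
         pd_vh = whole[groups == "pd_vh"])),
  subnet_vh_vs_nonvh = compare_groups(
    list(pd_nonvh = sub[groups == "pd_nonvh"],
         pd_vh = sub[groups == "pd_vh"]), alternative = "greater"),
  subnet_vh_vs_control = compare_groups(
    list(control = sub[groups == "control"],
         pd_vh = sub[groups == "pd_vh"]), alternative = "greater"))
for (nm in names(tests))
  message(sprintf("%-22s %s = %.1f, p = %.4g", nm, tests[[nm]]$test,
                  tests[[nm]]$statistic, tests[[nm]]$p))
jsonlite::write_json(c(tests, list(strength_ctrb_spearman = rho)),
                     file.path(out_dir, "group_comparisons.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", out_dir)
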