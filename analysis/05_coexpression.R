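#!/usr/bin/env Rscript
# Region-as-sample gene co-expression analysis.  A synthetic regional
# expression atlas (emulating the 180-region left-cortical transcription
# matrix) is generated with planted modules, two of which are tied to
# membership in the subnetwork found by the NBS stage.  The trait handed
# to the module-trait stage is the *detected* subnetwork, not the plant.

library(vhconnect)

nbs_dir <- "results/nbs"
out_dir <- "results/coexpression"
if (!file.exists(file.path(nbs_dir, "subnetwork_nodes.tsv")))
  stop("run analysis/03_subnetwork_nbs.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sub_nodes <- read.delim(file.path(nbs_dir, "subnetwork_nodes.tsv"))$node
node_idx <- as.integer(sub("node_", "", sub_nodes))

cfg <- atlas_config(n_regions = 180, trait_regions = node_idx,
                    force_bad_regions = c(44L, 91L, 150L), seed = 3L)
atl <- generate_expression_atlas(cfg)
write.table(cbind(region = rownames(atl$expr$values),
                  as.data.frame(atl$expr$values)),
            file.path(out_dir, "expression_atlas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# trait: detected subnetwork membership by region label
regions <- atl$expr$region_labels
trait <- as.integer(regions %in% sprintf("region_%03d", node_idx))
expr <- expression_matrix(atl$expr$values, trait)

ms <- coexpression_analysis(expr, beta = 6)
print(ms)
message(sprintf("QC removed %d region(s): %s",
                length(ms$qc_report$regions_removed),
                paste(ms$qc_report$regions_removed, collapse = ", ")))

labels <- ms$labels
own_kme <- vapply(seq_along(labels), function(g) {
  if (labels[g] == 0) NA_real_
  else ms$kme[names(labels)[g], paste0("ME", labels[g])]
}, 0)
write.table(data.frame(gene_id = names(labels), module = labels,
                       kme_own = own_kme,
                       gene_significance =
                         ms$gene_significance[names(labels)]),
            file.path(out_dir, "module_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(region = rownames(ms$eigengenes),
                  as.data.frame(ms$eigengenes)),
            file.path(out_dir, "eigengenes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(ms$module_trait, file.path(out_dir, "module_trait.csv"),
          row.names = FALSE)

truth_map <- table(ms$labels, atl$truth$module_of[names(ms$labels)])
ari <- adjusted_rand_index(ms$labels,
                           atl$truth$module_of[names(ms$labels)])
message(sprintf("adjusted Rand index vs planted modules: %.3f", ari))

for (nm in names(ranked_gene_lists(ms))) {
  writeLines(ranked_gene_lists(ms)[[nm]],
             file.path(out_dir, paste0("ranked_genes_", nm, ".txt")))
}
message("wrote ", out_dir)
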