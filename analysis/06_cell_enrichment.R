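#!/usr/bin/env Rscript
# Expression-weighted cell-type enrichment of the trait-associated
# modules' ranked gene lists against a synthetic single-cell reference in
# which the markers of one cell type (oligodendrocytes, mirroring the
# down-weighted module's expected signature) coincide with the planted
# down-weighted module.

library(vhconnect)

coex_dir <- "results/coexpression"
out_dir <- "results/ewce"
lists <- list.files(coex_dir, pattern = "^ranked_genes_.*\\.txt$",
                    full.names = TRUE)
if (length(lists) == 0)
  stop("run analysis/05_coexpression.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# the down-weighted module's planted genes double as oligodendrocyte
# markers; the atlas in 05 plants module 2 as the down-weighted one, with
# genes 101..200 (second block of 100)
ref <- generate_cell_reference(
  n_genes = 2000,
  cell_types = c("neuron", "astrocyte", "oligodendrocyte", "microglia"),
  marker_map = list(oligodendrocyte = 101:200),
  seed = 4L)

for (path in lists) {
  nm <- sub("^ranked_genes_(.*)\\.txt$", "\\1", basename(path))
  target <- readLines(path)
  res <- ewce_test(target, ref$reference, n_boot = 10000, seed = 5L)
  message(sprintf("-- %s (%d genes) --", nm, res$n_target_used))
  print(res)
  write.csv(res$table, file.path(out_dir, paste0("ewce_", nm, ".csv")),
            row.names = FALSE)
}
message("wrote ", out_dir)
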