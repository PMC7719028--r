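# Expression-weighted cell-type enrichment.  A target gene list's summed
# cell-type specificity is compared with a bootstrap null of same-length
# lists drawn from the background, matched to the targets on transcript
# length and GC content via joint quantile bins.

#' Cell-type specificity matrix
#'
#' `s_gc = mean_expr[g, c] / sum_c' mean_expr[g, c']`; rows sum to 1.
#' Genes with zero total expression are excluded and reported.
#'
#' @param reference a `cell_type_reference` (see
#'   [generate_cell_reference()]) or a gene x cell-type matrix.
#' @return List with `specificity` (matrix, rows summing to 1) and
#'   `excluded` (all-zero gene ids).
#' @export
specificity <- function(reference) {
  me <- if (inherits(reference, "cell_type_reference"))
    reference$mean_expr else reference
  totals <- rowSums(me)
  excluded <- rownames(me)[totals == 0]
  keep <- totals > 0
  s <- me[keep, , drop = FALSE] / totals[keep]
  list(specificity = s, excluded = excluded)
}

# Joint quantile bins on (transcript length, GC); empty target bins are
# impossible by construction (bins are defined on the background and every
# target gene is a background gene), but sparse bins are widened by
# lowering the grid resolution until every bin holds >= min_per_bin
# background genes.
covariate_bins <- function(covariates, n_bins = 10, min_per_bin = 5) {
  requested <- n_bins
  repeat {
    ql <- quantile(covariates$transcript_length,
                   probs = seq(0, 1, length.out = n_bins + 1))
    qg <- quantile(covariates$gc_content,
                   probs = seq(0, 1, length.out = n_bins + 1))
    bl <- cut(covariates$transcript_length, unique(ql),
              include.lowest = TRUE, labels = FALSE)
    bg <- cut(covariates$gc_content, unique(qg),
              include.lowest = TRUE, labels = FALSE)
    bin <- paste(bl, bg)
    if (min(table(bin)) >= min_per_bin || n_bins == 1) break
    n_bins <- n_bins - 1
  }
  if (n_bins < requested)
    warnf("sparse covariate bins; widened to a %d x %d quantile grid",
          n_bins, n_bins)
  bin
}

#' Expression-weighted cell-type enrichment test
#'
#' Observed statistic per cell type is the sum of specificity over the
#' target genes.  The null resamples, for each target gene, a background
#' gene from the same joint decile bin of transcript length and GC
#' content, `n_boot` times.  `z = (obs - null mean) / null sd`; one-sided
#' enrichment `p = (1 + #\{null >= obs\}) / (1 + n_boot)`; q by
#' Benjamini-Hochberg across cell types.
#'
#' @param target_genes character vector of gene ids (must be a subset of
#'   the background).
#' @param reference a `cell_type_reference` with `mean_expr` and
#'   `covariates`.
#' @param background_genes background gene ids; defaults to all genes in
#'   the reference.
#' @param n_boot bootstrap lists (study setting 100000; >= 1000 required).
#' @param seed integer seed.
#' @return An object of class `ewce_result`: data frame `table` with
#'   per-cell-type `observed`, `boot_mean`, `boot_sd`, `z`, `p`, `q`, plus
#'   `n_boot`, `seed`, `n_target_used`, `dropped_targets`.
#' @export
ewce_test <- function(target_genes, reference, background_genes = NULL,
                      n_boot = 10000, seed = 1L) {
  if (n_boot < 1000) stopf("n_boot must be >= 1000")
  sp <- specificity(reference)
  s <- sp$specificity
  background_genes <- background_genes %||% rownames(s)
  background_genes <- intersect(background_genes, rownames(s))
  dropped <- setdiff(target_genes, background_genes)
  target_genes <- intersect(target_genes, background_genes)
  if (length(target_genes) == 0) stopf("no target genes in background")
  cov <- reference$covariates
  cov <- cov[match(background_genes, cov$gene_id), ]
  bins <- covariate_bins(cov)
  bin_members <- split(seq_along(background_genes), bins)
  target_idx <- match(target_genes, background_genes)
  target_bins <- bins[target_idx]

  s_bg <- s[background_genes, , drop = FALSE]
  observed <- colSums(s_bg[target_idx, , drop = FALSE])

  set.seed(seed)
  n_t <- length(target_idx)
  # one n_boot x n_t matrix of bin-matched background indices
  samp <- matrix(0L, n_boot, n_t)
  for (j in seq_len(n_t)) {
    members <- bin_members[[target_bins[j]]]
    samp[, j] <- members[sample.int(length(members), n_boot,
                                    replace = TRUE)]
  }
  n_ct <- ncol(s_bg)
  boot_mean <- boot_sd <- p <- numeric(n_ct)
  z <- numeric(n_ct)
  for (c_i in seq_len(n_ct)) {
    null_stat <- rowSums(matrix(s_bg[samp, c_i], n_boot, n_t))
    boot_mean[c_i] <- mean(null_stat)
    boot_sd[c_i] <- sd(null_stat)
    z[c_i] <- (observed[c_i] - boot_mean[c_i]) / boot_sd[c_i]
    p[c_i] <- (1 + sum(null_stat >= observed[c_i])) / (1 + n_boot)
  }
  tab <- data.frame(cell_type = colnames(s_bg), observed = observed,
                    boot_mean = boot_mean, boot_sd = boot_sd, z = z,
                    p = p, q = p.adjust(p, "BH"), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_boot = n_boot, seed = seed,
                 n_target_used = n_t, dropped_targets = dropped),
            class = "ewce_result")
}

#' @export
print.ewce_result <- function(x, ...) {
  cat(sprintf("ewce: %d target genes, %d bootstrap lists\n",
              x$n_target_used, x$n_boot))
  sig <- x$table[x$table$q < 0.05, ]
  if (nrow(sig) > 0)
    cat(sprintf("  enriched: %s\n",
                paste(sprintf("%s (z = %.2f, q = %.3g)", sig$cell_type,
                              sig$z, sig$q), collapse = ", ")))
  else cat("  no cell type enriched at q < 0.05\n")
  invisible(x)
}
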