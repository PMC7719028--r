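# Region-as-sample weighted gene co-expression analysis.  Regions of the
# atlas are the samples, genes the variables; the binary trait marks
# whether a region belongs to the structurally affected subnetwork.
# Pipeline: QC -> soft-threshold signed adjacency -> topological overlap
# -> average-linkage tree cut with k-means eigengene refinement ->
# eigengenes, kME, module-trait biweight midcorrelation with FDR, and
# per-gene trait significance.

#' Region-by-gene expression matrix
#'
#' @param values numeric region x gene matrix (dimnames used as labels
#'   when present); missing entries allowed before QC.
#' @param trait per-region binary vector (1 = region carries the trait,
#'   i.e. participates in the subnetwork).
#' @param region_labels,gene_ids optional label vectors.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, trait, region_labels = NULL,
                              gene_ids = NULL) {
  if (!is.matrix(values)) stopf("values must be a matrix")
  region_labels <- region_labels %||% rownames(values) %||%
    sprintf("region_%03d", seq_len(nrow(values)))
  gene_ids <- gene_ids %||% colnames(values) %||%
    sprintf("gene_%05d", seq_len(ncol(values)))
  if (anyDuplicated(region_labels)) stopf("region labels not unique")
  if (anyDuplicated(gene_ids)) stopf("gene ids not unique")
  if (length(trait) != nrow(values))
    stopf("trait length %d != number of regions %d", length(trait),
          nrow(values))
  if (!all(trait %in% c(0, 1))) stopf("trait must be binary 0/1")
  dimnames(values) <- list(region_labels, gene_ids)
  structure(list(values = values, region_labels = region_labels,
                 gene_ids = gene_ids, trait = as.integer(trait)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d regions x %d genes, %d trait regions\n",
              nrow(x$values), ncol(x$values), sum(x$trait)))
  invisible(x)
}

#' Quality-control filter
#'
#' Drops regions with more than 50% missing entries, then genes with more
#' than 50% missing entries or zero variance; remaining missing values are
#' imputed by the gene median.
#'
#' @param expr an [expression_matrix()].
#' @return List with `expr` (filtered, complete matrix) and `report`
#'   (`regions_removed`, `genes_removed`, `n_imputed`).
#' @export
qc_filter <- function(expr) {
  v <- expr$values
  bad_regions <- rowMeans(is.na(v)) > 0.5
  v2 <- v[!bad_regions, , drop = FALSE]
  trait2 <- expr$trait[!bad_regions]
  gene_missing <- colMeans(is.na(v2)) > 0.5
  gene_var <- apply(v2, 2, var, na.rm = TRUE)
  bad_genes <- gene_missing | is.na(gene_var) | gene_var == 0
  v2 <- v2[, !bad_genes, drop = FALSE]
  if (nrow(v2) < 3) stopf("fewer than 3 regions survive QC")
  n_imputed <- sum(is.na(v2))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(v2)) > 0)) {
      nas <- is.na(v2[, j])
      v2[nas, j] <- median(v2[, j], na.rm = TRUE)
    }
  }
  list(expr = expression_matrix(v2, trait2),
       report = list(
         regions_removed = expr$region_labels[bad_regions],
         genes_removed = expr$gene_ids[bad_genes],
         n_imputed = n_imputed))
}

# Scale-free topology fit index: R^2 of the log-log regression of the
# binned connectivity distribution, signed by the slope (negative slope
# counts as fit, positive as anti-fit).
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < 10 || max(k) == min(k)) return(0)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kc <- tapply(k, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(kc) & kc > 0
  if (sum(ok) < 3) return(0)
  fit <- lm(log10(pk[ok]) ~ log10(kc[ok]))
  r2 <- summary(fit)$r.squared
  if (coef(fit)[2] > 0) -r2 else r2
}

#' Choose the soft-threshold power
#'
#' Picks the smallest candidate power whose signed scale-free topology fit
#' index reaches `r2_target`; if none does, the power with the maximum fit
#' is returned with a warning.
#'
#' @param expr a QC'd [expression_matrix()].
#' @param candidate_powers integer candidates (>= 3 of them unless a
#'   single forced value is supplied).
#' @param r2_target fit threshold.
#' @return List with `power`, `fit_table` (power, r2, mean_k).
#' @export
pick_soft_power <- function(expr, candidate_powers = c(1:10, 12, 14, 16,
                                                       18, 20),
                            r2_target = 0.8) {
  cm <- cor(expr$values, use = "pairwise.complete.obs")
  if (all(abs(cm[upper.tri(cm)]) > 1 - 1e-12))
    stopf("degenerate correlations: all gene pairs perfectly correlated")
  fit_table <- data.frame(power = candidate_powers, r2 = NA_real_,
                          mean_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    a <- ((1 + cm) / 2)^candidate_powers[i]
    k <- colSums(a) - 1
    fit_table$r2[i] <- scale_free_fit(k)
    fit_table$mean_k[i] <- mean(k)
  }
  hit <- which(fit_table$r2 >= r2_target)
  if (length(hit) > 0) {
    power <- candidate_powers[hit[1]]
  } else {
    power <- candidate_powers[which.max(fit_table$r2)]
    warnf("no candidate power reaches scale-free fit R^2 >= %.2f; using %d (R^2 = %.2f)",
          r2_target, power, max(fit_table$r2))
  }
  list(power = power, fit_table = fit_table)
}

#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(g_i, g_j)) / 2)^beta`, diagonal 1.
#'
#' @param expr an [expression_matrix()] (or a plain correlation matrix via
#'   `cor_matrix`).
#' @param beta soft-threshold power (>= 1).
#' @param cor_matrix optional precomputed gene-gene correlation matrix.
#' @return Symmetric gene x gene matrix with entries in \[0, 1\].
#' @export
coexpression_adjacency <- function(expr, beta = 6, cor_matrix = NULL) {
  if (beta < 1) stopf("beta must be >= 1")
  cm <- cor_matrix %||% cor(expr$values)
  a <- ((1 + cm) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' diagonal 1.
#'
#' @param adj symmetric adjacency with entries in \[0, 1\].
#' @return Symmetric TOM with entries in \[0, 1\], diagonal 1.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a                 # L_ij plus no diagonal terms to remove:
  # (a %*% a)_ij = sum_u a_iu a_uj over u != i, j automatically since
  # diag(a) = 0 removes u = i and u = j terms
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

# First principal component of a standardized gene block, unit variance,
# oriented so its correlation with the block's mean expression is >= 0.
module_eigengene_one <- function(block) {
  zs <- scale(block)
  if (ncol(zs) == 1) return(as.vector(zs))
  pc <- prcomp(zs, center = FALSE, scale. = FALSE)
  eg <- pc$x[, 1]
  eg <- eg / sd(eg)
  if (cor(eg, rowMeans(zs)) < 0) eg <- -eg
  as.vector(eg)
}

#' Module eigengenes
#'
#' First principal component of each module's standardized gene columns,
#' scaled to unit variance and sign-oriented so it correlates positively
#' with the module's mean expression.
#'
#' @param expr a QC'd [expression_matrix()].
#' @param labels per-gene module labels (0 = unassigned).
#' @return Region x module numeric matrix, columns named `ME<label>`.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(setdiff(unique(labels), 0))
  if (length(mods) == 0) stopf("no assigned modules")
  eg <- vapply(mods, function(m) {
    module_eigengene_one(expr$values[, labels == m, drop = FALSE])
  }, numeric(nrow(expr$values)))
  colnames(eg) <- paste0("ME", mods)
  rownames(eg) <- expr$region_labels
  eg
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on 1 - TOM, a dynamic-height
#' tree cut, then k-means-style refinement at the eigengene level.  The
#' cut height is chosen by scanning the merge-height range for the cut
#' that yields the most clusters of at least `min_size` genes (ties go to
#' the largest such height, which aggregates stray genes rather than
#' splitting branches).  Refinement then iteratively reassigns each gene
#' to the module whose eigengene it correlates with best; genes whose best
#' correlation falls below `kme_min` are unassigned, and modules that end
#' up smaller than `min_size` are dissolved into their closest module.
#'
#' @param expr a QC'd [expression_matrix()].
#' @param tom the [tom_similarity()] matrix of the same genes.
#' @param min_size minimum module size.
#' @param n_cut_heights resolution of the cut-height scan.
#' @param kme_min minimum |kME| to stay assigned.
#' @param max_iter refinement iteration cap.
#' @return Integer vector of per-gene module labels (0 = unassigned),
#'   named by gene id, with consecutive labels 1, 2, ... sorted by
#'   decreasing module size.
#' @export
detect_modules <- function(expr, tom, min_size = 30,
                           n_cut_heights = 50, kme_min = 0.3,
                           max_iter = 20) {
  d <- as.dist(1 - tom)
  h <- hclust(d, method = "average")
  hts <- quantile(h$height, probs = seq(0.5, 1, length.out = n_cut_heights))
  hts <- unique(hts * (1 - 1e-9))
  n_big <- vapply(hts, function(ht) {
    sum(table(cutree(h, h = ht)) >= min_size)
  }, 0L)
  if (max(n_big) == 0) {
    warnf("no module of size >= %d at any cut", min_size)
    return(setNames(rep(0L, ncol(expr$values)), expr$gene_ids))
  }
  cut_h <- max(hts[n_big == max(n_big)])
  labels <- cutree(h, h = cut_h)
  sizes <- table(labels)
  labels[labels %in% as.integer(names(sizes)[sizes < min_size])] <- 0L
  if (all(labels == 0)) {
    warnf("no module of size >= %d at the initial cut", min_size)
    return(setNames(rep(0L, ncol(expr$values)), expr$gene_ids))
  }
  v <- expr$values
  for (iter in seq_len(max_iter)) {
    eg <- module_eigengenes(expr, labels)
    mods <- as.integer(sub("ME", "", colnames(eg)))
    kme <- cor(v, eg)
    best <- max.col(kme, ties.method = "first")
    best_r <- kme[cbind(seq_len(nrow(kme)), best)]
    new_labels <- ifelse(best_r >= kme_min, mods[best], 0L)
    # dissolve undersized modules into their best-correlated neighbour
    repeat {
      sz <- table(new_labels[new_labels != 0])
      small <- as.integer(names(sz)[sz < min_size])
      if (length(small) == 0 || length(sz) <= 1) break
      m <- small[1]
      keep_mods <- setdiff(as.integer(names(sz)), m)
      keep_cols <- match(paste0("ME", keep_mods), colnames(eg))
      keep_cols <- keep_cols[!is.na(keep_cols)]
      if (length(keep_cols) == 0) break
      gi <- which(new_labels == m)
      sub_kme <- kme[gi, keep_cols, drop = FALSE]
      b2 <- max.col(sub_kme, ties.method = "first")
      r2 <- sub_kme[cbind(seq_along(gi), b2)]
      mods2 <- as.integer(sub("ME", "", colnames(kme)[keep_cols]))
      new_labels[gi] <- ifelse(r2 >= kme_min, mods2[b2], 0L)
    }
    if (all(new_labels == labels)) break
    labels <- new_labels
    if (all(labels == 0)) {
      warnf("all genes unassigned after refinement")
      break
    }
  }
  # relabel by decreasing size
  sz <- sort(table(labels[labels != 0]), decreasing = TRUE)
  remap <- setNames(seq_along(sz), names(sz))
  out <- ifelse(labels == 0, 0L, as.integer(remap[as.character(labels)]))
  setNames(out, expr$gene_ids)
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene with every module eigengene.
#'
#' @param expr a QC'd [expression_matrix()].
#' @param eigengenes a [module_eigengenes()] matrix.
#' @return Gene x module matrix of correlations in \[-1, 1\].
#' @export
module_membership <- function(expr, eigengenes) {
  kme <- cor(expr$values, eigengenes)
  rownames(kme) <- expr$gene_ids
  kme
}

#' Biweight midcorrelation against a binary trait
#'
#' Robust correlation with Tukey biweights on the numeric side; the
#' binary side uses plain centring (the documented Pearson fallback, since
#' the MAD of a binary vector can be zero).
#'
#' @param x numeric vector.
#' @param y binary 0/1 vector of the same length.
#' @return Correlation in \[-1, 1\].
#' @export
bicor_binary <- function(x, y) {
  med <- median(x)
  madx <- mad(x, constant = 1)
  if (madx == 0) {
    xs <- x - mean(x)                # robust weights undefined; fall back
  } else {
    u <- (x - med) / (9 * madx)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xs <- (x - med) * w
  }
  ys <- y - mean(y)
  denom <- sqrt(sum(xs^2)) * sqrt(sum(ys^2))
  if (denom == 0) return(0)
  sum(xs * ys) / denom
}

#' Module-trait association
#'
#' Biweight midcorrelation between each module eigengene and the binary
#' trait; p-values from the t-transform of r at n - 2 df, q-values by
#' Benjamini-Hochberg across modules.
#'
#' @param eigengenes a [module_eigengenes()] matrix.
#' @param trait per-region binary vector, both classes present.
#' @return Data frame with `module`, `r`, `p`, `q`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (length(unique(trait)) < 2) stopf("trait is constant")
  n <- nrow(eigengenes)
  r <- apply(eigengenes, 2, bicor_binary, y = trait)
  r_c <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_c * sqrt((n - 2) / (1 - r_c^2))
  p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  data.frame(module = colnames(eigengenes), r = r, p = p,
             q = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gene significance for the trait
#'
#' Absolute correlation between each gene's expression and the binary
#' trait.
#'
#' @param expr a QC'd [expression_matrix()].
#' @param trait optional override of `expr$trait`.
#' @return Named numeric vector in \[0, 1\].
#' @export
gene_significance <- function(expr, trait = expr$trait) {
  gs <- abs(as.vector(cor(expr$values, trait)))
  setNames(gs, expr$gene_ids)
}

#' Full co-expression analysis
#'
#' Runs QC, soft-power selection (or a fixed power), adjacency, TOM,
#' module detection, eigengenes, kME, module-trait association and gene
#' significance in one call.
#'
#' @param expr an [expression_matrix()] (pre-QC).
#' @param beta fixed soft power, or `NULL` for data-driven selection.
#' @param min_size minimum module size.
#' @return An object of class `module_set`: list with `labels`,
#'   `eigengenes`, `kme`, `module_trait`, `gene_significance`, `power`,
#'   `qc_report`, `expr` (the QC'd matrix).
#' @export
coexpression_analysis <- function(expr, beta = 6, min_size = 30) {
  qc <- qc_filter(expr)
  e <- qc$expr
  if (is.null(beta)) beta <- pick_soft_power(e)$power
  adj <- coexpression_adjacency(e, beta)
  tom <- tom_similarity(adj)
  labels <- detect_modules(e, tom, min_size = min_size)
  if (all(labels == 0)) {
    return(structure(list(labels = labels, eigengenes = NULL, kme = NULL,
                          module_trait = NULL,
                          gene_significance = gene_significance(e),
                          power = beta, qc_report = qc$report, expr = e),
                     class = "module_set"))
  }
  eg <- module_eigengenes(e, labels)
  kme <- module_membership(e, eg)
  mt <- module_trait_correlation(eg, e$trait)
  structure(list(labels = labels, eigengenes = eg, kme = kme,
                 module_trait = mt,
                 gene_significance = gene_significance(e),
                 power = beta, qc_report = qc$report, expr = e),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$labels), 0))
  cat(sprintf("module_set: %d modules over %d genes (power %s, %d unassigned)\n",
              n_mod, length(x$labels), x$power, sum(x$labels == 0)))
  if (!is.null(x$module_trait)) {
    sig <- x$module_trait[x$module_trait$q < 0.05, ]
    if (nrow(sig) > 0)
      cat(sprintf("  trait-associated: %s\n",
                  paste(sprintf("%s (r = %.3f, q = %.3g)", sig$module,
                                sig$r, sig$q), collapse = ", ")))
  }
  invisible(x)
}

#' Ranked gene lists for significant modules
#'
#' For every module with trait q below `alpha`, returns its genes ranked
#' by gene significance (default) or by |kME| to the module.
#'
#' @param modules a [coexpression_analysis()] result.
#' @param alpha FDR threshold.
#' @param rank_by `"gene_significance"` or `"kme"`.
#' @return Named list of character vectors of gene ids, most significant
#'   first.
#' @export
ranked_gene_lists <- function(modules, alpha = 0.05,
                              rank_by = c("gene_significance", "kme")) {
  rank_by <- match.arg(rank_by)
  if (is.null(modules$module_trait)) return(list())
  sig <- modules$module_trait$module[modules$module_trait$q < alpha]
  out <- list()
  for (m in sig) {
    mid <- as.integer(sub("ME", "", m))
    genes <- names(modules$labels)[modules$labels == mid]
    score <- if (rank_by == "gene_significance")
      modules$gene_significance[genes]
    else abs(modules$kme[genes, m])
    out[[m]] <- genes[order(-score)]
  }
  out
}
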