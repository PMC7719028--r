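# Synthetic cohort, expression atlas and cell-type reference with known
# planted structure.  Every downstream stage of the pipeline is exercised
# against these ground truths: a subset of edges whose weights are reduced
# only in the hallucinating (VH) group, gene modules built from latent
# factors some of which are tied to a binary region trait, and marker
# genes with elevated expression in their cell type.

#' Cohort generator configuration
#'
#' Edge weights follow a log-normal baseline (tractography streamline
#' weights are heavy-tailed) with additive Gaussian subject noise on the
#' log scale, linear age and intracranial-volume effects on all edges, and
#' a multiplicative reduction by `effect_size` on the planted edges in the
#' VH group only.
#'
#' @param n_nodes number of parcels.
#' @param n_controls,n_nonvh,n_vh group sizes.
#' @param planted_edges 2-column matrix of node index pairs (upper
#'   triangle, no self pairs); `NULL` plants a random connected clique-ish
#'   edge set of `n_planted_edges` edges.
#' @param n_planted_edges used only when `planted_edges` is `NULL`.
#' @param effect_size fractional weight reduction in the VH group, in
#'   \[0, 1\]; 0.5 halves the planted weights.
#' @param edge_weight_scale median baseline edge weight.
#' @param baseline_sd spread of the per-edge log-baseline.
#' @param noise_sd subject-level noise sd on the log scale.
#' @param beta_age,beta_tiv slopes of log edge weight on centred age
#'   (years) and centred intracranial volume (ml).
#' @param seed integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nodes = 30, n_controls = 20, n_nonvh = 20,
                          n_vh = 20, planted_edges = NULL,
                          n_planted_edges = 15, effect_size = 0.5,
                          edge_weight_scale = 1, baseline_sd = 0.5,
                          noise_sd = 0.3, beta_age = -0.005,
                          beta_tiv = 0.0005, seed = 1L) {
  for (fld in c("n_nodes", "n_controls", "n_nonvh", "n_vh")) {
    v <- get(fld)
    if (!is.numeric(v) || v < 1) stopf("invalid config: %s must be >= 1",
                                       fld)
  }
  if (effect_size < 0 || effect_size > 1)
    stopf("invalid config: effect_size must be in [0, 1]")
  if (edge_weight_scale <= 0)
    stopf("invalid config: edge_weight_scale must be positive")
  if (noise_sd < 0) stopf("invalid config: noise_sd must be >= 0")
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (any(planted_edges[, 1] >= planted_edges[, 2]))
      stopf("invalid config: planted_edges must be upper-triangle pairs")
    if (any(planted_edges > n_nodes))
      stopf("invalid config: planted_edges out of node range")
  }
  structure(list(n_nodes = n_nodes, n_controls = n_controls,
                 n_nonvh = n_nonvh, n_vh = n_vh,
                 planted_edges = planted_edges,
                 n_planted_edges = n_planted_edges,
                 effect_size = effect_size,
                 edge_weight_scale = edge_weight_scale,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 beta_age = beta_age, beta_tiv = beta_tiv,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Plant a compact edge set: edges among a small node clique, taken in
# order, so the planted subnetwork is connected.
default_planted_edges <- function(n_nodes, n_edges) {
  k <- 2
  while (k * (k - 1) / 2 < n_edges) k <- k + 1
  nodes <- seq_len(k)
  pairs <- upper_pairs(k)
  pairs[seq_len(n_edges), , drop = FALSE]
}

#' Generate a synthetic cohort of connectomes
#'
#' @param config a [cohort_config()].
#' @return List with `connectomes` (list of [connectome()]), `truth`
#'   (planted edge matrix, planted node labels, effect size), `meta`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  planted <- config$planted_edges %||%
    default_planted_edges(n, config$n_planted_edges)
  labels <- sprintf("node_%03d", seq_len(n))
  groups <- rep(c("control", "pd_nonvh", "pd_vh"),
                c(config$n_controls, config$n_nonvh, config$n_vh))
  n_sub <- length(groups)
  # population means loosely matched to the cohort's demographics
  age <- rnorm(n_sub, 65, 8)
  tiv <- rnorm(n_sub, 1450, 120)
  n_edges <- n * (n - 1) / 2
  log_base <- rnorm(n_edges, log(config$edge_weight_scale),
                    config$baseline_sd)
  # all per-edge vectors use the column-major upper-triangle order
  ut <- upper.tri(matrix(0, n, n))
  ord <- arrayInd(which(ut), c(n, n))
  key <- paste(ord[, 1], ord[, 2])
  planted_ut <- match(paste(planted[, 1], planted[, 2]), key)
  if (anyNA(planted_ut)) stopf("internal: planted edge not in edge order")
  connectomes <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    lw <- log_base +
      config$beta_age * (age[s] - 65) +
      config$beta_tiv * (tiv[s] - 1450) +
      rnorm(n_edges, 0, config$noise_sd)
    w_ut <- exp(lw)
    if (groups[s] == "pd_vh" && config$effect_size > 0)
      w_ut[planted_ut] <- w_ut[planted_ut] * (1 - config$effect_size)
    w <- matrix(0, n, n)
    w[ut] <- w_ut
    w <- w + t(w)
    connectomes[[s]] <- connectome(w, sprintf("sub_%03d", s), groups[s],
                                   age[s], tiv[s], node_labels = labels)
  }
  truth <- list(planted_edges = planted,
                planted_edge_labels = cbind(labels[planted[, 1]],
                                            labels[planted[, 2]]),
                planted_nodes = labels[sort(unique(as.vector(planted)))],
                effect_size = config$effect_size)
  meta <- data.frame(subject_id = sprintf("sub_%03d", seq_len(n_sub)),
                     group = groups, age = age, tiv = tiv,
                     stringsAsFactors = FALSE)
  list(connectomes = connectomes, truth = truth, meta = meta)
}

#' Expression atlas generator configuration
#'
#' Each planted module m is built from a latent region factor f_m: gene
#' columns are `sqrt(rho) * f_m + sqrt(1 - rho) * noise`, giving mean
#' within-module gene-gene correlation rho.  A module listed in
#' `modules_linked_to_trait` has its factor mixed with the standardized
#' binary trait, `f = sign * gamma * t_std + sqrt(1 - gamma^2) * z`, so the
#' eigengene-trait correlation targets `sign * gamma`.
#'
#' @param n_regions,n_genes atlas dimensions (study scale: 180 regions).
#' @param module_sizes integer vector of planted module sizes; the
#'   remaining genes are independent noise.
#' @param within_module_cor target within-module correlation rho in (0,1).
#' @param trait_regions indices of regions carrying the binary trait
#'   (region participates in the subnetwork); `NULL` picks the first
#'   quarter of regions.
#' @param modules_linked_to_trait named numeric vector: entry `"2" = -0.5`
#'   links module 2 with eigengene-trait correlation target -0.5.
#' @param missing_fraction fraction of entries set missing at random.
#' @param force_bad_regions region indices forced above 50% missingness
#'   (to exercise QC).
#' @param seed integer seed.
#' @return A list of class `atlas_config`.
#' @export
atlas_config <- function(n_regions = 180, n_genes = 2000,
                         module_sizes = rep(100, 4),
                         within_module_cor = 0.7, trait_regions = NULL,
                         modules_linked_to_trait = c("1" = 0.5,
                                                     "2" = -0.5),
                         missing_fraction = 0.02,
                         force_bad_regions = integer(0), seed = 1L) {
  if (sum(module_sizes) > n_genes)
    stopf("invalid config: module_sizes sum exceeds n_genes")
  if (within_module_cor <= 0 || within_module_cor >= 1)
    stopf("invalid config: within_module_cor must be in (0, 1)")
  if (!is.null(trait_regions) && any(trait_regions > n_regions))
    stopf("invalid config: trait_regions out of range")
  if (length(modules_linked_to_trait) > 0) {
    mi <- as.integer(names(modules_linked_to_trait))
    if (anyNA(mi) || any(mi < 1) || any(mi > length(module_sizes)))
      stopf("invalid config: modules_linked_to_trait names must index modules")
    if (any(abs(modules_linked_to_trait) >= 1))
      stopf("invalid config: trait correlation targets must be in (-1, 1)")
  }
  structure(list(n_regions = n_regions, n_genes = n_genes,
                 module_sizes = module_sizes,
                 within_module_cor = within_module_cor,
                 trait_regions = trait_regions,
                 modules_linked_to_trait = modules_linked_to_trait,
                 missing_fraction = missing_fraction,
                 force_bad_regions = force_bad_regions,
                 seed = as.integer(seed)),
            class = "atlas_config")
}

#' Generate a synthetic regional expression atlas
#'
#' @param config an [atlas_config()].
#' @return List with `expr` (an `expression_matrix`, see
#'   [expression_matrix()]), `truth` (per-gene planted module labels, the
#'   latent factors, trait targets).
#' @export
generate_expression_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  set.seed(config$seed)
  nr <- config$n_regions; ng <- config$n_genes
  trait_regions <- config$trait_regions %||% seq_len(max(1, nr %/% 4))
  trait <- as.integer(seq_len(nr) %in% trait_regions)
  t_std <- as.vector(scale(trait))
  n_mod <- length(config$module_sizes)
  module_of <- rep(0L, ng)
  vals <- matrix(rnorm(nr * ng), nr, ng)
  factors <- matrix(NA_real_, nr, n_mod)
  g0 <- 0
  rho <- config$within_module_cor
  for (m in seq_len(n_mod)) {
    z <- rnorm(nr)
    tgt <- config$modules_linked_to_trait[as.character(m)]
    f <- if (!is.na(tgt) && length(tgt) == 1 && !is.null(tgt)) {
      tgt * t_std + sqrt(1 - tgt^2) * z
    } else z
    factors[, m] <- f
    idx <- g0 + seq_len(config$module_sizes[m])
    module_of[idx] <- m
    vals[, idx] <- sqrt(rho) * f +
      sqrt(1 - rho) * matrix(rnorm(nr * length(idx)), nr)
    g0 <- g0 + config$module_sizes[m]
  }
  if (config$missing_fraction > 0) {
    miss <- runif(nr * ng) < config$missing_fraction
    vals[miss] <- NA
  }
  for (r in config$force_bad_regions) {
    drop_idx <- sample.int(ng, ceiling(0.6 * ng))
    vals[r, drop_idx] <- NA
  }
  region_labels <- sprintf("region_%03d", seq_len(nr))
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  dimnames(vals) <- list(region_labels, gene_ids)
  expr <- expression_matrix(vals, trait = trait)
  truth <- list(module_of = setNames(module_of, gene_ids),
                factors = factors,
                trait_regions = region_labels[trait_regions],
                modules_linked_to_trait = config$modules_linked_to_trait)
  list(expr = expr, truth = truth)
}

#' Generate a synthetic cell-type reference
#'
#' Marker genes get their mean expression multiplied by `marker_fold` in
#' their own cell type; per-gene transcript length (bp) and GC fraction
#' covariates are attached.
#'
#' @param n_genes number of genes; ids `gene_00001`-style so references
#'   align with [generate_expression_atlas()] output.
#' @param cell_types character vector of cell-type names.
#' @param marker_map named list, cell type -> integer gene indices; no
#'   gene may be a marker for two cell types.
#' @param marker_fold expression multiplier for a marker in its own type.
#' @param seed integer seed.
#' @return List with `reference` (a `cell_type_reference`: `mean_expr`
#'   gene x cell-type matrix, `covariates` data frame) and `truth`.
#' @export
generate_cell_reference <- function(n_genes, cell_types, marker_map,
                                    marker_fold = 5, seed = 1L) {
  all_markers <- unlist(marker_map)
  if (anyDuplicated(all_markers))
    stopf("invalid config: gene %d assigned to multiple cell types",
          all_markers[duplicated(all_markers)][1])
  if (!all(names(marker_map) %in% cell_types))
    stopf("invalid config: marker_map names must be cell types")
  set.seed(seed)
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  me <- matrix(rlnorm(n_genes * length(cell_types), 0, 0.5),
               n_genes, length(cell_types),
               dimnames = list(gene_ids, cell_types))
  for (ct in names(marker_map))
    me[marker_map[[ct]], ct] <- me[marker_map[[ct]], ct] * marker_fold
  covariates <- data.frame(
    gene_id = gene_ids,
    transcript_length = round(rlnorm(n_genes, log(2500), 0.8)),
    gc_content = pmin(pmax(rnorm(n_genes, 0.45, 0.08), 0.2), 0.8),
    stringsAsFactors = FALSE)
  reference <- structure(list(mean_expr = me, covariates = covariates),
                         class = "cell_type_reference")
  list(reference = reference,
       truth = list(marker_map = lapply(marker_map,
                                        function(i) gene_ids[i])))
}
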