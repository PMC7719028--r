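# End-to-end orchestration: synthesize (or load) the cohort, compute
# topology, detect the reduced-connectivity subnetwork, compare
# controllability within it, hand subnetwork membership to the
# co-expression stage as the region trait, and test the resulting gene
# lists for cell-type enrichment.

#' Pipeline configuration
#'
#' Defaults follow the study settings: NBS threshold t = 3.1, family-wise
#' error level 0.05; the synthetic-cohort, atlas and reference
#' configurations control the planted ground truth.
#'
#' @param cohort a [cohort_config()].
#' @param atlas an [atlas_config()]; `NULL` derives one whose trait
#'   regions are the planted subnetwork nodes.
#' @param nbs_threshold t threshold for the edge statistic.
#' @param nbs_n_perm permutations for the NBS null.
#' @param nbs_direction direction of the tested contrast.
#' @param alpha FWE / FDR significance level used at every stage.
#' @param beta soft-threshold power for the co-expression network
#'   (`NULL` = data-driven).
#' @param min_module_size minimum co-expression module size.
#' @param ewce_n_boot bootstrap lists for the enrichment test.
#' @param cell_types,marker_map,marker_modules cell-type reference plan:
#'   `marker_modules` names, per cell type, the planted expression module
#'   whose genes double as that type's markers (`NULL` skips the stage).
#' @param seed global seed, split deterministically into per-stage seeds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            atlas = NULL,
                            nbs_threshold = 3.1, nbs_n_perm = 5000,
                            nbs_direction = "less", alpha = 0.05,
                            beta = 6, min_module_size = 30,
                            ewce_n_boot = 10000,
                            cell_types = c("neuron", "astrocyte",
                                           "oligodendrocyte",
                                           "microglia"),
                            marker_modules = c(oligodendrocyte = 2L),
                            seed = 1L) {
  structure(list(cohort = cohort, atlas = atlas,
                 nbs_threshold = nbs_threshold, nbs_n_perm = nbs_n_perm,
                 nbs_direction = nbs_direction, alpha = alpha,
                 beta = beta, min_module_size = min_module_size,
                 ewce_n_boot = ewce_n_boot, cell_types = cell_types,
                 marker_modules = marker_modules,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Group comparison of global topology metrics
#'
#' Per metric: Shapiro-Wilk normality gate, then ANOVA across the three
#' groups (Kruskal-Wallis when any group is non-normal) and a t-test
#' (Mann-Whitney) for the VH vs non-VH contrast.
#'
#' @param connectomes list of [connectome()] objects spanning the groups.
#' @return Data frame with `metric`, `test_3group`, `stat_3group`,
#'   `p_3group`, `test_vh`, `stat_vh`, `p_vh`.
#' @export
compare_topology <- function(connectomes) {
  groups <- vapply(connectomes, `[[`, "", "group")
  tops <- lapply(connectomes, topology_summary)
  metrics <- c("density", "mean_clustering", "char_path_length",
               "mean_strength")
  rows <- lapply(metrics, function(m) {
    vals <- vapply(tops, `[[`, 0, m)
    by_group <- split(vals, groups)
    if (sd(vals) == 0) {
      # metric constant across the cohort (e.g. density of dense graphs)
      return(data.frame(metric = m, test_3group = "constant",
                        stat_3group = NA, p_3group = NA,
                        test_vh = "constant", stat_vh = NA, p_vh = NA,
                        stringsAsFactors = FALSE))
    }
    normal <- all(vapply(by_group, function(v) {
      length(unique(v)) < 3 || shapiro.test(v)$p.value > 0.05
    }, TRUE))
    if (length(by_group) >= 3) {
      if (normal) {
        fit <- aov(vals ~ factor(groups))
        s3 <- summary(fit)[[1]]
        test3 <- "anova"; stat3 <- s3$`F value`[1]; p3 <- s3$`Pr(>F)`[1]
      } else {
        kt <- kruskal.test(by_group)
        test3 <- "kruskal_wallis"; stat3 <- unname(kt$statistic)
        p3 <- kt$p.value
      }
    } else {
      test3 <- NA; stat3 <- NA; p3 <- NA
    }
    if (all(c("pd_vh", "pd_nonvh") %in% names(by_group))) {
      a <- by_group$pd_vh; b <- by_group$pd_nonvh
      if (normal) {
        tt <- t.test(a, b)
        testv <- "t_test"; statv <- unname(tt$statistic)
        pv <- tt$p.value
      } else {
        wt <- wilcox.test(a, b)
        testv <- "mann_whitney"; statv <- unname(wt$statistic)
        pv <- wt$p.value
      }
    } else {
      testv <- NA; statv <- NA; pv <- NA
    }
    data.frame(metric = m, test_3group = test3, stat_3group = stat3,
               p_3group = p3, test_vh = testv, stat_vh = statv,
               p_vh = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Map subnetwork node labels from the connectome space onto expression
# region labels.  With an explicit mapping data frame (node_label,
# region_label) the join is by label; without one, node_%03d labels are
# matched to region_%03d labels positionally, the synthetic convention.
map_nodes_to_regions <- function(node_labels, region_labels,
                                 mapping = NULL) {
  if (!is.null(mapping)) {
    hit <- mapping$region_label[match(node_labels, mapping$node_label)]
    return(intersect(region_labels, hit[!is.na(hit)]))
  }
  idx <- as.integer(sub("node_", "", node_labels))
  intersect(region_labels, sprintf("region_%03d", idx))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: cohort synthesis, topology comparison, network-based statistic
#' for the reduced-connectivity subnetwork, controllability comparison
#' within that subnetwork, co-expression module detection with subnetwork
#' membership as the region trait, and cell-type enrichment of the
#' trait-associated modules.  When the NBS stage finds no significant
#' subnetwork the trait-dependent stages are skipped with a notice, and
#' the partial bundle is returned.
#'
#' @param config a [pipeline_config()].
#' @return A results bundle (class `pipeline_result`): list with
#'   `topology`, `nbs`, `controllability`, `modules`, `gene_lists`,
#'   `ewce`, `truth`, `provenance`, `notices`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seeds <- list(cohort = split_seed(config$seed, 1),
                nbs = split_seed(config$seed, 2),
                atlas = split_seed(config$seed, 3),
                reference = split_seed(config$seed, 4),
                ewce = split_seed(config$seed, 5))
  notices <- character(0)
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- seeds$cohort
  cohort <- generate_cohort(cohort_cfg)

  topology <- compare_topology(cohort$connectomes)

  stack <- assemble_cohort(cohort$connectomes,
                           contrast = c("pd_nonvh", "pd_vh"))
  nbs <- nbs_test(stack, threshold = config$nbs_threshold,
                  direction = config$nbs_direction,
                  n_perm = config$nbs_n_perm, seed = seeds$nbs)
  sig_nodes <- subnetwork_nodes(nbs, alpha = config$alpha)

  profiles <- lapply(cohort$connectomes, controllability_profile)
  groups <- vapply(cohort$connectomes, `[[`, "", "group")
  whole <- vapply(profiles, function(p) mean(p$avg_ctrb), 0)
  ctrb <- list(
    whole_network = compare_groups(split(whole, groups),
                                   test = "kruskal_wallis"),
    whole_vh_vs_nonvh = compare_groups(
      list(pd_nonvh = whole[groups == "pd_nonvh"],
           pd_vh = whole[groups == "pd_vh"]),
      test = "mann_whitney"))
  if (length(sig_nodes) > 0) {
    sub_mean <- vapply(profiles, subnetwork_summary,
                       0, node_subset = sig_nodes)
    ctrb$subnetwork_vh_vs_nonvh <- compare_groups(
      list(pd_nonvh = sub_mean[groups == "pd_nonvh"],
           pd_vh = sub_mean[groups == "pd_vh"]),
      test = "mann_whitney", alternative = "greater")
    ctrb$subnetwork_vh_vs_control <- compare_groups(
      list(control = sub_mean[groups == "control"],
           pd_vh = sub_mean[groups == "pd_vh"]),
      test = "mann_whitney", alternative = "greater")
  }

  modules <- NULL; gene_lists <- list(); ewce <- list()
  atlas_truth <- NULL; ref_truth <- NULL
  if (length(sig_nodes) == 0) {
    notices <- c(notices,
                 "no significant subnetwork: trait stages skipped")
  } else {
    atlas_cfg <- config$atlas
    if (is.null(atlas_cfg)) {
      node_idx <- as.integer(sub("node_", "", sig_nodes))
      atlas_cfg <- atlas_config(
        n_regions = max(180, cohort_cfg$n_nodes),
        trait_regions = node_idx, seed = seeds$atlas)
    }
    atlas_cfg$seed <- seeds$atlas
    atlas <- generate_expression_atlas(atlas_cfg)
    atlas_truth <- atlas$truth
    # trait from the NBS result, not the plant
    regions <- map_nodes_to_regions(sig_nodes,
                                    atlas$expr$region_labels)
    trait <- as.integer(atlas$expr$region_labels %in% regions)
    expr <- expression_matrix(atlas$expr$values, trait)
    modules <- coexpression_analysis(expr, beta = config$beta,
                                     min_size = config$min_module_size)
    gene_lists <- ranked_gene_lists(modules, alpha = config$alpha)
    if (length(gene_lists) == 0) {
      notices <- c(notices,
                   "no trait-associated module: enrichment skipped")
    } else if (length(config$marker_modules) > 0) {
      marker_map <- lapply(config$marker_modules, function(m) {
        which(atlas$truth$module_of == m)
      })
      ref <- generate_cell_reference(
        n_genes = ncol(atlas$expr$values),
        cell_types = config$cell_types, marker_map = marker_map,
        seed = seeds$reference)
      ref_truth <- ref$truth
      for (lst in names(gene_lists)) {
        ewce[[lst]] <- ewce_test(gene_lists[[lst]], ref$reference,
                                 n_boot = config$ewce_n_boot,
                                 seed = seeds$ewce)
      }
    }
  }
  structure(list(topology = topology, nbs = nbs,
                 controllability = ctrb, modules = modules,
                 gene_lists = gene_lists, ewce = ewce,
                 truth = list(cohort = cohort$truth,
                              atlas = atlas_truth, reference = ref_truth),
                 provenance = list(seed = config$seed,
                                   stage_seeds = seeds,
                                   nbs_threshold = config$nbs_threshold,
                                   nbs_n_perm = config$nbs_n_perm,
                                   beta = config$beta,
                                   ewce_n_boot = config$ewce_n_boot),
                 notices = notices),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== pipeline result ==\n")
  print(x$nbs)
  if (!is.null(x$controllability$subnetwork_vh_vs_nonvh)) {
    s <- x$controllability$subnetwork_vh_vs_nonvh
    cat(sprintf("subnetwork controllability, VH < non-VH: U = %.1f, p = %.4g\n",
                s$statistic, s$p))
  }
  if (!is.null(x$modules)) print(x$modules)
  for (lst in names(x$ewce)) {
    cat(sprintf("-- enrichment for %s --\n", lst))
    print(x$ewce[[lst]])
  }
  for (n in x$notices) cat("notice:", n, "\n")
  invisible(x)
}
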