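test_that("QC drops bad regions and degenerate genes, imputes the rest", {
  set.seed(1)
  v <- matrix(rnorm(200), 10, 20)
  v[2, 1:15] <- NA                       # region > 50% missing
  v[, 3] <- 5                            # constant gene
  v[4, 7] <- NA                          # isolated missing value
  expr <- expression_matrix(v, trait = rep(c(0, 1), each = 5))
  qc <- qc_filter(expr)
  expect_identical(qc$report$regions_removed, "region_002")
  expect_identical(qc$report$genes_removed, "gene_00003")
  expect_false(anyNA(qc$expr$values))
  expect_identical(qc$report$n_imputed, 1L)
  # imputed by gene median
  expect_equal(qc$expr$values["region_004", "gene_00007"],
               median(v[-2, 7], na.rm = TRUE))
  expect_error(qc_filter(expression_matrix(matrix(NA_real_, 4, 3),
                                           trait = rep(0:1, 2))),
               "3 regions")
})

test_that("signed adjacency follows ((1 + r) / 2)^beta", {
  x <- rnorm(50)
  v <- cbind(g1 = x, g2 = x, g3 = -x)
  expr <- expression_matrix(v, trait = rep(0:1, 25))
  a <- coexpression_adjacency(expr, beta = 6)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0, tolerance = 1e-12)
  # r = 0 exactly: 0.5^6
  cm <- diag(2)
  expect_equal(coexpression_adjacency(NULL, beta = 6,
                                      cor_matrix = cm)[1, 2], 0.015625)
  expect_error(coexpression_adjacency(expr, beta = 0.5), "beta")
})

test_that("TOM matches the hand example and the brute-force oracle", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  tom3 <- tom_similarity(a3)
  expect_equal(tom3[1, 2], 0.5)
  # disconnected pair with no shared neighbours
  a0 <- diag(4)
  expect_equal(tom_similarity(a0)[1, 2], 0)
  for (s in 1:10) {
    set.seed(600 + s)
    a <- matrix(runif(64), 8, 8)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("eigengenes are unit variance, sign-oriented and order-invariant", {
  atl <- generate_expression_atlas(small_atlas(seed = 7, missing = 0))
  e <- atl$expr
  labels <- atl$truth$module_of
  eg <- module_eigengenes(e, labels)
  expect_equal(unname(apply(eg, 2, sd)), rep(1, 4), tolerance = 1e-12)
  for (m in 1:4) {
    block <- scale(e$values[, labels == m])
    expect_gte(cor(eg[, paste0("ME", m)], rowMeans(block)), 0)
  }
  # permuting gene order leaves eigengenes unchanged
  p <- sample(ncol(e$values))
  e2 <- expression_matrix(e$values[, p], e$trait)
  eg2 <- module_eigengenes(e2, labels[p])
  expect_equal(eg2, eg, tolerance = 1e-10)
  # flipping the sign of all module genes flips nothing after orientation
  v3 <- e$values
  v3[, labels == 1] <- -v3[, labels == 1]
  eg3 <- module_eigengenes(expression_matrix(v3, e$trait), labels)
  expect_equal(abs(cor(eg3[, "ME1"], eg[, "ME1"])), 1, tolerance = 1e-10)
  # module of identical columns: eigengene is the standardized column
  vv <- cbind(a = rnorm(30), b = 0)
  vv[, "b"] <- vv[, "a"]
  eg1 <- module_eigengenes(expression_matrix(vv, rep(0:1, 15)),
                           c(1, 1))
  expect_equal(abs(cor(eg1[, 1], vv[, 1])), 1, tolerance = 1e-12)
})

test_that("kME is the gene-eigengene correlation with sensible nulls", {
  atl <- generate_expression_atlas(small_atlas(seed = 8, missing = 0))
  e <- atl$expr
  labels <- atl$truth$module_of
  eg <- module_eigengenes(e, labels)
  kme <- module_membership(e, eg)
  expect_true(all(kme >= -1 & kme <= 1))
  # a gene equal to an eigengene has kME 1
  v2 <- cbind(e$values, exact = eg[, "ME1"])
  e2 <- expression_matrix(v2, e$trait)
  kme2 <- module_membership(e2, eg)
  expect_equal(kme2["exact", "ME1"], 1, tolerance = 1e-12)
  # own-module kME beats other-module kME for nearly all planted genes
  own_best <- vapply(which(labels > 0), function(g) {
    which.max(kme[g, ]) == labels[g]
  }, TRUE)
  expect_gte(mean(own_best), 0.95)
  # independent noise genes have small |kME|
  noise <- which(labels == 0)
  expect_lt(max(abs(kme[noise, ])), 0.5)
})

test_that("bicor handles exact, binary-degenerate and robust cases", {
  tr <- rep(c(0, 1), each = 20)
  expect_equal(bicor_binary(as.numeric(tr), tr), 1)
  expect_equal(bicor_binary(1 - tr, tr), -1)
  set.seed(2)
  x <- as.numeric(tr) + rnorm(40, 0, 0.5)
  # close to Pearson on clean data
  expect_equal(bicor_binary(x, tr), cor(x, tr), tolerance = 0.15)
  # an extreme outlier barely moves bicor but wrecks Pearson
  x_out <- x; x_out[1] <- 1000
  expect_lt(abs(bicor_binary(x_out, tr) - bicor_binary(x, tr)), 0.05)
  expect_gt(abs(cor(x_out, tr) - cor(x, tr)), 0.3)
  # zero-MAD numeric side falls back to plain centring
  expect_equal(bicor_binary(as.numeric(tr), tr), 1)
})

test_that("module-trait association recovers planted signs with BH-monotone q", {
  atl <- generate_expression_atlas(small_atlas(seed = 10, missing = 0))
  e <- atl$expr
  eg <- module_eigengenes(e, atl$truth$module_of)
  mt <- module_trait_correlation(eg, e$trait)
  expect_gt(mt$r[mt$module == "ME1"], 0)
  expect_lt(mt$r[mt$module == "ME2"], 0)
  expect_lt(max(mt$q[mt$module %in% c("ME1", "ME2")]), 0.05)
  expect_true(all(mt$q >= mt$p - 1e-15))
  ord <- order(mt$p)
  expect_true(all(diff(mt$q[ord]) >= -1e-15))
  expect_error(module_trait_correlation(eg, rep(1, nrow(eg))), "constant")
})

test_that("gene significance is |cor(gene, trait)|", {
  atl <- generate_expression_atlas(small_atlas(seed = 11, missing = 0))
  e <- atl$expr
  v <- cbind(e$values, exact = as.numeric(e$trait))
  e2 <- expression_matrix(v, e$trait)
  gs <- gene_significance(e2)
  expect_equal(unname(gs["exact"]), 1, tolerance = 1e-12)
  expect_true(all(gs >= 0 & gs <= 1))
  # within trait-linked modules, gene significance tracks |kME|
  labels <- atl$truth$module_of
  eg <- module_eigengenes(e, labels)
  kme <- module_membership(e, eg)
  g1 <- which(labels == 1)
  expect_gt(cor(gs[g1], abs(kme[g1, "ME1"])), 0)
})

test_that("module detection recovers the planted partition", {
  atl <- generate_expression_atlas(small_atlas(seed = 14, missing = 0))
  ms <- coexpression_analysis(atl$expr, beta = 6)
  truth <- atl$truth$module_of[names(ms$labels)]
  ari <- adjusted_rand_index(ms$labels, truth)
  expect_gte(ari, 0.8)
  # package ARI agrees with the independent mclust implementation
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(ms$labels, truth),
               tolerance = 1e-12)
})

test_that("pure-noise genes stay mostly unassigned", {
  cfg <- atlas_config(n_regions = 60, n_genes = 400,
                      module_sizes = integer(0),
                      modules_linked_to_trait = setNames(numeric(0),
                                                         character(0)),
                      missing_fraction = 0, seed = 15)
  atl <- generate_expression_atlas(cfg)
  tom <- tom_similarity(coexpression_adjacency(atl$expr, 6))
  labels <- detect_modules(atl$expr, tom)
  expect_gt(mean(labels == 0), 0.5)
})

test_that("soft power selection picks the smallest power reaching the target", {
  atl <- generate_expression_atlas(atlas_config(seed = 16,
                                                missing_fraction = 0))
  res <- suppressWarnings(pick_soft_power(atl$expr))
  expect_true(res$power %in% res$fit_table$power)
  # the contract: smallest candidate whose fit reaches the target
  target <- 0.5
  res2 <- pick_soft_power(atl$expr, r2_target = target)
  hit <- res2$fit_table$power[res2$fit_table$r2 >= target]
  expect_identical(res2$power, min(hit))
  # a single forced candidate is honoured
  res1 <- suppressWarnings(pick_soft_power(atl$expr,
                                           candidate_powers = 6,
                                           r2_target = 0.99))
  expect_identical(res1$power, 6)
  # independent noise: warning path
  cfg <- atlas_config(n_regions = 40, n_genes = 200,
                      module_sizes = integer(0),
                      modules_linked_to_trait = setNames(numeric(0),
                                                         character(0)),
                      missing_fraction = 0, seed = 17)
  noise <- generate_expression_atlas(cfg)
  expect_warning(pick_soft_power(noise$expr,
                                 candidate_powers = c(1, 2, 3),
                                 r2_target = 0.95), "scale-free")
})

test_that("ranked gene lists order significant-module genes by the chosen score", {
  atl <- generate_expression_atlas(small_atlas(seed = 18, missing = 0))
  ms <- coexpression_analysis(atl$expr, beta = 6)
  lists <- ranked_gene_lists(ms)
  expect_gte(length(lists), 1)
  g <- lists[[1]]
  gs <- ms$gene_significance[g]
  expect_true(all(diff(gs) <= 1e-15))
  lists_kme <- ranked_gene_lists(ms, rank_by = "kme")
  expect_setequal(lists_kme[[1]], g)
})
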