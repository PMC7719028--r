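test_that("config validation names the offending field", {
  expect_error(cohort_config(n_nodes = 0), "n_nodes")
  expect_error(cohort_config(effect_size = 1.2), "effect_size")
  expect_error(cohort_config(edge_weight_scale = -1), "edge_weight_scale")
  expect_error(cohort_config(planted_edges = cbind(3, 2)),
               "upper-triangle")
  expect_error(atlas_config(n_genes = 100, module_sizes = c(60, 60)),
               "module_sizes")
  expect_error(atlas_config(within_module_cor = 1), "within_module_cor")
  expect_error(generate_cell_reference(100, c("a", "b"),
                                       list(a = 1:5, b = 3:8)),
               "multiple cell types")
})

test_that("generated cohorts are symmetric, nonnegative and reproducible", {
  cfg <- cohort_config(n_controls = 3, n_nonvh = 3, n_vh = 3, seed = 5)
  coh <- generate_cohort(cfg)
  for (x in coh$connectomes) {
    expect_identical(x$weights, t(x$weights))
    expect_true(all(x$weights >= 0))
    expect_equal(unname(diag(x$weights)), rep(0, nrow(x$weights)))
  }
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$connectomes[[1]]$weights,
                   coh2$connectomes[[1]]$weights)
  cfg2 <- cohort_config(n_controls = 3, n_nonvh = 3, n_vh = 3, seed = 6)
  expect_false(identical(generate_cohort(cfg2)$connectomes[[1]]$weights,
                         coh$connectomes[[1]]$weights))
})

test_that("noise-free halving plants an exact factor-two reduction", {
  cfg <- cohort_config(n_controls = 2, n_nonvh = 2, n_vh = 2,
                       effect_size = 0.5, noise_sd = 0,
                       beta_age = 0, beta_tiv = 0, seed = 2)
  coh <- generate_cohort(cfg)
  groups <- vapply(coh$connectomes, `[[`, "", "group")
  pe <- coh$truth$planted_edges
  w_vh <- coh$connectomes[[which(groups == "pd_vh")[1]]]$weights
  w_ref <- coh$connectomes[[which(groups == "pd_nonvh")[1]]]$weights
  expect_equal(w_vh[pe], w_ref[pe] / 2, tolerance = 1e-12)
  # non-planted edges identical
  off <- cbind(cfg$n_nodes - 1, cfg$n_nodes)
  expect_equal(w_vh[off], w_ref[off], tolerance = 1e-12)
})

test_that("null effect leaves group means on planted edges equal within noise", {
  cfg <- cohort_config(n_controls = 20, n_nonvh = 20, n_vh = 20,
                       effect_size = 0, seed = 8)
  coh <- generate_cohort(cfg)
  groups <- vapply(coh$connectomes, `[[`, "", "group")
  pe <- coh$truth$planted_edges
  mean_planted <- vapply(coh$connectomes,
                         function(x) mean(log(x$weights[pe])), 0)
  p <- t.test(mean_planted[groups == "pd_vh"],
              mean_planted[groups != "pd_vh"])$p.value
  expect_gt(p, 0.01)
})

test_that("increasing effect size monotonically strengthens the planted signal", {
  mean_t <- function(effect) {
    ts <- vapply(1:20, function(r) {
      cfg <- cohort_config(n_controls = 2, n_nonvh = 10, n_vh = 10,
                           n_nodes = 10, n_planted_edges = 6,
                           effect_size = effect, seed = 900 + r)
      coh <- generate_cohort(cfg)
      stack <- assemble_cohort(coh$connectomes)
      stats <- edge_glm(stack)
      pe <- coh$truth$planted_edges
      mean(stats$t_stat[pe])
    }, 0)
    mean(ts)
  }
  ts <- vapply(c(0, 0.3, 0.6), mean_t, 0)
  expect_true(all(diff(-ts) > 0))   # VH coded 1: larger effect, more negative t
})

test_that("planted expression modules have the requested correlation structure", {
  # near-perfect module: first PC explains > 90% variance
  cfg <- atlas_config(n_regions = 100, n_genes = 60,
                      module_sizes = 50, within_module_cor = 0.99,
                      modules_linked_to_trait = c("1" = 0.5),
                      missing_fraction = 0, seed = 3)
  atl <- generate_expression_atlas(cfg)
  block <- atl$expr$values[, atl$truth$module_of == 1]
  pc <- prcomp(scale(block))
  expect_gt(pc$sdev[1]^2 / sum(pc$sdev^2), 0.9)

  # within-module correlation close to target
  cfg2 <- small_atlas(seed = 4, missing = 0)
  atl2 <- generate_expression_atlas(cfg2)
  b2 <- atl2$expr$values[, atl2$truth$module_of == 1]
  cm <- cor(b2)
  expect_equal(mean(cm[upper.tri(cm)]), 0.7, tolerance = 0.1)

  # trait-linked factors carry the requested sign
  tr <- atl2$expr$trait
  expect_gt(cor(atl2$truth$factors[, 1], tr), 0)
  expect_lt(cor(atl2$truth$factors[, 2], tr), 0)
})

test_that("null trait plant yields near-zero eigengene-trait correlations", {
  cfg <- small_atlas(seed = 9, linked = setNames(numeric(0), character(0)),
                     missing = 0)
  atl <- generate_expression_atlas(cfg)
  tr <- atl$expr$trait
  rs <- vapply(1:4, function(m) {
    eg <- vhconnect:::module_eigengene_one(
      atl$expr$values[, atl$truth$module_of == m])
    abs(cor(eg, tr))
  }, 0)
  # |r| below about twice the alpha = 0.05 critical value at n = 60
  expect_lt(mean(rs), 2 * 2 / sqrt(60))
})

test_that("forced bad regions exceed 50% missingness and only they do", {
  cfg <- small_atlas(seed = 12, missing = 0.01)
  cfg$force_bad_regions <- 7L
  atl <- generate_expression_atlas(cfg)
  frac <- rowMeans(is.na(atl$expr$values))
  expect_gt(frac[7], 0.5)
  expect_true(all(frac[-7] < 0.5))
})

test_that("cell reference plants markers and is seed-stable", {
  mm <- list(neuron = 1:10, astrocyte = 11:20)
  ref <- generate_cell_reference(50, c("neuron", "astrocyte", "microglia"),
                                 mm, seed = 4)
  me <- ref$reference$mean_expr
  expect_gt(mean(me[1:10, "neuron"]), 2 * mean(me[1:10, "astrocyte"]))
  ref2 <- generate_cell_reference(50, c("neuron", "astrocyte", "microglia"),
                                  mm, seed = 4)
  expect_identical(me, ref2$reference$mean_expr)
  # no markers: specificity near-uniform
  ref0 <- generate_cell_reference(2000, c("a", "b"), list(), seed = 1)
  s0 <- specificity(ref0$reference)$specificity
  expect_equal(mean(s0[, "a"]), 0.5, tolerance = 0.02)
})
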