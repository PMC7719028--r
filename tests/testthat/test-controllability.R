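test_that("stabilization scales by 1 + largest eigenvalue", {
  sys <- stabilize(matrix(c(0, 1, 1, 0), 2))
  expect_equal(sys$a, matrix(c(0, 0.5, 0.5, 0), 2,
                             dimnames = list(sys$node_labels,
                                             sys$node_labels)))
  expect_equal(sys$scale_factor, 2)
  expect_equal(stabilize(matrix(0, 3, 3))$a,
               matrix(0, 3, 3, dimnames = list(sprintf("node_%03d", 1:3),
                                               sprintf("node_%03d", 1:3))))
  # scaling weights leaves the eigenvector structure unchanged
  w <- random_weights(6, seed = 1)
  v1 <- eigen(stabilize(w)$a, symmetric = TRUE)$vectors[, 1]
  v2 <- eigen(stabilize(3 * w)$a, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(v1), abs(v2), tolerance = 1e-10)
  expect_error(stabilize(matrix(c(0, NA, NA, 0), 2)), "non-finite")
})

test_that("simulate_step computes A x + B u", {
  sys <- stabilize(matrix(c(0, 1, 1, 0), 2))
  zero_sys <- stabilize(matrix(0, 2, 2))
  expect_equal(simulate_step(zero_sys, c(0, 0), 1,
                             b = matrix(c(1, 0), 2, 1)), c(1, 0))
  expect_equal(simulate_step(sys, c(1, 0), c(0, 0)), c(0, 0.5))
  x <- c(0.3, -0.2)
  expect_equal(simulate_step(sys, x, c(0, 0)), as.vector(sys$a %*% x))
  expect_error(simulate_step(sys, c(1, 0, 0), c(0, 0)), "length")
  expect_error(simulate_step(sys, c(1, 0), c(1, 1, 1),
                             b = matrix(1, 2, 1)), "control matrix")
})

test_that("average controllability: closed forms and Lyapunov-oracle agreement", {
  # A = 0: Gramian is B B', trace 1
  zero_sys <- stabilize(matrix(0, 3, 3))
  expect_equal(average_controllability(zero_sys, 2), 1)
  # stabilized 2-node cycle: trace = sum_k V[1,k]^2 / (1 - 0.25) = 4/3
  sys2 <- stabilize(matrix(c(0, 1, 1, 0), 2))
  expect_equal(average_controllability(sys2, 1), 4 / 3, tolerance = 1e-12)
  # horizon-1 truncation is exactly the tau = 0 term
  expect_equal(average_controllability_bruteforce(sys2, 1, horizon = 1), 1)
  # truncated sum converges monotonically upward
  hs <- vapply(c(1, 2, 5, 20, 100),
               function(h) average_controllability_bruteforce(sys2, 1, h), 0)
  expect_true(all(diff(hs) >= 0))
  expect_equal(hs[5], 4 / 3, tolerance = 1e-10)

  set.seed(99)
  for (s in 1:20) {
    n <- sample(5:50, 1)
    sys <- random_stable_system(n, seed = 400 + s)
    node <- sample(n, 1)
    expect_lt(abs(average_controllability(sys, node) -
                    average_controllability_bruteforce(sys, node, 200)),
              1e-8)
  }
})

test_that("Gramian trace is at least 1 for every node of a stabilized system", {
  for (s in 1:10) {
    sys <- stabilize(random_weights(12, density = 0.6, seed = 500 + s))
    expect_true(all(average_controllability_all(sys) >= 1))
  }
  unstable <- structure(list(a = diag(2) * 1.5, scale_factor = 1,
                             node_labels = c("a", "b")),
                        class = "linear_system")
  expect_error(average_controllability_all(unstable), "stabilize")
})

test_that("ranks are dense, label-ordered, and hubs rank first", {
  expect_equal(unname(rank_nodes(c(a = 3, b = 1, c = 2))), c(1L, 3L, 2L))
  expect_equal(unname(rank_nodes(c(a = 2, b = 2, c = 2))), c(1L, 1L, 1L))
  expect_equal(unname(rank_nodes(c(a = 1, b = 5, c = 5, d = 2))),
               c(3L, 1L, 1L, 2L))
  # hub with maximal strength has the top controllability rank
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  prof <- controllability_profile(toy_connectome(star))
  expect_identical(unname(prof$ranks[1]), 1L)
})

test_that("subnetwork summaries reduce to means over labelled subsets", {
  prof <- controllability_profile(toy_connectome(random_weights(8, seed = 6)))
  expect_equal(subnetwork_summary(prof, names(prof$avg_ctrb)),
               mean(prof$avg_ctrb))
  expect_equal(subnetwork_summary(prof, "node_003"),
               unname(prof$avg_ctrb["node_003"]))
  expect_error(subnetwork_summary(prof, character(0)), "empty")
  expect_error(subnetwork_summary(prof, "node_999"), "unknown")
})

test_that("group comparisons use exact Mann-Whitney and Kruskal-Wallis", {
  res <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_identical(res$test, "mann_whitney")
  # fully separated groups: U = 0 under the wilcox.test convention,
  # exact two-sided p = 2/20 = 0.1
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  same <- compare_groups(list(a = c(1, 5, 3, 2), b = c(1, 5, 3, 2)))
  expect_gt(same$p, 0.9)
  kr <- compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6),
                            c = c(7, 8, 9)))
  expect_identical(kr$test, "kruskal_wallis")
  expect_equal(kr$statistic,
               unname(kruskal.test(list(c(1, 2, 3), c(4, 5, 6),
                                        c(7, 8, 9)))$statistic))
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "observations")
})

test_that("node strength and controllability are positively associated", {
  coh <- generate_cohort(cohort_config(n_controls = 5, n_nonvh = 2,
                                       n_vh = 2, seed = 17))
  rhos <- vapply(coh$connectomes[1:5], function(x) {
    s <- node_strength(x)
    a <- controllability_profile(x)$avg_ctrb
    cor(s, a, method = "spearman")
  }, 0)
  expect_true(all(rhos > 0))
})
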