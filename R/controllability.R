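# Linear network control on the stabilized connectome.  The dynamics are
# the discrete linear system x_{t+1} = A x_t + B u_t, with A the
# connectome weights scaled so its spectral radius is below 1 and B a
# selector of control nodes.  Average controllability of a node is the
# trace of the infinite-horizon controllability Gramian
# W_c = sum_{tau >= 0} A^tau B B' (A')^tau with B = e_node, i.e. the
# solution of the discrete Lyapunov equation W_c = A W_c A' + B B'.

#' Stabilize a connectome into a linear system
#'
#' Scales the weight matrix by 1 / (1 + lambda_max), lambda_max the
#' largest eigenvalue, guaranteeing spectral radius < 1 for nonnegative
#' symmetric weights.
#'
#' @param x a [connectome()] object or a symmetric nonnegative matrix.
#' @return An object of class `linear_system`: list with `a` (stabilized
#'   matrix), `scale_factor` (1 + lambda_max), `node_labels`.
#' @export
stabilize <- function(x) {
  w <- if (inherits(x, "connectome")) x$weights else x
  if (!all(is.finite(w))) stopf("non-finite weights")
  labels <- if (inherits(x, "connectome")) x$node_labels
            else rownames(w) %||% sprintf("node_%03d", seq_len(nrow(w)))
  lam_max <- if (all(w == 0)) 0 else max(eigen(w, symmetric = TRUE,
                                               only.values = TRUE)$values)
  a <- w / (1 + lam_max)
  dimnames(a) <- list(labels, labels)
  structure(list(a = a, scale_factor = 1 + lam_max,
                 node_labels = labels),
            class = "linear_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One step of the linear dynamics
#'
#' Returns `A x_t + B u_t` for the system's state and input vectors.
#'
#' @param system a [stabilize()]d linear system.
#' @param x_t state vector (length n).
#' @param u_t input vector applied to the control nodes.
#' @param b control matrix (n x m); defaults to the identity.
#' @return The next state vector.
#' @export
simulate_step <- function(system, x_t, u_t, b = diag(nrow(system$a))) {
  n <- nrow(system$a)
  if (length(x_t) != n) stopf("state length %d != system order %d",
                              length(x_t), n)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1)
  if (nrow(b) != n || ncol(b) != length(u_t))
    stopf("control matrix is %d x %d but input has length %d",
          nrow(b), ncol(b), length(u_t))
  as.vector(system$a %*% x_t + b %*% u_t)
}

check_stable <- function(system) {
  rho <- max(abs(eigen(system$a, symmetric = TRUE,
                       only.values = TRUE)$values))
  if (rho >= 1)
    stopf("spectral radius %.4f >= 1; stabilize the system first", rho)
  invisible(rho)
}

#' Average controllability of a single control node
#'
#' Trace of the infinite-horizon controllability Gramian for B = e_node,
#' obtained from the discrete Lyapunov equation.  For symmetric
#' A = V diag(lambda) V' the trace reduces to
#' sum_k V\[node, k\]^2 / (1 - lambda_k^2).
#'
#' @param system a [stabilize()]d linear system.
#' @param node node index or label.
#' @return A number >= 1 (the tau = 0 term contributes exactly 1).
#' @export
average_controllability <- function(system, node) {
  if (is.character(node)) node <- match(node, system$node_labels)
  if (is.na(node) || node < 1 || node > nrow(system$a))
    stopf("invalid node")
  unname(average_controllability_all(system)[node])
}

#' Average controllability of every node
#'
#' @param system a [stabilize()]d linear system.
#' @return Named numeric vector of per-node Gramian traces.
#' @export
average_controllability_all <- function(system) {
  check_stable(system)
  ev <- eigen(system$a, symmetric = TRUE)
  denom <- 1 - ev$values^2
  ac <- as.vector((ev$vectors^2) %*% (1 / denom))
  setNames(ac, system$node_labels)
}

#' Truncated-sum average controllability (oracle)
#'
#' Explicit finite-horizon Gramian trace
#' \eqn{\sum_{\tau=0}^{H-1} (A^\tau e_i)' (A^\tau e_i)}, kept as an
#' independent check on the Lyapunov route.
#'
#' @param system a [stabilize()]d linear system.
#' @param node node index.
#' @param horizon number of terms H (>= 1).
#' @return A number; converges monotonically upward to the
#'   infinite-horizon value as the horizon grows.
#' @export
average_controllability_bruteforce <- function(system, node,
                                               horizon = 200) {
  if (horizon < 1) stopf("horizon must be >= 1")
  v <- numeric(nrow(system$a))
  v[node] <- 1
  total <- 0
  for (tau in seq_len(horizon)) {
    total <- total + sum(v^2)
    v <- as.vector(system$a %*% v)
  }
  total
}

#' Per-subject controllability profile
#'
#' @param x a [connectome()] object.
#' @return An object of class `controllability_profile`: list with
#'   `subject_id`, `avg_ctrb` (named vector), `ranks` (dense, 1 = highest).
#' @export
controllability_profile <- function(x) {
  sys <- stabilize(x)
  ac <- average_controllability_all(sys)
  structure(list(subject_id = x$subject_id, avg_ctrb = ac,
                 ranks = rank_nodes(ac)),
            class = "controllability_profile")
}

#' Dense controllability ranks
#'
#' Rank 1 is the highest controllability; ties share a rank (dense
#' ranking), broken deterministically by node label order.
#'
#' @param avg_ctrb named numeric vector of controllability values.
#' @return Named integer vector of ranks.
#' @export
rank_nodes <- function(avg_ctrb) {
  ord <- order(-avg_ctrb, names(avg_ctrb))
  vals <- avg_ctrb[ord]
  dense <- cumsum(c(1L, diff(vals) != 0))
  setNames(dense[order(ord)], names(avg_ctrb))
}

#' Mean controllability over a node subset
#'
#' Summarizes one subject's profile inside a subnetwork (for example the
#' node set returned by [subnetwork_nodes()]).
#'
#' @param profile a [controllability_profile()].
#' @param node_subset node labels or indices; must be nonempty and within
#'   the node set.
#' @return The mean `avg_ctrb` over the subset.
#' @export
subnetwork_summary <- function(profile, node_subset) {
  if (length(node_subset) == 0) stopf("node subset is empty")
  vals <- profile$avg_ctrb[node_subset]
  if (anyNA(vals)) stopf("unknown node in subset")
  mean(vals)
}

#' Nonparametric group comparison
#'
#' Two-sided Mann-Whitney U for two groups (exact when sample sizes allow,
#' normal approximation otherwise), Kruskal-Wallis H for three or more.
#' The U statistic reported for two groups follows the `wilcox.test`
#' convention (rank sum of the first group minus its minimum).
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param test `"auto"` (by group count), `"mann_whitney"` or
#'   `"kruskal_wallis"`.
#' @param alternative passed to the two-group test.
#' @return List with `test`, `statistic`, `p`, `medians`.
#' @export
compare_groups <- function(values_by_group,
                           test = c("auto", "mann_whitney",
                                    "kruskal_wallis"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  k <- length(values_by_group)
  if (k < 2) stopf("need at least two groups")
  if (any(vapply(values_by_group, length, 0L) < 2))
    stopf("every group needs at least 2 observations")
  if (test == "auto") test <- if (k == 2) "mann_whitney"
                              else "kruskal_wallis"
  medians <- vapply(values_by_group, median, 0)
  if (test == "mann_whitney") {
    if (k != 2) stopf("mann_whitney requires exactly 2 groups")
    # normal approximation kicks in with ties; its warning is expected
    wt <- suppressWarnings(
      wilcox.test(values_by_group[[1]], values_by_group[[2]],
                  alternative = alternative, exact = NULL))
    list(test = "mann_whitney", statistic = unname(wt$statistic),
         p = wt$p.value, medians = medians)
  } else {
    kt <- kruskal.test(values_by_group)
    list(test = "kruskal_wallis", statistic = unname(kt$statistic),
         p = kt$p.value, medians = medians)
  }
}
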