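# Network-based statistics: an edge-wise general linear model with
# nuisance covariates, suprathreshold component extraction, and
# permutation-based family-wise error control over the maximum component
# size.  Permutation uses the Freedman-Lane scheme: residuals of the
# reduced (covariates-only) model are permuted, so nuisance effects are
# preserved under the null.

# Flatten the upper-triangle edges of a cohort stack into a subjects x
# edges matrix, dropping edges that are zero in every subject.
edge_matrix <- function(stack) {
  n <- length(stack$node_labels)
  pairs <- upper_pairs(n)
  subj <- which(stack$in_contrast)
  y <- t(apply(stack$weights[, , subj, drop = FALSE], 3,
               function(m) m[upper.tri(m)]))
  if (length(subj) == 1) y <- matrix(y, nrow = 1)
  # apply() fills upper.tri in column-major order; align pairs to it
  ord <- which(upper.tri(matrix(0, n, n)))
  idx <- arrayInd(ord, c(n, n))
  keep <- colSums(y != 0) > 0
  list(y = y[, keep, drop = FALSE],
       pairs = idx[keep, , drop = FALSE],
       n_nodes = n, dropped = sum(!keep))
}

# t-statistics for the group coefficient, one per column of y.
# Returns a list with t, df and a degenerate flag (zero residual variance).
glm_tstats <- function(x_design, y, coef_index = 2L) {
  n <- nrow(x_design); p <- ncol(x_design)
  xtx_inv <- chol2inv(chol(crossprod(x_design)))
  cmat <- xtx_inv %*% t(x_design)           # p x n
  b <- cmat %*% y                            # p x edges
  resid <- y - x_design %*% b
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * xtx_inv[coef_index, coef_index])
  tt <- b[coef_index, ] / se
  # a residual variance at rounding-noise level (e.g. identical weights
  # across subjects) makes t meaningless; flag and zero it
  scale2 <- colSums(y^2) / n
  degenerate <- sigma2 <= 1e-20 * (scale2 + 1e-300) | se == 0 |
    !is.finite(tt)
  tt[degenerate] <- 0
  list(t = tt, df = df, degenerate = degenerate)
}

#' Edge-wise general linear model
#'
#' Fits, for every upper-triangle edge present in at least one subject, an
#' ordinary least squares model of edge weight on (intercept, group, age,
#' tiv) and returns the t-statistic for the group coefficient.
#'
#' @param stack a [assemble_cohort()] stack.
#' @return An object of class `edge_stat_map`: list with `t_stat`
#'   (symmetric node x node matrix, NA on never-present edges), `pairs`,
#'   `t` (per tested edge), `df`, `degenerate`, `contrast`.
#' @export
edge_glm <- function(stack) {
  x <- stack$design
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  em <- edge_matrix(stack)
  ts <- glm_tstats(x, em$y)
  n <- em$n_nodes
  tm <- matrix(NA_real_, n, n,
               dimnames = list(stack$node_labels, stack$node_labels))
  tm[em$pairs] <- ts$t
  tm[em$pairs[, c(2, 1), drop = FALSE]] <- ts$t
  structure(list(t_stat = tm, pairs = em$pairs, t = ts$t, df = ts$df,
                 degenerate = ts$degenerate, contrast = stack$contrast,
                 node_labels = stack$node_labels),
            class = "edge_stat_map")
}

# Component sizes (edge counts) of a graph given by passing edge pairs.
# Union-find keyed on node index; cheap for the sparse suprathreshold sets
# the permutation loop produces.
component_edge_sizes <- function(pairs) {
  if (nrow(pairs) == 0) return(list(max = 0L, comp_of_edge = integer(0)))
  nodes <- sort(unique(as.vector(pairs)))
  parent <- seq_along(nodes)
  id <- match(as.vector(pairs), nodes)
  a <- id[seq_len(nrow(pairs))]
  b <- id[-seq_len(nrow(pairs))]
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(pairs))) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(a, find, 0L)
  sizes <- table(roots)
  list(max = as.integer(max(sizes)), comp_of_edge = match(roots,
                                                          names(sizes)))
}

#' Suprathreshold components of an edge-statistic map
#'
#' Binarizes edges whose signed t-statistic exceeds the threshold in the
#' stated direction and returns the connected components, sized by edge
#' count, sorted descending.
#'
#' @param stats an [edge_glm()] result.
#' @param threshold positive t threshold.
#' @param direction `"greater"` (t > threshold) or `"less"`
#'   (t < -threshold).
#' @return List of components, each with `edges` (2-column label matrix),
#'   `nodes`, `size_edges`.
#' @export
suprathreshold_components <- function(stats, threshold,
                                      direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (threshold <= 0) stopf("threshold must be positive")
  pass <- if (direction == "greater") stats$t > threshold
          else stats$t < -threshold
  pairs <- stats$pairs[pass, , drop = FALSE]
  cs <- component_edge_sizes(pairs)
  if (cs$max == 0L) return(list())
  comps <- lapply(seq_len(max(cs$comp_of_edge)), function(k) {
    ep <- pairs[cs$comp_of_edge == k, , drop = FALSE]
    labs <- stats$node_labels
    list(edges = cbind(labs[ep[, 1]], labs[ep[, 2]]),
         nodes = labs[sort(unique(as.vector(ep)))],
         size_edges = nrow(ep))
  })
  comps[order(vapply(comps, `[[`, 0L, "size_edges"), decreasing = TRUE)]
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Network-based statistic test
#'
#' Scores observed suprathreshold components against the permutation
#' distribution of the maximum component edge count.  Family-wise error
#' corrected p-values are `(1 + #\{perm max >= observed\}) / (1 + n_perm)`.
#'
#' @param stack a [assemble_cohort()] stack.
#' @param threshold t threshold (study setting 3.1).
#' @param direction `"greater"` or `"less"`; `"less"` tests for reduced
#'   connectivity in the group coded 1.
#' @param n_perm number of permutations (study setting 5000).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `subnetwork_result`: list with `components`
#'   (each with `edges`, `nodes`, `size_edges`, `fwe_p`), `threshold`,
#'   `direction`, `n_perm`, `seed`, `null_max_sizes`, `edge_stats`.
#' @export
nbs_test <- function(stack, threshold = 3.1,
                     direction = c("less", "greater"),
                     n_perm = 5000, seed = 1L) {
  direction <- match.arg(direction)
  if (n_perm < 100) stopf("n_perm must be at least 100")
  stats <- edge_glm(stack)
  comps <- suprathreshold_components(stats, threshold, direction)

  x <- stack$design
  z <- x[, -2, drop = FALSE]                # reduced model: nuisance only
  em <- edge_matrix(stack)
  hz <- z %*% chol2inv(chol(crossprod(z))) %*% t(z)
  fitted_z <- hz %*% em$y
  resid_z <- em$y - fitted_z
  n_sub <- nrow(em$y)

  perms <- NULL
  if (n_sub <= 7 && factorial(n_sub) < n_perm) {
    warnf("only %d distinct permutations achievable; enumerating exactly",
          factorial(n_sub))
    perms <- all_permutations(n_sub)
    n_perm <- nrow(perms)
  }
  set.seed(seed)
  null_max <- integer(n_perm)
  sign_keep <- if (direction == "greater") 1 else -1
  for (b in seq_len(n_perm)) {
    pi_b <- if (is.null(perms)) sample.int(n_sub) else perms[b, ]
    y_star <- fitted_z + resid_z[pi_b, , drop = FALSE]
    tt <- glm_tstats(x, y_star)$t
    pass <- sign_keep * tt > threshold
    null_max[b] <- component_edge_sizes(
      em$pairs[pass, , drop = FALSE])$max
  }
  for (k in seq_along(comps)) {
    comps[[k]]$fwe_p <-
      (1 + sum(null_max >= comps[[k]]$size_edges)) / (1 + n_perm)
  }
  structure(list(components = comps, threshold = threshold,
                 direction = direction, n_perm = n_perm, seed = seed,
                 null_max_sizes = null_max, edge_stats = stats),
            class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf("nbs: threshold t = %.2f (%s), %d permutations\n",
              x$threshold, x$direction, x$n_perm))
  if (length(x$components) == 0) {
    cat("no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      c_k <- x$components[[k]]
      cat(sprintf("  component %d: %d edges, %d nodes, FWE p = %.4g\n",
                  k, c_k$size_edges, length(c_k$nodes), c_k$fwe_p))
    }
  }
  invisible(x)
}

#' Nodes of the significant subnetwork
#'
#' Convenience accessor: labels of all nodes in components with FWE
#' p below `alpha` (the "VH subnetwork" when the contrast is
#' PD-non-VH vs PD-VH in the `"less"` direction).
#'
#' @param result an [nbs_test()] result.
#' @param alpha FWE significance level.
#' @return Character vector of node labels (empty when nothing passes).
#' @export
subnetwork_nodes <- function(result, alpha = 0.05) {
  sig <- Filter(function(c_k) c_k$fwe_p < alpha, result$components)
  sort(unique(unlist(lapply(sig, `[[`, "nodes"))))
}
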