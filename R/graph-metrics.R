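# Global and nodal topology of a weighted undirected connectome: density,
# node strength, the Onnela weighted clustering coefficient, and the
# characteristic path length under the reciprocal weight-to-length map.

#' Connection density
#'
#' Fraction of possible undirected edges with nonzero weight.
#'
#' @param x a [connectome()] object.
#' @return A number in \[0, 1\].
#' @export
connectome_density <- function(x) {
  w <- x$weights
  n <- nrow(w)
  if (n < 2) stopf("density undefined for n < 2 nodes")
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

#' Node strength
#'
#' Per-node sum of incident edge weights (the weighted degree).
#'
#' @param x a [connectome()] object.
#' @return Named numeric vector, one entry per node.
#' @export
node_strength <- function(x) {
  setNames(rowSums(x$weights), x$node_labels)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean-of-triangles clustering on weights normalized by the
#' maximum weight: with \eqn{\hat w = w / \max(w)},
#' \eqn{C_i = (\hat W^{1/3})^3_{ii} / (k_i (k_i - 1))} where \eqn{k_i} is
#' the binary degree.  Nodes with degree < 2 score 0.
#'
#' @param x a [connectome()] object.
#' @return List with `per_node` (named vector) and `mean`.
#' @export
clustering_coefficient <- function(x) {
  w <- x$weights
  mx <- max(w)
  if (mx == 0) {
    cc <- setNames(rep(0, nrow(w)), x$node_labels)
    return(list(per_node = cc, mean = 0))
  }
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)  # 2 x sum of triangle geometric means
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  cc <- setNames(cc, x$node_labels)
  list(per_node = cc, mean = mean(cc))
}

#' Characteristic path length
#'
#' Edge weights are mapped to lengths by the reciprocal (length = 1/weight;
#' zero weight = no edge); all-pairs shortest path lengths are averaged
#' over connected pairs of distinct nodes.  Disconnected pairs are
#' excluded from the mean and their fraction is reported.
#'
#' @param x a [connectome()] object.
#' @return List with `char_path_length`, `frac_disconnected`.
#' @export
characteristic_path_length <- function(x) {
  w <- x$weights
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  du <- d[upper.tri(d)]
  finite <- is.finite(du)
  if (!any(finite)) stopf("graph is fully disconnected")
  list(char_path_length = mean(du[finite]),
       frac_disconnected = mean(!finite))
}

#' Global topology summary for one subject
#'
#' @param x a [connectome()] object.
#' @return List with `density`, `mean_clustering`, `char_path_length`,
#'   `frac_disconnected`, `strength` and `mean_strength`.
#' @export
topology_summary <- function(x) {
  cc <- clustering_coefficient(x)
  cpl <- characteristic_path_length(x)
  s <- node_strength(x)
  list(density = connectome_density(x),
       mean_clustering = cc$mean,
       char_path_length = cpl$char_path_length,
       frac_disconnected = cpl$frac_disconnected,
       strength = s,
       mean_strength = mean(s))
}
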