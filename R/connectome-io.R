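#' Subject-level structural connectome
#'
#' A weighted, undirected structural connectivity matrix for one subject
#' (nodes are atlas parcels; the reference parcellation has 379 = 360
#' cortical + 19 subcortical regions) together with group membership and
#' the nuisance covariates used throughout the pipeline.
#'
#' @param weights square numeric matrix of nonnegative edge weights.
#'   Asymmetry up to 1e-8 (relative to the largest weight) is symmetrized
#'   by averaging; larger asymmetry is rejected.
#' @param subject_id character scalar.
#' @param group one of `"control"`, `"pd_nonvh"`, `"pd_vh"`.
#' @param age age in years.
#' @param tiv total intracranial volume in ml.
#' @param node_labels character vector of parcel names; defaults to the
#'   matrix dimnames or `"node_001"`-style labels.
#' @return An object of class `connectome`: a list with elements
#'   `weights`, `subject_id`, `group`, `age`, `tiv`, `node_labels`.
#' @export
connectome <- function(weights, subject_id, group, age, tiv,
                       node_labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stopf("weights must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n) stopf("weights must be square (got %d x %d)",
                                n, ncol(weights))
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-finite weight at [%d, %d]", bad[1, 1], bad[1, 2])
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stopf("negative weight at [%d, %d]", neg[1, 1], neg[1, 2])
  asym <- abs(weights - t(weights))
  tol <- 1e-8 * max(1, max(weights))
  if (max(asym) > tol) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stopf("matrix asymmetric beyond tolerance at [%d, %d]", w[1], w[2])
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels))
      node_labels <- sprintf("node_%03d", seq_len(n))
  }
  if (length(node_labels) != n)
    stopf("node_labels length (%d) != matrix order (%d)",
          length(node_labels), n)
  group <- match.arg(group, c("control", "pd_nonvh", "pd_vh"))
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(weights = weights, subject_id = as.character(subject_id),
                 group = group, age = as.numeric(age), tiv = as.numeric(tiv),
                 node_labels = node_labels),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %s (%s), %d nodes, density %.3f\n",
              x$subject_id, x$group, length(x$node_labels),
              connectome_density(x)))
  invisible(x)
}

#' Read a connectome adjacency matrix from TSV
#'
#' The TSV carries node labels in the header row and the first column.
#'
#' @param path TSV file path.
#' @param metadata_row a list or one-row data frame with `subject_id`,
#'   `group`, `age`, `tiv`.
#' @return A [connectome()] object.
#' @export
read_connectome <- function(path, metadata_row) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("%s: non-numeric entries", path)
  connectome(m, subject_id = metadata_row$subject_id,
             group = metadata_row$group, age = metadata_row$age,
             tiv = metadata_row$tiv, node_labels = rownames(m))
}

#' Write a connectome adjacency matrix to TSV
#'
#' @param x a [connectome()] object.
#' @param path output path.
#' @export
write_connectome <- function(x, path) {
  df <- as.data.frame(x$weights)
  write.table(cbind(node = x$node_labels, df), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble subject connectomes into a cohort stack
#'
#' Stacks subjects sharing a node order and builds the design matrix for
#' the edge-wise general linear model: intercept, a 0/1 indicator for the
#' active group contrast, and the nuisance covariates age and total
#' intracranial volume.
#'
#' @param connectomes list of [connectome()] objects with identical
#'   `node_labels`.
#' @param contrast character vector of length 2 `c(reference, test)`
#'   naming the groups coded 0 and 1; subjects in other groups are kept in
#'   the stack but excluded from the design (flagged in `in_contrast`).
#' @return An object of class `cohort_stack` with elements `weights`
#'   (3-d array node x node x subject), `meta` (data frame), `design`
#'   (numeric matrix for subjects in the contrast), `in_contrast`
#'   (logical), `node_labels`, `contrast`.
#' @export
assemble_cohort <- function(connectomes,
                            contrast = c("pd_nonvh", "pd_vh")) {
  if (length(connectomes) < 2) stopf("need at least two subjects")
  labels <- connectomes[[1]]$node_labels
  for (i in seq_along(connectomes)) {
    li <- connectomes[[i]]$node_labels
    if (!identical(li, labels)) {
      j <- which(li != labels)[1]
      stopf("subject %s node label mismatch at position %d ('%s' vs '%s')",
            connectomes[[i]]$subject_id, j, li[j], labels[j])
    }
  }
  n <- length(labels)
  w <- array(0, dim = c(n, n, length(connectomes)),
             dimnames = list(labels, labels, NULL))
  for (i in seq_along(connectomes)) w[, , i] <- connectomes[[i]]$weights
  meta <- data.frame(
    subject_id = vapply(connectomes, `[[`, "", "subject_id"),
    group = vapply(connectomes, `[[`, "", "group"),
    age = vapply(connectomes, `[[`, 0, "age"),
    tiv = vapply(connectomes, `[[`, 0, "tiv"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta$subject_id))
    stopf("duplicate subject_id: %s",
          meta$subject_id[duplicated(meta$subject_id)][1])
  in_contrast <- meta$group %in% contrast
  if (sum(meta$group == contrast[1]) < 2 ||
      sum(meta$group == contrast[2]) < 2)
    stopf("each contrast level needs at least 2 subjects")
  sub <- meta[in_contrast, ]
  design <- cbind(intercept = 1,
                  group = as.numeric(sub$group == contrast[2]),
                  age = sub$age, tiv = sub$tiv)
  structure(list(weights = w, meta = meta, design = design,
                 in_contrast = in_contrast, node_labels = labels,
                 contrast = contrast),
            class = "cohort_stack")
}

#' @export
print.cohort_stack <- function(x, ...) {
  cat(sprintf("cohort_stack: %d subjects (%s), %d nodes\n",
              nrow(x$meta),
              paste(sprintf("%s=%d", names(table(x$meta$group)),
                            table(x$meta$group)), collapse = ", "),
              length(x$node_labels)))
  invisible(x)
}
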