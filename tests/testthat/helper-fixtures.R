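# Fixture builders shared across the suite.  Everything is generated in
# code; nothing is read from disk.

toy_connectome <- function(w, group = "control", id = "sub_t",
                           age = 65, tiv = 1450) {
  connectome(w, subject_id = id, group = group, age = age, tiv = tiv)
}

# symmetric nonnegative random weights, zero diagonal
random_weights <- function(n, density = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  if (density < 1) w[matrix(runif(n * n) > density, n, n)] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# two-group stack with independent covariates and an optional shift added
# to one edge's weight in the second group
toy_stack <- function(n_per_group = 10, n_nodes = 6, shift_edge = NULL,
                      shift = 0, seed = 1) {
  set.seed(seed)
  groups <- rep(c("pd_nonvh", "pd_vh"), each = n_per_group)
  cons <- lapply(seq_along(groups), function(i) {
    w <- random_weights(n_nodes) + 0.5
    diag(w) <- 0
    if (!is.null(shift_edge) && groups[i] == "pd_vh") {
      w[shift_edge[1], shift_edge[2]] <- w[shift_edge[1], shift_edge[2]] + shift
      w[shift_edge[2], shift_edge[1]] <- w[shift_edge[1], shift_edge[2]]
    }
    connectome(w, sprintf("s%02d", i), groups[i],
               age = rnorm(1, 65, 8), tiv = rnorm(1, 1450, 100))
  })
  assemble_cohort(cons)
}

# random stable symmetric system with spectral radius capped at rho
random_stable_system <- function(n, seed, rho = 0.85) {
  w <- random_weights(n, seed = seed)
  lam <- max(abs(eigen(w, symmetric = TRUE, only.values = TRUE)$values))
  stabilize(w * rho / (lam * (1 - rho)))   # scaled so lam/(1+lam) = rho
}

# Independent brute-force topology oracles (triangle enumeration and
# Floyd-Warshall), deliberately naive.
oracle_clustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in nb) for (h in nb) {
      if (j != h) acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    cc[i] <- acc / (k * (k - 1))
  }
  cc
}

oracle_cpl <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  du <- d[upper.tri(d)]
  mean(du[is.finite(du)])
}

# Naive TOM by triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

small_atlas <- function(seed, n_regions = 60, n_genes = 500,
                        module_sizes = rep(100, 4),
                        within = 0.7,
                        linked = c("1" = 0.5, "2" = -0.5),
                        missing = 0) {
  atlas_config(n_regions = n_regions, n_genes = n_genes,
               module_sizes = module_sizes, within_module_cor = within,
               modules_linked_to_trait = linked,
               missing_fraction = missing, seed = seed)
}

# Map each recovered module label to the planted module it overlaps most
match_modules <- function(labels, truth) {
  mods <- setdiff(unique(labels), 0)
  out <- setNames(integer(length(mods)), mods)
  for (m in mods) {
    tab <- table(truth[labels == m])
    out[as.character(m)] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}
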