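#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test coef complete.cases ecdf hclust as.dist
#'   cutree dist kruskal.test lm mad median na.omit p.adjust pnorm prcomp pt
#'   quantile rbinom residuals rlnorm rnorm runif sd setNames shapiro.test
#'   t.test var wilcox.test aov
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

# Derive a per-stage seed from a global seed.  The rule is fixed so that
# toggling stages on and off never changes another stage's stream.  Offsets
# are small integers per stage; the result stays inside the 32-bit range.
split_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 101L + offset * 7919) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovered co-expression modules against planted ones.
#'
#' @param a,b integer or character label vectors of equal length.
#' @return A single number, 1 for identical partitions, about 0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Upper-triangle index pairs of an n x n matrix, as a 2-column matrix.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
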