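#' Within-cluster sum of squares
#'
#' The k-means objective: \eqn{\sum_c \sum_{y \in S_c} \|y - \mu_c\|^2},
#' evaluated block-wise so that at most `block` rows are in memory at a
#' time. The result is independent of the block size.
#'
#' @param m a [data_matrix][open_matrix] or plain matrix.
#' @param labels 1-based cluster labels of length `n_obs`.
#' @param centroids a [centroid_set()] (or k x G matrix).
#' @param block rows per step (default 10,000).
#' @return an object of class `wcss_report` with `per_cluster` (length k;
#'   a cluster with no members contributes 0) and `total` (their sum).
#' @examples
#' x <- matrix(c(0, 2), ncol = 1)
#' wcss(x, c(1, 1), centroid_set(matrix(1)))$total  # 1^2 + 1^2 = 2
#' @export
wcss <- function(m, labels, centroids, block = 10000L) {
  m <- as_data_matrix(m)
  if (!inherits(centroids, "centroid_set")) {
    centroids <- centroid_set(as.matrix(centroids))
  }
  block <- as_count(block, "block")
  n <- m$n_obs
  k <- nrow(centroids$values)
  if (length(labels) != n) {
    stop("labels must have length n_obs = ", n, call. = FALSE)
  }
  if (any(labels < 1L) || any(labels > k)) {
    stop("label outside [1, k]", call. = FALSE)
  }
  if (ncol(centroids$values) != m$n_feat) {
    stop("centroid feature dimension does not match matrix", call. = FALSE)
  }
  per_cluster <- numeric(k)
  mu <- centroids$values
  start <- 1L
  while (start <= n) {
    end <- min(start + block - 1L, n)
    x <- read_rows(m, start:end)
    lab <- labels[start:end]
    d2 <- pmax(rowSums((x - mu[lab, , drop = FALSE])^2), 0)
    sums <- rowsum(d2, group = lab)
    per_cluster[as.integer(rownames(sums))] <-
      per_cluster[as.integer(rownames(sums))] + sums[, 1L]
    start <- end + 1L
  }
  structure(list(per_cluster = per_cluster, total = sum(per_cluster)),
            class = "wcss_report")
}

#' @export
print.wcss_report <- function(x, ...) {
  cat(sprintf("<wcss_report> total %.6g over %d cluster(s)\n",
              x$total, length(x$per_cluster)))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' observations (Hubert-Arabie adjustment): 1 for identical partitions (up
#' to relabeling), about 0 for independent random partitions. Computed from
#' the label contingency table,
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}
#'                  {\tfrac12\left(\sum_i \binom{a_i}{2} +
#'                   \sum_j \binom{b_j}{2}\right) - E}, \quad
#'        E = \frac{\sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2}}
#'                 {\binom{n}{2}}.}
#' Pair counts are exact in double precision for n well beyond 10^6
#' (the largest count, \eqn{\binom{n}{2}}, stays below 2^53). When the
#' adjustment denominator vanishes — both partitions a single cluster, or
#' both all singletons — the partitions are identical and the index is 1.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type;
#'   length at least 2).
#' @return a scalar in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # relabeling: 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # crossed: -0.5
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  tab <- table(labels_a, labels_b)
  nij <- as.numeric(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  sum_ij <- sum(choose(nij, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
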