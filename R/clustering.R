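#' Centroid set
#'
#' A k x G matrix of cluster centroids together with the iteration counter of
#' the fit it belongs to.
#'
#' @param values numeric k x G matrix, all finite.
#' @param iteration non-negative integer.
#' @return an object of class `centroid_set`.
#' @export
centroid_set <- function(values, iteration = 0L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("centroid values must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("centroid values must be finite", call. = FALSE)
  }
  if (iteration < 0) stop("iteration must be >= 0", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, iteration = as.integer(iteration)),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("<centroid_set> k = %d, G = %d, iteration %d\n",
              nrow(x$values), ncol(x$values), x$iteration))
  invisible(x)
}

#' k-means++ initialization on a random subsample
#'
#' Draws a without-replacement subsample of `b_init` observations and runs
#' k-means++ within it: the first centroid is a uniformly chosen subsample
#' row; each subsequent centroid is a subsample row drawn with probability
#' proportional to its squared Euclidean distance to the nearest
#' already-chosen centroid (D-squared sampling). Initializing on a subsample
#' of the batch size keeps memory bounded while still giving a robust
#' starting point. Consumes the current RNG state; seed the session (or use
#' the `seed` argument of [fit_minibatch()]) for reproducibility.
#'
#' @param m a [data_matrix][open_matrix] (or plain matrix).
#' @param k number of centroids, `1 <= k < n_obs`.
#' @param b_init subsample size; defaults to `min(10000, n_obs)`.
#' @return a [centroid_set()] at iteration 0.
#' @export
kmeanspp_init <- function(m, k, b_init = NULL) {
  m <- as_data_matrix(m)
  n <- m$n_obs
  if (is.null(b_init)) b_init <- min(10000L, n)
  k <- as_count(k, "k")
  b_init <- as_count(b_init, "b_init")
  if (b_init > n) stop("b_init must be <= number of observations",
                       call. = FALSE)
  if (k > b_init) stop("k must be <= b_init", call. = FALSE)

  sub_idx <- sample.int(n, b_init)
  x <- read_rows(m, sub_idx)
  chosen <- integer(k)
  chosen[1L] <- sample.int(b_init, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[chosen[1L], ], "-")^2)
    for (j in 2L:k) {
      tot <- sum(d2)
      if (tot <= 0) {
        stop("fewer than k distinct points in the initialization subsample",
             call. = FALSE)
      }
      pick <- sample.int(b_init, 1L, prob = d2)
      chosen[j] <- pick
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[pick, ], "-")^2))
    }
  }
  centroid_set(x[chosen, , drop = FALSE], iteration = 0L)
}

#' Sample a mini-batch of observation indices
#'
#' Draws `b` distinct indices uniformly without replacement from `1..n`.
#' Consecutive calls are independent draws.
#'
#' @param n number of observations.
#' @param b batch size, `1 <= b <= n`.
#' @return integer vector of length `b`.
#' @export
sample_batch <- function(n, b) {
  n <- as_count(n, "n")
  b <- as_count(b, "b")
  if (b > n) stop("batch size b must be <= n", call. = FALSE)
  sample.int(n, b)
}

#' Assign a block of observations to their nearest centroids
#'
#' Computes squared Euclidean distances between each block row and each
#' centroid and assigns every row to the closest centroid; exact ties go to
#' the lowest centroid index. Distances use the expansion
#' \eqn{\|y - \mu\|^2 = \|y\|^2 + \|\mu\|^2 - 2 y^\top \mu} so the block is
#' processed with one matrix product, in double precision.
#'
#' @param block dense numeric block (rows x G).
#' @param centroids a [centroid_set()] with matching G.
#' @return list with `labels` (1-based centroid indices) and `dist2`
#'   (attained minimum squared distances, clamped at 0).
#' @export
assign_batch <- function(block, centroids) {
  stopifnot(inherits(centroids, "centroid_set"))
  if (!is.matrix(block)) block <- matrix(block, nrow = 1L)
  mu <- centroids$values
  if (ncol(block) != ncol(mu)) {
    stop("block has ", ncol(block), " features but centroids have ",
         ncol(mu), call. = FALSE)
  }
  d2 <- squared_distances(block, mu)
  labels <- max.col(-d2, ties.method = "first")
  dist2 <- pmax(d2[cbind(seq_len(nrow(block)), labels)], 0)
  list(labels = labels, dist2 = dist2)
}

squared_distances <- function(x, mu) {
  cross <- tcrossprod(x, mu)                       # n x k
  d2 <- -2 * cross
  d2 <- d2 + rowSums(x^2)                          # recycles down columns
  sweep(d2, 2L, rowSums(mu^2), "+")
}

#' Update centroids from an assigned mini-batch
#'
#' Each cluster that received at least one batch row gets the mean of those
#' rows as its new centroid; a cluster that received none keeps its previous
#' centroid. The iteration counter advances by one.
#'
#' @param block dense batch block.
#' @param labels 1-based assignments for the block rows.
#' @param prev the previous [centroid_set()].
#' @return the updated `centroid_set`.
#' @export
update_centroids <- function(block, labels, prev) {
  stopifnot(inherits(prev, "centroid_set"))
  if (!is.matrix(block)) block <- matrix(block, nrow = 1L)
  k <- nrow(prev$values)
  if (length(labels) != nrow(block)) {
    stop("labels length must match block rows", call. = FALSE)
  }
  if (any(labels < 1L) || any(labels > k)) {
    stop("label outside [1, k]", call. = FALSE)
  }
  new_vals <- prev$values
  sums <- rowsum(block, group = labels)
  counts <- tabulate(labels, nbins = k)
  present <- as.integer(rownames(sums))
  new_vals[present, ] <- sums / counts[present]
  centroid_set(new_vals, iteration = prev$iteration + 1L)
}

#' Frobenius norm of the centroid displacement
#'
#' The convergence quantity of the mini-batch iteration: the entry-wise L2
#' norm of the difference between consecutive centroid sets,
#' \eqn{\|\hat\mu^{(t)} - \hat\mu^{(t-1)}\|_2}.
#'
#' @param prev,cur two [centroid_set()]s of identical shape.
#' @return non-negative scalar.
#' @export
centroid_shift <- function(prev, cur) {
  stopifnot(inherits(prev, "centroid_set"), inherits(cur, "centroid_set"))
  if (!all(dim(prev$values) == dim(cur$values))) {
    stop("centroid sets differ in shape", call. = FALSE)
  }
  sqrt(sum((cur$values - prev$values)^2))
}

#' Fit mini-batch k-means
#'
#' Clusters the N observations of `m` into `k` groups by the mini-batch
#' k-means iteration: after k-means++ initialization on a subsample of
#' `b_init` rows, each iteration samples a fresh batch of `b` rows without
#' replacement, assigns them to the nearest centroid, and replaces each
#' receiving centroid by the mean of its assigned batch rows. Iteration
#' stops when the Frobenius norm of the centroid displacement drops to
#' `tol` or after `max_iter` iterations. The final centroids then label all
#' N observations block-wise ([predict_blockwise()]) and the within-cluster
#' sum of squares is evaluated on the full data.
#'
#' Only `max(b_init, b, prediction_block)` rows are ever read at a time, so
#' the same call runs on in-memory and HDF5-backed matrices with identical
#' results for the same seed: a single seeded generator drives the init
#' subsample, the k-means++ draws, and every batch draw in a fixed order.
#'
#' The minimization target is the global k-means objective (the WCSS over
#' all N observations); the batch-size default of `min(10000, N)` balances
#' accuracy against per-iteration cost, and batches of at least 500
#' observations lose no accuracy relative to full k-means on data of this
#' kind.
#'
#' @param m a [data_matrix][open_matrix], or a plain/sparse matrix which is
#'   wrapped automatically (observations in rows).
#' @param k number of clusters, `1 <= k < N`.
#' @param b batch size; default `min(10000, N)`.
#' @param b_init initialization subsample size; default `b`.
#' @param max_iter iteration cap (default 100).
#' @param tol convergence threshold on the centroid shift (default 1e-4).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param prediction_block rows per block in the final assignment pass;
#'   default `b`.
#' @param init_centroids optional [centroid_set()] (or k x G matrix) to use
#'   instead of k-means++ initialization.
#' @param restarts number of independent fits (seeds derived from `seed`);
#'   the fit with the lowest total WCSS is returned. Default 1.
#' @param keep_history if `TRUE`, store the centroid set after every
#'   iteration in `$history` (for diagnostics; memory grows with k*G per
#'   iteration).
#' @return an object of class `mbk_fit`: `labels` (length N, 1-based),
#'   `centroids` (final [centroid_set()]), `wcss_per_cluster`, `wcss_total`,
#'   `cluster_sizes`, `n_iter`, `converged`, `shift_trace`, `config`, and
#'   optionally `history`.
#' @examples
#' sim <- generate_mixture(mixture_spec(n_obs = 300, n_feat = 5, k_true = 3,
#'                                      centroid_spread = 5, seed = 1))
#' fit <- fit_minibatch(sim$matrix, k = 3, b = 100, seed = 1)
#' adjusted_rand_index(fit$labels, sim$labels)
#' @export
fit_minibatch <- function(m, k, b = NULL, b_init = NULL,
                          max_iter = 100L, tol = 1e-4, seed = NULL,
                          prediction_block = NULL, init_centroids = NULL,
                          restarts = 1L, keep_history = FALSE) {
  m <- as_data_matrix(m)
  n <- m$n_obs
  k <- as_count(k, "k")
  if (k >= n) stop("k must be < number of observations", call. = FALSE)
  if (is.null(b)) b <- min(10000L, n)
  b <- as_count(b, "b")
  if (b > n) stop("batch size b must be <= N", call. = FALSE)
  if (is.null(b_init)) b_init <- b
  b_init <- as_count(b_init, "b_init")
  if (b_init < k) stop("b_init must be >= k", call. = FALSE)
  max_iter <- as_count(max_iter, "max_iter")
  if (!is.numeric(tol) || length(tol) != 1L || tol < 0) {
    stop("tol must be a non-negative number", call. = FALSE)
  }
  if (is.null(prediction_block)) prediction_block <- b
  prediction_block <- as_count(prediction_block, "prediction_block")
  restarts <- as_count(restarts, "restarts")

  if (restarts > 1L) {
    seeds <- if (is.null(seed)) {
      sample.int(.Machine$integer.max, restarts)
    } else {
      as.integer(seed) + seq_len(restarts) - 1L
    }
    fits <- lapply(seeds, function(s) {
      fit_minibatch(m, k = k, b = b, b_init = b_init, max_iter = max_iter,
                    tol = tol, seed = s, prediction_block = prediction_block,
                    init_centroids = init_centroids, restarts = 1L,
                    keep_history = keep_history)
    })
    best <- which.min(vapply(fits, function(f) f$wcss_total, numeric(1)))
    out <- fits[[best]]
    out$config$restarts <- restarts
    return(out)
  }

  if (!is.null(seed)) set.seed(as.integer(seed))

  cent <- if (is.null(init_centroids)) {
    kmeanspp_init(m, k, b_init)
  } else {
    ic <- if (inherits(init_centroids, "centroid_set")) init_centroids
          else centroid_set(as.matrix(init_centroids))
    if (nrow(ic$values) != k || ncol(ic$values) != m$n_feat) {
      stop("init_centroids must be k x n_feat", call. = FALSE)
    }
    centroid_set(ic$values, iteration = 0L)
  }

  shift_trace <- numeric(0)
  history <- if (keep_history) list() else NULL
  converged <- FALSE
  n_iter <- 0L
  for (t in seq_len(max_iter)) {
    idx <- sample_batch(n, b)
    block <- read_rows(m, idx)
    a <- assign_batch(block, cent)
    nxt <- update_centroids(block, a$labels, cent)
    shift <- centroid_shift(cent, nxt)
    shift_trace <- c(shift_trace, shift)
    cent <- nxt
    n_iter <- t
    if (keep_history) history[[t]] <- cent
    if (shift <= tol) {
      converged <- TRUE
      break
    }
  }

  labels <- predict_blockwise(m, cent, prediction_block)
  w <- wcss(m, labels, cent, block = prediction_block)

  structure(
    list(
      labels = labels,
      centroids = cent,
      wcss_per_cluster = w$per_cluster,
      wcss_total = w$total,
      cluster_sizes = tabulate(labels, nbins = k),
      n_iter = n_iter,
      converged = converged,
      shift_trace = shift_trace,
      history = history,
      config = list(k = k, b = b, b_init = b_init, max_iter = max_iter,
                    tol = tol, seed = seed, prediction_block = prediction_block,
                    restarts = restarts, n_obs = n, n_feat = m$n_feat,
                    backend = m$backend)
    ),
    class = "mbk_fit"
  )
}

#' @export
print.mbk_fit <- function(x, ...) {
  cat(sprintf("Mini-batch k-means fit: k = %d on %d x %d [%s backend]\n",
              x$config$k, x$config$n_obs, x$config$n_feat, x$config$backend))
  cat(sprintf("  %d iteration(s), %s (final shift %.3g, tol %.3g)\n",
              x$n_iter,
              if (x$converged) "converged" else "iteration cap reached",
              tail(x$shift_trace, 1L), x$config$tol))
  cat(sprintf("  total WCSS: %.6g\n", x$wcss_total))
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Label all observations block-wise with fixed centroids
#'
#' Applies [assign_batch()] over consecutive row blocks so that at most
#' `block` rows are in memory at a time; the result is identical for every
#' block size, including a single whole-matrix pass.
#'
#' @param m a [data_matrix][open_matrix] or plain matrix.
#' @param centroids a [centroid_set()].
#' @param block rows per step (default 10,000).
#' @return integer vector of length `n_obs` with 1-based cluster labels.
#' @export
predict_blockwise <- function(m, centroids, block = 10000L) {
  m <- as_data_matrix(m)
  stopifnot(inherits(centroids, "centroid_set"))
  block <- as_count(block, "block")
  n <- m$n_obs
  labels <- integer(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + block - 1L, n)
    a <- assign_batch(read_rows(m, start:end), centroids)
    labels[start:end] <- a$labels
    start <- end + 1L
  }
  labels
}

as_data_matrix <- function(m) {
  if (inherits(m, "data_matrix")) return(m)
  open_matrix(m, format = "dense")
}
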