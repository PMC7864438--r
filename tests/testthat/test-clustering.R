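test_that("k-means++ handles the single-centroid and exhaustion cases", {
  x <- rand_matrix(8, 3, seed = 101)
  m <- open_matrix(x)
  set.seed(1)
  c1 <- kmeanspp_init(m, k = 1, b_init = 8)
  expect_equal(dim(c1$values), c(1L, 3L))
  expect_true(any(apply(x, 1, function(r) all(r == c1$values[1, ]))))
  expect_equal(c1$iteration, 0L)

  # k = N = b_init with distinct rows: the chosen centroids exhaust the rows
  set.seed(2)
  call <- kmeanspp_init(m, k = 8, b_init = 8)
  expect_equal(dim(call$values), c(8L, 3L))
  perm <- apply(call$values, 1, function(r) {
    which(apply(x, 1, function(s) all(s == r)))
  })
  expect_setequal(perm, 1:8)

  # fewer than k distinct points is degenerate
  dup <- matrix(1, 5, 2)
  set.seed(3)
  expect_error(kmeanspp_init(open_matrix(dup), k = 2, b_init = 5),
               "distinct")
})

test_that("batch sampling is without replacement with uniform inclusion", {
  set.seed(111)
  expect_setequal(sample_batch(10, 10), 1:10)
  expect_true(sample_batch(10, 1) %in% 1:10)
  expect_error(sample_batch(5, 6), "<= n")

  # inclusion frequency of each index must match b/n
  counts <- integer(10)
  for (i in 1:30000) {
    idx <- sample_batch(10, 3)
    counts[idx] <- counts[idx] + 1L
  }
  p <- stats::chisq.test(counts, p = rep(1 / 10, 10))$p.value
  expect_gt(p, 0.01)
})

test_that("assignment matches a brute-force scan and breaks ties downward", {
  set.seed(121)
  mu <- centroid_set(rand_matrix(4, 3))
  # a row equal to centroid 3 is assigned there with distance 0
  a <- assign_batch(mu$values[3, , drop = FALSE], mu)
  expect_equal(a$labels, 3L)
  expect_equal(a$dist2, 0, tolerance = 1e-12)

  # exact tie goes to the lowest centroid index
  tie <- assign_batch(matrix(0.5), centroid_set(matrix(c(0, 1), 2, 1)))
  expect_equal(tie$labels, 1L)
  expect_equal(tie$dist2, 0.25)

  blk <- rand_matrix(10, 3)
  got <- assign_batch(blk, mu)
  want <- oracle_assign(blk, mu$values)
  expect_equal(got$labels, want$labels)
  expect_equal(got$dist2, want$dist2, tolerance = 1e-9)

  expect_error(assign_batch(rand_matrix(2, 5), mu), "features")
})

test_that("centroid update averages per cluster and keeps empty clusters", {
  prev <- centroid_set(matrix(c(10, 10, -5, -5), 2, 2, byrow = TRUE))
  blk <- matrix(c(0, 0, 2, 0, 5, 5), 3, 2, byrow = TRUE)
  up <- update_centroids(blk, c(1L, 1L, 2L), prev)
  expect_equal(up$values, matrix(c(1, 0, 5, 5), 2, 2, byrow = TRUE))
  expect_equal(up$iteration, 1L)

  # all rows to cluster 1: cluster 2 retains its previous coordinates
  up2 <- update_centroids(blk, c(1L, 1L, 1L), prev)
  expect_equal(up2$values[1, ], colMeans(blk))
  expect_equal(up2$values[2, ], prev$values[2, ])

  expect_error(update_centroids(blk, c(1L, 3L, 1L), prev), "label")
})

test_that("centroid shift is the Frobenius norm of the displacement", {
  a <- centroid_set(matrix(0, 1, 2))
  expect_equal(centroid_shift(a, a), 0)
  expect_equal(centroid_shift(a, centroid_set(matrix(c(3, 4), 1, 2))), 5)

  set.seed(131)
  p <- centroid_set(rand_matrix(3, 4))
  q <- centroid_set(rand_matrix(3, 4))
  naive <- 0
  for (i in 1:3) for (j in 1:4) {
    naive <- naive + (q$values[i, j] - p$values[i, j])^2
  }
  expect_equal(centroid_shift(p, q), sqrt(naive), tolerance = 1e-12)
  expect_error(centroid_shift(p, centroid_set(rand_matrix(2, 4))), "shape")
})

test_that("full-batch fitting degenerates to Lloyd's algorithm", {
  set.seed(141)
  x <- rand_matrix(12, 2)
  init <- x[c(1, 7), ]
  fit <- fit_minibatch(x, k = 2, b = 12, b_init = 12, seed = 9, tol = 0,
                       max_iter = 25, init_centroids = init,
                       keep_history = TRUE)
  ora <- oracle_lloyd(x, init, max_iter = 25)
  for (t in seq_len(min(length(fit$history), length(ora$history)))) {
    expect_equal(fit$history[[t]]$values, ora$history[[t]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(fit$labels, ora$labels)
})

test_that("k = 1 with a full batch converges to the grand mean in one
           update", {
  x <- rand_matrix(30, 4, seed = 151)
  fit <- fit_minibatch(x, k = 1, b = 30, seed = 5)
  expect_equal(fit$centroids$values[1, ], colMeans(x), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(fit$labels == 1L))
  expect_true(fit$converged)
})

test_that("well-separated 1-D blobs are recovered exactly across seeds", {
  set.seed(161)
  truth <- rep(1:2, each = 200)
  x <- matrix(rnorm(400, mean = c(0, 100)[truth], sd = 1), ncol = 1)
  for (s in 1:20) {
    fit <- fit_minibatch(x, k = 2, b = 100, seed = s)
    expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  }
})

test_that("fits are deterministic given a seed and labels are nearest-
           centroid consistent", {
  x <- rand_matrix(150, 6, seed = 171)
  f1 <- fit_minibatch(x, k = 4, b = 40, seed = 77)
  f2 <- fit_minibatch(x, k = 4, b = 40, seed = 77)
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$centroids$values, f2$centroids$values, tolerance = 1e-10)
  expect_identical(f1$shift_trace, f2$shift_trace)

  # label validity: brute-force re-assignment reproduces the labels
  expect_equal(oracle_assign(x, f1$centroids$values)$labels, f1$labels)
  # bookkeeping invariants
  expect_equal(sum(f1$cluster_sizes), 150L)
  expect_equal(f1$wcss_total, sum(f1$wcss_per_cluster))
  expect_equal(f1$converged,
               tail(f1$shift_trace, 1) <= f1$config$tol)
})

test_that("full-batch WCSS is non-increasing across iterations", {
  x <- rand_matrix(80, 3, seed = 181)
  set.seed(4)
  init <- kmeanspp_init(open_matrix(x), 3, b_init = 80)
  fit <- fit_minibatch(x, k = 3, b = 80, init_centroids = init, seed = 10,
                       tol = 0, max_iter = 20, keep_history = TRUE)
  wtrace <- vapply(fit$history, function(cs) {
    lab <- oracle_assign(x, cs$values)$labels
    oracle_wcss(x, lab, cs$values)$total
  }, numeric(1))
  expect_true(all(diff(wtrace) <= 1e-9))
})

test_that("restarts keep the lowest-WCSS fit", {
  x <- rand_matrix(100, 4, seed = 191)
  multi <- fit_minibatch(x, k = 3, b = 50, seed = 42, restarts = 3)
  singles <- vapply(42:44, function(s) {
    fit_minibatch(x, k = 3, b = 50, seed = s)$wcss_total
  }, numeric(1))
  expect_equal(multi$wcss_total, min(singles), tolerance = 1e-12)
})

test_that("block-wise prediction is invariant to the block size", {
  x <- rand_matrix(37, 5, seed = 201)
  mu <- centroid_set(x[c(3, 20, 31), ])
  full <- assign_batch(x, mu)$labels
  for (blk in c(1, 7, 37, 100)) {
    expect_equal(predict_blockwise(x, mu, block = blk), full)
  }
  # rows equal to the centroid rows map to the identity labelling
  expect_equal(predict_blockwise(mu$values, mu, block = 2), 1:3)
})

test_that("fit configuration is validated", {
  x <- rand_matrix(20, 2, seed = 211)
  expect_error(fit_minibatch(x, k = 20), "k must be <")
  expect_error(fit_minibatch(x, k = 0), "positive")
  expect_error(fit_minibatch(x, k = 2, b = 21), "<= N")
  expect_error(fit_minibatch(x, k = 5, b = 10, b_init = 3), ">= k")
  expect_error(fit_minibatch(x, k = 2, tol = -1), "non-negative")
})
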