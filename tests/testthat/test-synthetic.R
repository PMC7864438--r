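test_that("mixture spec validates its fields", {
  expect_error(mixture_spec(2, 10, 3), ">= k_true")
  expect_error(mixture_spec(10, 10, 3, proportions = c(0.5, 0.5)),
               "proportions")
  expect_error(mixture_spec(10, 10, 2, proportions = c(0.7, 0.4)),
               "proportions")
  expect_error(mixture_spec(10, 10, 2, noise_sd = -1), "noise_sd")
  s <- mixture_spec(10, 5, 2, seed = 3)
  expect_equal(s$proportions, c(0.5, 0.5))
})

test_that("generated data have the contracted shape and are seed-
           deterministic", {
  spec <- mixture_spec(200, 7, 4, seed = 31)
  sim1 <- generate_mixture(spec)
  sim2 <- generate_mixture(spec)
  expect_identical(sim1$matrix, sim2$matrix)
  expect_identical(sim1$labels, sim2$labels)
  expect_equal(dim(sim1$matrix), c(200L, 7L))
  expect_equal(dim(sim1$centroids), c(4L, 7L))
  expect_true(all(sim1$labels %in% 1:4))
})

test_that("zero noise collapses every observation onto its component mean
           and clustering recovers the partition exactly", {
  sim <- generate_mixture(mixture_spec(120, 6, 3, noise_sd = 0, seed = 41))
  expect_equal(sim$matrix, sim$centroids[sim$labels, ], ignore_attr = TRUE)
  fit <- fit_minibatch(sim$matrix, k = 3, b = 120, seed = 1)
  expect_equal(adjusted_rand_index(fit$labels, sim$labels), 1)
})

test_that("component counts follow the multinomial sampling distribution", {
  sim <- generate_mixture(mixture_spec(10000, 2, 4, seed = 51))
  counts <- tabulate(sim$labels, nbins = 4)
  # 99.9% acceptance region via the chi-square statistic
  p <- stats::chisq.test(counts, p = rep(0.25, 4))$p.value
  expect_gt(p, 0.001)

  skew <- generate_mixture(mixture_spec(10000, 2, 3,
                                        proportions = c(0.7, 0.2, 0.1),
                                        seed = 52))
  p2 <- stats::chisq.test(tabulate(skew$labels, nbins = 3),
                          p = c(0.7, 0.2, 0.1))$p.value
  expect_gt(p2, 0.001)
})

test_that("separation-controlled mixtures are recovered by full k-means", {
  # spread/noise ratio 10: the acceptance simulations rely on this regime
  # being unambiguous for Lloyd's algorithm at the true k
  sim <- generate_mixture(mixture_spec(5000, 20, 3, centroid_spread = 10,
                                       noise_sd = 1, seed = 61))
  km <- stats::kmeans(sim$matrix, centers = sim$centroids,
                      algorithm = "Lloyd", iter.max = 50)
  expect_gte(adjusted_rand_index(km$cluster, sim$labels), 0.99)
})

test_that("fixtures round-trip through hdf5 exactly and csv to formatting
           precision", {
  sim <- generate_mixture(mixture_spec(100, 20, 3, seed = 71))

  h5 <- tempfile(fileext = ".h5")
  files <- write_fixture(sim, h5, format = "hdf5", geometry = "by_cell")
  m <- open_matrix(h5, format = "hdf5")
  expect_identical(read_rows(m, 1:100), sim$matrix)
  expect_equal(as.integer(readLines(files[["labels"]])), sim$labels)
  # by_cell on a matrix smaller than the area bound: one full-feature slab
  expect_equal(hdf5_chunk_dims(h5), c(100L, 20L))

  csv <- tempfile(fileext = ".csv")
  write_fixture(sim$matrix, csv, format = "csv")
  mc <- open_matrix(csv, format = "csv")
  expect_equal(read_rows(mc, 1:100), sim$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(write_fixture(matrix(c(1, NA), 1, 2), tempfile()), "finite")
})

test_that("explicit chunk slabs show up in the fixture metadata", {
  sim <- generate_mixture(mixture_spec(200, 50, 3, seed = 81))
  h5 <- tempfile(fileext = ".h5")
  write_fixture(sim$matrix, h5, format = "hdf5",
                geometry = chunk_geometry(64, 50))
  expect_equal(hdf5_chunk_dims(h5), c(64L, 50L))
})
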