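#' Specification of a Gaussian-mixture expression simulation
#'
#' Parameters for [generate_mixture()]: N observations in G dimensions drawn
#' from a mixture of `k_true` isotropic Gaussian components. Component means
#' are i.i.d. N(0, `centroid_spread`^2) per coordinate, so the typical
#' between-mean distance grows like `sqrt(2 * G) * centroid_spread`; with
#' the defaults (`centroid_spread = 1`, `noise_sd = 1`) components are well
#' separated once G is in the hundreds, which is the regime of simulated
#' expression data with G = 1000 genes.
#'
#' @param n_obs number of observations N (at least `k_true`).
#' @param n_feat number of features G.
#' @param k_true number of mixture components.
#' @param proportions mixing weights, length `k_true`, non-negative, summing
#'   to 1 (within 1e-12); default uniform.
#' @param centroid_spread standard deviation of the component-mean
#'   coordinates (controls separation); default 1.
#' @param noise_sd within-component standard deviation (isotropic);
#'   default 1. May be 0 for noiseless data.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_obs, n_feat, k_true,
                         proportions = NULL,
                         centroid_spread = 1, noise_sd = 1,
                         seed = NULL) {
  n_obs <- as_count(n_obs, "n_obs")
  n_feat <- as_count(n_feat, "n_feat")
  k_true <- as_count(k_true, "k_true")
  if (n_obs < k_true) stop("n_obs must be >= k_true", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / k_true, k_true)
  if (length(proportions) != k_true || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-12) {
    stop("proportions must be k_true non-negative weights summing to 1",
         call. = FALSE)
  }
  if (!is.numeric(centroid_spread) || centroid_spread < 0) {
    stop("centroid_spread must be >= 0", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  structure(
    list(n_obs = n_obs, n_feat = n_feat, k_true = k_true,
         proportions = proportions, centroid_spread = centroid_spread,
         noise_sd = noise_sd, seed = if (is.null(seed)) NULL
                                     else as.integer(seed)),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf(
    "<mixture_spec> N = %d, G = %d, k_true = %d, spread = %g, noise = %g\n",
    x$n_obs, x$n_feat, x$k_true, x$centroid_spread, x$noise_sd))
  invisible(x)
}

#' Simulate an expression matrix from a Gaussian mixture
#'
#' Draws component means once, assigns every observation to a component
#' according to the mixing proportions, and adds isotropic Gaussian noise.
#' Fully seed-deterministic: the RNG consumption order is fixed (means,
#' then memberships, then noise). Values are real-valued and may be
#' negative; no count-distribution emulation is attempted.
#'
#' @param spec a [mixture_spec()].
#' @return a list of class `mixture_data`: `matrix` (N x G), `labels`
#'   (length N, values in `1..k_true`), `centroids` (k_true x G true
#'   component means), and the `spec`.
#' @examples
#' sim <- generate_mixture(mixture_spec(100, 10, 3, noise_sd = 0, seed = 1))
#' all(sim$matrix == sim$centroids[sim$labels, ])
#' @export
generate_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  k <- spec$k_true
  g <- spec$n_feat
  n <- spec$n_obs
  centroids <- matrix(rnorm(k * g, sd = spec$centroid_spread), nrow = k)
  labels <- sample.int(k, n, replace = TRUE, prob = spec$proportions)
  x <- centroids[labels, , drop = FALSE]
  if (spec$noise_sd > 0) {
    x <- x + matrix(rnorm(n * g, sd = spec$noise_sd), nrow = n)
  }
  structure(list(matrix = x, labels = labels, centroids = centroids,
                 spec = spec),
            class = "mixture_data")
}

#' @export
print.mixture_data <- function(x, ...) {
  cat(sprintf("<mixture_data> %d x %d from %d component(s)\n",
              nrow(x$matrix), ncol(x$matrix), x$spec$k_true))
  invisible(x)
}

#' Write a simulated matrix (plus labels) as an on-disk fixture
#'
#' Writes the matrix as either a chunked HDF5 dataset or a CSV file,
#' together with a single-column text sidecar holding the true labels.
#' Reopening the file via [open_matrix()] reproduces the matrix (exactly
#' for HDF5; to formatting precision for CSV).
#'
#' @param x numeric matrix (observations x features), or a `mixture_data`
#'   object from [generate_mixture()].
#' @param path output file path.
#' @param labels integer labels of length `nrow(x)`; taken from `x` when
#'   `x` is a `mixture_data`. `NULL` skips the sidecar.
#' @param format `"hdf5"` or `"csv"`.
#' @param geometry chunk geometry or preset for HDF5 output (see
#'   [rechunk_hdf5()]); default `"by_cell"`.
#' @param dataset HDF5 dataset name (default `"counts"`).
#' @param labels_path sidecar path; default `paste0(path, ".labels.txt")`.
#' @param level gzip level for HDF5 (default 0).
#' @return named character vector of the files written, invisibly.
#' @export
write_fixture <- function(x, path, labels = NULL,
                          format = c("hdf5", "csv"),
                          geometry = "by_cell", dataset = "counts",
                          labels_path = paste0(path, ".labels.txt"),
                          level = 0) {
  format <- match.arg(format)
  if (inherits(x, "mixture_data")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$matrix
  }
  if (!is.matrix(x) || !all(is.finite(x))) {
    stop("fixture matrix must be a finite numeric matrix", call. = FALSE)
  }
  if (format == "hdf5") {
    geom <- resolve_geometry(geometry, nrow(x), ncol(x))
    if (file.exists(path)) {
      stop("output file already exists: ", path, call. = FALSE)
    }
    rhdf5::h5createFile(path)
    rhdf5::h5createDataset(path, dataset, dims = dim(x),
                           chunk = c(geom$chunk_rows, geom$chunk_cols),
                           storage.mode = storage.mode(x), level = level)
    rhdf5::h5write(x, path, dataset)
    rhdf5::h5closeAll()
  } else {
    data.table::fwrite(as.data.frame(x), path, col.names = TRUE)
  }
  files <- c(data = path)
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) {
      stop("labels length must match matrix rows", call. = FALSE)
    }
    writeLines(as.character(labels), labels_path)
    files <- c(files, labels = labels_path)
  }
  invisible(files)
}
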