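#' Open a matrix source as a backend-neutral data matrix
#'
#' Wraps an in-memory array, a delimited text file, a MatrixMarket file, or a
#' dense 2-D HDF5 dataset in a uniform handle whose logical shape is always
#' observations x features. Single-cell files commonly store the transpose
#' (features in rows); declare that with `orientation = "feat_rows"` and the
#' handle presents the transposed logical view without rewriting the file.
#' HDF5 sources are not read at open time: only the rows requested later via
#' [read_rows()] are decoded, which is what makes out-of-core fitting
#' possible.
#'
#' @param source an in-memory matrix (dense or a \pkg{Matrix} sparse matrix),
#'   or a path to a file for the file-based formats.
#' @param format one of `"dense"`, `"csv"`, `"tsv"`, `"mtx"`, `"hdf5"`. For
#'   in-memory input the default `"dense"` keeps a dense or sparse backend
#'   according to the class of `source`; for paths the format is inferred
#'   from the file extension when not given.
#' @param dataset name of the 2-D dataset inside an HDF5 file
#'   (default `"counts"`).
#' @param orientation `"obs_rows"` if the stored rows are observations,
#'   `"feat_rows"` if the stored rows are features.
#' @param header,row_names for csv/tsv: does the file carry a header line,
#'   and is the first column a row-name column? Both default to
#'   auto-detection by \code{data.table::fread} for the header and `FALSE`
#'   for row names.
#' @return an object of class `data_matrix` with elements `n_obs`, `n_feat`,
#'   `backend` (`"dense"`, `"sparse"` or `"hdf5"`), `orientation` and
#'   `source`.
#' @examples
#' m <- open_matrix(matrix(1:6, nrow = 3))
#' dim(m)
#' read_rows(m, c(3, 1))
#' @export
open_matrix <- function(source,
                        format = NULL,
                        dataset = "counts",
                        orientation = c("obs_rows", "feat_rows"),
                        header = "auto",
                        row_names = FALSE) {
  orientation <- match.arg(orientation)
  if (is.null(format)) {
    format <- if (is.character(source) && length(source) == 1L) {
      guess_format(source)
    } else {
      "dense"
    }
  }
  format <- match.arg(format, c("dense", "csv", "tsv", "mtx", "hdf5"))

  if (format == "dense" && is.character(source)) {
    stop("format 'dense' expects an in-memory matrix, not a path",
         call. = FALSE)
  }
  if (format != "dense") {
    if (!is.character(source) || length(source) != 1L) {
      stop("format '", format, "' expects a single file path", call. = FALSE)
    }
    if (!file.exists(source)) {
      stop("input file not found: ", source, call. = FALSE)
    }
  }

  switch(format,
    dense = open_in_memory(source, orientation),
    csv   = open_delim(source, sep = ",", orientation, header, row_names),
    tsv   = open_delim(source, sep = "\t", orientation, header, row_names),
    mtx   = open_in_memory(methods::as(Matrix::readMM(source), "CsparseMatrix"),
                           orientation, source_path = source),
    hdf5  = open_hdf5(source, dataset, orientation)
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "csv" = "csv",
    "tsv" = "tsv", "tab" = "tsv", "txt" = "tsv",
    "mtx" = "mtx",
    "h5" = "hdf5", "hdf5" = "hdf5", "he5" = "hdf5",
    stop("cannot infer format from extension '", ext,
         "'; pass `format` explicitly", call. = FALSE)
  )
}

open_in_memory <- function(x, orientation, source_path = NULL) {
  sparse <- methods::is(x, "sparseMatrix")
  if (!sparse) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x) || !is.numeric(x)) {
      stop("in-memory input must be a numeric matrix or a sparse Matrix",
           call. = FALSE)
    }
  }
  if (length(dim(x)) != 2L) stop("input must be 2-D", call. = FALSE)
  if (orientation == "feat_rows") x <- Matrix::t(x)
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("matrix must have at least one row and one column", call. = FALSE)
  }
  new_data_matrix(
    backend = if (sparse) "sparse" else "dense",
    n_obs = nrow(x), n_feat = ncol(x),
    orientation = orientation,
    data = x,
    source = source_path
  )
}

open_delim <- function(path, sep, orientation, header, row_names) {
  dt <- data.table::fread(path, sep = sep, header = header,
                          data.table = FALSE, showProgress = FALSE)
  if (isTRUE(row_names)) {
    rn <- dt[[1L]]
    dt <- dt[, -1L, drop = FALSE]
    x <- as.matrix(dt)
    rownames(x) <- as.character(rn)
  } else {
    x <- as.matrix(dt)
  }
  if (!is.numeric(x)) {
    stop("delimited file does not parse to a numeric matrix", call. = FALSE)
  }
  open_in_memory(x, orientation, source_path = path)
}

open_hdf5 <- function(path, dataset, orientation) {
  dims <- hdf5_dataset_dims(path, dataset)
  if (length(dims) != 2L) {
    stop("HDF5 dataset '", dataset, "' is not 2-D (rank ", length(dims), ")",
         call. = FALSE)
  }
  if (orientation == "obs_rows") {
    n_obs <- dims[1L]; n_feat <- dims[2L]
  } else {
    n_obs <- dims[2L]; n_feat <- dims[1L]
  }
  stats_env <- new.env(parent = emptyenv())
  stats_env$reads <- numeric(0)
  new_data_matrix(
    backend = "hdf5",
    n_obs = n_obs, n_feat = n_feat,
    orientation = orientation,
    data = NULL,
    source = list(path = path, dataset = dataset),
    stats = stats_env
  )
}

new_data_matrix <- function(backend, n_obs, n_feat, orientation,
                            data = NULL, source = NULL, stats = NULL) {
  structure(
    list(backend = backend, n_obs = as.integer(n_obs),
         n_feat = as.integer(n_feat), orientation = orientation,
         data = data, source = source, stats = stats),
    class = "data_matrix"
  )
}

#' @export
dim.data_matrix <- function(x) c(x$n_obs, x$n_feat)

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d obs x %d features [%s backend]\n",
              x$n_obs, x$n_feat, x$backend))
  if (x$backend == "hdf5") {
    cat(sprintf("  source: %s :%s (stored %s)\n", x$source$path,
                x$source$dataset, x$orientation))
  }
  invisible(x)
}

#' Read a subset of observations as a dense block
#'
#' Returns the requested rows of the logical (observations x features)
#' matrix, in the requested order, as a base dense matrix in double
#' precision. For HDF5 backends only the requested rows (plus the storage
#' chunks covering them) are decoded; indices are sorted internally for
#' contiguous access and the block is returned in the original request
#' order. Every returned block is checked for non-finite values.
#'
#' @param m a [data_matrix][open_matrix] handle.
#' @param indices integer vector of row ids in `1..n_obs`; duplicates are an
#'   error (mini-batches are sampled without replacement, so a duplicate
#'   indicates a caller bug).
#' @return a dense `length(indices)` x `n_feat` numeric matrix.
#' @export
read_rows <- function(m, indices) {
  stopifnot(inherits(m, "data_matrix"))
  indices <- validate_indices(indices, m$n_obs)
  block <- switch(m$backend,
    dense  = m$data[indices, , drop = FALSE],
    sparse = as.matrix(m$data[indices, , drop = FALSE]),
    hdf5   = read_rows_hdf5(m, indices)
  )
  if (!is.double(block)) storage.mode(block) <- "double"
  if (anyNA(block) || !all(is.finite(block))) {
    stop("non-finite values in matrix block", call. = FALSE)
  }
  block
}

validate_indices <- function(indices, n_obs) {
  if (length(indices) == 0L) stop("empty index set", call. = FALSE)
  if (!is.numeric(indices) || any(indices != floor(indices))) {
    stop("row indices must be integers", call. = FALSE)
  }
  indices <- as.integer(indices)
  if (any(indices < 1L) || any(indices > n_obs)) {
    stop("row index out of range [1, ", n_obs, "]", call. = FALSE)
  }
  if (anyDuplicated(indices)) {
    stop("duplicate row indices are not allowed", call. = FALSE)
  }
  indices
}

read_rows_hdf5 <- function(m, indices) {
  ord <- order(indices)
  sorted <- indices[ord]
  idx <- if (m$orientation == "obs_rows") {
    list(sorted, NULL)
  } else {
    list(NULL, sorted)
  }
  block <- rhdf5::h5read(m$source$path, m$source$dataset, index = idx)
  if (m$orientation == "feat_rows") block <- t(block)
  # undo the internal sort so row j corresponds to indices[j]
  out <- block[order(ord), , drop = FALSE]
  m$stats$reads <- c(m$stats$reads, length(indices))
  out
}

#' Peak number of rows materialized by an instrumented backend
#'
#' HDF5-backed matrices record the size of every [read_rows()] request. The
#' peak is the largest single request since the last [reset_read_stats()] —
#' the working-set bound of an out-of-core fit: a complete
#' [fit_minibatch()] run with batch size `b`, init subsample `b_init` and
#' prediction block `p` never requests more than `max(b_init, b, p)` rows at
#' a time, regardless of the total number of observations.
#'
#' @param m an HDF5-backed [data_matrix][open_matrix].
#' @return integer; 0 when no reads have occurred since the last reset.
#' @export
peak_rows_resident <- function(m) {
  stopifnot(inherits(m, "data_matrix"))
  if (m$backend != "hdf5" || is.null(m$stats)) {
    stop("peak_rows_resident() requires an instrumented (hdf5) backend",
         call. = FALSE)
  }
  if (length(m$stats$reads) == 0L) return(0L)
  as.integer(max(m$stats$reads))
}

#' @rdname peak_rows_resident
#' @export
reset_read_stats <- function(m) {
  stopifnot(inherits(m, "data_matrix"))
  if (m$backend != "hdf5" || is.null(m$stats)) {
    stop("reset_read_stats() requires an instrumented (hdf5) backend",
         call. = FALSE)
  }
  m$stats$reads <- numeric(0)
  invisible(m)
}

hdf5_dataset_dims <- function(path, dataset) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fid <- tryCatch(rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY"),
                  error = function(e) {
                    stop("cannot open HDF5 file: ", path, call. = FALSE)
                  })
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  if (!rhdf5::H5Lexists(fid, dataset)) {
    stop("dataset '", dataset, "' not found in ", path, call. = FALSE)
  }
  did <- rhdf5::H5Dopen(fid, dataset)
  on.exit(rhdf5::H5Dclose(did), add = TRUE)
  sid <- rhdf5::H5Dget_space(did)
  on.exit(rhdf5::H5Sclose(sid), add = TRUE)
  rhdf5::H5Sget_simple_extent_dims(sid)$size
}

#' Chunk dimensions of an HDF5 dataset
#'
#' @param path,dataset file and dataset name.
#' @return integer vector of chunk dimensions in R (row, column) order, or
#'   `NULL` for contiguous (unchunked) storage.
#' @export
hdf5_chunk_dims <- function(path, dataset = "counts") {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  if (!rhdf5::H5Lexists(fid, dataset)) {
    stop("dataset '", dataset, "' not found in ", path, call. = FALSE)
  }
  did <- rhdf5::H5Dopen(fid, dataset)
  on.exit(rhdf5::H5Dclose(did), add = TRUE)
  pid <- rhdf5::H5Dget_create_plist(did)
  on.exit(rhdf5::H5Pclose(pid), add = TRUE)
  layout <- rhdf5::H5Pget_layout(pid)
  if (!identical(layout, "H5D_CHUNKED")) return(NULL)
  # HDF5 reports chunk dims in C (row-major) order; reverse to R order
  rev(rhdf5::H5Pget_chunk(pid))
}
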