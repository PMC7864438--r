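#' Chunk geometry for a dense 2-D HDF5 dataset
#'
#' An HDF5 dataset is stored as a grid of rectangular chunks; a read decodes
#' every chunk it touches, so the chunk shape determines the I/O and memory
#' cost of row-subset access. `chunk_geometry()` builds a validated geometry;
#' `default_chunk_geometry()` chooses one automatically under three
#' constraints: (i) chunk area strictly below `max_area` elements,
#' (ii) the chunk fits inside the matrix, and (iii) the chunk aspect ratio is
#' as close as achievable to the matrix aspect ratio. When the whole matrix
#' is already smaller than `max_area` the whole matrix is the chunk —
#' a single small chunk is optimal there.
#'
#' The aspect-matching rule is deterministic: both dimensions are scaled by
#' `sqrt((max_area - 1) / (n_rows * n_cols))` (capped at 1), floored, clamped
#' to at least 1, and the larger dimension is then decremented until the area
#' drops below `max_area`.
#'
#' @param chunk_rows,chunk_cols positive chunk dimensions.
#' @param n_rows,n_cols dimensions of the stored matrix.
#' @param max_area maximum chunk area in elements (exclusive bound unless the
#'   whole matrix is smaller); default 1,000,000.
#' @return a `chunk_geometry` object with elements `chunk_rows`, `chunk_cols`.
#' @examples
#' default_chunk_geometry(100, 100)       # whole matrix: area 10,000
#' default_chunk_geometry(5000, 5000)     # ~999 x 999 square
#' default_chunk_geometry(11720, 1232055) # wide matrix -> wide chunk
#' @export
chunk_geometry <- function(chunk_rows, chunk_cols) {
  chunk_rows <- as_count(chunk_rows, "chunk_rows")
  chunk_cols <- as_count(chunk_cols, "chunk_cols")
  structure(list(chunk_rows = chunk_rows, chunk_cols = chunk_cols),
            class = "chunk_geometry")
}

#' @export
print.chunk_geometry <- function(x, ...) {
  cat(sprintf("<chunk_geometry> %d x %d (area %s)\n", x$chunk_rows,
              x$chunk_cols,
              format(as.numeric(x$chunk_rows) * x$chunk_cols,
                     big.mark = ",", scientific = FALSE)))
  invisible(x)
}

as_count <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 ||
      x != floor(x)) {
    stop(what, " must be a single positive integer", call. = FALSE)
  }
  as.integer(x)
}

#' @rdname chunk_geometry
#' @export
default_chunk_geometry <- function(n_rows, n_cols, max_area = 1e6) {
  n_rows <- as_count(n_rows, "n_rows")
  n_cols <- as_count(n_cols, "n_cols")
  if (length(max_area) != 1L || !is.numeric(max_area) || max_area < 1) {
    stop("max_area must be a positive number", call. = FALSE)
  }
  area <- as.numeric(n_rows) * n_cols
  if (area < max_area) {
    return(chunk_geometry(n_rows, n_cols))
  }
  scale <- min(1, sqrt((max_area - 1) / area))
  r <- max(1L, as.integer(floor(scale * n_rows)))
  cc <- max(1L, as.integer(floor(scale * n_cols)))
  # flooring alone keeps the area below the bound unless a dimension was
  # clamped up to 1; then shrink the other dimension to restore (i)
  if (as.numeric(r) * cc >= max_area) {
    if (r >= cc) r <- max(1L, as.integer((max_area - 1) %/% cc))
    else cc <- max(1L, as.integer((max_area - 1) %/% r))
  }
  chunk_geometry(min(r, n_rows), min(cc, n_cols))
}

resolve_geometry <- function(geometry, n_rows, n_cols, n_feat_axis = 2L,
                             slab = NULL, max_area = 1e6) {
  if (inherits(geometry, "chunk_geometry")) return(geometry)
  if (!is.character(geometry) || length(geometry) != 1L) {
    stop("geometry must be a chunk_geometry or a preset name", call. = FALSE)
  }
  preset <- match.arg(geometry,
                      c("default", "by_cell", "by_gene", "single_chunk"))
  obs_axis_len <- if (n_feat_axis == 2L) n_rows else n_cols
  feat_axis_len <- if (n_feat_axis == 2L) n_cols else n_rows
  switch(preset,
    default = default_chunk_geometry(n_rows, n_cols, max_area),
    single_chunk = chunk_geometry(n_rows, n_cols),
    by_cell = {
      depth <- slab_depth(slab, feat_axis_len, obs_axis_len, max_area)
      if (n_feat_axis == 2L) chunk_geometry(depth, feat_axis_len)
      else chunk_geometry(feat_axis_len, depth)
    },
    by_gene = {
      depth <- slab_depth(slab, obs_axis_len, feat_axis_len, max_area)
      if (n_feat_axis == 2L) chunk_geometry(obs_axis_len, depth)
      else chunk_geometry(depth, obs_axis_len)
    }
  )
}

# slab depth along the sliced axis so that chunk area sits just under
# max_area, unless the caller fixes it
slab_depth <- function(slab, span_len, axis_len, max_area) {
  if (!is.null(slab)) return(min(as_count(slab, "slab"), axis_len))
  max(1L, min(axis_len, as.integer((max_area - 1) %/% span_len)))
}

#' Rewrite an HDF5 dataset with a new chunk layout
#'
#' Copies a dense 2-D dataset into a new file with the requested chunk
#' geometry, streaming bounded row slabs so the full matrix is never held in
#' memory. Values are conserved exactly. Presets (interpreted in the logical
#' observations x features sense via `orientation`):
#' \describe{
#'   \item{`by_cell`}{each chunk spans the full feature dimension for a slab
#'     of observations — the layout that minimizes RAM and time for the
#'     row-sampled access pattern of mini-batch k-means;}
#'   \item{`by_gene`}{the transpose: full observation dimension per slab of
#'     features;}
#'   \item{`single_chunk`}{one chunk covering the whole matrix;}
#'   \item{`default`}{the aspect-matched rectangle of
#'     [default_chunk_geometry()].}
#' }
#'
#' @param in_path,in_dataset input file and dataset.
#' @param out_path,out_dataset output file and dataset (the output file is
#'   created; an existing file at `out_path` is an error).
#' @param geometry a [chunk_geometry()] or preset name.
#' @param orientation whether stored rows of the *input* are observations or
#'   features; presets are interpreted accordingly. The stored orientation is
#'   preserved in the output.
#' @param slab optional slab depth for the `by_cell` / `by_gene` presets;
#'   default makes the chunk area just under 1,000,000 elements.
#' @param level gzip compression level 0-9 (0 = none).
#' @return `out_path`, invisibly.
#' @export
rechunk_hdf5 <- function(in_path, in_dataset = "counts",
                         out_path, out_dataset = in_dataset,
                         geometry = "by_cell",
                         orientation = c("obs_rows", "feat_rows"),
                         slab = NULL, level = 0) {
  orientation <- match.arg(orientation)
  dims <- hdf5_dataset_dims(in_path, in_dataset)
  if (length(dims) != 2L) stop("input dataset is not 2-D", call. = FALSE)
  n_feat_axis <- if (orientation == "obs_rows") 2L else 1L
  geom <- resolve_geometry(geometry, dims[1L], dims[2L],
                           n_feat_axis = n_feat_axis, slab = slab)
  if (geom$chunk_rows > dims[1L] || geom$chunk_cols > dims[2L]) {
    stop("chunk geometry ", geom$chunk_rows, " x ", geom$chunk_cols,
         " exceeds matrix ", dims[1L], " x ", dims[2L], call. = FALSE)
  }
  if (file.exists(out_path)) {
    stop("output file already exists: ", out_path, call. = FALSE)
  }

  probe <- rhdf5::h5read(in_path, in_dataset, index = list(1L, NULL))
  smode <- storage.mode(probe)

  rhdf5::h5createFile(out_path)
  ok <- rhdf5::h5createDataset(
    out_path, out_dataset, dims = dims,
    chunk = c(geom$chunk_rows, geom$chunk_cols),
    storage.mode = smode, level = level
  )
  if (!isTRUE(ok)) stop("failed to create output dataset", call. = FALSE)

  # stream aligned row slabs; at least one chunk row, at most ~4e6 elements
  step <- max(geom$chunk_rows, max(1L, as.integer(4e6 %/% dims[2L])))
  step <- min(step, dims[1L])
  start <- 1L
  while (start <= dims[1L]) {
    end <- min(start + step - 1L, dims[1L])
    slab_block <- rhdf5::h5read(in_path, in_dataset,
                                index = list(start:end, NULL))
    rhdf5::h5write(slab_block, out_path, out_dataset,
                   index = list(start:end, NULL))
    start <- end + 1L
  }
  rhdf5::h5closeAll()
  invisible(out_path)
}
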