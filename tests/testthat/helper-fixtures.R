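# fixture builders; all files go to tempdir() and are removed by the caller
# via withr or left for the session cleanup

tmp_h5 <- function(x, dataset = "counts", chunk = NULL, transpose = FALSE) {
  path <- tempfile(fileext = ".h5")
  stored <- if (transpose) t(x) else x
  rhdf5::h5createFile(path)
  if (is.null(chunk)) chunk <- dim(stored)
  rhdf5::h5createDataset(path, dataset, dims = dim(stored), chunk = chunk,
                         storage.mode = storage.mode(stored), level = 0)
  rhdf5::h5write(stored, path, dataset)
  rhdf5::h5closeAll()
  path
}

tmp_csv <- function(x) {
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(as.data.frame(x), path, col.names = TRUE)
  path
}

tmp_mtx <- function(x) {
  path <- tempfile(fileext = ".mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE),
                              "generalMatrix"), path)
  path
}

rand_matrix <- function(n, g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * g), n, g)
}
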