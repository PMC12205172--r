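#' Construct a modality object
#'
#' A modality is one cell-by-feature numeric matrix, the unit on which
#' manifolds are built. Optional cell identifiers and per-cell labels travel
#' with the matrix through the pipeline.
#'
#' @param x Numeric matrix, cells in rows, features in columns. At least 3
#'   cells and 1 feature; non-finite values are rejected.
#' @param cell_ids Optional character vector of length `nrow(x)`.
#' @param labels Optional vector (coerced to factor) of length `nrow(x)`.
#' @return An object of class `sonata_modality`: a list with elements
#'   `matrix`, `cell_ids`, `labels`.
#' @examples
#' m <- modality(matrix(rnorm(30), 10, 3))
#' m
#' @export
modality <- function(x, cell_ids = NULL, labels = NULL) {
  stop_if_not_matrix(x, "x")
  if (nrow(x) < 3L) stop("a modality needs at least 3 cells", call. = FALSE)
  if (ncol(x) < 1L) stop("a modality needs at least 1 feature", call. = FALSE)
  if (!is.null(cell_ids)) {
    cell_ids <- as.character(cell_ids)
    if (length(cell_ids) != nrow(x))
      stop("`cell_ids` length must equal the number of cells", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != nrow(x))
      stop("`labels` length must equal the number of cells", call. = FALSE)
  }
  structure(list(matrix = x, cell_ids = cell_ids, labels = labels),
            class = "sonata_modality")
}

#' @export
print.sonata_modality <- function(x, ...) {
  cat(sprintf("<sonata_modality> %d cells x %d features%s%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$cell_ids)) ", with cell ids" else "",
              if (!is.null(x$labels))
                sprintf(", %d label levels", nlevels(x$labels)) else ""))
  invisible(x)
}

#' @export
dim.sonata_modality <- function(x) dim(x$matrix)

as_modality <- function(x) {
  if (inherits(x, "sonata_modality")) return(x)
  modality(as.matrix(x))
}

#' Read a modality from a delimited or MatrixMarket file
#'
#' TSV/CSV files hold one row per cell; with `id_column = TRUE` the first
#' column is taken as cell identifiers. Sparse MatrixMarket (`.mtx`) input is
#' densified; cell identifiers then come from `ids_file` (one per line).
#'
#' @param path File to read.
#' @param format `"auto"` (from extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param header Does the delimited file have a header line?
#' @param id_column Is the first column a cell-identifier column?
#' @param ids_file Optional path of per-cell identifiers (one per line).
#' @param labels_file Optional path of per-cell labels (one per line).
#' @return A [modality()] object.
#' @export
read_modality <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                          header = FALSE, id_column = FALSE,
                          ids_file = NULL, labels_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  ids <- NULL
  if (format == "mtx") {
    x <- as.matrix(Matrix::readMM(path))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.table(path, sep = sep, header = header,
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (id_column) {
      ids <- as.character(df[[1L]])
      df <- df[, -1L, drop = FALSE]
    }
    bad <- !vapply(df, is.numeric, logical(1L))
    if (any(bad))
      stop(sprintf("non-numeric column(s) in %s: %s", path,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    x <- as.matrix(df)
    dimnames(x) <- NULL
  }
  if (!is.null(ids_file)) ids <- readLines(ids_file)
  labels <- if (!is.null(labels_file)) read_labels(labels_file) else NULL
  modality(x, cell_ids = ids, labels = labels)
}

#' Write a modality matrix to TSV, CSV or MatrixMarket
#'
#' @param m A [modality()] object or numeric matrix.
#' @param path Output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @export
write_modality <- function(m, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  m <- as_modality(m)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m$matrix, sparse = TRUE), path)
  } else {
    write.table(m$matrix, path, sep = if (format == "csv") "," else "\t",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read per-cell labels (one label per line)
#' @param path File with one label per line.
#' @return A factor.
#' @export
read_labels <- function(path) {
  as.factor(readLines(path))
}
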