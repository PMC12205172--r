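# Readers/writers for couplings and diagnosis artifacts. Indices in files
# are 0-based (documented in each header line); in-memory objects are
# 1-based as usual in R.

#' Write a coupling matrix with a JSON metadata sidecar
#'
#' Dense TSV by default; MatrixMarket when more than 90 percent of entries
#' are zero. The sidecar `<path>.json` records marginals, epsilon,
#' objective and convergence when available.
#'
#' @param cpl `sonata_coupling` or matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coupling <- function(cpl, path) {
  G <- if (inherits(cpl, "sonata_coupling")) cpl$gamma else cpl
  sparse <- mean(G == 0) > 0.9
  if (sparse) {
    # * 1.0 keeps 0/1 matrices numeric (a pattern matrix would read back
    # as logical)
    Matrix::writeMM(Matrix::Matrix(G, sparse = TRUE) * 1.0, path)
  } else {
    write.table(G, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(n_rows = nrow(G), n_cols = ncol(G),
               format = if (sparse) "mtx" else "tsv")
  if (inherits(cpl, "sonata_coupling"))
    meta <- c(meta, list(epsilon = cpl$epsilon, objective = cpl$objective,
                         converged = cpl$converged,
                         marginal_error = cpl$marginal_error,
                         p = cpl$p, q = cpl$q))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a coupling matrix written by [write_coupling()]
#'
#' @param path File holding a dense TSV or MatrixMarket matrix.
#' @return A numeric matrix.
#' @export
read_coupling <- function(path) {
  first <- readLines(path, n = 1L)
  out <- if (startsWith(first, "%%MatrixMarket")) {
    as.matrix(Matrix::readMM(path))
  } else {
    as.matrix(read.table(path, sep = "\t", header = FALSE))
  }
  dimnames(out) <- NULL
  storage.mode(out) <- "double"
  out
}

#' Write ambiguity calls as TSV
#'
#' Columns: `cell_i`, `cell_j` (0-based), `geodesic_dist`, `observed`,
#' `expected`, `deviation`, `p_value`, `significant`.
#'
#' @param ambiguity A [ambiguity_pvalues()] result.
#' @param path Output file.
#' @export
write_ambiguity <- function(ambiguity, path) {
  stopifnot(inherits(ambiguity, "sonata_ambiguity"))
  df <- ambiguity$pairs
  out <- data.frame(cell_i = df$i - 1L, cell_j = df$j - 1L,
                    geodesic_dist = df$distance, observed = df$observed,
                    expected = df$expected, deviation = df$deviation,
                    p_value = df$p_value,
                    significant = as.integer(df$significant))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cell indices are 0-based", con)
  write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write group assignments as TSV
#'
#' Columns `cell_index` (0-based) and `group_id` (0-based; -1 for
#' unambiguous cells).
#'
#' @param groups A [find_ambiguous_groups()] result.
#' @param path Output file.
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "sonata_groups"))
  gid <- groups$assignment
  out <- data.frame(cell_index = seq_along(gid) - 1L,
                    group_id = ifelse(is.na(gid), -1L, gid - 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cell_index is 0-based; group_id -1 marks unambiguous cells", con)
  write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an elbow curve as TSV
#' @param groups A [find_ambiguous_groups()] result.
#' @param path Output file.
#' @export
write_elbow <- function(groups, path) {
  stopifnot(inherits(groups, "sonata_groups"))
  write.table(groups$elbow, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a fitted null spline as JSON
#' @param spline A [fit_null_spline()] result.
#' @param path Output file.
#' @export
write_null_spline <- function(spline, path) {
  stopifnot(inherits(spline, "sonata_null_spline"))
  jsonlite::write_json(list(grid_x = spline$grid_x, grid_y = spline$grid_y,
                            range = spline$range,
                            step_fallback = spline$step_fallback),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
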