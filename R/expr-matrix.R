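#' Expression matrix container
#'
#' A genes/probe-sets x arrays numeric matrix with a `space` tag recording the
#' scale the values live on. The orientation is fixed package-wide: rows are
#' genes (or probes / probe-sets), columns are arrays.
#'
#' @param values numeric matrix with unique, non-empty rownames and colnames.
#' @param space one of `"raw"`, `"log2"`, `"log2_centered"`, `"normalized"`.
#'   Raw-space values must be non-negative and free of missing values.
#' @param allow_na permit missing values in log spaces (default FALSE).
#' @return an `expr_mat` object.
#' @export
expr_mat <- function(values, space = c("raw", "log2", "log2_centered", "normalized"),
                     allow_na = FALSE) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    np_abort("`values` must be a numeric matrix", "validation_error")
  rn <- rownames(values); cn <- colnames(values)
  # R stores no dimnames for a zero-extent dimension; only non-empty
  # dimensions must be named
  if ((is.null(rn) && nrow(values) > 0) || (is.null(cn) && ncol(values) > 0))
    np_abort("expression matrix needs row and column names", "validation_error")
  if (anyDuplicated(rn))
    np_abort(paste0("duplicate row id: ", rn[duplicated(rn)][1]), "validation_error")
  if (anyDuplicated(cn))
    np_abort(paste0("duplicate column id: ", cn[duplicated(cn)][1]), "validation_error")
  if (anyNA(values) && (space == "raw" || !allow_na))
    np_abort("missing values not permitted in this space", "validation_error")
  if (space == "raw" && any(values < 0, na.rm = TRUE))
    np_abort("raw-space values must be >= 0", "validation_error")
  structure(values, space = space, class = c("expr_mat", "matrix", "array"))
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d x %d [%s]\n", nrow(x), ncol(x), expr_space(x)))
  invisible(x)
}

#' Space tag of an expression matrix
#' @param x an `expr_mat`.
#' @return character scalar.
#' @export
expr_space <- function(x) attr(x, "space") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset an expression matrix, keeping class and space
#' @param mat an `expr_mat`.
#' @param rows,cols row / column ids or indices (NULL keeps all).
#' @return an `expr_mat`.
#' @export
expr_subset <- function(mat, rows = NULL, cols = NULL) {
  v <- unclass(mat)
  if (!is.null(rows)) v <- v[rows, , drop = FALSE]
  if (!is.null(cols)) v <- v[, cols, drop = FALSE]
  expr_mat(v, expr_space(mat), allow_na = TRUE)
}

#' @export
tidy.expr_mat <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("row_id", "array_id", "value"))
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of array ids and a first column of row ids. Duplicate
#' ids on either axis are rejected.
#'
#' @param path file path.
#' @param space space tag to stamp on the result (see [expr_mat()]).
#' @return an `expr_mat`.
#' @export
read_expression_matrix <- function(path, space = "raw") {
  if (!file.exists(path)) np_abort(paste0("no such file: ", path), "io_error")
  lines <- readLines(path)
  if (length(lines) < 2)
    np_abort(sprintf("parse error in %s: need a header and at least one data row", path),
             "parse_error")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  ncol_expect <- length(header)
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(cells) != ncol_expect)
  if (length(bad))
    np_abort(sprintf("parse error in %s at line %d: expected %d fields, got %d",
                     path, bad[1] + 1L, ncol_expect, lengths(cells)[bad[1]]),
             "parse_error")
  row_ids <- vapply(cells, `[[`, "", 1L)
  vals <- t(vapply(cells, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    v
  }, numeric(ncol_expect - 1L)))
  if (ncol_expect == 2L) vals <- matrix(vals, ncol = 1L)
  nan_line <- which(apply(is.na(vals), 1, any))
  if (space == "raw" && length(nan_line))
    np_abort(sprintf("parse error in %s at line %d: non-numeric or missing value",
                     path, nan_line[1] + 1L), "parse_error")
  dimnames(vals) <- list(row_ids, header[-1])
  expr_mat(vals, space, allow_na = TRUE)
}

#' Write an expression matrix to TSV
#'
#' @param mat an `expr_mat`.
#' @param path output file path.
#' @param digits significant digits written (default 10; round-trips to the
#'   tolerances used throughout the package).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, digits = 10) {
  df <- data.frame(row_id = rownames(mat),
                   signif(unclass(mat), digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
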