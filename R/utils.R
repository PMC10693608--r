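`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stopf("'%s' must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

#' Coerce a counts object to a sparse column-compressed matrix
#'
#' Genes are rows, cells are columns. Values must be nonnegative integers;
#' dimnames must be present and free of duplicates.
#' @keywords internal
as_count_matrix <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stopf("count matrix must carry gene rownames and cell barcode colnames")
  if (anyDuplicated(rownames(m))) stopf("duplicate gene identifiers in count matrix")
  if (anyDuplicated(colnames(m))) stopf("duplicate cell barcodes in count matrix")
  v <- m@x
  if (length(v) && (min(v) < 0 || any(v != round(v))))
    stopf("count matrix must contain nonnegative integers")
  m
}

# Column sums of a sparse matrix restricted to a row subset, without densifying.
col_sums_rows <- function(m, rows) {
  if (length(rows) == 0L) return(numeric(ncol(m)))
  Matrix::colSums(m[rows, , drop = FALSE])
}
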