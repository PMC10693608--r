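#' Read a 10x-style matrix bundle
#'
#' Reads a MatrixMarket sparse count matrix (`matrix.mtx`) together with
#' `genes.tsv` (one gene symbol per line), `barcodes.tsv` (one barcode per
#' line) and, when present, `metadata.tsv` (tab-separated cell metadata with a
#' `barcode` column). On disk the matrix is genes x cells, the 10x convention.
#'
#' @param path Directory containing the bundle files.
#' @param require_metadata Error if `metadata.tsv` is absent (default `FALSE`).
#' @return A list with `counts` (sparse genes x cells integer matrix) and
#'   `meta` (a `data.frame`, or `NULL` when no metadata file exists).
#' @export
read_matrix_bundle <- function(path, require_metadata = FALSE) {
  mtx <- file.path(path, "matrix.mtx")
  gf  <- file.path(path, "genes.tsv")
  bf  <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, gf, bf)) if (!file.exists(f)) stopf("missing bundle file: %s", f)
  m <- Matrix::readMM(mtx)
  genes <- readLines(gf)
  barcodes <- readLines(bf)
  if (nrow(m) != length(genes))
    stopf("dimension mismatch: matrix has %d rows but genes.tsv has %d entries",
          nrow(m), length(genes))
  if (ncol(m) != length(barcodes))
    stopf("dimension mismatch: matrix has %d columns but barcodes.tsv has %d entries",
          ncol(m), length(barcodes))
  if (anyDuplicated(barcodes))
    stopf("duplicate barcodes in barcodes.tsv: %s",
          paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  dimnames(m) <- list(genes, barcodes)
  counts <- as_count_matrix(m)
  meta <- NULL
  mf <- file.path(path, "metadata.tsv")
  if (file.exists(mf)) {
    meta <- utils::read.delim(mf, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"barcode" %in% names(meta)) stopf("metadata.tsv lacks a 'barcode' column")
    absent <- setdiff(barcodes, meta$barcode)
    if (length(absent))
      stopf("metadata missing for %d barcode(s): %s%s", length(absent),
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "")
    meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
    rownames(meta) <- NULL
  } else if (require_metadata) {
    stopf("metadata.tsv required but absent in %s", path)
  }
  list(counts = counts, meta = meta)
}

#' Write a 10x-style matrix bundle
#'
#' Inverse of [read_matrix_bundle()]; a write/read cycle round-trips to an
#' identical logical matrix.
#'
#' @param counts Sparse genes x cells count matrix with dimnames.
#' @param path Output directory (created if needed).
#' @param meta Optional cell metadata `data.frame` with a `barcode` column.
#' @return `path`, invisibly.
#' @export
write_matrix_bundle <- function(counts, path, meta = NULL) {
  counts <- as_count_matrix(counts)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts, file.path(path, "matrix.mtx"))
  writeLines(rownames(counts), file.path(path, "genes.tsv"))
  writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  if (!is.null(meta)) {
    if (!"barcode" %in% names(meta)) stopf("meta lacks a 'barcode' column")
    utils::write.table(meta, file.path(path, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Order is
#' preserved; duplicate genes within a set are collapsed with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("GMT line %d: set '%s' is empty", i, if (length(f)) f[1] else "?")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("GMT line %d: set '%s' is empty", i, f[1])
    if (anyDuplicated(genes)) {
      warnf("GMT set '%s': %d duplicate gene id(s) collapsed",
            f[1], sum(duplicated(genes)))
      genes <- genes[!duplicated(genes)]
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param description Optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && !is.na(description[nm])) description[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

SEROLOGY_COLS <- c("infant", "vaccine", "antigen", "timepoint", "value", "units")

#' Read a serology titer table
#'
#' CSV with columns `infant, vaccine, antigen, timepoint, value, units`;
#' `timepoint` is `pre`/`post`; unit strings are preserved verbatim.
#'
#' @param path CSV file path.
#' @return `data.frame` of titer records.
#' @export
read_serology <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(SEROLOGY_COLS, names(tab))
  if (length(missing_cols))
    stopf("serology table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  val <- suppressWarnings(as.numeric(tab$value))
  bad <- which(is.na(val) & !is.na(tab$value) & nzchar(tab$value))
  if (length(bad))
    stopf("non-numeric titer value '%s' at row %d", tab$value[bad[1]], bad[1])
  if (any(val < 0, na.rm = TRUE))
    stopf("negative titer value at row %d", which(val < 0)[1])
  tab$value <- val
  tab[SEROLOGY_COLS]
}

#' Write a serology titer table to CSV
#' @param titers `data.frame` with the standard serology columns.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_serology <- function(titers, path) {
  utils::write.csv(titers[SEROLOGY_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bulk expression matrix with sample metadata
#'
#' `matrix.tsv` holds probes x samples positive intensities (probe ids in the
#' first column); `samples.tsv` maps `sample` to `day`.
#' @param path Directory with `matrix.tsv` and `samples.tsv`.
#' @return List with `exprs` (numeric matrix) and `samples` (`data.frame`).
#' @export
read_bulk_bundle <- function(path) {
  mt <- utils::read.delim(file.path(path, "matrix.tsv"), check.names = FALSE)
  exprs <- as.matrix(mt[, -1, drop = FALSE])
  rownames(exprs) <- mt[[1]]
  if (any(exprs <= 0)) stopf("bulk intensities must be positive")
  samples <- utils::read.delim(file.path(path, "samples.tsv"), check.names = FALSE)
  if (!all(c("sample", "day") %in% names(samples)))
    stopf("samples.tsv must have 'sample' and 'day' columns")
  samples$day <- as.character(samples$day)
  missing_samp <- setdiff(colnames(exprs), samples$sample)
  if (length(missing_samp))
    stopf("no day label for sample(s): %s", paste(missing_samp, collapse = ", "))
  list(exprs = exprs, samples = samples)
}

#' Write a bulk expression matrix with sample metadata
#' @param exprs Probes x samples matrix of positive intensities.
#' @param samples `data.frame` with `sample` and `day` columns.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_bulk_bundle <- function(exprs, samples, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(probe = rownames(exprs), exprs, check.names = FALSE),
                     file.path(path, "matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples, file.path(path, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground truth (or any report list) as JSON
#' @param x A list.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}
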