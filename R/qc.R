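#' Quality-control parameters
#'
#' Defaults follow common droplet scRNA-seq practice: genes must be detected
#' (count > 0) in at least 3 cells; cells must have at least 750 total
#' transcripts, between 250 and 3500 detected genes (bounds inclusive), at most
#' 15% mitochondrial transcripts, and — when a doublet score is available — a
#' doublet score of at most 0.25.
#'
#' @param min_cells_per_gene,min_total_counts,min_genes,max_genes,max_mito_frac,max_doublet_score
#'   Filter thresholds; see Details for boundary semantics.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes when
#'   the metadata has no `mito_frac` column.
#' @details Boundary semantics are keep-if: total >= `min_total_counts`;
#'   `min_genes` <= detected genes <= `max_genes`; mito fraction <=
#'   `max_mito_frac`; doublet score <= `max_doublet_score`.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_cells_per_gene = 3, min_total_counts = 750,
                      min_genes = 250, max_genes = 3500,
                      max_mito_frac = 0.15, max_doublet_score = 0.25,
                      mito_prefix = "MT-") {
  p <- list(min_cells_per_gene = min_cells_per_gene,
            min_total_counts = min_total_counts,
            min_genes = min_genes, max_genes = max_genes,
            max_mito_frac = max_mito_frac,
            max_doublet_score = max_doublet_score,
            mito_prefix = mito_prefix)
  num <- p[setdiff(names(p), "mito_prefix")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) < 0))
    stopf("qc thresholds must be nonnegative numbers")
  if (p$min_genes >= p$max_genes) stopf("min_genes must be < max_genes")
  class(p) <- "qc_params"
  p
}

#' Apply cell and gene quality filters
#'
#' Rules are applied in order: (0) doublet removal (only when a score exists),
#' (1) genes detected in fewer than `min_cells_per_gene` cells are dropped,
#' (2) cells with fewer than `min_total_counts` total transcripts are removed,
#' (3) cells with a detected-gene count outside `[min_genes, max_genes]` are
#' removed, (4) cells whose mitochondrial fraction exceeds `max_mito_frac` are
#' removed. Each rule sees the matrix left by the previous one, and the ordered
#' pass repeats until nothing changes, so the filter is idempotent (removing
#' cells can push a gene back below the detection floor).
#'
#' The mitochondrial fraction is taken from a `mito_frac` metadata column when
#' present, else computed from the input matrix over genes whose symbol starts
#' with `mito_prefix`. Doublet scores come from a `doublet_score` column; the
#' rule is skipped when the column is absent.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param meta Cell metadata `data.frame` with a `barcode` column, aligned to
#'   the matrix columns.
#' @param params A [qc_params()] object.
#' @return List with filtered `counts`, `meta`, and `report` (per-rule removal
#'   counts in application order, plus surviving dimensions).
#' @export
apply_qc <- function(counts, meta = NULL, params = qc_params()) {
  counts <- as_count_matrix(counts)
  if (is.null(meta)) meta <- data.frame(barcode = colnames(counts))
  if (!"barcode" %in% names(meta)) stopf("meta lacks a 'barcode' column")
  if (!identical(meta$barcode, colnames(counts)))
    meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
  if (anyNA(meta$barcode)) stopf("metadata missing for some barcodes")

  n_genes_in <- nrow(counts); n_cells_in <- ncol(counts)

  # per-cell mito fraction, fixed from the input state of each cell
  if ("mito_frac" %in% names(meta)) {
    mito <- meta$mito_frac
  } else {
    mito_genes <- grep(paste0("^", params$mito_prefix), rownames(counts), value = TRUE)
    tot <- Matrix::colSums(counts)
    mito <- if (length(mito_genes)) col_sums_rows(counts, mito_genes) / pmax(tot, 1)
            else numeric(ncol(counts))
  }
  names(mito) <- colnames(counts)
  dscore <- if ("doublet_score" %in% names(meta)) stats::setNames(meta$doublet_score, meta$barcode) else NULL

  removed <- c(doublet = 0L, gene_detection = 0L, total_counts = 0L,
               gene_count_bounds = 0L, mito_fraction = 0L)
  m <- counts
  repeat {
    changed <- FALSE
    if (!is.null(dscore)) {
      drop <- colnames(m)[dscore[colnames(m)] > params$max_doublet_score]
      if (length(drop)) {
        removed["doublet"] <- removed["doublet"] + length(drop)
        m <- m[, setdiff(colnames(m), drop), drop = FALSE]; changed <- TRUE
      }
    }
    detected <- Matrix::rowSums(m > 0)
    gdrop <- rownames(m)[detected < params$min_cells_per_gene]
    if (length(gdrop)) {
      removed["gene_detection"] <- removed["gene_detection"] + length(gdrop)
      m <- m[setdiff(rownames(m), gdrop), , drop = FALSE]; changed <- TRUE
    }
    tot <- Matrix::colSums(m)
    drop <- colnames(m)[tot < params$min_total_counts]
    if (length(drop)) {
      removed["total_counts"] <- removed["total_counts"] + length(drop)
      m <- m[, setdiff(colnames(m), drop), drop = FALSE]; changed <- TRUE
    }
    ng <- Matrix::colSums(m > 0)
    drop <- colnames(m)[ng < params$min_genes | ng > params$max_genes]
    if (length(drop)) {
      removed["gene_count_bounds"] <- removed["gene_count_bounds"] + length(drop)
      m <- m[, setdiff(colnames(m), drop), drop = FALSE]; changed <- TRUE
    }
    drop <- colnames(m)[mito[colnames(m)] > params$max_mito_frac]
    if (length(drop)) {
      removed["mito_fraction"] <- removed["mito_fraction"] + length(drop)
      m <- m[, setdiff(colnames(m), drop), drop = FALSE]; changed <- TRUE
    }
    if (!changed) break
  }
  if (ncol(m) == 0L) stopf("no cells survive quality control")

  report <- list(
    cells_in = n_cells_in, genes_in = n_genes_in,
    removed = as.list(removed),
    cells_removed = n_cells_in - ncol(m),
    genes_removed = n_genes_in - nrow(m),
    cells_out = ncol(m), genes_out = nrow(m))
  meta_out <- meta[match(colnames(m), meta$barcode), , drop = FALSE]
  rownames(meta_out) <- NULL
  list(counts = m, meta = meta_out, report = report)
}

#' Counts-per-million normalization
#'
#' Scales every cell to a total of 1e6 and optionally applies `log1p`
#' (natural log by default; set `log_base = 2` for log2). The sparsity pattern
#' is preserved.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param log_transform Apply `log1p` after scaling (default `TRUE`).
#' @param log_base Logarithm base for the transform (default `exp(1)`).
#' @return Sparse genes x cells normalized matrix.
#' @export
normalize_cpm <- function(counts, log_transform = TRUE, log_base = exp(1)) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stopf("cell(s) with zero total counts: %s",
          paste(utils::head(colnames(counts)[tot == 0], 5), collapse = ", "))
  m <- counts
  m@x <- m@x / rep.int(tot, diff(m@p)) * 1e6
  if (log_transform) {
    m@x <- log1p(m@x)
    if (!isTRUE(all.equal(log_base, exp(1)))) m@x <- m@x / log(log_base)
  }
  m
}
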