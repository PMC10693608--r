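library(Matrix)   # attach so base-matrix coercions resolve in every test file

# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately literal and loop-based so it shares no code
# path with the package implementation it checks.

# random sparse-ish count fixture with dimnames
rand_counts <- function(n_genes, n_cells, seed, mu = 2, size = 0.5,
                        gene_prefix = "g", cell_prefix = "c") {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu, size = size),
              nrow = n_genes,
              dimnames = list(sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
                              sprintf("%s%04d", cell_prefix, seq_len(n_cells))))
  methods::as(m, "CsparseMatrix")
}

# scaled-down simulation config for fast tests
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_genes = 800, n_cells_per_sample = 80, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# exhaustive rank-sum enumeration: p = P(|W - EW| >= |w - EW|) over all
# choose(n1+n2, n1) assignments of the observed ranks
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# hand-coded Welch t-test p (textbook formula)
welch_p <- function(x, y) {
  v1 <- stats::var(x) / length(x); v2 <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# literal per-cell QC oracle: applies the five rules in order on the current
# matrix, cell by cell, and repeats the pass until nothing changes
oracle_qc <- function(counts, meta, params) {
  m <- as.matrix(counts)
  mito <- if ("mito_frac" %in% names(meta)) {
    stats::setNames(meta$mito_frac, meta$barcode)
  } else {
    mg <- grep(paste0("^", params$mito_prefix), rownames(m))
    tot0 <- colSums(m)
    stats::setNames(if (length(mg)) colSums(m[mg, , drop = FALSE]) / pmax(tot0, 1)
                    else rep(0, ncol(m)), colnames(m))
  }
  ds <- if ("doublet_score" %in% names(meta))
    stats::setNames(meta$doublet_score, meta$barcode) else NULL
  repeat {
    before <- dim(m)
    if (!is.null(ds)) {
      keep <- logical(ncol(m))
      for (j in seq_len(ncol(m))) keep[j] <- ds[colnames(m)[j]] <= params$max_doublet_score
      m <- m[, keep, drop = FALSE]
    }
    gkeep <- logical(nrow(m))
    for (i in seq_len(nrow(m))) gkeep[i] <- sum(m[i, ] > 0) >= params$min_cells_per_gene
    m <- m[gkeep, , drop = FALSE]
    keep <- logical(ncol(m))
    for (j in seq_len(ncol(m))) keep[j] <- sum(m[, j]) >= params$min_total_counts
    m <- m[, keep, drop = FALSE]
    keep <- logical(ncol(m))
    for (j in seq_len(ncol(m))) {
      ng <- sum(m[, j] > 0)
      keep[j] <- ng >= params$min_genes && ng <= params$max_genes
    }
    m <- m[, keep, drop = FALSE]
    keep <- logical(ncol(m))
    for (j in seq_len(ncol(m))) keep[j] <- mito[colnames(m)[j]] <= params$max_mito_frac
    m <- m[, keep, drop = FALSE]
    if (identical(dim(m), before)) break
  }
  list(genes = rownames(m), cells = colnames(m))
}

# literal G2DA oracle: loops over every (gene, subcluster, time point) and
# tests the five clauses one by one (pooled post mode, increase-only folds)
oracle_g2da <- function(counts, norm, meta, gene_set, params,
                        baseline = "A", post = c("B", "C")) {
  cm <- as.matrix(counts)
  nm <- as.matrix(norm)
  genes <- intersect(gene_set, rownames(cm))
  res <- list()
  for (sc in unique(meta$subcluster)) {
    cells_sc <- meta$barcode[meta$subcluster == sc]
    cells_A <- cells_sc[meta$timepoint[match(cells_sc, meta$barcode)] == baseline]
    cells_post_all <- cells_sc[meta$timepoint[match(cells_sc, meta$barcode)] %in% post]
    for (g in genes) {
      if (length(cells_A) == 0) { res[[paste(g, sc)]] <- "none"; next }
      expr_post <- cells_post_all[cm[g, cells_post_all] > 0]
      c1 <- length(expr_post) >= params$min_cells
      c2 <- length(expr_post) > 0 &&
        mean(cm[g, expr_post]) >= params$min_mean_reads
      frac_A <- sum(cm[g, cells_A] > 0) / length(cells_A)
      expr_A <- cells_A[cm[g, cells_A] > 0]
      flags <- character()
      for (tp in post) {
        cells_t <- cells_sc[meta$timepoint[match(cells_sc, meta$barcode)] == tp]
        if (!length(cells_t)) next
        frac_t <- sum(cm[g, cells_t] > 0) / length(cells_t)
        c3 <- frac_t >= params$min_frac
        c4 <- if (frac_A == 0) frac_t > 0 else frac_t / frac_A >= params$fold_frac
        expr_t <- cells_t[cm[g, cells_t] > 0]
        c5 <- if (!length(expr_t)) FALSE
        else if (!length(expr_A)) TRUE
        else mean(expm1(nm[g, expr_t])) / mean(expm1(nm[g, expr_A])) >= params$fold_expr
        if (c1 && c2 && c3 && c4 && c5) flags <- c(flags, tp)
      }
      res[[paste(g, sc)]] <- if (length(flags)) paste(flags, collapse = "&") else "none"
    }
  }
  unlist(res)
}

# Fixture with one cell on each side of every filter boundary. Filler cells
# (f1-f3) keep gene detection above the 3-cell floor across passes.
boundary_fixture <- function() {
  genes <- sprintf("g%04d", 1:3501)
  cell <- function(idx, count) {
    v <- numeric(3501); v[idx] <- count; v
  }
  cols <- list(
    f1     = cell(2:3501, 1),              # exactly 3500 genes -> kept
    f2     = cell(2:3501, 1),
    f3     = cell(2:3501, 1),
    b3501  = cell(1:3501, 1),              # 3501 genes -> removed
    k250   = cell(1:250, 3),               # 250 genes, total 750 -> kept
    r249   = cell(1:249, 4),               # 249 genes -> removed
    r749   = c(cell(1:249, 3)[1:249], 2, numeric(3251)),  # total 749 -> removed
    kmito  = cell(1:300, 3),               # mito 0.15 -> kept
    rmito  = cell(1:300, 3),               # mito 0.16 -> removed
    kdoub  = cell(1:300, 3),               # doublet 0.25 -> kept
    rdoub  = cell(1:300, 3))               # doublet 0.26 -> removed
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  meta <- data.frame(
    barcode = colnames(m),
    mito_frac = c(0, 0, 0, 0, 0, 0, 0, 0.15, 0.16, 0, 0),
    doublet_score = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0.25, 0.26),
    stringsAsFactors = FALSE)
  list(counts = methods::as(m, "CsparseMatrix"), meta = meta)
}

# cell metadata with random subcluster/timepoint labels for g2da fixtures
rand_sc_meta <- function(barcodes, n_sc, seed, timepoints = c("A", "B", "C")) {
  set.seed(seed)
  data.frame(barcode = barcodes,
             subcluster = sample(sprintf("SC%d", seq_len(n_sc)),
                                 length(barcodes), replace = TRUE),
             timepoint = sample(timepoints, length(barcodes), replace = TRUE),
             stringsAsFactors = FALSE)
}
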