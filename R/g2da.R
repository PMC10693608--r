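#' Parameters of the gene two-dimension augmentation (G2DA) scan
#'
#' The five criteria a gene must pass, per subcluster, to be called
#' 2D-augmented at a post-vaccination time point: (1) at least `min_cells`
#' cells express it post-vaccination; (2) at least `min_mean_reads` raw
#' counts on average among expressing cells post-vaccination; (3) expressing
#' cells comprise at least `min_frac` of the cells at the candidate time
#' point; (4) a fold increase of at least `fold_frac` in fractional abundance
#' versus baseline; (5) a fold increase of at least `fold_expr` in expression
#' level among expressing cells versus baseline.
#'
#' @param min_cells Minimum expressing cells post-vaccination (default 10).
#' @param min_mean_reads Minimum mean raw count among expressing cells
#'   post-vaccination (default 50).
#' @param min_frac Minimum fractional abundance at the candidate time point
#'   (default 0.01).
#' @param fold_frac Fractional-abundance fold threshold (default 1.5).
#' @param fold_expr Expression-level fold threshold (default 1.5).
#' @return List of class `g2da_params`.
#' @export
g2da_params <- function(min_cells = 10, min_mean_reads = 50, min_frac = 0.01,
                        fold_frac = 1.5, fold_expr = 1.5) {
  p <- list(min_cells = min_cells, min_mean_reads = min_mean_reads,
            min_frac = min_frac, fold_frac = fold_frac, fold_expr = fold_expr)
  if (any(unlist(p) <= 0)) stopf("all G2DA thresholds must be > 0")
  if (p$fold_frac < 1 || p$fold_expr < 1) stopf("fold thresholds must be >= 1")
  class(p) <- "g2da_params"
  p
}

#' Fraction of cells expressing a gene
#'
#' Number of cells with count > 0 divided by the number of cells considered.
#'
#' @param counts Genes x cells count matrix.
#' @param cells Barcodes of the cells observed (e.g. one time point).
#' @param gene Gene identifier.
#' @return Fraction in `[0, 1]`.
#' @export
fractional_abundance <- function(counts, cells, gene) {
  if (!length(cells)) stopf("empty cell set")
  sum(counts[gene, cells, drop = FALSE] > 0) / length(cells)
}

#' Scan a gene set for two-dimension augmentation per subcluster
#'
#' Evaluates the five [g2da_params()] criteria for every (gene, subcluster)
#' pair. In the default pooled mode, criteria (1)-(2) use the pooled
#' post-vaccination cells (all non-baseline time points), while (3)-(5) are
#' evaluated separately at each post time point against baseline; the strict
#' per-time-point mode (`post_pool = FALSE`) evaluates (1)-(2) at each
#' candidate time point too. Expression level for criterion (5) is the mean
#' normalized expression among expressing cells, with the fold taken on the
#' `expm1` scale; the raw-count analog is also reported for audit. Fold
#' criteria compare increases only by default; `symmetric_fold = TRUE`
#' accepts changes in either direction via `max(r, 1/r)`. When the baseline
#' fraction (or expression) is zero the corresponding fold criterion passes,
#' provided the floor criteria hold — a zero-to-positive jump is an increase.
#'
#' Subclusters without baseline cells yield records with `no_baseline = TRUE`
#' and no flag.
#'
#' @param counts Genes x cells raw count matrix.
#' @param norm Matching normalized (log1p CPM) matrix.
#' @param meta Cell metadata with `barcode`, `subcluster`, `timepoint`.
#' @param gene_set Genes to scan (absent genes are skipped).
#' @param params [g2da_params()] thresholds.
#' @param baseline Baseline time point label (default `"A"`).
#' @param post Post-vaccination labels (default all others, in order).
#' @param post_pool Pool post cells for criteria (1)-(2) (default `TRUE`).
#' @param symmetric_fold Use symmetric fold criteria (default `FALSE`).
#' @return `data.frame` with one row per (gene, subcluster): the flag
#'   (`"B"`, `"C"`, `"B&C"`, `"none"` for default post labels), fractional
#'   abundances, expressing-cell counts and means (raw and normalized) per
#'   time point, pooled post quantities, and per-criterion booleans.
#' @export
g2da_scan <- function(counts, norm, meta, gene_set, params = g2da_params(),
                      baseline = "A", post = NULL, post_pool = TRUE,
                      symmetric_fold = FALSE) {
  stopifnot(inherits(params, "g2da_params"))
  genes <- intersect(gene_set, rownames(counts))
  if (!length(genes)) stopf("no gene of the set is present in the matrix")
  tps <- unique(meta$timepoint)
  if (!baseline %in% tps) stopf("baseline time point '%s' absent", baseline)
  post <- post %||% sort(setdiff(tps, baseline))

  fold_ok <- function(ratio, thr) {
    if (symmetric_fold) pmax(ratio, 1 / ratio) >= thr else ratio >= thr
  }

  out <- list()
  for (sc in unique(meta$subcluster)) {
    bc_sc <- meta$barcode[meta$subcluster == sc]
    tp_of <- meta$timepoint[match(bc_sc, meta$barcode)]
    cells_tp <- split(bc_sc, factor(tp_of, levels = c(baseline, post)))
    nb <- length(cells_tp[[baseline]]) == 0L

    stat_tp <- lapply(cells_tp, function(cl) {
      if (!length(cl)) {
        z <- rep(NA_real_, length(genes))
        return(list(n = 0L, nexpr = rep(0, length(genes)), frac = z,
                    mean_raw = z, mean_norm = z))
      }
      cr <- counts[genes, cl, drop = FALSE]
      nr <- norm[genes, cl, drop = FALSE]
      nexpr <- Matrix::rowSums(cr > 0)
      sum_raw <- Matrix::rowSums(cr)
      en <- nr; en@x <- expm1(en@x)
      sum_norm <- Matrix::rowSums(en)
      list(n = length(cl), nexpr = nexpr, frac = nexpr / length(cl),
           mean_raw = ifelse(nexpr > 0, sum_raw / nexpr, NA_real_),
           mean_norm = ifelse(nexpr > 0, sum_norm / nexpr, NA_real_))
    })

    post_cells <- unlist(cells_tp[post], use.names = FALSE)
    if (length(post_cells)) {
      crp <- counts[genes, post_cells, drop = FALSE]
      nexpr_post <- Matrix::rowSums(crp > 0)
      mean_raw_post <- ifelse(nexpr_post > 0,
                              Matrix::rowSums(crp) / nexpr_post, NA_real_)
    } else {
      nexpr_post <- rep(0, length(genes)); mean_raw_post <- rep(NA_real_, length(genes))
    }

    rec <- data.frame(gene = genes, subcluster = sc, stringsAsFactors = FALSE)
    for (tp in c(baseline, post)) {
      s <- stat_tp[[tp]]
      rec[[paste0("n_cells_", tp)]] <- s$n
      rec[[paste0("n_expr_", tp)]] <- s$nexpr
      rec[[paste0("frac_", tp)]] <- s$frac
      rec[[paste0("mean_raw_", tp)]] <- s$mean_raw
      rec[[paste0("mean_norm_", tp)]] <- s$mean_norm
    }
    rec$n_expr_post <- nexpr_post
    rec$mean_raw_post <- mean_raw_post
    rec$no_baseline <- nb

    sA <- stat_tp[[baseline]]
    pass_pool_c1 <- nexpr_post >= params$min_cells
    pass_pool_c2 <- !is.na(mean_raw_post) & mean_raw_post >= params$min_mean_reads
    flagged_at <- rep("", length(genes))
    for (tp in post) {
      s <- stat_tp[[tp]]
      if (post_pool) {
        c1 <- pass_pool_c1; c2 <- pass_pool_c2
      } else {
        c1 <- s$nexpr >= params$min_cells
        c2 <- !is.na(s$mean_raw) & s$mean_raw >= params$min_mean_reads
      }
      c3 <- !is.na(s$frac) & s$frac >= params$min_frac
      c4 <- ifelse(is.na(s$frac), FALSE,
                   ifelse(sA$n == 0 | is.na(sA$frac), FALSE,
                          ifelse(sA$frac == 0, s$frac > 0,
                                 fold_ok(s$frac / sA$frac, params$fold_frac))))
      c5 <- ifelse(s$nexpr == 0, FALSE,
                   ifelse(is.na(sA$mean_norm), TRUE,
                          fold_ok(s$mean_norm / sA$mean_norm, params$fold_expr)))
      pass <- !nb & c1 & c2 & c3 & c4 & c5
      rec[[paste0("pass_c1_", tp)]] <- c1
      rec[[paste0("pass_c2_", tp)]] <- c2
      rec[[paste0("pass_c3_", tp)]] <- c3
      rec[[paste0("pass_c4_", tp)]] <- c4 & !nb
      rec[[paste0("pass_c5_", tp)]] <- c5 & !nb
      rec[[paste0("augmented_", tp)]] <- pass
      flagged_at <- ifelse(pass, ifelse(nzchar(flagged_at),
                                        paste0(flagged_at, "&", tp), tp),
                           flagged_at)
    }
    rec$flag <- ifelse(nzchar(flagged_at), flagged_at, "none")
    out[[sc]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stream-plot (stacked ribbon) data for augmented genes
#'
#' For every subcluster, augmented genes become ribbons whose thickness at
#' each time point equals the gene's fractional abundance there. Ribbons are
#' stacked deterministically: flag category first (time-B only, both, time-C
#' only), then gene name. Subclusters without augmented genes yield empty
#' panels.
#'
#' @param records Output of [g2da_scan()].
#' @param timepoints Ordered time point labels (default `c("A","B","C")`).
#' @return List with `ribbons` (`data.frame`: subcluster, gene, flag,
#'   timepoint, `frac`, `ymin`, `ymax`) and `totals` (stacked total per
#'   subcluster and time point).
#' @export
stream_plot_data <- function(records, timepoints = c("A", "B", "C")) {
  post <- setdiff(timepoints, timepoints[1])
  flag_levels <- c(post[1],
                   paste(post, collapse = "&"),
                   rev(post)[1])
  aug <- records[records$flag != "none", , drop = FALSE]
  ribbons <- list(); totals <- list()
  for (sc in unique(records$subcluster)) {
    a <- aug[aug$subcluster == sc, , drop = FALSE]
    if (nrow(a)) {
      ord <- order(match(a$flag, flag_levels), a$gene)
      a <- a[ord, , drop = FALSE]
      for (tp in timepoints) {
        fr <- a[[paste0("frac_", tp)]]
        fr[is.na(fr)] <- 0
        ymax <- cumsum(fr)
        ribbons[[length(ribbons) + 1L]] <- data.frame(
          subcluster = sc, gene = a$gene, flag = a$flag, timepoint = tp,
          frac = fr, ymin = ymax - fr, ymax = ymax, stringsAsFactors = FALSE)
        totals[[length(totals) + 1L]] <- data.frame(
          subcluster = sc, timepoint = tp, total = sum(fr),
          n_genes = nrow(a), stringsAsFactors = FALSE)
      }
    } else {
      for (tp in timepoints)
        totals[[length(totals) + 1L]] <- data.frame(
          subcluster = sc, timepoint = tp, total = 0, n_genes = 0L,
          stringsAsFactors = FALSE)
    }
  }
  list(ribbons = if (length(ribbons)) do.call(rbind, ribbons)
                 else data.frame(subcluster = character(), gene = character(),
                                 flag = character(), timepoint = character(),
                                 frac = numeric(), ymin = numeric(),
                                 ymax = numeric(), stringsAsFactors = FALSE),
       totals = do.call(rbind, totals))
}

#' Group augmented genes by expression pattern
#'
#' Each gene's feature vector is its average normalized expression per
#' (subcluster, time point), z-scaled per gene; genes are clustered by
#' agglomerative hierarchical clustering with correlation distance and
#' complete linkage, and the tree is cut at `k` groups. Deterministic for a
#' given input order. Genes with a constant profile (undefined correlation)
#' are placed at maximal distance from all others.
#'
#' @param norm Genes x cells normalized matrix.
#' @param meta Cell metadata with `barcode`, `subcluster`, `timepoint`.
#' @param genes Genes to group (e.g. the augmented set).
#' @param k Number of groups (default 9); must not exceed `length(genes)`.
#' @return Named integer vector gene -> group label (1..k).
#' @export
group_augmented_genes <- function(norm, meta, genes, k = 9) {
  genes <- intersect(genes, rownames(norm))
  if (k > length(genes))
    stopf("k (%d) exceeds the number of genes (%d)", k, length(genes))
  key <- interaction(meta$subcluster, meta$timepoint, drop = TRUE)
  cells_by <- split(meta$barcode, key)
  feat <- vapply(cells_by, function(cl)
    Matrix::rowMeans(norm[genes, cl, drop = FALSE]), numeric(length(genes)))
  feat <- matrix(feat, nrow = length(genes),
                 dimnames = list(genes, names(cells_by)))
  z <- t(scale(t(feat)))
  z[is.nan(z)] <- 0
  cr <- suppressWarnings(stats::cor(t(z)))
  cr[is.na(cr)] <- -1          # constant profiles: maximal distance
  diag(cr) <- 1
  d <- stats::as.dist(1 - cr)
  hc <- stats::hclust(d, method = "complete")
  stats::cutree(hc, k = k)
}
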