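#' Per-cell gene-set module score
#'
#' In the default binned-control mode, the score of a cell is the mean
#' normalized expression of the set genes minus the mean over control genes
#' drawn to match the set's expression profile: genes are binned into
#' `n_bins` bins of their population average expression, and for each set
#' gene `n_ctrl` controls are sampled (with replacement, seeded) from its
#' bin. A positive score means the set is expressed above what the cell's
#' background expression level predicts. The `"plain"` mode returns the mean
#' over set genes only.
#'
#' @param norm Genes x cells normalized matrix (log1p CPM).
#' @param gene_set Character vector of set genes; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins Number of average-expression bins (default 25; must be >= 2).
#' @param n_ctrl Controls sampled per set gene (default 100).
#' @param seed Seed for control sampling (default 0).
#' @param method `"binned"` (default) or `"plain"`.
#' @param score_name Score label attached to the output.
#' @return `data.frame` with `barcode`, `score_name`, `score`.
#' @export
module_score <- function(norm, gene_set, n_bins = 25, n_ctrl = 100, seed = 0,
                         method = c("binned", "plain"), score_name = "score") {
  method <- match.arg(method)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  present <- intersect(gene_set, rownames(norm))
  if (!length(present)) stopf("no gene of the set is present in the matrix")
  if (length(present) < length(gene_set))
    warnf("%d/%d set genes absent from the matrix; dropped",
          length(gene_set) - length(present), length(gene_set))

  set_mean <- col_sums_rows(norm, present) / length(present)
  if (method == "plain") {
    return(data.frame(barcode = colnames(norm), score_name = score_name,
                      score = as.numeric(set_mean), stringsAsFactors = FALSE))
  }

  gene_avg <- Matrix::rowMeans(norm)
  # rank-based binning: near-equal occupancy even with heavily tied means
  bins <- ceiling(rank(gene_avg, ties.method = "first") / length(gene_avg) * n_bins)
  bin_members <- split(rownames(norm), bins)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- bin_members[[as.character(bins[match(g, rownames(norm))])]]
    sample(pool, n_ctrl, replace = TRUE)
  }), use.names = FALSE)
  # controls keep multiplicity: average over all n_set * n_ctrl draws
  tab <- table(factor(ctrl, levels = rownames(norm)))
  w <- as.numeric(tab)
  ctrl_mean <- as.numeric(Matrix::crossprod(norm, w)) / sum(w)
  data.frame(barcode = colnames(norm), score_name = score_name,
             score = as.numeric(set_mean - ctrl_mean), stringsAsFactors = FALSE)
}

#' Compare per-cell scores between time points
#'
#' Welch two-sided t-tests of score distributions, per subcluster for each
#' consecutive time-point pair (`mode = "consecutive"`), or per (infant,
#' subcluster) pooling the post-vaccination time points against baseline
#' (`mode = "post_vs_baseline"`). Significance is flagged at unadjusted
#' p < `alpha`. Degenerate groups (fewer than 2 cells, or zero variance in
#' both groups) yield `testable = FALSE` rows rather than being dropped.
#'
#' @param scores Output of [module_score()].
#' @param meta Cell metadata with `barcode`, `subcluster`, `timepoint` (and
#'   `infant` for the post-vs-baseline mode).
#' @param mode `"consecutive"` or `"post_vs_baseline"`.
#' @param timepoints Ordered time point labels (default `c("A","B","C")`).
#' @param alpha Flagging level (default 0.05, unadjusted).
#' @return `data.frame` with one row per comparison: group keys, `n1`, `n2`,
#'   `t`, `p`, `mean_diff` (second minus first group), `significant`,
#'   `testable`.
#' @export
compare_scores <- function(scores, meta, mode = c("consecutive", "post_vs_baseline"),
                           timepoints = c("A", "B", "C"), alpha = 0.05) {
  mode <- match.arg(mode)
  df <- merge(scores, meta, by = "barcode")
  welch <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2 || (stats::var(x) == 0 && stats::var(y) == 0)) {
      return(list(t = NA_real_, p = NA_real_, testable = FALSE,
                  n1 = n1, n2 = n2, d = mean(y) - mean(x)))
    }
    tt <- stats::t.test(y, x, var.equal = FALSE)
    list(t = unname(tt$statistic), p = tt$p.value, testable = TRUE,
         n1 = n1, n2 = n2, d = mean(y) - mean(x))
  }
  out <- list()
  if (mode == "consecutive") {
    for (sc in unique(df$subcluster)) {
      d_sc <- df[df$subcluster == sc, ]
      for (i in seq_len(length(timepoints) - 1)) {
        t1 <- timepoints[i]; t2 <- timepoints[i + 1]
        r <- welch(d_sc$score[d_sc$timepoint == t1],
                   d_sc$score[d_sc$timepoint == t2])
        out[[length(out) + 1L]] <- data.frame(
          subcluster = sc, comparison = paste0(t1, "->", t2),
          n1 = r$n1, n2 = r$n2, t = r$t, p = r$p, mean_diff = r$d,
          significant = isTRUE(r$p < alpha), testable = r$testable,
          stringsAsFactors = FALSE)
      }
    }
  } else {
    base <- timepoints[1]; post <- timepoints[-1]
    for (inf in unique(df$infant)) {
      d_i <- df[df$infant == inf, ]
      for (sc in unique(d_i$subcluster)) {
        d_sc <- d_i[d_i$subcluster == sc, ]
        r <- welch(d_sc$score[d_sc$timepoint == base],
                   d_sc$score[d_sc$timepoint %in% post])
        out[[length(out) + 1L]] <- data.frame(
          infant = inf, subcluster = sc,
          comparison = paste0(base, "->", paste(post, collapse = "+")),
          n1 = r$n1, n2 = r$n2, t = r$t, p = r$p, mean_diff = r$d,
          significant = isTRUE(r$p < alpha), testable = r$testable,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
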