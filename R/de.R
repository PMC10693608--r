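#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p-values are computed whenever both groups have at most `exact_max`
#' observations, by convolving the rank multiset (a subset-sum dynamic
#' program over ranks, valid under ties); otherwise the normal approximation
#' with tie correction and continuity correction is used. The exact two-sided
#' p is `P(|W - E[W]| >= |w - E[W]|)` under uniformly random group
#' assignment, which reduces to the classical exact two-sided p when there
#' are no ties. A gene where every value is tied yields p = 1.
#'
#' @param x,y Numeric vectors (test and reference group).
#' @param exact_max Largest per-group size for the exact path (default 10).
#' @return Two-sided p-value.
#' @export
wilcox_rank_sum_p <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  if (max(n1, n2) <= exact_max) {
    return(exact_rank_sum_p(r, n1, w, mu))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

# Exact null distribution of the rank sum via convolution over the rank
# multiset: dp[k+1, s+1] counts size-k subsets with doubled-rank sum s.
exact_rank_sum_p <- function(r, n1, w, mu) {
  r2 <- as.integer(round(2 * r))        # half-ranks from ties become integers
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1) {
      shifted <- dp[k, ]
      idx <- which(shifted != 0)
      if (length(idx)) {
        tgt <- idx + v
        keep <- tgt <= smax + 1
        dp[k + 1, tgt[keep]] <- dp[k + 1, tgt[keep]] + shifted[idx[keep]]
      }
    }
  }
  counts <- dp[n1 + 1, ]
  sums <- (seq_along(counts) - 1) / 2
  dev <- abs(w - mu)
  tail <- sum(counts[abs(sums - mu) >= dev - 1e-9])
  tail / sum(counts)
}

#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Tests each gene between two cell groups of a normalized (log1p CPM)
#' matrix. Genes are tested when expressed (count > 0) in at least
#' `detect_frac` of the cells of at least one group. The log2 fold change is
#' `log2((mean(expm1(test)) + 1) / (mean(expm1(ref)) + 1))`, i.e. computed on
#' the CPM scale with a pseudocount of 1 — this convention keeps fold changes
#' finite and gates the sDEG rule, so it is stated prominently. P-values are
#' Benjamini-Hochberg adjusted across the tested genes of the comparison; the
#' sDEG flag is `|log2FC| > lfc_thresh` and adjusted p < `alpha`.
#'
#' @param norm Genes x cells normalized matrix (log1p CPM).
#' @param cells_test,cells_ref Barcode vectors of the two groups.
#' @param detect_frac Detection floor (default 0.10).
#' @param exact_max Exact-test size limit passed to [wilcox_rank_sum_p()].
#' @param alpha Adjusted-p threshold of the sDEG rule (default 0.05).
#' @param lfc_thresh Absolute log2FC threshold of the sDEG rule (default 0.25).
#' @return `data.frame` with `gene`, `n_test`, `n_ref`, `log2fc`, `p`,
#'   `p_adj`, `direction`, `sdeg`.
#' @export
rank_sum_de <- function(norm, cells_test, cells_ref, detect_frac = 0.10,
                        exact_max = 10, alpha = 0.05, lfc_thresh = 0.25) {
  if (!length(cells_test) || !length(cells_ref))
    stopf("both cell groups must be non-empty")
  mt <- norm[, cells_test, drop = FALSE]
  mr <- norm[, cells_ref, drop = FALSE]
  det_t <- Matrix::rowSums(mt > 0) / ncol(mt)
  det_r <- Matrix::rowSums(mr > 0) / ncol(mr)
  tested <- rownames(norm)[det_t >= detect_frac | det_r >= detect_frac]
  if (!length(tested))
    return(data.frame(gene = character(), n_test = integer(), n_ref = integer(),
                      log2fc = numeric(), p = numeric(), p_adj = numeric(),
                      direction = character(), sdeg = logical(),
                      stringsAsFactors = FALSE))
  xt <- as.matrix(mt[tested, , drop = FALSE])
  xr <- as.matrix(mr[tested, , drop = FALSE])
  p <- vapply(seq_along(tested), function(i)
    wilcox_rank_sum_p(xt[i, ], xr[i, ], exact_max = exact_max), numeric(1))
  lfc <- log2((rowMeans(expm1(xt)) + 1) / (rowMeans(expm1(xr)) + 1))
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = tested, n_test = ncol(xt), n_ref = ncol(xr),
             log2fc = as.numeric(lfc), p = p, p_adj = padj,
             direction = ifelse(lfc >= 0, "up", "down"),
             sdeg = abs(lfc) > lfc_thresh & padj < alpha,
             stringsAsFactors = FALSE)
}

#' Marker genes of one label versus all remaining cells
#'
#' One-vs-rest [rank_sum_de()], filtered to sDEGs upregulated in the target
#' label and ranked by decreasing log2 fold change.
#'
#' @param norm Genes x cells normalized matrix.
#' @param labels Character vector of cell labels aligned to columns.
#' @param target_label Label whose markers are sought (needs >= 3 cells).
#' @param top_n Maximum markers returned (default 15).
#' @param ... Passed to [rank_sum_de()].
#' @return `data.frame` of up to `top_n` marker rows.
#' @export
find_markers <- function(norm, labels, target_label, top_n = 15, ...) {
  if (!target_label %in% labels) stopf("label '%s' absent", target_label)
  cells_t <- colnames(norm)[labels == target_label]
  if (length(cells_t) < 3) stopf("label '%s' has fewer than 3 cells", target_label)
  cells_r <- colnames(norm)[labels != target_label]
  de <- rank_sum_de(norm, cells_t, cells_r, ...)
  up <- de[de$sdeg & de$direction == "up", , drop = FALSE]
  up <- up[order(-up$log2fc), , drop = FALSE]
  utils::head(up, top_n)
}

#' Overlap enrichment between two gene sets
#'
#' Builds the 2x2 membership table over a finite universe and reports the
#' Fisher exact two-sided p-value, the sample (cross-product) odds ratio and
#' the Jaccard index.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector defining the background.
#' @return One-row `data.frame`: sizes, `overlap`, `universe_size`, `p`,
#'   `odds_ratio`, `jaccard`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  if (!length(universe)) stopf("universe is empty")
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stopf("set gene(s) outside the universe: %s",
          paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  a <- unique(set_a); b <- unique(set_b)
  k <- length(intersect(a, b))
  a_only <- length(a) - k
  b_only <- length(b) - k
  neither <- length(universe) - k - a_only - b_only
  tab <- matrix(c(k, a_only, b_only, neither), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  orat <- if (a_only * b_only == 0) {
    if (k * neither == 0) NaN else Inf
  } else (k * neither) / (a_only * b_only)
  uni_ab <- k + a_only + b_only
  data.frame(size_a = length(a), size_b = length(b), overlap = k,
             universe_size = length(universe), p = p, odds_ratio = orat,
             jaccard = if (uni_ab == 0) 0 else k / uni_ab,
             stringsAsFactors = FALSE)
}
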