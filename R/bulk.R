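#' Bulk differential expression across study days
#'
#' Per-probe Kruskal-Wallis test across the day groups on log2 intensities,
#' Benjamini-Hochberg adjusted across probes. The fold change of a probe is
#' the largest deviation of a post-baseline day's group mean from the
#' baseline-day mean, measured as `max(ratio, 1/ratio)` of linear-scale
#' means. A probe is differentially expressed when adjusted p < `alpha` and
#' fold change > `fc_thresh`. When only two day groups are present the test
#' reduces to a rank-sum-equivalent two-group decision.
#'
#' @param exprs Probes x samples positive intensity matrix.
#' @param samples `data.frame` with `sample`, `day`.
#' @param baseline_day Baseline group label (default `"0"`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param fc_thresh Fold-change threshold (default 1.5).
#' @return `data.frame` with `probe`, `H`, `p`, `p_adj`, `fold_change`,
#'   `direction_day7`-style per-day directions, `de` flag.
#' @export
bulk_de <- function(exprs, samples, baseline_day = "0", alpha = 0.05,
                    fc_thresh = 1.5) {
  days <- unique(as.character(samples$day))
  if (!baseline_day %in% days) stopf("baseline day '%s' missing", baseline_day)
  if (length(days) < 2) stopf("need at least two day groups")
  grp <- factor(as.character(samples$day)[match(colnames(exprs), samples$sample)],
                levels = days)
  if (anyNA(grp)) stopf("day label missing for some samples")
  lx <- log2(exprs)
  kw <- apply(lx, 1, function(v) {
    k <- stats::kruskal.test(v, grp)
    c(H = unname(k$statistic), p = k$p.value)
  })
  means <- vapply(days, function(d)
    rowMeans(exprs[, grp == d, drop = FALSE]), numeric(nrow(exprs)))
  post <- setdiff(days, baseline_day)
  ratios <- means[, post, drop = FALSE] / means[, baseline_day]
  fold <- apply(pmax(ratios, 1 / ratios), 1, max)
  res <- data.frame(probe = rownames(exprs), H = kw["H", ], p = kw["p", ],
                    p_adj = stats::p.adjust(kw["p", ], "BH"),
                    fold_change = fold, stringsAsFactors = FALSE)
  for (d in post)
    res[[paste0("direction_day", d)]] <- ifelse(ratios[, d] >= 1, "up", "down")
  res$de <- res$p_adj < alpha & res$fold_change > fc_thresh
  rownames(res) <- NULL
  res
}

#' Modular transcriptional fingerprint
#'
#' For each module and post-baseline day, every module probe present in the
#' matrix is tested against baseline with a two-sided rank-sum test
#' (unadjusted p < `alpha`) and a linear-scale mean fold change > `fc_thresh`.
#' The fingerprint entry reports the percentage of module probes significantly
#' over- and under-expressed (probes absent from the matrix are excluded from
#' the denominator), and the dominant direction.
#'
#' @param exprs Probes x samples positive intensity matrix.
#' @param samples `data.frame` with `sample`, `day`.
#' @param modules Named list of probe/gene-id vectors.
#' @param baseline_day Baseline group (default `"0"`).
#' @param alpha Unadjusted per-gene p threshold (default 0.05).
#' @param fc_thresh Per-gene fold-change threshold (default 1.5).
#' @return `data.frame` with `module`, `day`, `n_genes`, `percent_up`,
#'   `percent_down`, `dominant`, `evaluable`.
#' @export
module_fingerprint <- function(exprs, samples, modules, baseline_day = "0",
                               alpha = 0.05, fc_thresh = 1.5) {
  if (!length(modules)) stopf("modules must be non-empty")
  grp <- as.character(samples$day)[match(colnames(exprs), samples$sample)]
  post <- setdiff(unique(grp), baseline_day)
  base_cols <- which(grp == baseline_day)
  out <- list()
  for (mod in names(modules)) {
    present <- intersect(modules[[mod]], rownames(exprs))
    for (d in post) {
      d_cols <- which(grp == d)
      if (!length(present)) {
        out[[length(out) + 1L]] <- data.frame(
          module = mod, day = d, n_genes = 0L, percent_up = NA_real_,
          percent_down = NA_real_, dominant = NA_character_,
          evaluable = FALSE, stringsAsFactors = FALSE)
        next
      }
      up <- 0L; down <- 0L
      for (g in present) {
        xb <- exprs[g, base_cols]; xd <- exprs[g, d_cols]
        pv <- wilcox_rank_sum_p(xd, xb)
        ratio <- mean(xd) / mean(xb)
        if (pv < alpha && max(ratio, 1 / ratio) > fc_thresh) {
          if (ratio >= 1) up <- up + 1L else down <- down + 1L
        }
      }
      pu <- 100 * up / length(present); pd <- 100 * down / length(present)
      out[[length(out) + 1L]] <- data.frame(
        module = mod, day = d, n_genes = length(present),
        percent_up = pu, percent_down = pd,
        dominant = if (pu == 0 && pd == 0) "none" else if (pu >= pd) "up" else "down",
        evaluable = TRUE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
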