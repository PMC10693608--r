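#' Per-infant subcluster frequencies over time
#'
#' For every (infant, time point), the fraction of that sample's cells in
#' each subcluster (fractions sum to 1 over subclusters), plus the relative
#' change versus baseline, `fraction_t / fraction_baseline - 1`, so that "no
#' change" is 0. A zero baseline fraction makes the relative change
#' undefined (`NA`, flagged); an infant missing a time point yields rows
#' with `missing = TRUE` and `NA` fractions.
#'
#' @param meta Cell metadata with `barcode`, `infant`, `timepoint`,
#'   `subcluster`.
#' @param timepoints Ordered time point labels (default `c("A","B","C")`);
#'   the first is the baseline.
#' @return `data.frame` with `infant`, `timepoint`, `subcluster`, `n_cells`,
#'   `fraction`, `rel_change`, `rel_change_defined`, `missing`.
#' @export
cell_frequencies <- function(meta, timepoints = c("A", "B", "C")) {
  baseline <- timepoints[1]
  scs <- sort(unique(meta$subcluster))
  out <- list()
  for (inf in unique(meta$infant)) {
    d_i <- meta[meta$infant == inf, , drop = FALSE]
    frac_tp <- list()
    for (tp in timepoints) {
      d <- d_i[d_i$timepoint == tp, , drop = FALSE]
      n_tot <- nrow(d)
      n_sc <- table(factor(d$subcluster, levels = scs))
      frac <- if (n_tot > 0) as.numeric(n_sc) / n_tot else rep(NA_real_, length(scs))
      frac_tp[[tp]] <- frac
      out[[length(out) + 1L]] <- data.frame(
        infant = inf, timepoint = tp, subcluster = scs,
        n_cells = as.integer(n_sc), fraction = frac,
        missing = n_tot == 0, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  base <- res[res$timepoint == baseline, c("infant", "subcluster", "fraction")]
  names(base)[3] <- "base_fraction"
  res <- merge(res, base, by = c("infant", "subcluster"), sort = FALSE)
  res$rel_change_defined <- !is.na(res$base_fraction) & res$base_fraction > 0 &
    !is.na(res$fraction)
  res$rel_change <- ifelse(res$rel_change_defined,
                           res$fraction / res$base_fraction - 1, NA_real_)
  res$rel_change[res$timepoint == baseline & res$rel_change_defined] <- 0
  res$base_fraction <- NULL
  res <- res[order(res$infant, match(res$timepoint, timepoints), res$subcluster), ]
  rownames(res) <- NULL
  res
}

#' Associate cell frequencies and interferon scores with responder class
#'
#' Produces heatmap-ready per-infant summaries: subcluster frequencies and
#' mean module scores per (infant, subcluster, time point), each annotated
#' with the infant's responder class, plus per-(infant, subcluster) Welch
#' t-tests of post-vaccination scores versus baseline — pooled over the post
#' time points, and additionally per individual post time point. Flags use
#' unadjusted p < `alpha`. Infants present in the frequency table but
#' without scores are excluded with a warning.
#'
#' @param freq Output of [cell_frequencies()].
#' @param scores Output of [module_score()] (e.g. the interferon score).
#' @param meta Cell metadata with `barcode`, `infant`, `subcluster`,
#'   `timepoint`.
#' @param responders Output of [rank_responders()] (`infant`, `class`).
#' @param timepoints Ordered labels, baseline first (default `c("A","B","C")`).
#' @param alpha Flagging level (default 0.05, unadjusted).
#' @return List with `frequencies` (freq rows + `class`), `mean_scores`
#'   (per infant x subcluster x time point + `class`), and `tests` (pooled
#'   and per-time-point post-vs-baseline results with `significant`,
#'   `testable`).
#' @export
response_association <- function(freq, scores, meta, responders,
                                 timepoints = c("A", "B", "C"), alpha = 0.05) {
  cls <- stats::setNames(responders$class, responders$infant)
  df <- merge(scores, meta[c("barcode", "infant", "subcluster", "timepoint")],
              by = "barcode")
  no_scores <- setdiff(unique(freq$infant), unique(df$infant))
  if (length(no_scores))
    warnf("no scores for infant(s) %s; excluded from association",
          paste(no_scores, collapse = ", "))

  agg <- stats::aggregate(score ~ infant + subcluster + timepoint, df, mean)
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg$class <- unname(cls[agg$infant])

  base <- timepoints[1]; post <- timepoints[-1]
  tests <- list()
  run_test <- function(x, y) {
    if (length(x) < 2 || length(y) < 2 ||
        (stats::var(x) == 0 && stats::var(y) == 0))
      return(list(p = NA_real_, testable = FALSE, d = mean(y) - mean(x)))
    tt <- stats::t.test(y, x, var.equal = FALSE)
    list(p = tt$p.value, testable = TRUE, d = mean(y) - mean(x))
  }
  for (inf in unique(df$infant)) {
    d_i <- df[df$infant == inf, , drop = FALSE]
    for (sc in unique(d_i$subcluster)) {
      d_sc <- d_i[d_i$subcluster == sc, , drop = FALSE]
      x <- d_sc$score[d_sc$timepoint == base]
      comparisons <- c(list(pooled = post), as.list(stats::setNames(post, post)))
      for (cname in names(comparisons)) {
        y <- d_sc$score[d_sc$timepoint %in% comparisons[[cname]]]
        r <- run_test(x, y)
        tests[[length(tests) + 1L]] <- data.frame(
          infant = inf, subcluster = sc,
          comparison = if (cname == "pooled")
            paste0(base, "->", paste(post, collapse = "+"))
          else paste0(base, "->", cname),
          pooled = cname == "pooled", n_base = length(x), n_post = length(y),
          mean_diff = r$d, p = r$p,
          significant = isTRUE(r$p < alpha), testable = r$testable,
          class = unname(cls[inf]), stringsAsFactors = FALSE)
      }
    }
  }
  freq_out <- freq[freq$infant %in% unique(df$infant), , drop = FALSE]
  freq_out$class <- unname(cls[freq_out$infant])
  list(frequencies = freq_out, mean_scores = agg,
       tests = do.call(rbind, tests))
}
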