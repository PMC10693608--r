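#' Simulate a longitudinal single-cell UMI count matrix
#'
#' Generates a genes x cells sparse integer matrix for `n_infants` infants at
#' every time point, with cell metadata (infant, time point, batch, cell type,
#' subcluster, doublet score) and the planted ground truth. Background genes
#' are negative binomial with log-normal baseline means; each subcluster gets
#' dedicated boosted marker genes; interferon-set genes follow a hurdle model
#' (see [sim_config()]) so that induction at time B raises both the fraction
#' of expressing cells and the expression level among them. Batches map one
#' infant per batch, mirroring a design where all time points of a child are
#' processed together.
#'
#' @param config A [sim_config()] object.
#' @return List with `counts`, `meta`, `gene_sets` (ISG/INFLM/CTX lists), and
#'   `truth`: `induced_genes` (`data.frame` subcluster x timepoint x gene for
#'   every fold >= `effect_threshold`), `infant_folds`, `responder_classes`,
#'   `markers` (per-subcluster planted markers), and the program parameters.
#' @export
simulate_sc_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  infants <- names(cfg$responder_classes)
  tps <- cfg$timepoints
  ss <- cfg$subcluster_spec
  n_sc <- nrow(ss)

  # --- gene universe -------------------------------------------------------
  n_mito <- 10L
  n_mark <- cfg$marker_genes_per_sc * n_sc
  isg  <- sprintf("ISG%03d", seq_len(cfg$isg_set_size))
  infl <- sprintf("INF%03d", seq_len(cfg$inflm_set_size))
  ctx  <- sprintf("CTX%03d", seq_len(cfg$ctx_set_size))
  mito <- sprintf("MT-G%02d", seq_len(n_mito))
  mark <- as.vector(vapply(seq_len(n_sc), function(i)
    sprintf("MRK_%s_%02d", ss$subcluster[i], seq_len(cfg$marker_genes_per_sc)),
    character(cfg$marker_genes_per_sc)))
  n_bg <- cfg$n_genes - length(isg) - length(infl) - length(ctx) -
    n_mito - length(mark)
  bg <- sprintf("BG%04d", seq_len(n_bg))
  genes <- c(isg, infl, ctx, mark, mito, bg)

  # baseline NB means for everything but the interferon program genes
  base_mu <- stats::setNames(
    stats::rlnorm(length(genes), cfg$baseline_mean_logdist[[1]],
                  cfg$baseline_mean_logdist[[2]]), genes)
  base_mu[mito] <- base_mu[mito] * 0.5

  # hurdle parameters for interferon program genes
  prog_pi <- stats::setNames(
    stats::runif(length(isg), cfg$program_pi_range[1], cfg$program_pi_range[2]), isg)
  prog_mu <- stats::setNames(
    stats::rlnorm(length(isg), cfg$program_mean_logdist[[1]],
                  cfg$program_mean_logdist[[2]]), isg)

  n_induced <- round(cfg$frac_induced * length(isg))
  induced <- if (n_induced > 0) sort(sample(isg, n_induced)) else character()

  marker_rows <- split(mark, rep(ss$subcluster, each = cfg$marker_genes_per_sc))

  # --- cells ---------------------------------------------------------------
  blocks <- list(); metas <- list()
  isg_idx <- match(isg, genes)
  other_idx <- setdiff(seq_along(genes), isg_idx)
  sqrt_fold_vec <- function(fold) {
    s <- rep(1, length(isg))
    s[isg %in% induced] <- sqrt(fold)
    s
  }

  for (inf in infants) {
    for (tp in tps) {
      n <- cfg$n_cells_per_sample
      frac <- ss[[paste0("fraction_", tp)]]
      sc_cells <- sample(ss$subcluster, n, replace = TRUE, prob = frac)
      lib <- stats::rlnorm(n, cfg$libsize_logdist[[1]], cfg$libsize_logdist[[2]])
      fold <- induction_fold_for(cfg, inf, tp)
      sf <- sqrt_fold_vec(fold)

      m <- matrix(0, nrow = length(genes), ncol = n)
      # background / set / marker / mito genes: plain NB
      mu_bg <- outer(base_mu[other_idx], lib)
      for (s in names(marker_rows)) {
        idx_cells <- which(sc_cells == s)
        if (length(idx_cells)) {
          ridx <- match(marker_rows[[s]], genes[other_idx])
          mu_bg[ridx, idx_cells] <- mu_bg[ridx, idx_cells] * cfg$marker_fold
        }
      }
      m[other_idx, ] <- stats::rnbinom(length(mu_bg), mu = mu_bg,
                                       size = cfg$dispersion)
      # interferon program genes: Bernoulli(on) x NB(on-mean)
      pi_eff <- pmin(prog_pi * sf, 0.98)
      on <- matrix(stats::rbinom(length(isg) * n, 1L, rep(pi_eff, n)),
                   nrow = length(isg))
      mu_on <- outer(prog_mu * sf, lib)
      m[isg_idx, ] <- on * stats::rnbinom(length(mu_on), mu = mu_on,
                                          size = cfg$program_dispersion)

      barcodes <- sprintf("%s_%s_c%04d", inf, tp, seq_len(n))
      dimnames(m) <- list(genes, barcodes)
      blocks[[paste(inf, tp)]] <- Matrix::Matrix(m, sparse = TRUE)
      metas[[paste(inf, tp)]] <- data.frame(
        barcode = barcodes, infant = inf, timepoint = tp,
        batch = paste0("batch_", inf),
        cell_type = ss$cell_type[match(sc_cells, ss$subcluster)],
        subcluster = sc_cells,
        doublet_score = stats::rbeta(n, 1, cfg$doublet_beta),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL

  # --- ground truth --------------------------------------------------------
  tp_fold <- vapply(tps, function(tp)
    max(vapply(infants, induction_fold_for, numeric(1), cfg = cfg, timepoint = tp)),
    numeric(1))
  gt_rows <- list()
  for (tp in tps) {
    if (tp_fold[[tp]] >= cfg$effect_threshold && length(induced)) {
      gt_rows[[tp]] <- expand.grid(subcluster = ss$subcluster, timepoint = tp,
                                   gene = induced, stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE)
    }
  }
  induced_df <- if (length(gt_rows)) do.call(rbind, gt_rows)
                else data.frame(subcluster = character(), timepoint = character(),
                                gene = character(), stringsAsFactors = FALSE)
  rownames(induced_df) <- NULL
  infant_folds <- do.call(rbind, lapply(infants, function(inf) data.frame(
    infant = inf, class = unname(cfg$responder_classes[[inf]]),
    fold_B = induction_fold_for(cfg, inf, "B"),
    fold_C = if ("C" %in% tps) induction_fold_for(cfg, inf, "C") else NA_real_,
    stringsAsFactors = FALSE)))

  list(counts = counts, meta = meta,
       gene_sets = list(ISG = isg, INFLM = infl, CTX = ctx),
       truth = list(induced_genes = induced_df,
                    induced_set = induced,
                    infant_folds = infant_folds,
                    responder_classes = as.list(cfg$responder_classes),
                    markers = marker_rows,
                    program_pi = prog_pi, program_mu = prog_mu))
}

#' Simulate a bulk probe-level expression matrix across study days
#'
#' Probes x samples positive intensities with log-normal noise around group
#' means. Probes are organized into named modules; `bulk_effect_spec` plants
#' multiplicative shifts on a module's probes at a given day relative to day
#' 0. Samples per day follow `bulk_samples_per_day`.
#'
#' @param config A [sim_config()] object.
#' @return List with `exprs` (probes x samples), `samples` (`data.frame` of
#'   `sample`, `day`), `modules` (named list of probe ids), and `truth`
#'   (`data.frame` module x day x fold for every planted fold deviating from 1
#'   by at least `effect_threshold` in either direction, plus shifted probes).
#' @export
simulate_bulk_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)

  module_names <- unique(c(cfg$bulk_effect_spec$module,
                           c("M1.2", "M3.4", "M5.12", "M3.2", "M4.2",
                             "M4.11", "M4.10", "M4.1")))
  n_mod <- length(module_names)
  need <- n_mod * cfg$bulk_module_size
  if (cfg$bulk_n_probes <= need)
    stopf("bulk_n_probes (%d) must exceed module probes (%d)",
          cfg$bulk_n_probes, need)
  probes <- sprintf("P%05d", seq_len(cfg$bulk_n_probes))
  modules <- stats::setNames(
    split(probes[seq_len(need)], rep(module_names, each = cfg$bulk_module_size)),
    module_names)[module_names]

  days <- names(cfg$bulk_samples_per_day)
  samples <- do.call(rbind, lapply(days, function(d) data.frame(
    sample = sprintf("S_d%s_%02d", d, seq_len(cfg$bulk_samples_per_day[[d]])),
    day = d, stringsAsFactors = FALSE)))

  base_log2 <- stats::runif(length(probes), 6, 12)
  names(base_log2) <- probes
  shift_log2 <- matrix(0, length(probes), length(days),
                       dimnames = list(probes, days))
  es <- cfg$bulk_effect_spec
  for (i in seq_len(nrow(es))) {
    pm <- modules[[es$module[i]]]
    shift_log2[pm, es$day[i]] <- log2(es$fold[i])
  }
  exprs <- matrix(0, length(probes), nrow(samples),
                  dimnames = list(probes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- base_log2 + shift_log2[, samples$day[j]]
    exprs[, j] <- 2^(mu + stats::rnorm(length(probes), 0, cfg$bulk_noise_sd))
  }

  eff <- es[pmax(es$fold, 1 / es$fold) >= cfg$effect_threshold, , drop = FALSE]
  truth <- list(
    effects = eff,
    shifted_probes = stats::setNames(
      lapply(seq_len(nrow(eff)), function(i) modules[[eff$module[i]]]),
      paste(eff$module, eff$day, sep = "@")))
  list(exprs = exprs, samples = samples, modules = modules, truth = truth)
}

#' Simulate pre/post serology titers for the cohort
#'
#' For each infant and antigen, draws a log-normal baseline (pre) titer and a
#' post titer `post = pre * fold`. Whether an antigen responds is Bernoulli
#' with the per-class `respond_prob` of its vaccine; responding antigens draw
#' their fold from the class fold distribution, non-responding antigens from a
#' tight distribution around 1. Titers are positive by construction.
#'
#' @param config A [sim_config()] object (uses `serology_spec` and
#'   `responder_classes`).
#' @return List with `titers` (long `data.frame` in the standard serology
#'   columns) and `truth` (per infant x antigen drawn response flag and fold,
#'   plus responder classes).
#' @export
simulate_serology <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 2L)
  infants <- names(cfg$responder_classes)
  spec <- cfg$serology_spec
  if (!length(spec)) stopf("serology_spec is empty")

  rows <- list(); truth_rows <- list()
  for (inf in infants) {
    cls <- cfg$responder_classes[[inf]]
    for (vx in names(spec)) {
      sp <- spec[[vx]]
      if (is.null(sp$fold_dist[[cls]]))
        stopf("serology_spec for '%s' lacks fold distribution for class '%s'", vx, cls)
      for (ag in sp$antigens) {
        pre <- stats::rlnorm(1, sp$baseline_logdist[[1]], sp$baseline_logdist[[2]])
        responds <- stats::runif(1) < sp$respond_prob[[cls]]
        fd <- sp$fold_dist[[cls]]
        fold <- if (responds) stats::rlnorm(1, fd[1], fd[2])
                else stats::rlnorm(1, 0, 0.05)
        post <- pre * fold
        rows[[length(rows) + 1L]] <- data.frame(
          infant = inf, vaccine = vx, antigen = ag,
          timepoint = c("pre", "post"), value = c(pre, post),
          units = sp$units, stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          infant = inf, vaccine = vx, antigen = ag, class = cls,
          responds = responds, fold = fold, stringsAsFactors = FALSE)
      }
    }
  }
  titers <- do.call(rbind, rows); rownames(titers) <- NULL
  truth <- do.call(rbind, truth_rows); rownames(truth) <- NULL
  list(titers = titers,
       truth = list(antigen_response = truth,
                    responder_classes = as.list(cfg$responder_classes)))
}
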