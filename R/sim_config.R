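#' Default subcluster composition for the synthetic cohort
#'
#' Six subclusters across four major cell types with fixed expected fractions
#' per time point (fractions sum to 1). Kept deliberately small so every
#' subcluster retains enough cells per time point for fraction-based criteria
#' at desk scale.
#' @return `data.frame` with `cell_type`, `subcluster`, `fraction`.
#' @export
default_subcluster_spec <- function() {
  data.frame(
    cell_type  = c("CD4_T", "CD4_T", "CD8_T", "B", "Mono", "NK"),
    subcluster = c("CD4_T_naive", "CD4_T_ISGhi", "CD8_T_naive",
                   "B_naive", "CD14_Mono", "CD16_NK"),
    fraction   = c(0.30, 0.10, 0.15, 0.15, 0.15, 0.15),
    stringsAsFactors = FALSE)
}

#' Default serology assay specification
#'
#' One entry per vaccine: antigen names, unit string, seropositivity cut-off,
#' a log-normal baseline titer distribution, per-responder-class log-normal
#' fold-response distributions `(meanlog, sdlog)`, and for multi-antigen
#' vaccines a per-class probability that a given antigen responds at all.
#' Baselines and folds emulate a 2-month-old priming cohort: a uniform strong
#' booster response to hepatitis B, pre-existing maternally derived tetanus
#' antibody that does not rise, and heterogeneous pneumococcal conjugate
#' responses whose breadth tracks responder class.
#' @return Named list of per-vaccine specifications.
#' @export
default_serology_spec <- function() {
  list(
    HepB = list(
      antigens = "HBsAg", units = "mIU/mL", cutoff = 0.8,
      baseline_logdist = c(meanlog = log(0.3), sdlog = 0.4),
      fold_dist = list(Best = c(log(40), 0.30), Good = c(log(25), 0.30),
                       Weak = c(log(15), 0.30)),
      respond_prob = c(Best = 1, Good = 1, Weak = 1)),
    Diphtheria = list(
      antigens = "DTxd", units = "IU/mL", cutoff = 0.01,
      baseline_logdist = c(meanlog = log(0.008), sdlog = 0.3),
      fold_dist = list(Best = c(log(2.2), 0.10), Good = c(log(1.1), 0.10),
                       Weak = c(log(1.0), 0.10)),
      respond_prob = c(Best = 1, Good = 0, Weak = 0)),
    Tetanus = list(
      antigens = "Ttx", units = "IU/mL", cutoff = 0.01,
      baseline_logdist = c(meanlog = log(0.4), sdlog = 0.3),
      fold_dist = list(Best = c(log(1.0), 0.05), Good = c(log(1.0), 0.05),
                       Weak = c(log(1.0), 0.05)),
      respond_prob = c(Best = 0, Good = 0, Weak = 0)),
    PCV13 = list(
      antigens = paste0("Ps", c(1, 3, 4, 5, "6a", "6b", "7f", "9v",
                                14, "18c", "19a", "19f", "23f")),
      units = "ug/mL", cutoff = 0.35,
      baseline_logdist = c(meanlog = log(0.08), sdlog = 0.5),
      fold_dist = list(Best = c(log(8), 0.30), Good = c(log(6), 0.30),
                       Weak = c(log(5), 0.30)),
      respond_prob = c(Best = 0.75, Good = 0.15, Weak = 0.03)),
    Rotavirus = list(
      antigens = "RV_IgA", units = "U/mL", cutoff = 20,
      baseline_logdist = c(meanlog = log(4), sdlog = 0.4),
      fold_dist = list(Best = c(log(15), 0.30), Good = c(log(12), 0.30),
                       Weak = c(log(8), 0.30)),
      respond_prob = c(Best = 1, Good = 1, Weak = 0.6)))
}

#' Simulation configuration
#'
#' Bundles every knob of the three generators ([simulate_sc_counts()],
#' [simulate_bulk_expression()], [simulate_serology()]) with validation.
#' Defaults describe a six-infant cohort sampled pre-vaccination (A), about
#' one week (B) and one month (C) post-vaccination, with a transient
#' interferon program induced at B whose strength depends on responder class
#' and which has decayed by C.
#'
#' Counts are gamma-Poisson (negative binomial) with log-normal per-gene
#' baseline means and log-normal cell library-size factors; interferon-program
#' genes follow a hurdle model (a per-cell Bernoulli "program on" indicator
#' times a negative binomial for expressing cells), so induction raises both
#' the fraction of expressing cells and the expression level among them. An
#' induction fold `F` multiplies the on-probability and the on-mean by
#' `sqrt(F)` each, leaving the pooled mean multiplied by exactly `F`.
#'
#' @param n_infants Number of infants (default 6).
#' @param timepoints Ordered time point labels (default `c("A","B","C")`).
#' @param subcluster_spec `data.frame` with `cell_type`, `subcluster` and
#'   either a single `fraction` column or one `fraction_<tp>` column per time
#'   point; fractions must sum to 1 per time point.
#' @param n_genes Total genes simulated, including set genes and markers.
#' @param n_cells_per_sample Cells per (infant, time point) sample.
#' @param baseline_mean_logdist `(meanlog, sdlog)` of background gene means.
#' @param dispersion Negative-binomial size for background genes.
#' @param libsize_logdist `(meanlog, sdlog)` of cell library-size factors.
#' @param isg_set_size,inflm_set_size,ctx_set_size Sizes of the interferon,
#'   inflammation and cytotoxicity gene sets (defaults 137, 334, 105).
#' @param program_pi_range Range of the per-gene baseline on-probability for
#'   interferon-program genes.
#' @param program_mean_logdist `(meanlog, sdlog)` of the on-cell mean for
#'   program genes.
#' @param program_dispersion NB size for on-cells of program genes.
#' @param induction_fold_B Multiplicative induction fold at time B: a single
#'   number applied to every infant, or a named vector per responder class
#'   (default `c(Best = 3, Good = 2, Weak = 1.3)`).
#' @param induction_fold_C Residual fold at time C (default 1: full decay).
#' @param frac_induced Fraction of interferon-set genes actually induced.
#' @param responder_classes Named character vector infant -> class.
#' @param effect_threshold Minimum fold counted as a planted effect in the
#'   ground truth (default 1.5).
#' @param marker_genes_per_sc,marker_fold Per-subcluster marker genes and
#'   their boost fold.
#' @param doublet_beta Shape2 of the Beta(1, shape2) doublet-score draw.
#' @param bulk_n_probes,bulk_samples_per_day,bulk_noise_sd,bulk_module_size
#'   Bulk generator: probe count, samples per day (named by day), log2-scale
#'   noise SD, genes per module.
#' @param bulk_effect_spec `data.frame(module, day, fold)` of planted bulk
#'   module shifts; the default induces interferon/inflammation modules 1.8x
#'   at day 7 (decayed by day 30) and a plasma-cell module 1.6x at day 30.
#' @param serology_spec Per-vaccine assay spec; see [default_serology_spec()].
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_infants = 6,
                       timepoints = c("A", "B", "C"),
                       subcluster_spec = default_subcluster_spec(),
                       n_genes = 2000,
                       n_cells_per_sample = 400,
                       baseline_mean_logdist = c(meanlog = log(4), sdlog = 1),
                       dispersion = 1,
                       libsize_logdist = c(meanlog = 0, sdlog = 0.3),
                       isg_set_size = 137,
                       inflm_set_size = 334,
                       ctx_set_size = 105,
                       program_pi_range = c(0.10, 0.30),
                       program_mean_logdist = c(meanlog = log(60), sdlog = 0.25),
                       program_dispersion = 2,
                       induction_fold_B = c(Best = 3, Good = 2, Weak = 1.3),
                       induction_fold_C = 1,
                       frac_induced = 79 / 137,
                       responder_classes = NULL,
                       effect_threshold = 1.5,
                       marker_genes_per_sc = 5,
                       marker_fold = 4,
                       doublet_beta = 15,
                       bulk_n_probes = 1200,
                       bulk_samples_per_day = c("0" = 24, "7" = 23, "30" = 21),
                       bulk_noise_sd = 0.35,
                       bulk_module_size = 30,
                       bulk_effect_spec = NULL,
                       serology_spec = default_serology_spec(),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_infants <- check_count(n_infants, "n_infants")
  cfg$n_genes <- check_count(n_genes, "n_genes")
  cfg$n_cells_per_sample <- check_count(n_cells_per_sample, "n_cells_per_sample")
  cfg$seed <- check_count(seed, "seed", min = 0L)
  infants <- paste0("I", seq_len(cfg$n_infants))
  if (is.null(responder_classes)) {
    # six-infant default mirrors the emulated cohort: one best responder,
    # two good, three weak (the unclassified infant is treated as weak)
    responder_classes <- if (cfg$n_infants == 6) {
      stats::setNames(c("Good", "Good", "Weak", "Weak", "Weak", "Best"), infants)
    } else {
      stats::setNames(rep(c("Best", "Good", "Weak"),
                          length.out = cfg$n_infants), infants)
    }
  }
  missing_cls <- setdiff(infants, names(responder_classes))
  if (length(missing_cls))
    stopf("responder class missing for infant(s): %s", paste(missing_cls, collapse = ", "))
  cfg$responder_classes <- responder_classes[infants]

  ss <- subcluster_spec
  frac_cols <- paste0("fraction_", timepoints)
  if ("fraction" %in% names(ss)) {
    for (fc in frac_cols) ss[[fc]] <- ss$fraction
  }
  if (!all(frac_cols %in% names(ss)))
    stopf("subcluster_spec needs a 'fraction' column or one per time point")
  for (fc in frac_cols) {
    f <- ss[[fc]]
    if (any(f < 0 | f > 1)) stopf("subcluster fractions must lie in [0,1]")
    if (abs(sum(f) - 1) > 1e-9)
      stopf("subcluster fractions for %s sum to %.12f, not 1", fc, sum(f))
  }
  if (anyDuplicated(ss$subcluster)) stopf("duplicate subcluster names")
  cfg$subcluster_spec <- ss

  folds <- c(unlist(induction_fold_B), unlist(induction_fold_C),
             marker_fold, effect_threshold)
  if (any(folds < 0)) stopf("induction and marker folds must be >= 0")
  if (length(induction_fold_B) > 1) {
    need <- setdiff(unique(cfg$responder_classes), names(induction_fold_B))
    if (length(need))
      stopf("induction_fold_B lacks entries for class(es): %s", paste(need, collapse = ", "))
  }
  if (frac_induced < 0 || frac_induced > 1) stopf("frac_induced must lie in [0,1]")

  n_reserved <- isg_set_size + inflm_set_size + ctx_set_size +
    marker_genes_per_sc * nrow(ss) + 10L
  if (cfg$n_genes <= n_reserved)
    stopf("n_genes (%d) must exceed reserved set/marker/mito genes (%d)",
          cfg$n_genes, n_reserved)

  if (is.null(cfg$bulk_effect_spec)) {
    cfg$bulk_effect_spec <- data.frame(
      module = c("M1.2", "M3.4", "M5.12", "M3.2", "M4.11", "M4.1"),
      day    = c("7",    "7",    "7",     "7",    "30",    "7"),
      fold   = c(1.8,    1.8,    1.8,     1.6,    1.6,     1 / 1.8),
      stringsAsFactors = FALSE)
  }
  if (any(cfg$bulk_samples_per_day < 2))
    stopf("bulk generator needs >= 2 samples per day group")

  class(cfg) <- "sim_config"
  cfg
}

# induction fold for one infant at one time point
induction_fold_for <- function(cfg, infant, timepoint) {
  pick <- function(f) {
    if (length(f) == 1 && is.null(names(f))) return(unname(f))
    cls <- cfg$responder_classes[[infant]]
    if (!is.null(names(f)) && cls %in% names(f)) return(unname(f[[cls]]))
    unname(f[[1]])
  }
  if (timepoint == cfg$timepoints[1]) return(1)
  if (timepoint == "B") pick(cfg$induction_fold_B)
  else pick(cfg$induction_fold_C)
}
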