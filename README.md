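# infantvax

Analysis toolkit for longitudinal transcriptome studies of infant
vaccination. Primary immunization of 2-month-old infants induces a strong
but transient wave of interferon-stimulated gene (ISG) expression about one
week after injection, visible in whole-blood arrays and across nearly every
PBMC subpopulation in single-cell data, while antibody responses to the
individual vaccine antigens are strikingly heterogeneous. `infantvax`
implements the full analysis chain for such a design — three time points
(baseline A, ~1 week B, ~1 month C), a bulk day-0/7/30 cohort, and pre/post
serology — together with seeded synthetic-data generators that emit the
planted ground truth, so the whole pipeline runs and is tested offline.

## What it computes

* **QC and normalization** — the standard droplet filters (doublet score
  ≤ 0.25; genes detected in ≥ 3 cells; ≥ 750 transcripts; 250–3500 detected
  genes; ≤ 15% mitochondrial) applied in order to a fixpoint, then
  counts-per-million with `log1p`.
* **Gene-set scores** — per-cell interferon / inflammation / cytotoxicity
  scores with binned-control background correction (25 expression bins, 100
  seeded controls per set gene), plus Welch t-tests of score dynamics
  between consecutive time points and post-vs-baseline per infant.
* **Differential expression** — two-sided Wilcoxon rank-sum per gene with
  exact p-values for small groups (valid under ties), BH adjustment, and the
  sDEG rule |log2FC| > 0.25 & adjusted p < 0.05; one-vs-rest markers;
  Fisher/odds-ratio/Jaccard set-overlap enrichment.
* **Bulk modular fingerprint** — Kruskal–Wallis DE across study days
  (adjusted p < 0.05, fold > 1.5) and the per-module percentage of probes
  significantly over-/under-expressed versus day 0.
* **G2DA** (gene two-dimension augmentation) — the core method. A gene is
  2D-augmented in a subcluster at a post-vaccination time point *t* when
  jointly:

  1. ≥ 10 cells express it post-vaccination,
  2. its mean raw count among expressing cells post-vaccination is ≥ 50,
  3. expressing cells are ≥ 1% of the cells at *t*,
  4. fractional abundance at *t* is ≥ 1.5 × baseline, and
  5. expression level among expressing cells at *t* is ≥ 1.5 × baseline,

  where fractional abundance = (# cells with count > 0) / (# cells at *t*).
  The scan reports per-criterion booleans and all intermediate quantities,
  feeds stream-plot (stacked-ribbon) data, and groups augmented genes by
  hierarchical clustering of their per-(subcluster × time point) profiles.
* **Serology** — seroprotection calls against per-vaccine cut-offs (PCV13
  requiring ≥ 4 antigens), fold responses (≥ 2-fold, boundary inclusive, or
  seroconversion), and the Best-R / Good-R / Weak-R responder ranking from a
  configurable rule table.
* **Association** — per-infant subcluster frequencies, relative change
  versus baseline, and frequency/IFN-score association with responder class.

## Worked example

Simulate the default cohort with a uniform 3-fold ISG induction at time B on
40 of the 137 interferon-set genes, run QC, normalize, scan, and score:

```r
library(infantvax)
cfg <- sim_config(seed = 1, induction_fold_B = 3, frac_induced = 40/137)
sim <- simulate_sc_counts(cfg)
qc  <- apply_qc(sim$counts, sim$meta)
norm <- normalize_cpm(qc$counts)

rec <- g2da_scan(qc$counts, norm, qc$meta, sim$gene_sets$ISG)
flagged <- unique(rec$gene[rec$augmented_B])
mean(sim$truth$induced_set %in% flagged)
```

This prints a sensitivity of `1.00`: all 40 planted genes are flagged at B,
none of the 97 null ISGs is flagged, and nothing is flagged at C (the
planted induction decays fully, and so do the flags). The interferon score
rises significantly at B in every subcluster:

```r
scores <- module_score(norm, sim$gene_sets$ISG, seed = 1, score_name = "IFN")
head(compare_scores(scores, qc$meta), 3)
#    subcluster comparison    t        p significant
# 1 CD4_T_naive       A->B 20.6 8.50e-83        TRUE
# 3     CD16_NK       A->B 18.6 3.33e-63        TRUE
# 5   CD14_Mono       A->B 14.6 2.48e-42        TRUE
```

The worked-example serology profiles (five infants with heterogeneous
primary responses) rank under the default rule table as:

```r
rank_responders(example_response_profiles())
#   infant n_full n_partial  class
# 1     I1      2         1 Good-R
# 2     I2      2         1 Good-R
# 3     I4      2         0 Weak-R
# 4     I5      1         1 Weak-R
# 5     I6      4         0 Best-R
```

i.e. one best responder (full response to four vaccines), two good
responders (two full plus a partial pneumococcal response) and two weak
responders.

## The analysis workflow

`analysis/` contains numbered drivers that run the whole study on the
synthetic cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R             # cohort + ground truth -> results/data/
Rscript analysis/02_qc_normalize.R         # filters + QC report
Rscript analysis/03_scores.R               # per-cell scores + score tests
Rscript analysis/04_de_markers.R           # per-subcluster DE, markers, enrichment
Rscript analysis/05_g2da.R                 # G2DA scan, binary map, streams, groups
Rscript analysis/06_bulk_fingerprint.R     # bulk DE + modular fingerprint
Rscript analysis/07_serology_association.R # responders + association
```

On the default conditions the drivers report, among other things, an
interferon-score rise at B and fall at C in 6/6 subclusters, a day-7 bulk
fingerprint with the interferon modules at ~100% up that is white again at
day 30, and mean time-B interferon scores ordered Best > Good > Weak across
responder classes.

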