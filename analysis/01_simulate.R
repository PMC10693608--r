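#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort under the default study conditions —
# six infants sampled pre-vaccination (A), ~1 week (B) and ~1 month (C)
# post-vaccination, with a transient interferon-program induction at B whose
# strength follows responder class (Best 3x, Good 2x, Weak 1.3x), a bulk
# cohort with day-7 interferon/inflammation module shifts, and pre/post
# serology titers. Everything is written in the same on-disk formats the
# pipeline reads back.

suppressPackageStartupMessages(library(infantvax))

cfg <- sim_config(seed = 1L)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

message("simulating single-cell cohort (", cfg$n_infants, " infants x ",
        length(cfg$timepoints), " time points, ", cfg$n_genes, " genes, ",
        cfg$n_cells_per_sample, " cells/sample)...")
sim <- simulate_sc_counts(cfg)
write_matrix_bundle(sim$counts, "results/data/sc", meta = sim$meta)
write_gene_sets(sim$gene_sets, "results/data/gene_sets.gmt",
                description = c(ISG = "interferon-stimulated genes",
                                INFLM = "inflammation-regulated genes",
                                CTX = "cytotoxicity-regulated genes"))
write_ground_truth(sim$truth[c("induced_set", "infant_folds",
                               "responder_classes")],
                   "results/data/sc_ground_truth.json")
message("  ", ncol(sim$counts), " cells, ",
        length(sim$truth$induced_set), "/", length(sim$gene_sets$ISG),
        " ISG genes carry a planted induction at time point B")

message("simulating bulk cohort (", cfg$bulk_n_probes, " probes; n = ",
        paste(cfg$bulk_samples_per_day, collapse = "/"), " per day)...")
bulk <- simulate_bulk_expression(cfg)
write_bulk_bundle(bulk$exprs, bulk$samples, "results/data/bulk")
write_gene_sets(bulk$modules, "results/data/bulk_modules.gmt")
write_ground_truth(bulk$truth["effects"], "results/data/bulk_ground_truth.json")

message("simulating serology titers...")
sero <- simulate_serology(cfg)
write_serology(sero$titers, "results/data/serology.csv")
write_ground_truth(sero$truth, "results/data/serology_ground_truth.json")

message("done: synthetic cohort written under results/data/")
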