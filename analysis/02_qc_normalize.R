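#!/usr/bin/env Rscript
# Stage 2: cell and gene quality control. Doublet-scored cells are dropped
# first, then the gene detection floor, the total-transcript floor, the
# detected-gene bounds and the mitochondrial-fraction cap are applied in
# order. The filtered counts are re-written as a bundle; downstream stages
# recompute CPM normalization from them (cheap, and keeps the store sparse
# integers).

suppressPackageStartupMessages({library(infantvax); library(jsonlite)})

b <- read_matrix_bundle("results/data/sc", require_metadata = TRUE)
res <- apply_qc(b$counts, b$meta, qc_params())
rep <- res$report
message(sprintf("QC: %d/%d cells and %d/%d genes retained",
                rep$cells_out, rep$cells_in, rep$genes_out, rep$genes_in))
for (rule in names(rep$removed))
  message(sprintf("  removed by %-18s %d", paste0(rule, ":"), rep$removed[[rule]]))

write_matrix_bundle(res$counts, "results/data/sc_filtered", meta = res$meta)
write_json(rep, "results/qc_report.json", auto_unbox = TRUE, pretty = TRUE)
message("filtered bundle written to results/data/sc_filtered")
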