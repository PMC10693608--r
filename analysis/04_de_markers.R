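#!/usr/bin/env Rscript
# Stage 4: per-subcluster Wilcoxon differential expression against baseline
# (time point A), the sDEG tally per (subcluster, time point), top-15 marker
# genes per subcluster, and overlap enrichment of the B-upregulated sDEGs
# with the interferon set.

suppressPackageStartupMessages(library(infantvax))

b <- read_matrix_bundle("results/data/sc_filtered", require_metadata = TRUE)
norm <- normalize_cpm(b$counts)
meta <- b$meta
sets <- read_gene_sets("results/data/gene_sets.gmt")

de_all <- list()
for (sc in sort(unique(meta$subcluster))) {
  bcs <- function(tp) meta$barcode[meta$subcluster == sc & meta$timepoint == tp]
  for (tp in c("B", "C")) {
    de <- rank_sum_de(norm, bcs(tp), bcs("A"))
    de$subcluster <- sc; de$comparison <- paste0("A->", tp)
    de_all[[paste(sc, tp)]] <- de
  }
}
de <- do.call(rbind, de_all)
utils::write.table(de, "results/de.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

tally <- stats::aggregate(sdeg ~ subcluster + comparison + direction, de, sum)
utils::write.table(tally, "results/sdeg_counts.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
n_b <- sum(de$sdeg[de$comparison == "A->B"])
n_c <- sum(de$sdeg[de$comparison == "A->C"])
message(sprintf("sDEGs (|log2FC| > 0.25, BH p < 0.05): %d at B, %d at C over all subclusters",
                n_b, n_c))

markers <- do.call(rbind, lapply(sort(unique(meta$subcluster)), function(sc) {
  mk <- find_markers(norm, meta$subcluster, sc)
  if (nrow(mk)) cbind(subcluster = sc, mk) else NULL
}))
utils::write.table(markers, "results/markers.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

up_b <- unique(de$gene[de$sdeg & de$direction == "up" & de$comparison == "A->B"])
enr <- overlap_enrichment(intersect(up_b, rownames(norm)),
                          intersect(sets$ISG, rownames(norm)), rownames(norm))
utils::write.table(enr, "results/isg_enrichment.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("B-up sDEGs vs ISG set: overlap %d, odds ratio %.1f, Jaccard %.2f, Fisher p %.3g",
                enr$overlap, enr$odds_ratio, enr$jaccard, enr$p))
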