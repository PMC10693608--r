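#!/usr/bin/env Rscript
# Stage 7: serology and its association with the single-cell readouts.
# Titers become fold responses (>= 2-fold or seroconversion), per-vaccine
# full/partial/none levels, and Best/Good/Weak responder classes; those
# classes are then set against subcluster frequencies and per-infant
# interferon scores (post-vs-baseline t-tests).

suppressPackageStartupMessages(library(infantvax))

titers <- read_serology("results/data/serology.csv")
thr <- sero_thresholds()
folds <- fold_response(titers, thr)
utils::write.table(folds, "results/serology_folds.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
prot <- seroprotection(titers, thr)
utils::write.table(prot, "results/seroprotection.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
levels <- vaccine_response_levels(folds, thr)
calls <- rank_responders(levels)
utils::write.table(calls, "results/responders.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("responder classes: ",
        paste(sprintf("%s=%s", calls$infant, calls$class), collapse = ", "))

b <- read_matrix_bundle("results/data/sc_filtered", require_metadata = TRUE)
scores <- utils::read.delim("results/scores.tsv")
ifn <- scores[scores$score_name == "ISG", ]
freq <- cell_frequencies(b$meta)
utils::write.table(freq, "results/cell_frequencies.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

assoc <- response_association(freq, ifn, b$meta, calls)
utils::write.table(assoc$mean_scores, "results/assoc_mean_scores.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(assoc$tests, "results/assoc_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

mb <- assoc$mean_scores[assoc$mean_scores$timepoint == "B", ]
cls_mean <- tapply(mb$mean_score, mb$class, mean)
message("mean time-B interferon score by responder class: ",
        paste(sprintf("%s %.3f", names(cls_mean), cls_mean), collapse = ", "))
sig <- assoc$tests[assoc$tests$pooled & assoc$tests$testable, ]
message(sprintf("post-vs-baseline interferon tests: %d/%d (infant x subcluster) flagged at p < 0.05",
                sum(sig$significant), nrow(sig)))
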