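#!/usr/bin/env Rscript
# Stage 6: bulk cohort. Kruskal-Wallis differential expression across days
# 0/7/30 (BH-adjusted, fold > 1.5), then the modular fingerprint: per module
# and day, the percentage of module probes significantly over-/under-
# expressed versus day 0. Expected on the default synthetic cohort: the
# interferon and inflammation modules light up at day 7 and are white again
# at day 30, while the plasma-cell module rises at day 30.

suppressPackageStartupMessages(library(infantvax))

bb <- read_bulk_bundle("results/data/bulk")
mods <- read_gene_sets("results/data/bulk_modules.gmt")

de <- bulk_de(bb$exprs, bb$samples)
utils::write.table(de, "results/bulk_de.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("bulk DE: %d/%d probes differentially expressed (%.0f%% up at day 7)",
                sum(de$de), nrow(de),
                100 * mean(de$direction_day7[de$de] == "up")))

fp <- module_fingerprint(bb$exprs, bb$samples, mods)
utils::write.table(fp, "results/fingerprint.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
for (d in unique(fp$day)) {
  f <- fp[fp$day == d & fp$evaluable, ]
  hot <- f[f$percent_up + f$percent_down >= 20, ]
  message(sprintf("day %s fingerprint: %s", d,
                  if (nrow(hot)) paste(sprintf("%s %s%.0f%%", hot$module,
                                               ifelse(hot$dominant == "up", "+", "-"),
                                               pmax(hot$percent_up, hot$percent_down)),
                                       collapse = ", ")
                  else "no module above 20%"))
}
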