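test_that("frequencies and relative changes follow their definitions", {
  meta <- data.frame(
    barcode = sprintf("c%02d", 1:18),
    infant = "I1",
    timepoint = rep(c("A", "B", "C"), each = 6),
    subcluster = c(rep(c("S1", "S2"), each = 3),        # A: 0.5 / 0.5
                   rep(c("S1", "S2"), c(3, 3)),         # B: 0.5 / 0.5
                   rep(c("S1", "S2"), c(4, 2))),        # C: 2/3 / 1/3
    stringsAsFactors = FALSE)
  fr <- cell_frequencies(meta)
  pick <- function(tp, sc) fr[fr$timepoint == tp & fr$subcluster == sc, ]
  expect_equal(pick("B", "S1")$rel_change, 0)           # equal fractions
  expect_equal(pick("C", "S1")$rel_change, (4 / 6) / 0.5 - 1)
  # fractions sum to 1 per (infant, timepoint)
  sums <- tapply(fr$fraction, paste(fr$infant, fr$timepoint), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # doubling fraction means +1.0
  meta2 <- meta
  meta2$subcluster <- c(rep(c("S1", "S2"), c(1, 5)),
                        rep(c("S1", "S2"), c(2, 4)),
                        rep(c("S1", "S2"), c(2, 4)))
  fr2 <- cell_frequencies(meta2)
  expect_equal(fr2$rel_change[fr2$timepoint == "B" & fr2$subcluster == "S1"], 1)

  # zero baseline fraction: change undefined, flagged
  meta3 <- meta
  meta3$subcluster[meta3$timepoint == "A"] <- "S1"
  fr3 <- cell_frequencies(meta3)
  row <- fr3[fr3$timepoint == "B" & fr3$subcluster == "S2", ]
  expect_false(row$rel_change_defined)
  expect_true(is.na(row$rel_change))

  # missing time point: explicit markers
  meta4 <- meta[meta$timepoint != "C", ]
  fr4 <- cell_frequencies(meta4)
  expect_true(all(fr4$missing[fr4$timepoint == "C"]))
  expect_true(all(is.na(fr4$fraction[fr4$timepoint == "C"])))
})

test_that("a planted subcluster expansion shows the right sign of change", {
  ss <- default_subcluster_spec()
  ss$fraction_A <- ss$fraction
  ss$fraction_B <- ss$fraction
  ss$fraction_C <- ss$fraction
  # expand the ISG-high subcluster at B at the expense of the naive one
  ss$fraction_B[ss$subcluster == "CD4_T_ISGhi"] <- 0.20
  ss$fraction_B[ss$subcluster == "CD4_T_naive"] <- 0.20
  ss$fraction <- NULL
  hits <- 0; total <- 0
  for (seed in 1:4) {
    sim <- simulate_sc_counts(sim_config(n_genes = 700, n_cells_per_sample = 150,
                                         subcluster_spec = ss, seed = seed))
    fr <- cell_frequencies(sim$meta)
    ch <- fr$rel_change[fr$subcluster == "CD4_T_ISGhi" & fr$timepoint == "B"]
    hits <- hits + sum(ch > 0); total <- total + length(ch)
  }
  expect_gte(hits / total, 0.95)
})

test_that("identical scores across time points raise no association flags", {
  meta <- data.frame(barcode = sprintf("c%03d", 1:90), infant = "I1",
                     subcluster = rep(c("S1", "S2", "S3"), 30),
                     timepoint = rep(c("A", "B", "C"), each = 30),
                     stringsAsFactors = FALSE)
  scores <- data.frame(barcode = meta$barcode, score_name = "IFN",
                       score = rep(c(0.2, 0.4, 0.6), 30),
                       stringsAsFactors = FALSE)
  responders <- data.frame(infant = "I1", class = "Best-R",
                           stringsAsFactors = FALSE)
  res <- response_association(cell_frequencies(meta), scores, meta, responders)
  expect_false(any(res$tests$significant))
})

test_that("planted induction flags the strong responder and orders classes", {
  cfg <- small_sim_config(seed = 23, n_cells_per_sample = 150)
  sim <- simulate_sc_counts(cfg)
  norm <- normalize_cpm(sim$counts)
  scores <- module_score(norm, sim$gene_sets$ISG, seed = 1, score_name = "IFN")
  responders <- data.frame(infant = names(cfg$responder_classes),
                           class = paste0(unname(cfg$responder_classes), "-R"),
                           stringsAsFactors = FALSE)
  res <- response_association(cell_frequencies(sim$meta), scores,
                               sim$meta, responders)
  tests <- res$tests

  # best responder (fold 3): flagged at B in >= 90% of subclusters with >= 30
  # baseline cells
  best <- responders$infant[responders$class == "Best-R"]
  tb <- tests[tests$infant %in% best & tests$comparison == "A->B" &
              tests$n_base >= 30, ]
  expect_gte(mean(tb$significant & tb$mean_diff > 0), 0.9)

  # planted effect-fold ordering Best > Good > Weak is reflected in the mean
  # time-B interferon score per infant
  ms <- res$mean_scores
  mb <- stats::aggregate(mean_score ~ infant + class,
                         ms[ms$timepoint == "B", ], mean)
  expect_gt(min(mb$mean_score[mb$class == "Best-R"]),
            max(mb$mean_score[mb$class == "Good-R"]))
  expect_gt(min(mb$mean_score[mb$class == "Good-R"]),
            max(mb$mean_score[mb$class == "Weak-R"]))

  # infants without scores are excluded with a warning
  sc2 <- scores[!(scores$barcode %in%
                    sim$meta$barcode[sim$meta$infant == "I1"]), ]
  expect_warning(response_association(cell_frequencies(sim$meta), sc2,
                                      sim$meta, responders), "I1")
})
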