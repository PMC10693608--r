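# dense matrix (genes x cells) as sparse for score tests
dense_norm <- function(m) methods::as(m, "CsparseMatrix")

test_that("binned-control score vanishes when expectation cancels", {
  # constant matrix: every gene identical in every cell
  m <- matrix(3, 200, 30, dimnames = list(sprintf("g%03d", 1:200),
                                          sprintf("c%02d", 1:30)))
  sc <- module_score(dense_norm(m), sprintf("g%03d", 1:40), seed = 1)
  expect_true(all(abs(sc$score) < 1e-9))

  # gene-constant per cell: set = all genes, controls = all genes
  m2 <- matrix(rep(stats::runif(30, 0, 5), each = 200), 200, 30,
               dimnames = dimnames(m))
  sc2 <- module_score(dense_norm(m2), rownames(m2), seed = 1)
  expect_true(all(abs(sc2$score) < 1e-9))
})

test_that("binned-control score recovers a planted shift", {
  set.seed(42)
  n_genes <- 400; n_cells <- 40
  base <- seq(0, 10, length.out = n_genes)          # fine grid of gene levels
  gset <- sample(sprintf("g%03d", 1:n_genes), 30)
  m <- matrix(rep(base, n_cells), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("c%02d", 1:n_cells)))
  delta <- 2
  half <- 1:(n_cells / 2)
  m[gset, half] <- m[gset, half] + delta            # + shift in half the cells
  m[gset, -half] <- m[gset, -half] - delta          # - shift in the rest
  sc <- module_score(dense_norm(m), gset, seed = 3)
  s_plus <- sc$score[half]; s_minus <- sc$score[-half]

  # oracle: recompute the control-bin draws literally (same seed) and derive
  # the expected score from plain arithmetic on the dense matrix
  gene_avg <- rowMeans(m)
  bins <- ceiling(rank(gene_avg, ties.method = "first") / n_genes * 25)
  set.seed(3)
  ctrl <- character()
  for (g in gset) {
    pool <- rownames(m)[bins == bins[match(g, rownames(m))]]
    ctrl <- c(ctrl, sample(pool, 100, replace = TRUE))
  }
  expected <- colMeans(m[gset, ]) - colMeans(m[ctrl, ])
  expect_equal(sc$score, unname(expected), tolerance = 1e-9)

  # the antisymmetric construction makes the two halves mirror each other:
  # control contamination by set genes cancels between halves
  expect_lt(stats::sd(s_plus + s_minus), 1e-9)
  # and the recovered shift sits near +/- delta (controls may include a few
  # set genes, which only shrinks the score toward zero)
  expect_true(all(s_plus > 0.8 * delta & s_plus < 1.1 * delta))
  expect_true(all(s_minus < -0.8 * delta & s_minus > -1.1 * delta))

  # plain mode: exact mean over set genes
  pl <- module_score(dense_norm(m), gset, method = "plain")
  expect_equal(pl$score[half], colMeans(m[gset, half]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("score is invariant to additive constants and monotone in set boosts", {
  set.seed(7)
  m <- matrix(stats::rnorm(300 * 20, 5, 1), 300, 20,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("c%02d", 1:20)))
  gset <- sprintf("g%03d", 1:25)
  s0 <- module_score(dense_norm(m), gset, seed = 2)$score
  s_shift <- module_score(dense_norm(m + 1.7), gset, seed = 2)$score
  expect_equal(s0, s_shift, tolerance = 1e-9)

  # monotone in a uniform boost applied to a cell group: gene averages are
  # held fixed by boosting antisymmetrically across two cell halves, so bins
  # and control draws are identical for every boost size and the boosted
  # cells' scores must rise strictly
  set.seed(8)
  base <- seq(0, 10, length.out = 400)
  g <- matrix(rep(base, 20), 400, 20,
              dimnames = list(sprintf("h%03d", 1:400), sprintf("c%02d", 1:20)))
  gset2 <- sample(rownames(g)[base > 2 & base < 7], 25)
  half <- 1:10
  means <- vapply(c(0, 0.5, 1, 1.5), function(b) {
    gb <- g
    gb[gset2, half] <- gb[gset2, half] + b       # boost in log space
    gb[gset2, -half] <- gb[gset2, -half] - b
    mean(module_score(dense_norm(gb), gset2, seed = 2)$score[half])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("absent set genes warn; fully absent set and bad bins error", {
  m <- dense_norm(matrix(1:20, 4, 5, dimnames = list(paste0("g", 1:4),
                                                     paste0("c", 1:5))))
  expect_warning(module_score(m, c("g1", "g2", "nope"), n_bins = 2), "absent")
  expect_error(module_score(m, c("x", "y")), "no gene")
  expect_error(module_score(m, "g1", n_bins = 1), "n_bins")
})

test_that("score comparisons match an independently coded Welch t-test", {
  set.seed(11)
  x <- stats::rnorm(50, 0, 1); y <- stats::rnorm(50, 1, 1)
  scores <- data.frame(barcode = sprintf("c%03d", 1:100), score_name = "s",
                       score = c(x, y), stringsAsFactors = FALSE)
  meta <- data.frame(barcode = scores$barcode, subcluster = "SC1",
                     timepoint = rep(c("A", "B"), each = 50),
                     stringsAsFactors = FALSE)
  res <- compare_scores(scores, meta, timepoints = c("A", "B"))
  expect_equal(res$p[1], welch_p(y, x), tolerance = 1e-10)
  expect_true(res$significant[1])

  # identical distributions in both groups: no flag
  scores$score <- rep(c(1, 2, 3, 4, 5), 20)
  res <- compare_scores(scores, meta, timepoints = c("A", "B"))
  expect_false(res$significant[1])

  # degenerate group is flagged untestable, not dropped
  meta2 <- meta; meta2$timepoint <- c("A", rep("B", 99))
  res <- compare_scores(scores, meta2, timepoints = c("A", "B"))
  expect_false(res$testable[1])
  expect_equal(nrow(res), 1)
})

test_that("planted induction produces a rise at B and a fall back at C", {
  cfg <- small_sim_config(seed = 21, induction_fold_B = 3)
  sim <- simulate_sc_counts(cfg)
  norm <- normalize_cpm(sim$counts)
  sc <- module_score(norm, sim$gene_sets$ISG, seed = 1,
                     score_name = "IFN")
  res <- compare_scores(sc, sim$meta)
  ab <- res[res$comparison == "A->B", ]
  bc <- res[res$comparison == "B->C", ]
  expect_true(all(ab$significant & ab$mean_diff > 0))
  expect_true(all(bc$significant & bc$mean_diff < 0))
})
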