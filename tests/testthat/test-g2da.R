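# small labelled fixture for scan tests
g2da_fixture <- function(n_genes, n_cells, n_sc, seed, mu = 2, size = 0.5) {
  counts <- rand_counts(n_genes, n_cells, seed = seed, mu = mu, size = size)
  keep <- Matrix::colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  meta <- rand_sc_meta(colnames(counts), n_sc, seed + 1000)
  list(counts = counts, norm = normalize_cpm(counts), meta = meta)
}

test_that("fractional abundance follows its definition exactly", {
  m <- methods::as(matrix(c(0, 0, 0, 0, 1, 5, 0, 2, 0, 3, 1, 1, 0, 0, 4, 9),
                          nrow = 2, dimnames = list(c("gA", "gB"),
                                                    sprintf("c%d", 1:8))),
                   "CsparseMatrix")
  expect_equal(fractional_abundance(m, colnames(m), "gA"), 3 / 8)
  expect_equal(fractional_abundance(m, colnames(m)[1:2], "gA"), 0)
  expect_equal(fractional_abundance(m, colnames(m)[c(3, 5, 6, 8)], "gB"), 1)
  expect_error(fractional_abundance(m, character(), "gA"), "empty")
})

test_that("individual criteria exclude genes as stated", {
  # 60 baseline + 60 post cells in one subcluster
  bc <- sprintf("c%03d", 1:120)
  meta <- data.frame(barcode = bc, subcluster = "SC1",
                     timepoint = rep(c("A", "B", "C"), each = 40),
                     stringsAsFactors = FALSE)
  m <- matrix(0, 3, 120, dimnames = list(c("few", "flatfrac", "good"), bc))
  # 'few': expressed in only 5 post cells (criterion 1)
  m["few", 41:45] <- 100
  # 'flatfrac': fraction 0.5 at A, B and C, strong expression (criterion 4)
  idx <- c(1:20, 41:60, 81:100)
  m["flatfrac", idx] <- 100
  # 'good': passes everything (0.1 -> 0.5 fraction, 20 -> 100 expression)
  m["good", 1:4] <- 20
  m["good", c(41:60, 81:100)] <- 100
  counts <- methods::as(m, "CsparseMatrix")
  # bystander gene keeps library sizes comparable across cells
  filler <- matrix(1000, 1, 120, dimnames = list("filler", bc))
  counts <- rbind(counts, methods::as(filler, "CsparseMatrix"))
  res <- g2da_scan(counts, normalize_cpm(counts), meta,
                   c("few", "flatfrac", "good"))
  expect_equal(res$flag[res$gene == "few"], "none")
  expect_false(any(res$pass_c1_B[res$gene == "few"]))
  expect_equal(res$flag[res$gene == "flatfrac"], "none")
  expect_false(any(res$pass_c4_B[res$gene == "flatfrac"]))
  expect_equal(res$flag[res$gene == "good"], "B&C")
})

test_that("scan flags equal the literal brute-force oracle on random fixtures", {
  for (seed in 1:8) {
    fx <- g2da_fixture(30, 300, sample(2:4, 1), seed = seed,
                       mu = sample(c(2, 20, 60), 1), size = 0.3)
    params <- g2da_params(min_cells = 5, min_mean_reads = 20,
                          min_frac = 0.02, fold_frac = 1.3, fold_expr = 1.3)
    res <- g2da_scan(fx$counts, fx$norm, fx$meta, rownames(fx$counts), params)
    orc <- oracle_g2da(fx$counts, fx$norm, fx$meta, rownames(fx$counts), params)
    got <- stats::setNames(res$flag, paste(res$gene, res$subcluster))
    expect_identical(got[names(orc)], stats::setNames(orc, names(orc)))
  }
})

test_that("raising any threshold never adds a flagged gene", {
  fx <- g2da_fixture(40, 400, 3, seed = 99, mu = 30, size = 0.4)
  base <- g2da_params(min_cells = 5, min_mean_reads = 10, min_frac = 0.01,
                      fold_frac = 1.1, fold_expr = 1.1)
  res0 <- g2da_scan(fx$counts, fx$norm, fx$meta, rownames(fx$counts), base)
  flagged0 <- paste(res0$gene, res0$subcluster)[res0$flag != "none"]
  for (fld in names(unclass(base))) {
    p <- unclass(base); p[[fld]] <- p[[fld]] * 2
    res1 <- g2da_scan(fx$counts, fx$norm, fx$meta, rownames(fx$counts),
                      do.call(g2da_params, p))
    flagged1 <- paste(res1$gene, res1$subcluster)[res1$flag != "none"]
    expect_true(all(flagged1 %in% flagged0))
  }
})

test_that("subclusters without baseline cells are excluded from flags", {
  bc <- sprintf("c%03d", 1:60)
  meta <- data.frame(barcode = bc, subcluster = rep(c("SC1", "SC2"), each = 30),
                     timepoint = c(rep(c("A", "B", "C"), each = 10),
                                   rep(c("B", "C"), 15)),
                     stringsAsFactors = FALSE)
  counts <- rand_counts(10, 60, seed = 8, mu = 50, size = 2)
  colnames(counts) <- bc
  res <- g2da_scan(counts, normalize_cpm(counts), meta, rownames(counts))
  expect_true(all(res$no_baseline[res$subcluster == "SC2"]))
  expect_true(all(res$flag[res$subcluster == "SC2"] == "none"))
})

test_that("stream-plot ribbons recompute fractional abundances and stack", {
  bc <- sprintf("c%03d", 1:90)
  meta <- data.frame(barcode = bc, subcluster = "SC1",
                     timepoint = rep(c("A", "B", "C"), each = 30),
                     stringsAsFactors = FALSE)
  m <- matrix(0, 3, 90, dimnames = list(c("gA", "gB", "filler"), bc))
  m["gA", c(1:3, 31:33, 61:63)] <- 60            # constant fraction 0.1
  m["gB", c(1:2, 31:36, 61:66)] <- 60            # 1/15 -> 0.2 -> 0.2
  m["filler", ] <- 500
  counts <- methods::as(m, "CsparseMatrix")
  res <- g2da_scan(counts, normalize_cpm(counts), meta, c("gA", "gB"),
                   g2da_params(min_cells = 3, min_mean_reads = 10,
                               min_frac = 0.01, fold_frac = 1.5,
                               fold_expr = 1.0001))
  sp <- stream_plot_data(res)
  rb <- sp$ribbons
  # gA not augmented (flat fraction), gB augmented at B and C
  expect_false("gA" %in% rb$gene)
  expect_equal(rb$frac[rb$gene == "gB" & rb$timepoint == "B"], 0.2)
  # thickness equals recomputed fractional abundance exactly
  expect_equal(rb$frac[rb$gene == "gB" & rb$timepoint == "A"],
               fractional_abundance(counts, bc[1:30], "gB"))

  # additivity of the stack when two genes are augmented
  res$flag <- "B"; res$augmented_B <- TRUE        # force both genes in
  sp2 <- stream_plot_data(res)
  totB <- sp2$totals$total[sp2$totals$timepoint == "B"]
  fB <- res$frac_B
  expect_equal(totB, sum(fB))
  rbB <- sp2$ribbons[sp2$ribbons$timepoint == "B", ]
  expect_equal(rbB$ymax[2], rbB$frac[1] + rbB$frac[2])
})

test_that("pattern grouping separates planted profiles and honors k", {
  set.seed(12)
  bc <- sprintf("c%03d", 1:120)
  meta <- data.frame(barcode = bc,
                     subcluster = rep(c("SC1", "SC2"), 60),
                     timepoint = rep(c("A", "B", "C"), each = 40),
                     stringsAsFactors = FALSE)
  n_genes <- 20
  m <- matrix(stats::rnorm(n_genes * 120, 5, 0.1), n_genes, 120,
              dimnames = list(sprintf("g%02d", 1:n_genes), bc))
  up_b <- sprintf("g%02d", 1:10)                  # pattern 1: high at B
  m[up_b, meta$timepoint == "B"] <- m[up_b, meta$timepoint == "B"] + 5
  up_c <- sprintf("g%02d", 11:20)                 # pattern 2: high at C
  m[up_c, meta$timepoint == "C"] <- m[up_c, meta$timepoint == "C"] + 5
  norm <- methods::as(m, "CsparseMatrix")
  grp <- group_augmented_genes(norm, meta, rownames(m), k = 2)
  expect_length(unique(grp[up_b]), 1)
  expect_length(unique(grp[up_c]), 1)
  expect_equal(length(unique(grp)), 2)
  # oracle: within-pattern correlation distance is smaller than between
  expect_true(grp[["g01"]] != grp[["g11"]])
  expect_equal(unique(group_augmented_genes(norm, meta, rownames(m), k = 1)),
               1, ignore_attr = TRUE)
  expect_error(group_augmented_genes(norm, meta, rownames(m), k = 50), "exceeds")
})

test_that("nine groups requested on a 79-gene augmented set are all non-empty", {
  set.seed(33)
  bc <- sprintf("c%03d", 1:180)
  meta <- data.frame(barcode = bc,
                     subcluster = rep(c("SC1", "SC2", "SC3"), 60),
                     timepoint = rep(c("A", "B", "C"), each = 60),
                     stringsAsFactors = FALSE)
  m <- matrix(stats::rnorm(79 * 180, 4, 0.5), 79, 180,
              dimnames = list(sprintf("ag%02d", 1:79), bc))
  norm <- methods::as(m, "CsparseMatrix")
  grp <- group_augmented_genes(norm, meta, rownames(m), k = 9)
  expect_equal(sort(unique(grp)), 1:9)
})
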