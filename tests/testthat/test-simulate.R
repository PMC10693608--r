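test_that("all three generators are deterministic given the seed", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_sc_counts(cfg); b <- simulate_sc_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  ba <- simulate_bulk_expression(cfg); bb <- simulate_bulk_expression(cfg)
  expect_identical(ba$exprs, bb$exprs)
  sa <- simulate_serology(cfg); sb <- simulate_serology(cfg)
  expect_identical(sa$titers, sb$titers)
})

test_that("no planted effect means empty ground truth and integer counts", {
  cfg <- small_sim_config(seed = 3, induction_fold_B = 1, induction_fold_C = 1)
  sim <- simulate_sc_counts(cfg)
  expect_equal(nrow(sim$truth$induced_genes), 0)
  v <- sim$counts@x
  expect_true(all(v >= 0) && all(v == round(v)))
  # conservation: per-cell totals equal the sum over genes exactly
  dense_tot <- colSums(as.matrix(sim$counts[, 1:20]))
  expect_identical(unname(Matrix::colSums(sim$counts)[1:20]), unname(dense_tot))
})

test_that("planted fold-3 induction gives a pooled mean fold near 3", {
  mean_fold <- function(cfg) {
    sim <- simulate_sc_counts(cfg)
    ind <- sim$truth$induced_set
    bcB <- sim$meta$barcode[sim$meta$timepoint == "B"]
    bcA <- sim$meta$barcode[sim$meta$timepoint == "A"]
    mean(Matrix::rowMeans(sim$counts[ind, bcB]) /
         Matrix::rowMeans(sim$counts[ind, bcA]))
  }
  base <- list(n_infants = 2, n_genes = 800, induction_fold_B = 3,
               frac_induced = 50 / 137)
  got <- mean_fold(do.call(sim_config, c(base, n_cells_per_sample = 100, seed = 5)))
  # oracle: same generator at 10x the cells
  ref <- mean_fold(do.call(sim_config, c(base, n_cells_per_sample = 1000, seed = 6)))
  expect_lt(abs(got - 3) / 3, 0.2)
  expect_lt(abs(got - ref) / ref, 0.2)
})

test_that("config validation rejects broken inputs", {
  expect_error(sim_config(n_cells_per_sample = -5), "integer")
  expect_error(sim_config(n_cells_per_sample = 2.5), "integer")
  expect_error(sim_config(responder_classes = c(I1 = "Best")), "responder class missing")
  bad <- default_subcluster_spec(); bad$fraction[1] <- bad$fraction[1] + 0.1
  expect_error(sim_config(subcluster_spec = bad), "sum to")
  expect_error(sim_config(frac_induced = 1.2), "frac_induced")
  expect_error(sim_config(n_genes = 100), "reserved")
})

test_that("bulk generator: null case is calibrated and planted shifts are recovered", {
  null_cfg <- sim_config(
    n_genes = 800, seed = 11,
    bulk_effect_spec = data.frame(module = "M1.2", day = "7", fold = 1),
    bulk_samples_per_day = c("0" = 10, "7" = 10, "30" = 10),
    bulk_n_probes = 600)
  nb <- simulate_bulk_expression(null_cfg)
  de <- bulk_de(nb$exprs, nb$samples)
  # without effects the raw-p distribution is uniform and the DE flag
  # (BH-adjusted + fold filter) fires essentially never
  expect_lte(mean(de$p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(de)))
  expect_lte(mean(de$de), 0.01)

  eff_cfg <- sim_config(
    n_genes = 800, seed = 12,
    bulk_effect_spec = data.frame(module = "M1.2", day = "7", fold = 1.8),
    bulk_samples_per_day = c("0" = 20, "7" = 20, "30" = 20),
    bulk_module_size = 40, bulk_n_probes = 600)
  eb <- simulate_bulk_expression(eff_cfg)
  de <- bulk_de(eb$exprs, eb$samples)
  planted <- eb$modules[["M1.2"]]
  expect_gte(mean(de$de[de$probe %in% planted]), 0.9)
  expect_equal(nrow(eb$truth$effects), 1)
})

test_that("serology generator honors degenerate and fixed fold distributions", {
  spec1 <- list(HepB = list(
    antigens = "HBsAg", units = "mIU/mL", cutoff = 0.8,
    baseline_logdist = c(meanlog = log(0.5), sdlog = 0),
    fold_dist = list(Best = c(log(1), 0), Good = c(log(1), 0), Weak = c(log(1), 0)),
    respond_prob = c(Best = 1, Good = 1, Weak = 1)))
  st <- simulate_serology(small_sim_config(seed = 2, serology_spec = spec1))
  wide <- reshape(st$titers, idvar = c("infant", "antigen"),
                  timevar = "timepoint", direction = "wide")
  expect_equal(wide$value.post / wide$value.pre, rep(1, nrow(wide)))

  spec20 <- spec1
  spec20$HepB$fold_dist$Best <- c(log(20), 0)
  st <- simulate_serology(sim_config(
    n_infants = 1, responder_classes = c(I1 = "Best"),
    serology_spec = spec20, seed = 2))
  expect_equal(st$titers$value[st$titers$timepoint == "post"], 10)

  # class-conditional mean fold matches the configured distribution within a
  # Monte-Carlo CI from direct resampling
  cfg <- sim_config(n_infants = 90, seed = 9,
                    responder_classes = stats::setNames(
                      rep(c("Best", "Good", "Weak"), 30), paste0("I", 1:90)))
  st <- simulate_serology(cfg)
  tr <- st$truth$antigen_response
  hb <- tr[tr$vaccine == "HepB", ]
  for (cls in c("Best", "Good", "Weak")) {
    fd <- cfg$serology_spec$HepB$fold_dist[[cls]]
    set.seed(100 + match(cls, c("Best", "Good", "Weak")))
    ref <- replicate(400, mean(stats::rlnorm(30, fd[1], fd[2])))
    got <- mean(hb$fold[hb$class == cls])
    expect_gt(got, stats::quantile(ref, 0.001))
    expect_lt(got, stats::quantile(ref, 0.999))
  }
})
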