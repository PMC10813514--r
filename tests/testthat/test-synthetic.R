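test_that("degenerate noise yields identical uniform baseline profiles", {
  cfg <- quiet_config(n_donors = 4, n_taxa = 10)
  b <- generate_baseline(cfg)
  expect_equal(unname(colSums(b$rel)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(abs(b$rel - 0.1) < 1e-12))
})

test_that("donors' dominant family matches their assigned enterotype template", {
  for (s in c(1, 11, 42)) {
    b <- generate_baseline(qmp_sim_config(rng_seed = s))
    famsum <- rowsum(b$rel, b$family)
    dominant <- rownames(famsum)[apply(famsum, 2, which.max)]
    expect_identical(dominant, unname(sub("_rich", "", b$template)))
  }
  # templates recycle round-robin over donors
  b <- generate_baseline(qmp_sim_config(rng_seed = 1))
  expect_identical(unname(b$template[1:3]), unname(b$template[4:6]))
})

test_that("baseline vectors always sum to one and generation is seed-deterministic", {
  cfg <- qmp_sim_config(rng_seed = 99)
  b1 <- generate_baseline(cfg)
  b2 <- generate_baseline(cfg)
  expect_identical(b1, b2)
  expect_equal(unname(colSums(b1$rel)), rep(1, 6), tolerance = 1e-9)
  expect_error(
    qmp_sim_config(n_taxa = 5),  # fewer taxa than template families
    "smaller than template support")
})

test_that("apply_effects with no planted effects and equal densities leaves arms equal", {
  cfg <- quiet_config()
  truth <- apply_effects(generate_baseline(cfg), cfg)
  for (d in c("D1", "D2")) {
    expect_equal(truth$true_abundance[, paste0(d, "_trt")],
                 truth$true_abundance[, paste0(d, "_NSC")])
  }
})

test_that("planted effects renormalise as expected in the two-taxon case", {
  ids <- c("OTU001", "OTU002")
  cfg <- quiet_config(n_donors = 1, n_taxa = 2,
                      effect_specs = effect_spec("trt", "OTU001", 1))
  truth <- apply_effects(generate_baseline(cfg), cfg)
  fc <- true_fold_change(truth, "trt", cfg)
  expect_equal(unname(fc[ids, "D1"]), c(2 / 1.5, 1 / 1.5), tolerance = 1e-12)
})

test_that("with no planted taxa a doubled density doubles every true fold change", {
  cfg <- quiet_config(n_donors = 2, n_taxa = 6, treatment_density = 2e9,
                      density = 1e9)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  fc <- true_fold_change(truth, "trt", cfg)
  expect_equal(unname(fc), matrix(2, 6, 2), tolerance = 1e-12)
})

test_that("ground-truth column sums equal the per-sample true density", {
  cfg <- qmp_sim_config(rng_seed = 3)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  expect_equal(colSums(truth$true_abundance), truth$true_density,
               tolerance = 1e-9)
})

test_that("sequencing columns sum to the realised depths", {
  cfg <- quiet_config(n_donors = 3, n_taxa = 10, depth = 500,
                      technical_cv = 0.15)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  ct <- simulate_sequencing(truth, cfg)
  expect_equal(unname(colSums(ct$counts)), rep(500, 6))
})

test_that("a single read lands on exactly one taxon", {
  cfg <- quiet_config(n_donors = 1, n_taxa = 8)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  cfg$read_depth_mean[] <- 1  # below the config floor; exercises the sampler
  ct <- simulate_sequencing(truth, cfg)
  expect_equal(unname(colSums(ct$counts)), rep(1, 2))
  expect_equal(unname(colSums(ct$counts >= 1)), rep(1, 2))
})

test_that("a growth-consistent treatment arm keeps non-responders at their control level", {
  cfg <- quiet_config(n_donors = 2, n_taxa = 4,
                      effect_specs = effect_spec("trt", "OTU001", 1))
  cfg$treatment_density_mean <- c(trt = NA_real_)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  fc <- true_fold_change(truth, "trt", cfg)
  expect_equal(unname(fc["OTU001", ]), c(2, 2), tolerance = 1e-12)
  expect_equal(unname(fc[c("OTU002", "OTU003", "OTU004"), "D1"]),
               rep(1, 3), tolerance = 1e-12)
  # the arm's total density follows the planted growth: 1 + 0.25 extra
  expect_equal(unname(truth$true_density["D1_trt"] /
                        truth$true_density["D1_NSC"]), 1.25,
               tolerance = 1e-12)
})

test_that("a 50/50 two-taxon sample at depth 1000 has binomial expectation", {
  cfg <- quiet_config(n_donors = 200, n_taxa = 2, depth = 1000)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  ct <- simulate_sequencing(truth, cfg)
  nsc <- grepl("_NSC$", colnames(ct$counts))
  m <- mean(ct$counts["OTU001", nsc])
  # per-sample SD sqrt(1000 * .25) ~ 15.8; SE over 200 samples ~ 1.12
  expect_lt(abs(m - 500), 4.5)
})

test_that("empirical proportions converge to the truth at high depth", {
  cfg <- quiet_config(n_donors = 1, n_taxa = 10, depth = 1e6)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  ct <- simulate_sequencing(truth, cfg)
  p_hat <- ct$counts[, "D1_NSC"] / sum(ct$counts[, "D1_NSC"])
  p <- truth$true_abundance[, "D1_NSC"] / truth$true_density["D1_NSC"]
  expect_true(all(abs(p_hat - p) < 3 * sqrt(p * (1 - p) / 1e6) + 1e-9))
})

test_that("measured cell counts equal the truth when density_cv is zero", {
  cfg <- quiet_config(n_donors = 3, n_taxa = 4)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  d1 <- simulate_cell_counts(truth, cfg)
  d2 <- simulate_cell_counts(truth, cfg)
  expect_identical(d1, d2)
  expect_equal(d1$total_cells_per_ml, unname(truth$true_density))
})

test_that("mean measured control density matches the configured 3.0e9 cells/mL", {
  cfg <- qmp_sim_config(n_donors = 150, effect_specs = NULL, rng_seed = 5)
  truth <- apply_effects(generate_baseline(cfg), cfg)
  dens <- simulate_cell_counts(truth, cfg)
  nsc <- truth$metadata$sample_id[truth$metadata$condition == "NSC"]
  m <- mean(dens$total_cells_per_ml[dens$sample_id %in% nsc])
  expect_lt(abs(m / 3.0e9 - 1), 0.05)
})

test_that("a full experiment has one sample per donor and condition", {
  ex <- generate_experiment(qmp_sim_config(rng_seed = 2))
  expect_identical(ncol(ex$counts$counts), 18L)  # 6 donors x 3 conditions
  expect_identical(colnames(ex$counts$counts), ex$metadata$sample_id)
  expect_identical(colnames(ex$truth$true_abundance),
                   colnames(ex$counts$counts))
  expect_setequal(unique(ex$metadata$condition), c("NSC", "inulin", "dextran"))

  # minimal configuration completes
  ex_min <- generate_experiment(quiet_config(n_donors = 1, n_taxa = 2))
  expect_identical(dim(ex_min$counts$counts), c(2L, 2L))

  # end-to-end seeded determinism
  ex2 <- generate_experiment(qmp_sim_config(rng_seed = 2))
  expect_identical(ex$counts$counts, ex2$counts$counts)
  expect_identical(ex$densities, ex2$densities)
})

test_that("noise-free deep sequencing recovers ground truth through quantify", {
  cfg <- quiet_config(n_donors = 2, n_taxa = 10, depth = 4e6,
                      effect_specs = effect_spec("trt", "OTU003", 1.5))
  truth <- apply_effects(generate_baseline(cfg), cfg)
  counts <- simulate_sequencing(truth, cfg)
  dens <- simulate_cell_counts(truth, cfg)
  est <- quantify(counts, dens)$cells_per_ml
  expect_true(all(abs(est / truth$true_abundance - 1) < 0.01))
})

test_that("config validation rejects inconsistent effect specs and parameters", {
  expect_error(quiet_config(effect_specs = effect_spec("trt", "OTU099", 1)),
               "outside the generated set")
  expect_error(quiet_config(effect_specs = effect_spec("NSC", "OTU001", 1)),
               "control arm|unknown treatment")
  expect_error(qmp_sim_config(technical_cv = -0.1), "must be >= 0")
  expect_error(qmp_sim_config(read_depth_mean = c(NSC = 50, inulin = 200,
                                                  dextran = 200)),
               ">= 100")
})

test_that("synthetic metabolites follow the condition profile", {
  md <- data.frame(sample_id = sprintf("D%d_%s", rep(1:40, each = 3),
                                       rep(c("NSC", "inulin", "dextran"), 40)),
                   donor_id = sprintf("D%d", rep(1:40, each = 3)),
                   condition = rep(c("NSC", "inulin", "dextran"), 40),
                   stringsAsFactors = FALSE)
  tab <- generate_metabolites(md, seed = 4)
  expect_true(all(tab$pH > 0 & tab$pH < 14))
  expect_true(all(tab[setdiff(names(tab), c("sample_id", "pH"))] >= 0))
  prof <- default_metabolite_profile()
  by_cond <- split(tab, md$condition)
  for (cond in names(by_cond)) {
    expect_lt(abs(mean(by_cond[[cond]]$propionate) /
                    prof$means[cond, "propionate"] - 1), 0.1)
  }
  expect_error(generate_metabolites(data.frame(sample_id = "a",
                                               donor_id = "D1",
                                               condition = "mystery")),
               "lacks condition")
})
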