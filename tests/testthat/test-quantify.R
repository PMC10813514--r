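test_that("relative abundances are per-sample proportions", {
  ct <- count_table(matrix(c(3L, 1L), nrow = 2,
                           dimnames = list(c("a", "b"), "S1")))
  expect_equal(unname(relative_abundances(ct)[, 1]), c(0.75, 0.25))

  single <- count_table(matrix(7L, dimnames = list("a", "S1")))
  expect_equal(unname(relative_abundances(single)[1, 1]), 1)

  zero <- matrix(c(1, 2, 0, 0), nrow = 2,
                 dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_error(relative_abundances(zero), "zero total reads: S2")
})

test_that("column sums of proportions are exactly one across random tables", {
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(60, lambda = 10) + (i == 1), nrow = 6)
    dimnames(m) <- list(paste0("t", 1:6), paste0("s", 1:10))
    m[1, ] <- m[1, ] + 1  # guard against all-zero columns
    expect_equal(unname(colSums(relative_abundances(m))), rep(1, 10),
                 tolerance = 1e-12)
  }
})

test_that("absolute abundances scale proportions by the sample density", {
  prop <- matrix(c(0.5, 0.5, 1, 0), nrow = 2,
                 dimnames = list(c("a", "b"), c("S1", "S2")))
  dens <- data.frame(sample_id = c("S1", "S2"),
                     total_cells_per_ml = c(1.0e9, 2.0e9))
  abs1 <- absolute_abundances(prop, dens)
  expect_equal(unname(abs1[, "S1"]), c(5e8, 5e8))
  expect_equal(unname(abs1["b", "S2"]), 0)  # zero proportion stays zero
  expect_equal(colSums(abs1), c(S1 = 1.0e9, S2 = 2.0e9))

  dens2 <- dens
  dens2$total_cells_per_ml[1] <- 2.0e9
  abs2 <- absolute_abundances(prop, dens2)
  expect_equal(abs2[, "S1"], 2 * abs1[, "S1"])  # linearity in density

  expect_error(absolute_abundances(prop, dens[1, ]),
               "no cell density for sample\\(s\\): S2")
})

test_that("proportional detection limit is one read in the total", {
  expect_equal(lod_fraction(1), 100)
  expect_equal(lod_fraction(18197), 100 / 18197)
  expect_error(lod_fraction(0), ">= 1")
})

test_that("reported LOD percentages reproduce the reference depths' limits", {
  expect_identical(lod_percent(c(18197, 32779, 25621)), c(0.006, 0.003, 0.004))
  expect_identical(lod_percent(1), 100)
})

test_that("cells/mL detection limit is density over reads", {
  expect_equal(sample_lod(10, 1000), 100)
  expect_equal(sample_lod(18197, 3.0e9), 3.0e9 / 18197)  # 1.6487...e5
  expect_error(sample_lod(0, 1e9), ">= 1")
  expect_error(sample_lod(10, 0), "> 0")

  reads <- c(1, 10, 100, 1e4, 1e6)
  dens <- c(1e6, 1e8, 3e9, 8.3e9)
  for (d in dens) expect_true(all(diff(sample_lod(reads, d)) < 0))
  for (r in reads) expect_true(all(diff(sample_lod(r, dens)) > 0))
  grid <- expand.grid(reads = reads, dens = dens)
  expect_equal(sample_lod(grid$reads, grid$dens),
               grid$dens * lod_fraction(grid$reads) / 100, tolerance = 1e-15)
})

test_that("quantify records per-sample LODs and reproduces densities", {
  ex <- generate_experiment(qmp_sim_config(rng_seed = 6))
  ab <- quantify(ex$counts, ex$densities)
  d <- stats::setNames(ex$densities$total_cells_per_ml,
                       ex$densities$sample_id)
  expect_equal(colSums(ab$cells_per_ml), d[colnames(ab$cells_per_ml)],
               tolerance = 1e-9)
  expect_equal(ab$lod, d[names(ab$lod)] / colSums(ex$counts$counts),
               tolerance = 1e-12)
  expect_false(any(ab$imputed))
})

test_that("imputation floors entries at the overall LOD and flags them", {
  ct <- count_table(matrix(c(999L, 1L, 0L, 100L, 100L, 0L), nrow = 3,
                           dimnames = list(c("a", "b", "c"), c("S1", "S2"))))
  dens <- data.frame(sample_id = c("S1", "S2"),
                     total_cells_per_ml = c(1e6, 2e6))
  ab <- quantify(ct, dens)
  # per-sample LODs: 1e6/1000 = 1e3 and 2e6/200 = 1e4; overall = 1e4
  imp <- impute_below_lod(ab)
  expect_equal(imp$lod_applied$overall, 1e4)
  expect_true(min(imp$cells_per_ml) >= 1e4)
  expect_identical(unname(imp$imputed[, "S1"]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(imp$cells_per_ml["b", "S1"]), 1e4)  # was 1e3
  expect_equal(unname(imp$cells_per_ml["a", "S1"]), 999e3) # untouched

  persample <- impute_below_lod(ab, policy = "per-sample")
  expect_equal(unname(persample$cells_per_ml["b", "S1"]), 1e3)

  # all entries above the LOD: nothing changes
  ct2 <- count_table(matrix(c(500L, 500L), nrow = 2,
                            dimnames = list(c("a", "b"), "S1")))
  ab2 <- impute_below_lod(quantify(ct2, dens[1, ]))
  expect_false(any(ab2$imputed))
  expect_equal(ab2$cells_per_ml, quantify(ct2, dens[1, ])$cells_per_ml)
})

test_that("top-n selection ranks by mean abundance with lexicographic ties", {
  ct <- count_table(matrix(c(5L, 2L, 9L), nrow = 3,
                           dimnames = list(c("t1", "t2", "t3"), "S1")))
  dens <- data.frame(sample_id = "S1", total_cells_per_ml = 16)
  ab <- quantify(ct, dens)
  expect_identical(rownames(select_top_n(ab, 2)$cells_per_ml), c("t3", "t1"))
  expect_identical(nrow(select_top_n(ab, 99)$cells_per_ml), 3L)

  tie <- count_table(matrix(c(3L, 3L, 2L), nrow = 3,
                            dimnames = list(c("b", "a", "c"), "S1")))
  ab2 <- quantify(tie, data.frame(sample_id = "S1", total_cells_per_ml = 8))
  expect_identical(rownames(select_top_n(ab2, 1)$cells_per_ml), "a")
})

test_that("abundance tables round-trip through TSV", {
  ex <- generate_experiment(quiet_config(n_donors = 2, n_taxa = 6,
                                         technical_cv = 0.1))
  ab <- impute_below_lod(quantify(ex$counts, ex$densities))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(ab, path)
  back <- read_abundance_table(path)
  expect_equal(back$cells_per_ml, ab$cells_per_ml, tolerance = 1e-6)
  expect_identical(back$taxonomy, ab$taxonomy)
})
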