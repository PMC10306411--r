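test_that("dataset splitting partitions columns exactly", {
  ds <- tiny_dataset(matrix(1:8, 2), q = c(1, 2), t = c(-5, 1, 100, 1000))
  halves <- split_dataset(ds, 100)
  expect_equal(halves$early$t, c(-5, 1))
  expect_equal(halves$late$t, c(100, 1000))
  expect_identical(cbind(halves$early$matrix, halves$late$matrix), ds$matrix)
  expect_error(split_dataset(ds, -5), "both sides")
  expect_error(split_dataset(ds, -100), "both sides")
})

test_that("data fully inside the trivial span pass the null test", {
  sc <- sim_config_chi3_like(hidden = FALSE, noise_rel = 0.05, seed = 2)
  sim <- simulate_dataset(sc$config)
  rep <- residual_test(sim$dataset, sc$trivials, factor = 3)
  expect_identical(rep$decision, "consistent_with_null")
  expect_true(rep$residual_fraction <= 3 * rep$noise_floor)
  expect_equal(nrow(rep$per_delay_norms), length(sim$dataset$t))
})

test_that("noiseless data in the trivial span leave a negligible residual", {
  sc <- sim_config_chi3_like(hidden = FALSE)
  sim <- simulate_dataset(sc$config)
  # no noise: use an explicit sigma floor for the decision denominator
  ds <- sim$dataset
  ds$sigma <- matrix(1e-6, length(ds$q), length(ds$t))
  rep <- residual_test(ds, sc$trivials)
  expect_lt(rep$residual_fraction, 1e-12)
  expect_identical(rep$decision, "consistent_with_null")
})

test_that("a hidden species produces a detectable projection residual", {
  sc <- sim_config_chi3_like(hidden = TRUE, noise_rel = 0.05, seed = 2)
  sim <- simulate_dataset(sc$config)
  rep <- residual_test(sim$dataset, sc$trivials, factor = 3)
  expect_identical(rep$decision, "signal_remains")
  rsv1 <- svd_decompose(rep$pepc)$rsv[, 1]
  expect_gt(abs(stats::cor(rsv1, sc$hidden_f)), 0.99)
})

test_that("the full pipeline recovers kinetics, species curves and hydrodynamics", {
  cfg <- sim_config_gtc_like(n_t = 40, noise_rel = 0.02, seed = 3,
                             basis_mode = "distinct")
  sim <- simulate_dataset(cfg)
  out <- run_full_analysis(list(
    data = sim$dataset, trivials = cfg$solvent_basis,
    n_exp = 3, irf_fwhm_ps = 0.48, t0_ps = 0, R = 1000,
    species = c("T1prime", "T1", "tetramer"),
    candidates = sim$truth$sads_real,
    solvent_basis = cfg$solvent_basis))
  expect_equal(out$rank, 3L)
  expect_lt(max(abs(out$fit$taus - c(1.7, 1000, 114000)) /
                  c(1.7, 1000, 114000)), 0.05)
  expect_length(out$corrections, 3L)
  expect_lt(rel_l2(out$hydro$dT, sim$truth$dT), 0.05)
  expect_identical(out$summary$selected_rank, 3L)
})

test_that("pipeline reruns and stage composition are file-identical", {
  cfg <- sim_config_gtc_like(n_t = 25, noise_rel = 0.05, seed = 6,
                             basis_mode = "distinct")
  sim <- simulate_dataset(cfg)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  conf <- list(data = sim$dataset, trivials = cfg$solvent_basis,
               n_exp = 3, irf_fwhm_ps = 0.48, R = 1000,
               candidates = sim$truth$sads_real,
               solvent_basis = cfg$solvent_basis)
  conf$out_dir <- dir1; run_full_analysis(conf)
  conf$out_dir <- dir2; run_full_analysis(conf)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)), label = f)
  }
  # pepc product equals the standalone stage output written the same way
  direct <- pepc_multi(sim$dataset, cfg$solvent_basis)$pepc
  p <- withr::local_tempfile()
  write_matrix(direct, p)
  expect_identical(readLines(p),
                   readLines(file.path(dir1, "pepc_matrix.tsv")))
})

test_that("early/late split analyses see their local kinetics", {
  cfg <- sim_config_gtc_like(n_t = 50, basis_mode = "distinct")
  sim <- simulate_dataset(cfg)
  out <- run_full_analysis(list(
    data = sim$dataset, trivials = cfg$solvent_basis,
    n_exp = 3, irf_fwhm_ps = 0.48, R = 1000,
    t_split = 100, n_exp_split = 2))
  expect_named(out$splits, c("early", "late"))
  expect_gte(out$splits$early$rank, 1L)
  expect_gte(out$splits$late$rank, 1L)
  # the fast 1.7 ps process lives in the early window
  expect_true(any(abs(out$splits$early$fit$taus - 1.7) / 1.7 < 0.1))
})

test_that("stage failures carry the stage name", {
  cfg <- sim_config_gtc_like(n_t = 10)
  sim <- simulate_dataset(cfg)
  bad <- trivial_set(curve_on(c(1, 2), c(1, 0)))
  expect_error(run_full_analysis(list(data = sim$dataset, trivials = bad)),
               "stage 'pepc'")
})
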