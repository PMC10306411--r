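test_that("a single first-order decay follows the textbook solution", {
  m <- kinetic_model("A", taus = 10)
  t <- c(0, 5, 10, 30)
  cp <- concentration_profiles(m, t)
  expect_equal(cp$C[, 1], exp(-t / 10))
  m2 <- kinetic_model(c("A", "B"), taus = c(10, 1e9))
  cp2 <- concentration_profiles(m2, t)
  expect_equal(cp2$C[, 2], 1 - exp(-t / 10), tolerance = 1e-7)
})

test_that("sequential chains match independent ODE integration", {
  taus <- c(10, 1000)
  m <- kinetic_model(c("A", "B"), taus = taus)
  t <- 10^seq(-1, 4, length.out = 25)
  cp <- concentration_profiles(m, t)
  # independent oracle: dense Runge-Kutta integration of the rate equations
  k <- 1 / taus
  deriv <- function(tt, y, p) list(c(-k[1] * y[1], k[1] * y[1] - k[2] * y[2]))
  sol <- deSolve::ode(c(1, 0), times = c(0, t), deriv, parms = NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  expect_equal(cp$C[, 1], sol[-1, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(cp$C[, 2], sol[-1, 3], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("mass is conserved including the implicit ground state", {
  m <- kinetic_model(c("A", "B", "C"), taus = c(1.7, 1000, 114000),
                     irf_fwhm = 0.48)
  t <- c(-5, 10^seq(-1, 6, length.out = 40))
  cp <- concentration_profiles(m, t)
  expect_true(all(cp$C >= 0 & cp$C <= 1))
  # before excitation nothing is populated; afterwards row sums decay from 1
  expect_true(all(rowSums(cp$C) <= 1 + 1e-9))
  mid <- which(t > 1 & t < 100)
  expect_true(all(rowSums(cp$C[mid, ]) > 0.99))
})

test_that("rate-matrix models agree with the equivalent sequential chain", {
  taus <- c(5, 800)
  K <- matrix(c(-1 / 5, 1 / 5, 0, -1 / 800), 2, 2)
  t <- 10^seq(-1, 4, length.out = 20)
  seq_m <- kinetic_model(c("A", "B"), taus = taus, irf_fwhm = 0.3)
  mat_m <- kinetic_model(c("A", "B"), K = K, irf_fwhm = 0.3)
  expect_equal(concentration_profiles(mat_m, t)$C,
               concentration_profiles(seq_m, t)$C, tolerance = 1e-9)
})

test_that("degenerate repeated rates fall back to numerical integration", {
  m <- kinetic_model(c("A", "B"), taus = c(10, 10))
  t <- c(1, 5, 10, 50)
  cp <- concentration_profiles(m, t)
  # closed form for equal rates: f_B = (t/tau) exp(-t/tau)
  expect_equal(cp$C[, 2], (t / 10) * exp(-t / 10), tolerance = 1e-6)
})

test_that("model construction rejects inconsistent inputs", {
  expect_error(kinetic_model(c("A", "B"), taus = c(1, -2)), "positive")
  expect_error(kinetic_model("A", taus = 1, initial_fractions = c(0.5, 0.5)),
               "simplex")
  expect_error(kinetic_model("A", taus = 1, K = matrix(-1)), "not both")
  expect_error(kinetic_model(c("A", "B"), K = matrix(c(1, 0, 0, -1), 2, 2)),
               "conserve mass")
})

test_that("noiseless species extraction inverts the forward model", {
  cfg <- sim_config_gtc_like(n_t = 30)
  sim <- simulate_dataset(cfg)
  pepc <- pepc_multi(sim$dataset, cfg$solvent_basis)$pepc
  sp <- extract_sads(pepc, sim$truth$conc, svd_rank = 3)
  for (k in 1:3)
    expect_lt(rel_l2(sp$curves[[k]]$values,
                     sim$truth$sads_perp$curves[[k]]$values), 1e-8)
  expect_identical(sp$kind, "pepc")
  expect_length(sp$residual_norms, 3L)
})

test_that("single-species data divide out to one consistent curve", {
  q <- seq(0.5, 8, length.out = 30)
  t <- 10^seq(-1, 3, length.out = 15)
  m <- kinetic_model("X", taus = 100)
  conc <- concentration_profiles(m, t, R = 500)
  s_true <- exp(-q) * sin(3 * q)
  ds <- trxl_dataset(q, t, (1 / 500) * s_true %o% conc$C[, 1])
  sp <- extract_sads(ds, conc)
  expect_equal(sp$curves[[1]]$values, s_true, tolerance = 1e-10)
})

test_that("permuting species order permutes the extracted curves", {
  cfg <- sim_config_gtc_like(n_t = 25)
  sim <- simulate_dataset(cfg)
  pepc <- pepc_multi(sim$dataset, cfg$solvent_basis)$pepc
  conc <- sim$truth$conc
  perm <- c(3, 1, 2)
  conc_p <- structure(list(t = conc$t, C = conc$C[, perm],
                           species = conc$species[perm], R = conc$R),
                      class = "concentration_matrix")
  sp <- extract_sads(pepc, conc, svd_rank = 3)
  sp_p <- extract_sads(pepc, conc_p, svd_rank = 3)
  for (i in seq_along(perm))
    expect_equal(sp_p$curves[[i]]$values, sp$curves[[perm[i]]]$values,
                 tolerance = 1e-9)
})

test_that("indistinguishable kinetics trigger a conditioning error", {
  q <- seq(0.5, 8, length.out = 20)
  t <- 10^seq(-1, 3, length.out = 10)
  prof <- exp(-t / 50)
  conc <- structure(list(t = t, C = cbind(prof, prof * (1 + 1e-13)),
                         species = c("A", "B"), R = 1),
                    class = "concentration_matrix")
  ds <- trxl_dataset(q, t, exp(-q) %o% prof)
  expect_error(extract_sads(ds, conc), "ill-conditioned")
})
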