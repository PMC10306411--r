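test_that("single-component projection reproduces hand-computed cases", {
  # column (3, 4) against basis (1, 0): parallel (3, 0), residual (0, 4)
  ds <- tiny_dataset(cbind(c(3, 4)))
  e1 <- curve_on(c(1, 2), c(1, 0))
  par <- project_parallel_single(ds, e1)
  expect_equal(par$matrix[, 1], c(3, 0))
  res <- pepc_single(ds, e1)
  expect_equal(res$pepc$matrix[, 1], c(0, 4))

  # column equal to the basis is returned unchanged by the projection
  u <- curve_on(c(1, 2, 3), c(2, -1, 0.5))
  ds2 <- tiny_dataset(cbind(u$values))
  expect_equal(project_parallel_single(ds2, u)$matrix[, 1], u$values)
  expect_equal(pepc_single(ds2, u)$pepc$matrix[, 1], rep(0, 3),
               tolerance = 1e-14)

  # (1,2,3) against (1,1,1): dot-product oracle gives parallel (2,2,2)
  ds3 <- tiny_dataset(cbind(c(1, 2, 3)))
  ones <- curve_on(c(1, 2, 3), c(1, 1, 1))
  expect_equal(project_parallel_single(ds3, ones)$matrix[, 1], c(2, 2, 2))
  expect_equal(pepc_single(ds3, ones)$pepc$matrix[, 1], c(-1, 0, 1))
})

test_that("zero-norm basis is rejected", {
  ds <- tiny_dataset(cbind(c(1, 2)))
  z <- structure(list(q = c(1, 2), values = c(0, 0), label = "z",
                      sigma = NULL), class = "trxl_curve")
  expect_error(project_parallel_single(ds, z), "zero norm")
})

test_that("multi-component projection solves orthonormal, collinear and oblique sets", {
  q3 <- c(1, 2, 3)
  # orthonormal axes: weights are the coordinates
  ts <- trivial_set(curve_on(q3, c(1, 0, 0)), curve_on(q3, c(0, 1, 0)))
  res <- pepc_multi(tiny_dataset(cbind(c(5, 7, 2)), q = q3), ts)
  expect_equal(res$pepc$matrix[, 1], c(0, 0, 2))
  expect_equal(unname(res$weights[, 1]), c(5, 7))
  expect_equal(res$trivial_rank, 2L)

  # collinear pair: rank 1, minimum-norm weights (0.6, 1.2) frozen from the
  # pseudoinverse of B = [(1,0), (2,0)] applied to (3, 4)
  tsc <- trivial_set(curve_on(c(1, 2), c(1, 0)), curve_on(c(1, 2), c(2, 0)))
  resc <- pepc_multi(tiny_dataset(cbind(c(3, 4))), tsc)
  expect_equal(resc$pepc$matrix[, 1], c(0, 4))
  expect_equal(resc$trivial_rank, 1L)
  expect_equal(unname(resc$weights[, 1]), c(0.6, 1.2))

  # oblique pair (1,1,0), (1,0,0) with column (2,3,5): Gram solve gives
  # weights (3, -1), parallel (2,3,0), residual (0,0,5)
  tso <- trivial_set(curve_on(q3, c(1, 1, 0)), curve_on(q3, c(1, 0, 0)))
  reso <- pepc_multi(tiny_dataset(cbind(c(2, 3, 5)), q = q3), tso)
  expect_equal(reso$pepc$matrix[, 1], c(0, 0, 5), tolerance = 1e-12)
  expect_equal(unname(reso$weights[, 1]), c(3, -1), tolerance = 1e-12)

  expect_error(pepc_multi(tiny_dataset(cbind(c(1, 2))), list()), "trivial_set")
})

test_that("parallel + residual reconstructs the input and the residual is orthogonal", {
  for (seed in 1:25) {
    inst <- random_projection_instance(seed)
    res <- pepc_multi(inst$ds, inst$trivials)
    expect_lt(max(abs(res$pepc$matrix + res$parallel$matrix -
                        inst$ds$matrix)),
              1e-12 * max(abs(inst$ds$matrix)))
    dots <- crossprod(inst$trivials$basis, res$pepc$matrix)
    scale <- outer(sqrt(colSums(inst$trivials$basis^2)),
                   sqrt(colSums(inst$ds$matrix^2)))
    expect_lt(max(abs(dots) / scale), 1e-10)
    expect_lte(res$trivial_rank, n_components(inst$trivials))
  }
})

test_that("projection is idempotent and linear", {
  inst <- random_projection_instance(101)
  res1 <- pepc_multi(inst$ds, inst$trivials)
  res2 <- pepc_multi(res1$pepc, inst$trivials)
  expect_equal(res2$pepc$matrix, res1$pepc$matrix, tolerance = 1e-12)

  instb <- random_projection_instance(102)
  dsb <- trxl_dataset(inst$ds$q, inst$ds$t,
                      matrix(rnorm(length(inst$ds$matrix)),
                             nrow(inst$ds$matrix)))
  a <- 2.3; b <- -0.7
  combo <- trxl_dataset(inst$ds$q, inst$ds$t,
                        a * inst$ds$matrix + b * dsb$matrix)
  lhs <- pepc_multi(combo, inst$trivials)$pepc$matrix
  rhs <- a * pepc_multi(inst$ds, inst$trivials)$pepc$matrix +
    b * pepc_multi(dsb, inst$trivials)$pepc$matrix
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("the residual depends only on the span of the trivial set", {
  inst <- random_projection_instance(7)
  ts <- inst$trivials
  m <- n_components(ts)
  res0 <- pepc_multi(inst$ds, ts)$pepc$matrix
  # invertible recombination
  set.seed(99)
  A <- matrix(rnorm(m * m), m, m) + diag(m) * 2
  mixed <- lapply(seq_len(m), function(i)
    trxl_curve(ts$q, drop(ts$basis %*% A[, i]), paste0("mix", i)))
  res1 <- pepc_multi(inst$ds, trivial_set(mixed))$pepc$matrix
  expect_lt(max(abs(res1 - res0)), 1e-10 * max(abs(inst$ds$matrix)))
  # duplicated component
  dup <- trivial_set(c(ts$components, ts$components[1]))
  res2 <- pepc_multi(inst$ds, dup)$pepc$matrix
  expect_lt(max(abs(res2 - res0)), 1e-10 * max(abs(inst$ds$matrix)))
})

test_that("Gram-Schmidt oracle agrees with the least-squares residual", {
  for (seed in 1:30) {
    inst <- random_projection_instance(seed + 500)
    res <- pepc_multi(inst$ds, inst$trivials)$pepc$matrix
    orc <- orthonormal_projection_oracle(inst$ds, inst$trivials)$matrix
    expect_lt(max(abs(res - orc)), 1e-10 * max(1, max(abs(inst$ds$matrix))))
  }
})

test_that("oracle reduces to the single-component residual and annihilates a full span", {
  inst <- random_projection_instance(11)
  one <- trivial_set(inst$trivials$components[[1]])
  expect_equal(orthonormal_projection_oracle(inst$ds, one)$matrix,
               pepc_single(inst$ds, inst$trivials$components[[1]])$pepc$matrix,
               tolerance = 1e-12)
  # full span of a 2-point grid
  ds <- tiny_dataset(cbind(c(3, 4), c(-1, 2)))
  full <- trivial_set(curve_on(c(1, 2), c(1, 1)), curve_on(c(1, 2), c(1, -1)))
  expect_lt(max(abs(orthonormal_projection_oracle(ds, full)$matrix)), 1e-12)
  expect_lt(max(abs(pepc_multi(ds, full)$pepc$matrix)), 1e-12)
})

test_that("solvent kinetics does not leak into the projected data", {
  # two simulations differing ONLY in the solvent time profiles give
  # identical projection residuals
  cfg1 <- sim_config_gtc_like(n_t = 25)
  cfg2 <- sim_config_gtc_like(n_t = 25)
  cfg2$dT_params <- list(amp_step = 2.4, amp_slow = 0.3, tau_slow_ps = 800)
  cfg2$drho_params <- list(amp = 3.1, tau_rise_ps = 120)
  sim1 <- simulate_dataset(cfg1)
  sim2 <- simulate_dataset(cfg2)
  r1 <- pepc_multi(sim1$dataset, cfg1$solvent_basis)$pepc$matrix
  r2 <- pepc_multi(sim2$dataset, cfg2$solvent_basis)$pepc$matrix
  expect_lt(max(abs(r1 - r2)), 1e-10 * max(abs(sim1$dataset$matrix)))
})

test_that("sigma-weighted projection still removes the trivial span exactly when it should", {
  q <- seq(1, 5, length.out = 20)
  base <- curve_on(q, sin(q))
  ds <- trxl_dataset(q, c(1, 10), cbind(3 * sin(q), -2 * sin(q)),
                     sigma = matrix(runif(40, 0.5, 2), 20, 2))
  res <- pepc_multi(ds, trivial_set(base), sigma_weighted = TRUE)
  expect_lt(max(abs(res$pepc$matrix)), 1e-12)
})
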