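test_that("curve and dataset constructors enforce their invariants", {
  expect_error(trxl_curve(q = c(2, 1, 3), values = 1:3), "increasing")
  expect_error(trxl_curve(q = c(-1, 1), values = 1:2), "positive")
  expect_error(trxl_curve(q = c(1, 2), values = 1:3), "equal length")
  expect_error(trxl_curve(q = c(1, 2), values = 1:2, sigma = c(-1, 0)),
               "non-negative")
  expect_error(trxl_dataset(q = c(1, 2), t = c(5, 1),
                            matrix = matrix(0, 2, 2)), "increasing")
  expect_error(trxl_dataset(q = c(1, 2), t = 1,
                            matrix = matrix(c(1, NA), 2, 1)), "non-finite")
  ds <- trxl_dataset(q = c(1, 2, 3), t = c(10, 100),
                     matrix = matrix(1:6, 3, 2))
  expect_identical(dim(ds$matrix), c(3L, 2L))
})

test_that("trivial sets require a shared grid and nonzero components", {
  q <- c(1, 2, 3)
  expect_error(trivial_set(trxl_curve(q, c(0, 0, 0))), "zero vector")
  expect_error(trivial_set(trxl_curve(q, 1:3),
                           trxl_curve(q + 0.5, 1:3)), "q-grid")
  ts <- trivial_set(trxl_curve(q, 1:3, "a"), trxl_curve(q, 3:1, "b"))
  expect_equal(n_components(ts), 2L)
  expect_identical(ts$labels, c("a", "b"))
})

test_that("matrix files round-trip at full precision", {
  ds <- trxl_dataset(q = c(1, exp(1), pi, 5.123456789012345),
                     t = c(-3.5, 1 / 3, 100),
                     matrix = matrix(rnorm(12), 4, 3),
                     sigma = matrix(abs(rnorm(12)), 4, 3),
                     meta = list(solvent = "water", R = 1000))
  path <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(ds, path, sigma_path = spath)
  back <- read_matrix(path, sigma_path = spath)
  expect_equal(back$q, ds$q, tolerance = 1e-14)
  expect_equal(back$t, ds$t, tolerance = 1e-14)
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-14)
  expect_equal(back$sigma, ds$sigma, tolerance = 1e-14)
  expect_equal(back$meta$solvent, "water")
  expect_equal(back$meta$R, 1000)
})

test_that("malformed matrix files produce located parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# t: 10 100", "1.0\t1\t2", "oops\t3\t4", "3.0\t5\t6"), path)
  expect_error(read_matrix(path), "row 2.*not numeric")
  writeLines(c("# t: 10 100", "2.0\t1\t2", "1.0\t3\t4", "3.0\t5\t6"), path)
  expect_error(read_matrix(path), "increasing")
  writeLines(c("1.0\t1\t2", "2.0\t3\t4"), path)
  expect_error(read_matrix(path), "delay line")
})

test_that("curve files round-trip, with and without sigma", {
  path <- withr::local_tempfile(fileext = ".tsv")
  crv <- trxl_curve(q = c(0.5, 1.5, 2.5, 3.5, 4.5),
                    values = rnorm(5), label = "heating")
  write_curve(crv, path)
  back <- read_curve(path)
  expect_equal(back$values, crv$values, tolerance = 1e-14)
  expect_identical(back$label, "heating")
  expect_null(back$sigma)
  crv$sigma <- abs(rnorm(5))
  write_curve(crv, path)
  expect_equal(read_curve(path)$sigma, crv$sigma, tolerance = 1e-14)
})

test_that("curve files reject wrong column counts and negative q", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1.0", "2.0"), path)
  expect_error(read_curve(path), "2 or 3 columns")
  writeLines(c("-1.0\t5", "2.0\t6"), path)
  expect_error(read_curve(path), "positive")
})

test_that("strict alignment passes identical grids and rejects others", {
  q <- c(1, 2, 3)
  a <- curve_on(q, c(1, 2, 3)); b <- curve_on(q, c(4, 5, 6))
  out <- align_to_grid(list(a, b), "strict")
  expect_identical(out[[1]]$values, a$values)
  expect_error(align_to_grid(list(a, curve_on(c(1, 2.1, 3), 1:3)), "strict"),
               "differ")
})

test_that("interpolation alignment is linear, idempotent, and rejects disjoint ranges", {
  ref <- curve_on(c(1.5, 2.5), c(0, 0))
  crv <- curve_on(c(1, 2, 3), c(10, 20, 30))
  out <- align_to_grid(list(ref, crv), "interpolate")
  expect_equal(out[[2]]$values, c(15, 25))
  again <- align_to_grid(out, "interpolate")
  expect_equal(again[[2]]$values, out[[2]]$values)
  expect_equal(again[[2]]$q, out[[2]]$q)
  far <- curve_on(c(30, 40), c(1, 2))
  expect_error(align_to_grid(list(crv, far), "interpolate"), "disjoint")
})

test_that("datasets align alongside curves onto the reference grid", {
  ds <- tiny_dataset(cbind(c(10, 20, 30), c(1, 2, 3)), q = c(1, 2, 3))
  ref <- curve_on(c(1.5, 2.5), c(0, 0))
  out <- align_to_grid(list(ref, ds), "interpolate")
  expect_equal(out[[2]]$matrix, cbind(c(15, 25), c(1.5, 2.5)))
})
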