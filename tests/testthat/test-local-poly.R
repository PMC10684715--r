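# The local 3D polynomial model and integer-offset estimation.

test_that("polynomial_basis builds the tensor-product monomials in order", {
  expect_equal(polynomial_basis(c(3, 5, 7), orders = c(1, 0, 0)),
               matrix(c(1, 3), 1))
  X <- polynomial_basis(c(1, 2, 3), orders = c(2, 2, 2))
  expect_equal(ncol(X), 27L)
  expect_equal(X[1, 1], 1)
  # at the normalization center every non-constant term vanishes
  Xc <- polynomial_basis(c(4, 5, 6), orders = c(2, 2, 2),
                         center = c(4, 5, 6), scale = c(2, 2, 2))
  expect_equal(as.numeric(Xc), c(1, rep(0, 26)))
  # lexicographic (l, m, n): second term is z (n = 1)
  X2 <- polynomial_basis(c(2, 3, 4), orders = c(1, 1, 1))
  expect_equal(as.numeric(X2), c(1, 4, 3, 12, 2, 8, 6, 24))
})

test_that("fit_local_polynomial reproduces polynomials and constants exactly", {
  # constant phase
  f <- fit_local_polynomial(matrix(c(1, 2, 3), 1), 2.5, orders = c(2, 2, 2))
  expect_equal(predict(f, c(9, -4, 12)), 2.5)
  expect_equal(f$fit_rms, 0)
  # truth inside the model class on a 5x5x5 grid
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4))
  q <- 1 + 0.1 * g[, 1]^2 - 0.2 * g[, 2] * g[, 3]
  f <- fit_local_polynomial(g, q, orders = c(2, 2, 2))
  expect_lt(f$fit_rms, 1e-8)
  expect_equal(predict(f, c(2, 2, 2)), 1 + 0.4 - 0.8, tolerance = 1e-8)
  expect_error(fit_local_polynomial(matrix(nrow = 0, ncol = 3), numeric(0)),
               "point")
})

test_that("rank-deficient fits return the minimum-norm interpolant", {
  set.seed(31)
  g <- matrix(runif(30, 0, 6), 10, 3)
  y <- runif(10)
  f <- fit_local_polynomial(g, y, orders = c(2, 2, 2))
  # interpolates all 10 phases
  expect_lt(max(abs(predict(f, g) - y)), 1e-8)
  # coefficients match an independent pseudo-inverse solve
  X <- polynomial_basis(g, c(2, 2, 2), f$center, f$scale)
  expect_equal(f$coeffs, oracle_minnorm(X, y), tolerance = 1e-8)
})

test_that("overdetermined solutions match a normal-equations oracle", {
  set.seed(32)
  g <- matrix(runif(600, 0, 10), 200, 3)
  y <- sin(g[, 1]) + 0.3 * g[, 2] - 0.05 * g[, 3]^2 + rnorm(200, 0, 0.1)
  f <- fit_local_polynomial(g, y, orders = c(2, 2, 2))
  X <- polynomial_basis(g, c(2, 2, 2), f$center, f$scale)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(f$coeffs, as.numeric(beta), tolerance = 1e-6)
})

test_that("fits are shift-equivariant and translation-invariant", {
  set.seed(33)
  g <- matrix(runif(240, 0, 8), 80, 3)
  y <- 0.5 * g[, 1] - 0.2 * g[, 2] + rnorm(80, 0, 0.05)
  f0 <- fit_local_polynomial(g, y)
  q <- c(4, 4, 4)
  for (j in c(-3L, 2L)) {
    fj <- fit_local_polynomial(g, y + 2 * pi * j)
    expect_equal(predict(fj, q), predict(f0, q) + 2 * pi * j,
                 tolerance = 1e-8)
    w0 <- wrap_to_principal(predict(f0, q) - 0.3)  # any wrapped value
    expect_equal(estimate_voxel_offset(fj, q, w0),
                 estimate_voxel_offset(f0, q, w0) + j)
  }
  tr <- c(7L, -2L, 5L)
  ft <- fit_local_polynomial(sweep(g, 2, -tr), y)
  expect_equal(predict(ft, q + tr), predict(f0, q), tolerance = 1e-8)
})

test_that("estimate_voxel_offset rounds the prediction gap to whole cycles", {
  f <- fit_local_polynomial(matrix(c(0, 0, 0), 1), 7.0, orders = c(0, 0, 0))
  expect_equal(estimate_voxel_offset(f, c(0, 0, 0), 0.71681), 1L)
  expect_equal(estimate_voxel_offset(f, c(0, 0, 0),
                                     wrap_to_principal(7.0)), 1L)
  f10 <- fit_local_polynomial(matrix(c(0, 0, 0), 1), 10.0,
                              orders = c(0, 0, 0))
  expect_equal(estimate_voxel_offset(f10, c(0, 0, 0), -2.56637), 2L)
  # k is exact whenever the prediction errs by less than pi
  set.seed(34)
  truth <- runif(100, -40, 40)
  wrapped <- wrap_to_principal(truth)
  kref <- round((truth - wrapped) / (2 * pi))
  err <- runif(100, -pi + 1e-6, pi - 1e-6)
  for (i in seq_len(100)) {
    fi <- fit_local_polynomial(matrix(0, 1, 3), truth[i] + err[i],
                               orders = c(0, 0, 0))
    expect_equal(estimate_voxel_offset(fi, c(0, 0, 0), wrapped[i]), kref[i])
  }
})

test_that("reduce_orders falls back for sparse point sets", {
  expect_equal(reduce_orders(100, c(2, 2, 2)), c(2L, 2L, 2L))
  expect_equal(reduce_orders(54, c(2, 2, 2)), c(2L, 2L, 2L))
  expect_equal(reduce_orders(53, c(2, 2, 2)), c(1L, 1L, 1L))
  expect_equal(reduce_orders(16, c(2, 2, 2)), c(1L, 1L, 1L))
  expect_equal(reduce_orders(15, c(2, 2, 2)), c(0L, 0L, 0L))
  expect_equal(reduce_orders(1, c(2, 2, 2)), c(0L, 0L, 0L))
})
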