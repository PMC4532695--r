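test_that("augmented system size is n + k n + k", {
  expect_identical(augmentedDimension(10, 3), 43L)
  expect_identical(augmentedDimension(10, 10), 120L)
  expect_identical(augmentedDimension(3, 2), 11L)
  expect_error(augmentedDimension(10, 11), "k")
  expect_error(augmentedDimension(10, 0), "k")
  sys <- diagonalLinear(c(-1, -2, -3))
  z <- makeAugmentedState(sys$y0, diag(3))
  expect_length(z, augmentedDimension(3, 3))
  expect_length(augmentedRHS(z, sys, 3), augmentedDimension(3, 3))
})

test_that("augmented rhs reproduces diagonal growth rates exactly", {
  rates <- c(-1, -2, -3)
  sys <- diagonalLinear(rates)
  z <- makeAugmentedState(c(1, 1, 1), diag(3))
  dz <- augmentedRHS(z, sys, 3, "continuous")
  # with standard basis tangent vectors, nu_i' = a_i and e_i' = 0
  expect_equal(dz[13:15], rates)
  expect_equal(dz[4:12], rep(0, 9))
  # discrete method integrates the raw tangent map
  dzd <- augmentedRHS(z, sys, 3, "discrete")
  expect_equal(matrix(dzd[4:12], 3, 3), diag(rates), ignore_attr = TRUE)
  expect_equal(dzd[13:15], rep(0, 3))
})

test_that("augmented rhs rejects a drifted tangent frame", {
  sys <- diagonalLinear(c(-1, -2, -3))
  E <- diag(3)
  E[1, 2] <- 1e-3
  z <- makeAugmentedState(c(1, 1, 1), E)
  expect_error(augmentedRHS(z, sys, 3), "orthonormal")
})

test_that("both backends recover the diagonal spectrum to 0.1 %", {
  rates <- c(-1, -2, -3)
  truth <- rates * 1000
  for (seed in 1:3) {
    rc <- computeSpectrum(diagonalLinear(rates), k = 3, tRun = 100,
                          seed = seed)
    rd <- benettinSpectrum(diagonalLinear(rates), k = 3, tRun = 100,
                          seed = seed)
    expect_equal(rc$exponents, truth, tolerance = 1e-3)
    expect_equal(rd$exponents, truth, tolerance = 1e-3)
  }
  # partial spectrum of a larger random stable system: top-3 rates
  set.seed(9)
  rates10 <- sort(-runif(10, 0.2, 3))
  # nearby rates need a longer alignment phase before accumulating
  r <- computeSpectrum(diagonalLinear(rates10), k = 3, tRun = 300,
                       tAlign = 50, seed = 1)
  expect_equal(r$exponents, sort(rates10, decreasing = TRUE)[1:3] * 1000,
               tolerance = 1e-3)
})

test_that("limit cycle benchmark gives a zero and minus-two-mu exponent", {
  for (seed in 1:3) {
    r <- computeSpectrum(hopfNormalForm(1, 1), k = 2, tRun = 3000,
                         seed = seed)
    expect_lt(abs(r$exponents[1]), 0.5)
    expect_equal(r$exponents[2], -2000, tolerance = 5e-3)
  }
})

test_that("Lorenz spectrum: zero exponent, cross-method and trace identity", {
  lz <- lorenz63()
  rc <- computeSpectrum(lz, k = 3, seed = 5)
  rd <- benettinSpectrum(lz, k = 3, seed = 5)
  # flow direction contributes a zero exponent
  expect_lt(min(abs(rc$exponents)), 0.5)
  # continuous and discrete backends agree on the positive exponent
  expect_lt(abs(rc$exponents[1] - rd$exponents[1]) / abs(rd$exponents[1]),
            0.02)
  # full-spectrum sum equals the (constant) Jacobian trace
  trace <- -(10 + 1 + 8 / 3) * 1000
  expect_equal(sum(rc$exponents), trace, tolerance = 0.01)
  expect_equal(sum(rd$exponents), trace, tolerance = 0.01)
})

test_that("backends agree on Liley spectra across seeded input points", {
  p <- demoParams()
  set.seed(33)
  pts <- cbind(runif(6, 0, 30), runif(6, 0, 10))
  for (i in seq_len(nrow(pts))) {
    pp <- setLileyParameters(p, p_ee = pts[i, 1], p_ei = pts[i, 2])
    sys <- lileySystem(pp, seed = i)
    rc <- computeSpectrum(sys, k = 3, tTransient = 3000, tRun = 8000,
                          seed = i)
    rd <- benettinSpectrum(sys, k = 3, tTransient = 3000, tRun = 8000,
                           seed = i)
    expect_false(rc$diverged)
    for (j in 1:3) {
      d <- abs(rc$exponents[j] - rd$exponents[j])
      expect_true(d <= 0.5 || d / abs(rd$exponents[j]) <= 0.02,
                  label = sprintf("point %d exponent %d (%.3f vs %.3f)",
                                  i, j, rc$exponents[j], rd$exponents[j]))
    }
  }
})

test_that("tangent frames stay orthonormal and exponents are ordered", {
  r <- computeSpectrum(lorenz63(), k = 3, tRun = 500, seed = 2)
  expect_lt(r$orthoDrift, 1e-6)
  expect_true(all(diff(r$exponents) <= 1e-9))
  rl <- computeSpectrum(demoParams(), k = 3, tTransient = 2000,
                        tRun = 5000, seed = 2)
  expect_lt(rl$orthoDrift, 1e-6)
})

test_that("identical seeds give bitwise-identical results", {
  a <- computeSpectrum(lorenz63(), k = 3, tRun = 300, seed = 11)
  b <- computeSpectrum(lorenz63(), k = 3, tRun = 300, seed = 11)
  expect_identical(a$exponents, b$exponents)
  expect_identical(a$history, b$history)
  c2 <- computeSpectrum(lorenz63(), k = 3, tRun = 300, seed = 12)
  expect_false(identical(a$exponents, c2$exponents))
})

test_that("lyapunov results serialize to the documented JSON shape", {
  r <- computeSpectrum(diagonalLinear(c(-1, -2)), k = 2, tRun = 50, seed = 1)
  f <- tempfile(fileext = ".json")
  writeLyapunovJSON(r, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(names(j), c("k", "exponents_per_s", "t_transient_ms",
                              "t_run_ms", "seed", "method", "diverged",
                              "history"))
  expect_identical(j$k, 2L)
  expect_false(j$diverged)
  expect_equal(j$exponents_per_s, r$exponents)
})
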