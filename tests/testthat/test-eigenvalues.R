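# Grid, discretized Laplacian, matrix eigenvalues, polishing,
# approximations and the zero-finding pipeline.

test_that("the radial grid matches its defining layout", {
  g <- build_grid(2, shell_geometry(R = 1, gamma = 5))
  expect_equal(g$h, 4)
  expect_equal(g$r, c(1, 5))
  g <- build_grid(5, shell_geometry(R = 1, gamma = 5))
  expect_equal(g$h, 1)
  expect_equal(g$r, 1:5)
  for (p in c(7, 33)) {
    expect_equal(build_grid(p, shell_geometry(R = 2, gamma = 3))$r[p], 6)
  }
  expect_error(build_grid(1, shell_geometry(R = 1, gamma = 5)))
})

test_that("the discretized Laplacian matches the printed stencils", {
  for (dim in c("cyl", "sph")) {
    grid <- build_grid(12, shell_geometry(R = 1, gamma = 5))
    L <- build_discrete_laplacian(dim, grid)
    expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-10)
    h <- grid$h
    if (dim == "cyl") {
      expect_equal(unname(diag(L)[2:11]), rep(-2 / h^2, 10))
    } else {
      r1h <- 1 + h / 2
      expect_equal(L[1, 1], -2 * r1h^2 / grid$r[1]^2 / h^2)
      expect_equal(L[1, 2], +2 * r1h^2 / grid$r[1]^2 / h^2)
    }
    # tridiagonal: nothing beyond the first off-diagonals
    expect_equal(max(abs(L[abs(row(L) - col(L)) > 1])), 0)
  }
})

test_that("the Neumann operator annihilates constants (nu = 0 zero mode)", {
  lam <- matrix_modes("cyl", 0, shell_geometry(1, 5), 400, 2)
  expect_lt(lam[1], 1e-4)
  expect_gt(lam[2], 0.5)
})

test_that("matrix eigenvalues converge at second order in the spacing", {
  exact <- first_polished_zero("cyl", 2, 5, p = 1000)
  ps <- c(250, 500, 1000, 2000)
  errs <- vapply(ps, function(p) {
    abs(matrix_modes("cyl", 2, shell_geometry(1, 5), p, 1)[1] - exact)
  }, 0)
  # error shrinks ~4x per doubling of p
  expect_equal(errs[1:3] / errs[2:4], rep(4, 3), tolerance = 0.15)
  slope <- -coef(lm(log(errs) ~ log(ps)))[[2]]
  expect_equal(slope, 2, tolerance = 0.2)
})

test_that("matrix eigenvalues land within 1e-3 of sign-change brackets", {
  lam <- matrix_modes("cyl", 2, shell_geometry(1, 5), 2000, 10)
  oracle <- scan_zeros_oracle("cyl", 2, 5, hi = 8.2, step = 1e-4, n_max = 10)
  expect_equal(lam, oracle, tolerance = 1e-3)
})

test_that("polishing is idempotent and reaches residual tolerance", {
  lam1 <- first_polished_zero("cyl", 2, 5)
  again <- polish_zero("cyl", 2, 5, lam1)
  expect_identical(again$iterations, 0L)
  expect_equal(again$lam, lam1)
  seeds <- matrix_modes("cyl", 2, shell_geometry(1, 5), 2000, 10)
  for (s in seeds) {
    expect_lt(polish_zero("cyl", 2, 5, s)$residual, 1e-12)
  }
})

test_that("complex-order roots obey the conjugation symmetry", {
  zp <- find_zeros("cyl", 2 + 1i, 5, 3, p = 300)
  zm <- find_zeros("cyl", 2 - 1i, 5, 3, p = 300)
  expect_lt(max(abs(zp$lambda - Conj(zm$lambda))), 1e-10)
  expect_lt(max(zp$residual), 1e-10)
  expect_true(all(Im(zp$lambda) != 0))
})

test_that("first-zero approximations have their printed limits and poles", {
  expect_equal(approx_first("cyl", 2, 1 + 1e-6, "small_lambda"), 2, tolerance = 1e-4)
  expect_equal(approx_first("sph", 2, 1 + 1e-6, "small_lambda"), sqrt(6),
               tolerance = 1e-4)
  expect_equal(approx_first("cyl", 0.3, 1 + 1e-8, "small_nu"), 0.3, tolerance = 1e-6)
  expect_error(approx_first("cyl", 1, 1.5, "small_lambda"), "pole")
  expect_error(approx_first("sph", 2, 1.5, "buchholz"), "cyl")
})

test_that("all five cylindrical first-zero approximations agree near gamma = 1", {
  lam1 <- first_polished_zero("cyl", 2, 1.2, p = 400)
  for (m in c("small_lambda", "small_nu", "gottlieb", "grebenkov", "buchholz")) {
    expect_equal(approx_first("cyl", 2, 1.2, m), lam1, tolerance = 0.05)
  }
})

test_that("McMahon/Buchholz asymptotics approach the polished zeros", {
  z20c <- Re(find_zeros("cyl", 2, 5, 20, p = 2000)$lambda[20])
  expect_equal(approx_higher("cyl", 2, 5, 20, "mcmahon"), z20c, tolerance = 1e-3)
  expect_equal(approx_higher("cyl", 2, 5, 20, "buchholz"), z20c, tolerance = 1e-3)
  z20s <- Re(find_zeros("sph", 2, 5, 20, p = 2000)$lambda[20])
  expect_equal(approx_higher("sph", 2, 5, 20, "mcmahon"), z20s, tolerance = 1e-3)
  # leading behaviour pi (n-1)/(gamma-1)
  n <- 400
  expect_equal(approx_higher("cyl", 2, 5, n, "mcmahon") * 4 / (pi * (n - 1)), 1,
               tolerance = 1e-4)
  expect_error(approx_higher("cyl", 2, 5, 1, "mcmahon"), "n >= 2")
})

test_that("find_zeros returns ordered polished zeros with metadata", {
  fz <- find_zeros("cyl", 2, 5, 10, p = 800)
  lam <- Re(fz$lambda)
  expect_true(all(diff(lam) > 0))
  expect_lt(max(fz$residual), 1e-12)
  fz0 <- find_zeros("cyl", 0, 5, 3, p = 800)
  expect_length(attr(fz0, "excluded"), 1)
  expect_lt(abs(attr(fz0, "excluded")[1]), 1e-3)
})

test_that("find_zeros respects the order symmetries", {
  a <- Re(find_zeros("cyl", 1.3, 5, 5, p = 600)$lambda)
  b <- Re(find_zeros("cyl", -1.3, 5, 5, p = 600)$lambda)
  expect_equal(a, b, tolerance = 1e-12)
  nu <- 1.3
  a <- Re(find_zeros("sph", nu - 0.5, 5, 5, p = 600)$lambda)
  b <- Re(find_zeros("sph", -nu - 0.5, 5, 5, p = 600)$lambda)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("zeros agree with the exhaustive bisection oracle", {
  for (dim in c("cyl", "sph")) {
    fz <- Re(find_zeros(dim, 2, 5, 10, p = 1500)$lambda)
    oracle <- scan_zeros_oracle(dim, 2, 5, hi = 8.4, step = 1e-4, n_max = 10)
    expect_equal(fz, oracle, tolerance = 1e-8)
  }
})

test_that("polished first zeros approach the thin-shell limits", {
  expect_equal(first_polished_zero("cyl", 2, 1.001, p = 400), 2, tolerance = 1e-2)
  expect_equal(first_polished_zero("sph", 2, 1.001, p = 400), sqrt(6),
               tolerance = 1e-2)
})

test_that("sph nu = 2 zeros satisfy the trigonometric secular equation", {
  g <- 0.1^(-1 / 3)     # eta = 0.1 in the volume-fraction parametrization
  fz <- Re(find_zeros("sph", 2, g, 5, p = 1200)$lambda)
  for (l in fz) expect_lt(abs(sph_secular_residual(l, g)), 1e-10)
  # midway between zeros the residual is bounded away from zero
  mid <- (fz[2] + fz[3]) / 2
  expect_gt(abs(sph_secular_residual(mid, g)), 1e-3)
})
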