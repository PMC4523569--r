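# Cross products, radial eigenfunctions, boundary values, Lommel functions
# and the classical polynomial families.

test_that("cross product symmetries in lambda, order and conjugation hold", {
  expect_equal(bessel_cross("cyl", 2, 5, 3), bessel_cross("cyl", 2, 5, -3),
               tolerance = 1e-12)
  expect_equal(bessel_cross("sph", 2, 5, 1.3), -bessel_cross("sph", 2, 5, -1.3),
               tolerance = 1e-12)
  expect_equal(bessel_cross("cyl", 1.3, 5, 2.1), bessel_cross("cyl", -1.3, 5, 2.1),
               tolerance = 1e-12)
  # g at nu - 1/2 equals g at -nu - 1/2
  nu <- 1.3
  expect_equal(bessel_cross("sph", nu - 0.5, 5, 2.1),
               bessel_cross("sph", -nu - 0.5, 5, 2.1), tolerance = 1e-12)
  set.seed(7)
  lam <- complex(real = runif(20, 0.5, 6), imaginary = runif(20, -1, 1))
  f1 <- vapply(lam, function(l) bessel_cross("cyl", 2 + 1i, 5, l), complex(1))
  f2 <- vapply(Conj(lam), function(l) bessel_cross("cyl", 2 - 1i, 5, l), complex(1))
  expect_lt(max(abs(f1 - Conj(f2))), 1e-12)
})

test_that("a dense sign scan brackets the first positive cylindrical root", {
  xs <- seq(0.1, 2, by = 1e-3)
  fs <- bessel_cross("cyl", 2, 5, xs)
  sgn <- which(fs[-1] * fs[-length(fs)] < 0)
  expect_gte(length(sgn), 1)
  root <- uniroot(function(l) bessel_cross("cyl", 2, 5, l),
                  c(xs[sgn[1]], xs[sgn[1] + 1]), tol = 1e-14)$root
  expect_lt(abs(bessel_cross("cyl", 2, 5, root)), 1e-12)
})

test_that("eigenfunctions take the Wronskian value at the inner boundary", {
  lam_c <- first_polished_zero("cyl", 2, 5)
  expect_equal(radial_eigenfunction("cyl", 2, lam_c, 1), 2 / (pi * lam_c),
               tolerance = 1e-12)
  lam_s <- first_polished_zero("sph", 2, 5)
  expect_equal(radial_eigenfunction("sph", 2, lam_s, 1), 1 / lam_s^2,
               tolerance = 1e-12)
  # reflecting boundary: central difference of Phi at rho = 1 vanishes
  h <- 1e-6
  d <- (radial_eigenfunction("cyl", 2, lam_c, 1 + h) -
          radial_eigenfunction("cyl", 2, lam_c, 1 - h)) / (2 * h)
  expect_lt(abs(d), 1e-6 * abs(radial_eigenfunction("cyl", 2, lam_c, 1)))
})

test_that("outer boundary value agrees between Wronskian forms and direct evaluation", {
  lam_c <- first_polished_zero("cyl", 2, 5)
  v <- boundary_value_outer("cyl", 2, lam_c, 5)     # errors if forms disagree
  expect_equal(v, radial_eigenfunction("cyl", 2, lam_c, 5), tolerance = 1e-10)
  lam_s <- first_polished_zero("sph", 2, 5)
  vs <- boundary_value_outer("sph", 2, lam_s, 5)
  expect_equal(vs, radial_eigenfunction("sph", 2, lam_s, 5), tolerance = 1e-10)
  # degenerate shell: outer value equals the inner Wronskian value
  expect_equal(boundary_value_outer("cyl", 2, lam_c, 1), 2 / (pi * lam_c))
  # a stale (non-zero) lambda is rejected
  expect_error(boundary_value_outer("cyl", 2, lam_c * 1.05, 5), "disagree")
})

test_that("lommel_s_small has the printed leading behaviour and nu-symmetry", {
  k <- 0.7; nu <- 1.2
  z <- 1e-4
  expect_equal(lommel_s_small(k, nu, z) / z^(k + 1), 1 / ((k + 1)^2 - nu^2),
               tolerance = 1e-7)
  expect_equal(lommel_s_small(k, nu, 2.3), lommel_s_small(k, -nu, 2.3),
               tolerance = 1e-14)
  expect_error(lommel_s_small(0.2, 1.2, 1), "pole")
  # closed-form oracle: S_{1,0} = 1 with complement sin(pi/2) J_0 gives
  # s_{1,0}(z) = 1 - J_0(z)
  z <- 2
  expect_equal(lommel_s_small(1, 0, z), 1 - besselJ(z, 0), tolerance = 1e-13)
})

test_that("lommel_S matches its printed special cases and recurrences", {
  for (z in c(0.5, 2.5, 7.0)) {
    expect_equal(lommel_S(1, 0, z, route = "series"), 1, tolerance = 1e-11)
  }
  for (z in c(0.8, 2, 5.5)) {
    expect_equal(lommel_S(-1, 2, z), 1 / z^2, tolerance = 1e-12)
    expect_equal(lommel_S(-2.5, 3.5, z), z^(-3.5), tolerance = 1e-12)
    expect_equal(lommel_S(-1.5, 2.5, z), z^(-2.5), tolerance = 1e-12)
  }
  # index recurrence S_{k+2,nu} + [(k+1)^2 - nu^2] S_{k,nu} = z^{k+1}
  k <- 0.3; nu <- 1.7; z <- 2.4
  expect_lt(abs(lommel_S(k + 2, nu, z) + ((k + 1)^2 - nu^2) * lommel_S(k, nu, z) -
                  z^(k + 1)), 1e-10)
  # the exceptional pair S_{-1,0} has no finite route
  expect_error(lommel_S(-1, 0, 2), "exceptional|no finite")
})

test_that("lommel_S solves the inhomogeneous Bessel equation (ODE residual)", {
  # independent check: S'' + S'/z + (1 - nu^2/z^2) S = z^{kappa-1},
  # with derivatives by central differences of the evaluated function
  cases <- list(c(1, 0), c(-1, 2), c(0.3, 1.7), c(-2.5, 3.5), c(1, 2), c(0, 1))
  for (cs in cases) {
    k <- cs[1]; nu <- cs[2]; z <- 2.37
    h <- 1e-4
    S <- function(x) lommel_S(k, nu, x)
    d1 <- (S(z + h) - S(z - h)) / (2 * h)
    d2 <- (S(z + h) - 2 * S(z) + S(z - h)) / h^2
    res <- d2 + d1 / z + (1 - nu^2 / z^2) * S(z) - z^(k - 1)
    expect_lt(abs(res), 1e-6)
  }
})

test_that("lommel_S closed forms agree with the series route where both exist", {
  # half-integer Gegenbauer cases are series-representable
  for (z in c(1.1, 3.3)) {
    expect_equal(lommel_S(-2.5, 3.5, z, route = "series"),
                 lommel_S(-2.5, 3.5, z, route = "closed_form"), tolerance = 1e-10)
    expect_equal(lommel_S(1, 0, z, route = "series"),
                 lommel_S(1, 0, z, route = "closed_form"), tolerance = 1e-10)
  }
  # integer pair with a Gamma pole: closed form against the shift recurrence
  z <- 2.9
  expect_equal(lommel_S(-1, 2, z, route = "closed_form"),
               lommel_S(-1, 2, z, route = "recurrence"), tolerance = 1e-10)
  # S_{0,2m+1} is printed both via Neumann and via Schlafli polynomials;
  # the registry (Neumann route) must agree with the Schlafli identity
  expect_equal(lommel_S(0, 1, z), classical_polynomial("schlafli_S", 1, z) / 2,
               tolerance = 1e-13)
  expect_equal(lommel_S(0, 3, z), classical_polynomial("schlafli_S", 3, z) / 2,
               tolerance = 1e-13)
})

test_that("derivative recurrence reproduces known Lommel derivatives", {
  z <- 2.2
  expect_equal(lommel_S_deriv(1, 0, z), 0)                      # S_{1,0} = 1
  expect_equal(lommel_S_deriv(-1, 2, z), -2 / z^3, tolerance = 1e-12)
  # finite-difference cross-check at generic indices
  k <- 0.3; nu <- 1.7; h <- 1e-5
  fd <- (lommel_S(k, nu, z + h) - lommel_S(k, nu, z - h)) / (2 * h)
  expect_equal(lommel_S_deriv(k, nu, z), fd, tolerance = 1e-8)
})

test_that("Gegenbauer polynomials match printed low orders and the shift relation", {
  nu <- 1.4; z <- 2.6
  expect_equal(gegenbauer_A(0, nu, z), gamma(nu + 1) * 2^nu / z, tolerance = 1e-13)
  expect_equal(gegenbauer_A(1, nu, z), gamma(nu + 2) * 2^(nu + 1) / z^2,
               tolerance = 1e-13)
  expect_equal(gegenbauer_A(2, nu, z),
               gamma(nu + 3) * (4 + 4 * nu + z^2) / (nu + 1) * 2^nu / z^3,
               tolerance = 1e-13)
  # A_{2p,1-g} = z A_{2p+1,-g} at p = 1, g = 0.4, z = 1.7
  expect_equal(gegenbauer_A(2, 1 - 0.4, 1.7), 1.7 * gegenbauer_A(3, -0.4, 1.7),
               tolerance = 1e-12)
})

test_that("classical polynomials match printed forms and the S_{1,2m} identity", {
  z <- 3.1
  expect_equal(classical_polynomial("neumann_O", 0, z), 1 / z)
  expect_equal(classical_polynomial("neumann_O", 1, z), 1 / z^2)
  expect_equal(classical_polynomial("neumann_O", 2, z), 1 / z + 4 / z^3)
  expect_equal(classical_polynomial("schlafli_S", 0, z), 0)
  expect_equal(classical_polynomial("schlafli_S", 1, z), 2 / z)
  expect_equal(classical_polynomial("schlafli_S", 2, z), 4 / z^2)
  expect_equal(lommel_S(1, 2, z), z * classical_polynomial("neumann_O", 2, z),
               tolerance = 1e-13)
  expect_error(classical_polynomial("neumann_O", -1, z))
})

test_that("hyp_1f2 enforces its domain and truncation contract", {
  expect_error(hyp_1f2(1, -2, 3, 0.5), "non-positive integer")
  expect_equal(hyp_1f2(1, 2, 2, 0), 1)
  expect_warning(lommel_s_small(0.3, 1.1, 45), "series range")
})
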