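# Closed-form normalization constants and Lommel integrals for the Neumann
# eigenfunctions, plus quadrature-based verification.  All integrals are
# computed in the nondimensional variable rho = r/R on [1, gamma]; the inner
# radius re-enters only through the printed 1/R^k prefactors, which are
# already divided out in the returned (dimensionless) values.

# adaptive quadrature of a possibly complex-valued integrand
quad_shell <- function(f, lower, upper, rel.tol = 1e-10, abs.tol = 1e-12) {
  re <- integrate(function(x) Re(f(x)), lower, upper,
                  rel.tol = rel.tol, abs.tol = abs.tol,
                  subdivisions = 500L, stop.on.error = FALSE)
  if (re$message != "OK" && !grepl("roundoff", re$message)) {
    stop("quadrature failed: ", re$message)
  }
  probe <- f((lower + upper) / 2)
  if (is.complex(probe)) {
    im <- integrate(function(x) Im(f(x)), lower, upper,
                    rel.tol = rel.tol, abs.tol = abs.tol,
                    subdivisions = 500L, stop.on.error = FALSE)
    re$value + 1i * im$value
  } else {
    re$value
  }
}

check_polished <- function(dim, nu, gamma, lam, tol = 1e-6) {
  if (cross_residual(dim, nu, gamma, lam) > tol) {
    stop(sprintf(
      "lam = %s is not a polished cross-product zero (residual %.3e); the closed form is only valid at zeros",
      format(lam), cross_residual(dim, nu, gamma, lam)))
  }
}

# At a cross-product zero the J'- and Y'-ratios are identical; numerically
# one of them can be catastrophically cancelled (deep evanescent modes with
# nu >> lam have J'(gamma*lam) tiny relative to the J_{nu+-1} terms it is
# assembled from).  Pick the form whose outer-boundary derivative is better
# conditioned.
deriv_ratio <- function(dim, nu, lam, gamma) {
  if (!(is_real_scalar(nu) && is_real_scalar(lam))) {
    return(if (dim == "cyl") {
      bessel_Jp(nu, lam) / bessel_Jp(nu, gamma * lam)
    } else {
      sph_jp(nu, lam) / sph_jp(nu, gamma * lam)
    })
  }
  nu <- Re(as.complex(nu)); lam <- Re(as.complex(lam))
  z <- gamma * lam
  if (dim == "cyl") {
    condJ <- abs(bessel_Jp(nu, z)) / (abs(bessel_J(nu - 1, z)) + abs(bessel_J(nu + 1, z)))
    condY <- abs(bessel_Yp(nu, z)) / (abs(bessel_Y(nu - 1, z)) + abs(bessel_Y(nu + 1, z)))
    if (condJ >= condY) {
      bessel_Jp(nu, lam) / bessel_Jp(nu, z)
    } else {
      bessel_Yp(nu, lam) / bessel_Yp(nu, z)
    }
  } else {
    condJ <- abs(sph_jp(nu, z)) / (abs(sph_j(nu - 1, z)) + abs(sph_j(nu + 1, z)))
    condY <- abs(sph_yp(nu, z)) / (abs(sph_y(nu - 1, z)) + abs(sph_y(nu + 1, z)))
    if (condJ >= condY) {
      sph_jp(nu, lam) / sph_jp(nu, z)
    } else {
      sph_yp(nu, lam) / sph_yp(nu, z)
    }
  }
}

#' Normalization constant of a radial Neumann eigenfunction
#'
#' The closed forms at a cross-product zero \eqn{\lambda}:
#' \deqn{N_\nu^{\mathrm{2D}} = \frac{2}{\pi^2\lambda^2}
#'   \left[1 - \frac{\nu^2}{\gamma^2\lambda^2}\right]
#'   \left[\frac{J'_\nu(\lambda)}{J'_\nu(\gamma\lambda)}\right]^2
#'   - \frac{2}{\pi^2\lambda^2}\left[1 - \frac{\nu^2}{\lambda^2}\right]}
#' and the 3-D analogue with the spherical derivative ratio, so that
#' \eqn{R^{-2}\int_R^{\gamma R} r\,\Phi^2\,dr = N} (weight \eqn{r^2} and
#' \eqn{R^{-3}} in 3-D).  For real order the constant is real and positive.
#'
#' @inheritParams bessel_cross
#' @param lam a polished cross-product zero.
#' @param check verify that `lam` is a zero before applying the formula.
#' @export
normalization <- function(dim, nu, lam, gamma, check = TRUE) {
  dim <- match_dim(dim)
  if (check) check_polished(dim, nu, gamma, lam)
  rr <- deriv_ratio(dim, nu, lam, gamma)
  val <- if (dim == "cyl") {
    2 / (pi^2 * lam^2) * (1 - nu^2 / (gamma^2 * lam^2)) * rr^2 -
      2 / (pi^2 * lam^2) * (1 - nu^2 / lam^2)
  } else {
    1 / (2 * gamma * lam^4) * rr^2 * (1 - nu * (nu + 1) / (gamma^2 * lam^2)) +
      1 / (2 * lam^4) * (nu * (nu + 1) / lam^2 - 1)
  }
  if (is_real_scalar(nu) && is_real_scalar(lam)) drop_imag(as.complex(val), 1e-10) else val
}

#' Lommel integral of a radial Neumann eigenfunction against a power
#'
#' The dimensionless moment
#' \eqn{R^{-(\alpha+1)} \int_R^{\gamma R} r^\alpha\, \Phi(r)\, dr}
#' evaluated by the boundary-term formula (no quadrature):
#' 2-D,
#' \deqn{\frac{2}{\pi\lambda^{\alpha+1}}\left[
#'   \frac{J'_\nu(\lambda)}{J'_\nu(\gamma\lambda)}
#'   S'_{\alpha,\nu}(\gamma\lambda) - S'_{\alpha,\nu}(\lambda)\right],}
#' and in 3-D the corresponding combination of the two half-integer Lommel
#' functions \eqn{S_{\alpha-3/2,\nu+3/2}} and \eqn{S_{\alpha-1/2,\nu+1/2}}.
#' Special cases: \eqn{\alpha=1,\nu=0} (2-D) and \eqn{\alpha=2,\nu=0} (3-D)
#' vanish identically — the eigenfunctions are orthogonal to the constant.
#'
#' @inheritParams normalization
#' @param alpha power of `r` in the integrand.
#' @export
lommel_integral <- function(dim, alpha, nu, lam, gamma, check = TRUE) {
  dim <- match_dim(dim)
  if (check) check_polished(dim, nu, gamma, lam)
  rr <- deriv_ratio(dim, nu, lam, gamma)
  val <- if (dim == "cyl") {
    2 / (pi * as.complex(lam)^(alpha + 1)) *
      (rr * lommel_S_deriv(alpha, nu, gamma * lam) - lommel_S_deriv(alpha, nu, lam))
  } else {
    c1 <- alpha - nu - 2
    term <- function(z) {
      t1 <- if (abs(c1) < 1e-14) 0 else z * c1 * lommel_S(alpha - 3 / 2, nu + 3 / 2, z)
      t2 <- if (abs(nu) < 1e-14) 0 else nu * lommel_S(alpha - 1 / 2, nu + 1 / 2, z)
      t1 + t2
    }
    gamma^(-3 / 2) / as.complex(lam)^(5 / 2 + alpha) * rr * term(gamma * lam) -
      1 / as.complex(lam)^(5 / 2 + alpha) * term(lam)
  }
  if (is_real_scalar(nu) && is_real_scalar(lam) && is_real_scalar(alpha)) {
    drop_imag(as.complex(val), 1e-9)
  } else {
    val
  }
}

#' Gram matrix of radial Neumann eigenfunctions by quadrature
#'
#' \eqn{G_{nn'} = \int_1^\gamma \rho^w\, \Phi_n(\rho) \Phi_{n'}(\rho)\,
#' d\rho} with weight \eqn{w = 1} (2-D) or \eqn{w = 2} (3-D), using the
#' plain (non-conjugated) product, which is the bilinear pairing under which
#' the eigenfunctions are orthogonal also for complex order.  Off-diagonals
#' vanish at polished zeros; diagonals reproduce [normalization()].
#'
#' @inheritParams bessel_cross
#' @param modes a `mode_table` from [find_zeros()].
#' @export
orthogonality_gram <- function(dim, nu, gamma, modes) {
  dim <- match_dim(dim)
  lam <- modes$lambda
  w <- if (dim == "cyl") 1 else 2
  k <- length(lam)
  G <- matrix(if (is_real_scalar(nu) && all(Im(lam) == 0)) 0 else 0i, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      li <- if (Im(lam[i]) == 0) Re(lam[i]) else lam[i]
      lj <- if (Im(lam[j]) == 0) Re(lam[j]) else lam[j]
      nn <- if (is_real_scalar(nu)) Re(as.complex(nu)) else nu
      G[i, j] <- G[j, i] <- quad_shell(function(rho) {
        rho^w * radial_eigenfunction(dim, nn, li, rho) *
          radial_eigenfunction(dim, nn, lj, rho)
      }, 1, gamma)
    }
  }
  G
}

#' Residual of the integrated Bessel differential equation
#'
#' Integrating the radial differential equation over the shell with Neumann
#' boundary conditions gives the exact identity
#' \deqn{\int_1^\gamma \rho\left[\frac{\nu^2}{\rho^2} - \lambda^2\right]
#'   \Phi(\rho)\, d\rho = 0}
#' (weight \eqn{\rho^2} and \eqn{\nu(\nu+1)} in 3-D).  The residual is
#' computed by adaptive quadrature; at a polished zero it vanishes to
#' quadrature accuracy.  For \eqn{\nu = 0} the identity reduces to the
#' orthogonality-to-constant statement scaled by \eqn{-\lambda^2}.
#'
#' @inheritParams normalization
#' @export
generalized_moment_identity <- function(dim, nu, lam, gamma) {
  dim <- match_dim(dim)
  w <- if (dim == "cyl") 1 else 2
  ord <- if (dim == "cyl") nu^2 else nu * (nu + 1)
  val <- quad_shell(function(rho) {
    rho^w * (ord / rho^2 - lam^2) * radial_eigenfunction(dim, nu, lam, rho)
  }, 1, gamma)
  if (is.complex(val)) abs(val) else abs(val)
}
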