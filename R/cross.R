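# Cross products of Bessel-function derivatives and the radial Neumann
# eigenfunctions on the shell R <= r <= gamma*R (all radial coordinates in
# units of R, rho = r/R in [1, gamma]).

match_dim <- function(dim) match.arg(dim, c("cyl", "sph"))

#' Cross product of Bessel-function derivatives
#'
#' The secular function whose zeros are the Neumann eigenvalues of the radial
#' Laplacian on the shell:
#' \deqn{f_\nu(\lambda) = Y'_\nu(\lambda) J'_\nu(\gamma\lambda) -
#'       J'_\nu(\lambda) Y'_\nu(\gamma\lambda)}
#' for `dim = "cyl"`, and the spherical analogue
#' \eqn{g_\nu(\lambda) = y'_\nu(\lambda) j'_\nu(\gamma\lambda) -
#' j'_\nu(\lambda) y'_\nu(\gamma\lambda)} for `dim = "sph"`.
#'
#' \eqn{f_\nu} is even in \eqn{\lambda} and in \eqn{\nu}; \eqn{g_\nu} is odd
#' in \eqn{\lambda} and symmetric under \eqn{\nu - 1/2 \to -\nu - 1/2}.  Both
#' satisfy the conjugation symmetry \eqn{f_{\nu^*}(\lambda) =
#' f_\nu^*(\lambda^*)}.  For real order and real \eqn{\lambda} the value is
#' real and is returned as a double.
#'
#' @param dim `"cyl"` (annulus) or `"sph"` (spherical shell).
#' @param nu Bessel order, real or complex scalar.
#' @param gamma outer/inner radius ratio, `gamma >= 1`.
#' @param lam evaluation point(s) \eqn{\lambda}; vectorized.
#' @return values of the cross product; real when inputs are real.
#' @export
bessel_cross <- function(dim, nu, gamma, lam) {
  dim <- match_dim(dim)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 1) {
    stop("gamma must be a scalar >= 1")
  }
  if (dim == "sph" && any(abs(lam) == 0)) {
    stop("lam = 0 is outside the domain of the spherical cross product")
  }
  if (dim == "cyl" && any(abs(lam) == 0)) {
    stop("lam = 0 is outside the domain of the cross product")
  }
  val <- if (dim == "cyl") {
    bessel_Yp(nu, lam) * bessel_Jp(nu, gamma * lam) -
      bessel_Jp(nu, lam) * bessel_Yp(nu, gamma * lam)
  } else {
    sph_yp(nu, lam) * sph_jp(nu, gamma * lam) -
      sph_jp(nu, lam) * sph_yp(nu, gamma * lam)
  }
  if (any(!is.finite(abs(val)))) {
    stop("bessel_cross: overflow/non-finite value (|Im(lam)| too large?)")
  }
  if (is_real_scalar(nu) && is.numeric(lam)) drop_imag(val, tol = 1e-8) else val
}

#' Radial Neumann eigenfunction on the shell
#'
#' \deqn{\Phi_\nu(\rho) = Y'_\nu(\lambda) J_\nu(\lambda\rho) -
#'       J'_\nu(\lambda) Y_\nu(\lambda\rho)}
#' for the annulus, and \eqn{\psi_\nu(\rho) = y'_\nu(\lambda) j_\nu(\lambda\rho)
#' - j'_\nu(\lambda) y_\nu(\lambda\rho)} for the spherical shell.  By
#' construction \eqn{\Phi'(1) = 0}; when `lam` is a cross-product zero the
#' derivative also vanishes at \eqn{\rho = \gamma}.  Abel's identity for the
#' Wronskian fixes the inner boundary values \eqn{\Phi(1) = 2/(\pi\lambda)}
#' and \eqn{\psi(1) = 1/\lambda^2}.
#'
#' @inheritParams bessel_cross
#' @param lam radial eigenvalue (any value is accepted; the function is an
#'   eigenfunction of the shell problem only at cross-product zeros).
#' @param rho radial coordinate in units of the inner radius, in
#'   `[1, gamma]`; vectorized.
#' @export
radial_eigenfunction <- function(dim, nu, lam, rho) {
  dim <- match_dim(dim)
  val <- if (dim == "cyl") {
    bessel_Yp(nu, lam) * bessel_J(nu, lam * rho) -
      bessel_Jp(nu, lam) * bessel_Y(nu, lam * rho)
  } else {
    sph_yp(nu, lam) * sph_j(nu, lam * rho) -
      sph_jp(nu, lam) * sph_y(nu, lam * rho)
  }
  if (is_real_scalar(nu) && is.numeric(lam) && is.numeric(rho)) {
    drop_imag(val, tol = 1e-8)
  } else {
    val
  }
}

#' Eigenfunction value at the outer shell boundary
#'
#' At a polished cross-product zero the outer boundary value follows from the
#' Wronskian without evaluating the eigenfunction:
#' \eqn{\Phi(\gamma) = 2/(\pi\gamma\lambda) \cdot J'_\nu(\lambda)/J'_\nu(\gamma\lambda)}
#' (annulus) and
#' \eqn{\psi(\gamma) = 1/(\gamma^2\lambda^2) \cdot j'_\nu(\lambda)/j'_\nu(\gamma\lambda)}
#' (spherical shell).  The equivalent form with \eqn{Y'} (resp. \eqn{y'})
#' ratios is evaluated as a cross-check; disagreement signals that `lam` is
#' not actually a zero.
#'
#' @inheritParams bessel_cross
#' @param lam a polished cross-product zero.
#' @param tol allowed relative disagreement between the two derivative-ratio
#'   forms.
#' @export
boundary_value_outer <- function(dim, nu, lam, gamma, tol = 1e-8) {
  dim <- match_dim(dim)
  if (gamma == 1) {
    return(if (dim == "cyl") drop_imag(2 / (pi * lam)) else drop_imag(1 / lam^2))
  }
  if (dim == "cyl") {
    vJ <- 2 / (pi * gamma * lam) * bessel_Jp(nu, lam) / bessel_Jp(nu, gamma * lam)
    vY <- 2 / (pi * gamma * lam) * bessel_Yp(nu, lam) / bessel_Yp(nu, gamma * lam)
  } else {
    vJ <- 1 / (gamma^2 * lam^2) * sph_jp(nu, lam) / sph_jp(nu, gamma * lam)
    vY <- 1 / (gamma^2 * lam^2) * sph_yp(nu, lam) / sph_yp(nu, gamma * lam)
  }
  if (abs(vJ - vY) > tol * max(1, abs(vJ))) {
    stop(sprintf(
      "boundary_value_outer: J'- and Y'-ratio forms disagree (%.3e rel); lam is not a polished zero",
      abs(vJ - vY) / max(1, abs(vJ))
    ))
  }
  if (is_real_scalar(nu) && is.numeric(lam)) drop_imag(vJ, 1e-8) else vJ
}
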