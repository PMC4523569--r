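#' @importFrom stats integrate rnorm runif sd uniroot
#' @importFrom utils head modifyList write.csv
NULL

is_real_scalar <- function(x, tol = 0) {
  is.numeric(x) || (is.complex(x) && all(abs(Im(x)) <= tol))
}

drop_imag <- function(x, tol = 1e-10) {
  # collapse numerically-real complex results to double
  if (is.complex(x) && all(abs(Im(x)) <= tol * pmax(1, abs(x)))) Re(x) else x
}

near_nonpos_int <- function(x, tol = 1e-12) {
  abs(Im(x)) <= tol & Re(x) <= tol & abs(Re(x) - round(Re(x))) <= tol
}

# ---- complex-order Bessel J: Miller backward recurrence -------------------
#
# Downward recurrence y_{k-1} = 2(nu+k)/z y_k - y_{k+1} from a start order
# well above |z|, normalized with the Neumann-series identity
#   (z/2)^nu = sum_m (nu+2m) Gamma(nu+m)/m! J_{nu+2m}(z),
# which holds for any order that is not a non-positive integer.  This is
# numerically stable for all moderate |z| and gives near machine precision,
# unlike the ascending series whose alternating terms cancel for |z| >~ 10.
bessel_j_rec <- function(nu, z, kmax = 1L) {
  if (abs(z) == 0) stop("bessel_j_rec: z = 0 not supported")
  if (near_nonpos_int(nu + 1)) {
    stop("bessel_j_rec: order is a negative integer; use integer-order routines")
  }
  K <- as.integer(ceiling(abs(z) + 30 + 12 * sqrt(abs(z)) + abs(Re(nu))))
  if (K %% 2L == 1L) K <- K + 1L
  M <- K %/% 2L
  # c_m = (nu+2m) Gamma(nu+m)/m!, built without dividing by (nu+2m-2)
  cm <- complex(length.out = M + 1L)
  gm <- pracma::gammaz(nu + 1)          # Gamma(nu+m)/m! at m = 1
  cm[1L] <- gm                          # c_0 = nu*Gamma(nu) = Gamma(nu+1)
  for (m in seq_len(M)) {
    cm[m + 1L] <- (nu + 2 * m) * gm
    gm <- gm * (nu + m) / (m + 1)
  }
  yk1 <- 0 + 0i
  yk <- 1e-30 + 0i
  S <- 0 + 0i
  out <- complex(length.out = kmax + 1L)
  for (k in K:0L) {
    if (k %% 2L == 0L) S <- S + cm[k / 2L + 1L] * yk
    if (k <= kmax) out[k + 1L] <- yk
    if (k > 0L) {
      ykm1 <- (2 * (nu + k) / z) * yk - yk1
      yk1 <- yk
      yk <- ykm1
      if (abs(yk) > 1e250) {
        sc <- abs(yk)
        yk <- yk / sc; yk1 <- yk1 / sc; S <- S / sc; out <- out / sc
      }
    }
  }
  if (!is.finite(abs(S)) || abs(S) == 0) {
    stop("bessel_j_rec: overflow in backward recurrence (|Im z| too large?)")
  }
  out * (exp(nu * log(z / 2)) / S)
}

# J_{nu-1}, J_nu, J_{nu+1} for complex order and/or argument
bessel_j_triplet <- function(nu, z) {
  y <- bessel_j_rec(nu, z, kmax = 1L)     # J_nu, J_{nu+1}
  jm1 <- (2 * nu / z) * y[1L] - y[2L]     # J_{nu-1} via upward relation
  c(jm1, y)
}

# unnormalized downward-recurrence sequence y_k ~ C * J_{nu+k}(z), k = 0,1
bessel_j_unnormalized <- function(nu, z) {
  K <- as.integer(ceiling(abs(z) + 30 + 12 * sqrt(abs(z)) + abs(Re(nu))))
  yk1 <- 0 + 0i
  yk <- 1e-30 + 0i
  out <- complex(2L)
  for (k in K:0L) {
    if (k <= 1L) out[k + 1L] <- yk
    if (k > 0L) {
      ykm1 <- (2 * (nu + k) / z) * yk - yk1
      yk1 <- yk
      yk <- ykm1
      if (abs(yk) > 1e250) {
        sc <- abs(yk)
        yk <- yk / sc; yk1 <- yk1 / sc; out <- out / sc
      }
    }
  }
  out
}

# J, J', Y, Y' at complex order nu (not integer) and complex argument z.
# The order with non-negative real part is normalized through the Neumann
# series (stable there); the mirrored order -mu is normalized against it
# through the Wronskian J_mu J'_{-mu} - J'_mu J_{-mu} = -2 sin(mu pi)/(pi z),
# which avoids the catastrophic cancellation the Neumann sum suffers at
# negative orders (where (z/2)^nu is exponentially small against the terms).
# Y then follows from the connection formula.
bessel_jy_complex <- function(nu, z) {
  s <- sin(pi * nu)
  if (abs(s) < 1e-8) {
    stop("complex-path Bessel Y needs a non-integer order (|sin(pi*nu)| too small)")
  }
  mu <- if (Re(nu) >= 0) nu else -nu
  jp3 <- bessel_j_triplet(mu, z)
  Jmu <- jp3[2L]; Jmup <- (jp3[1L] - jp3[3L]) / 2
  u <- bessel_j_unnormalized(-mu, z)     # ~ C * (J_{-mu}, J_{-mu+1})
  # J'_{-mu} = (-mu/z) J_{-mu} - J_{-mu+1}
  v0 <- u[1L]
  v1 <- (-mu / z) * u[1L] - u[2L]
  scl <- (-2 * sin(mu * pi) / (pi * z)) / (Jmu * v1 - Jmup * v0)
  Jm <- scl * v0; Jmp <- scl * v1
  cs <- cos(pi * mu); sm <- sin(pi * mu)
  Ymu <- (Jmu * cs - Jm) / sm
  Ymup <- (Jmup * cs - Jmp) / sm
  if (identical(mu, nu)) {
    list(J = Jmu, Jp = Jmup, Y = Ymu, Yp = Ymup)
  } else {
    # Y_{-mu} = (J_mu - J_{-mu} cos(mu pi)) / sin(mu pi) ... with a sign
    # from the reflection of the connection formula
    list(J = Jm, Jp = Jmp,
         Y = (Jm * cs - Jmu) / (-sm), Yp = (Jmp * cs - Jmup) / (-sm))
  }
}

# ---- user-facing cylindrical Bessel functions -----------------------------

#' Cylindrical Bessel functions for real or complex order and argument
#'
#' `bessel_J()` and `bessel_Y()` extend the base Bessel routines to complex
#' order and/or complex (or negative real) argument; `bessel_Jp()` and
#' `bessel_Yp()` are the derivatives, computed from the exact relation
#' \eqn{J'_\nu = (J_{\nu-1} - J_{\nu+1})/2} rather than finite differences.
#'
#' For real order and positive real argument the base routines are used.
#' For negative real argument the principal-branch analytic continuation
#' \eqn{J_\nu(z e^{i\pi}) = e^{i\pi\nu} J_\nu(z)} and
#' \eqn{Y_\nu(z e^{i\pi}) = e^{-i\pi\nu} Y_\nu(z) + 2i\cos(\pi\nu) J_\nu(z)}
#' is applied.  Genuinely complex cases go through a backward-recurrence
#' (Miller) evaluation with the Neumann-series normalization.
#'
#' @param nu order (real or complex scalar).
#' @param z argument; vectorized.
#' @return numeric vector when order and argument are real with positive
#'   argument, complex vector otherwise.
#' @export
bessel_J <- function(nu, z) {
  if (is_real_scalar(nu) && is.numeric(z) && all(z > 0)) {
    return(besselJ(z, Re(nu)))
  }
  nu <- as.complex(nu)
  vapply(as.complex(z), function(zz) {
    if (abs(Im(zz)) == 0 && Re(zz) > 0 && abs(Im(nu)) == 0) {
      as.complex(besselJ(Re(zz), Re(nu)))
    } else if (abs(Im(zz)) == 0 && Re(zz) < 0 && abs(Im(nu)) == 0) {
      exp(1i * pi * nu) * as.complex(besselJ(-Re(zz), Re(nu)))
    } else if (Re(nu) < 0 && abs(sin(pi * nu)) > 1e-8) {
      bessel_jy_complex(nu, zz)$J   # Wronskian-normalized at negative orders
    } else {
      bessel_j_triplet(nu, zz)[2L]
    }
  }, complex(1))
}

#' @rdname bessel_J
#' @export
bessel_Y <- function(nu, z) {
  if (is_real_scalar(nu) && is.numeric(z) && all(z > 0)) {
    return(besselY(z, Re(nu)))
  }
  nu <- as.complex(nu)
  vapply(as.complex(z), function(zz) {
    if (abs(Im(zz)) == 0 && Re(zz) > 0 && abs(Im(nu)) == 0) {
      as.complex(besselY(Re(zz), Re(nu)))
    } else if (abs(Im(zz)) == 0 && Re(zz) < 0 && abs(Im(nu)) == 0) {
      x <- -Re(zz); rnu <- Re(nu)
      exp(-1i * pi * nu) * besselY(x, rnu) + 2i * cos(pi * nu) * besselJ(x, rnu)
    } else {
      bessel_jy_complex(nu, zz)$Y
    }
  }, complex(1))
}

#' @rdname bessel_J
#' @export
bessel_Jp <- function(nu, z) {
  drop_imag((bessel_J(nu - 1, z) - bessel_J(nu + 1, z)) / 2)
}

#' @rdname bessel_J
#' @export
bessel_Yp <- function(nu, z) {
  drop_imag((bessel_Y(nu - 1, z) - bessel_Y(nu + 1, z)) / 2)
}

# ---- spherical Bessel functions -------------------------------------------

sqrt_pi_2z <- function(z) {
  if (is.numeric(z) && all(z > 0)) sqrt(pi / (2 * z)) else exp(0.5 * (log(pi / 2) - log(as.complex(z))))
}

#' Spherical Bessel functions and derivatives
#'
#' Computed from the half-integer-order cylindrical functions through
#' \eqn{j_\nu(z) = \sqrt{\pi/(2z)}\, J_{\nu+1/2}(z)} (and the analogue for
#' \eqn{y_\nu}), so real, negative and complex arguments and complex orders
#' are all supported through the same backend as [bessel_J()].
#'
#' @inheritParams bessel_J
#' @export
sph_j <- function(nu, z) drop_imag(sqrt_pi_2z(z) * bessel_J(nu + 0.5, z))

#' @rdname sph_j
#' @export
sph_y <- function(nu, z) drop_imag(sqrt_pi_2z(z) * bessel_Y(nu + 0.5, z))

#' @rdname sph_j
#' @export
sph_jp <- function(nu, z) {
  drop_imag(sqrt_pi_2z(z) * (bessel_Jp(nu + 0.5, z) - bessel_J(nu + 0.5, z) / (2 * z)))
}

#' @rdname sph_j
#' @export
sph_yp <- function(nu, z) {
  drop_imag(sqrt_pi_2z(z) * (bessel_Yp(nu + 0.5, z) - bessel_Y(nu + 0.5, z) / (2 * z)))
}
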