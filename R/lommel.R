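# Lommel functions S_{kappa,nu}(z), s_{kappa,nu}(z) and the classical
# polynomial families (Neumann, Schlafli, Gegenbauer) that provide their
# closed forms at special index combinations.

#' Generalized hypergeometric series 1F2
#'
#' Direct power series \eqn{{}_1F_2(a; b_1, b_2; x) = \sum_k (a)_k / ((b_1)_k
#' (b_2)_k) x^k / k!}, truncated when a term falls below `tol` times the
#' partial sum.  All parameters may be complex; lower parameters must not be
#' non-positive integers.
#'
#' @param a,b1,b2 series parameters.
#' @param x argument.
#' @param tol relative truncation tolerance.
#' @param max_terms error if the series has not settled after this many terms.
#' @export
hyp_1f2 <- function(a, b1, b2, x, tol = 1e-16, max_terms = 500L) {
  if (near_nonpos_int(b1) || near_nonpos_int(b2)) {
    stop("hyp_1f2: lower parameter is a non-positive integer")
  }
  term <- 1 + 0i
  s <- term
  for (k in 0:(max_terms - 1L)) {
    term <- term * (a + k) / ((b1 + k) * (b2 + k)) * x / (k + 1)
    s <- s + term
    if (abs(term) < tol * abs(s)) return(drop_imag(s, 1e-14))
  }
  stop("hyp_1f2: series did not converge within ", max_terms, " terms")
}

#' Lommel function of the first kind s_{kappa,nu}
#'
#' \deqn{s_{\kappa,\nu}(z) = \frac{z^{\kappa+1}}{(\kappa+1)^2-\nu^2}\,
#'   {}_1F_2\!\left(1; \frac{\kappa-\nu+3}{2}, \frac{\kappa+\nu+3}{2};
#'   -z^2/4\right).}
#' Symmetric in \eqn{\nu \to -\nu}.  Errors at the pole
#' \eqn{(\kappa+1)^2 = \nu^2}.  For `|z| > 40` the alternating series loses
#' accuracy and a warning is issued (no asymptotic expansion is implemented;
#' all in-package uses have moderate `|z|`).
#'
#' @param kappa,nu Lommel indices (real or complex scalars).
#' @param z argument.
#' @export
lommel_s_small <- function(kappa, nu, z) {
  den <- (kappa + 1)^2 - nu^2
  if (abs(den) < 1e-12) {
    stop("lommel_s_small: pole at (kappa+1)^2 = nu^2")
  }
  if (Mod(z) > 40) {
    warning("lommel_s_small: |z| > 40 is outside the validated series range")
  }
  zc <- as.complex(z)
  val <- exp((kappa + 1) * log(zc)) / den *
    hyp_1f2(1, (kappa - nu + 3) / 2, (kappa + nu + 3) / 2, -zc^2 / 4)
  if (is_real_scalar(kappa) && is_real_scalar(nu) && is.numeric(z) && all(z > 0)) {
    drop_imag(as.complex(val), 1e-13)
  } else {
    val
  }
}

# ---- classical polynomial families ----------------------------------------

#' Neumann and Schlafli polynomials
#'
#' Explicit finite sums (valid for every order, matching the printed
#' low-order cases \eqn{O_0 = 1/z}, \eqn{O_1 = 1/z^2}, \eqn{O_2 = 1/z +
#' 4/z^3}; \eqn{S_0 = 0}, \eqn{S_1 = 2/z}, \eqn{S_2 = 4/z^2}):
#' \deqn{O_m(z) = \frac14 \sum_{k=0}^{\lfloor m/2\rfloor}
#'   \frac{m\,(m-k-1)!}{k!} (2/z)^{m-2k+1}, \quad m \ge 1,}
#' \deqn{S_m(z) = \sum_{k=0}^{\lceil m/2\rceil - 1}
#'   \frac{(m-k-1)!}{k!} (2/z)^{m-2k}, \quad m \ge 1.}
#'
#' @param kind `"neumann_O"` or `"schlafli_S"`.
#' @param m polynomial order, non-negative integer.
#' @param z argument (possibly complex); vectorized.
#' @export
classical_polynomial <- function(kind, m, z) {
  kind <- match.arg(kind, c("neumann_O", "schlafli_S"))
  if (m < 0 || m != round(m)) stop("m must be a non-negative integer")
  if (kind == "neumann_O") {
    if (m == 0) return(1 / z)
    k <- 0:(m %/% 2)
    co <- m * factorial(m - k - 1) / factorial(k) / 4
    pw <- m - 2 * k + 1
  } else {
    if (m == 0) return(0 * z)
    k <- 0:(ceiling(m / 2) - 1)
    co <- factorial(m - k - 1) / factorial(k)
    pw <- m - 2 * k
  }
  vapply(seq_along(z), function(i) sum(co * (2 / z[i])^pw), z[1] * 0)
}

#' Gegenbauer polynomial A_{n,nu}
#'
#' \deqn{A_{n,\nu}(z) = 2^{\nu+n} \frac{\nu+n}{z^{n+1}}
#'   \sum_{m=0}^{\lfloor n/2\rfloor} \frac{\Gamma(\nu+n-m)}{m!} (z/2)^{2m}.}
#' Low orders reduce to \eqn{A_{0,\nu} = \Gamma(\nu+1) 2^\nu / z} and
#' \eqn{A_{1,\nu} = \Gamma(\nu+2) 2^{\nu+1} / z^2}, and the family satisfies
#' \eqn{A_{2p,1-\gamma}(z) = z A_{2p+1,-\gamma}(z)}.
#'
#' @param n non-negative integer degree.
#' @param nu index (real or complex).
#' @param z argument.
#' @export
gegenbauer_A <- function(n, nu, z) {
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer")
  m <- 0:(n %/% 2)
  zc <- as.complex(z)
  s <- sum(pracma::gammaz(nu + n - m) / factorial(m) * (zc / 2)^(2 * m))
  val <- 2^(nu + n) * (nu + n) * s / zc^(n + 1)
  if (is_real_scalar(nu) && is.numeric(z) && all(z > 0)) drop_imag(val, 1e-13) else val
}

# ---- Lommel function of the second kind -----------------------------------

lommel_closed_form <- function(kappa, nu, z) {
  # registered closed forms for (near-)integer / half-integer index pairs;
  # returns NULL when no pattern applies
  if (!is_real_scalar(kappa, 1e-12) || !is_real_scalar(nu, 1e-12)) return(NULL)
  ka <- Re(as.complex(kappa)); nu_r <- Re(as.complex(nu))
  is_int <- function(x) abs(x - round(x)) < 1e-12
  if (is_int(ka) && is_int(nu_r)) {
    ka <- round(ka); nr <- round(abs(nu_r))
    if (ka == 1 && nr %% 2 == 0) {          # S_{1,2m} = z O_{2m}(z)
      return(z * classical_polynomial("neumann_O", nr, z))
    }
    if (ka == 0 && nr %% 2 == 1) {          # S_{0,2m+1} = z O_{2m+1}(z)/(2m+1)
      return(z * classical_polynomial("neumann_O", nr, z) / nr)
    }
    if (ka == -1 && nr %% 2 == 0 && nr >= 2) {   # S_{-1,2m} = S_{2m}(z)/(4m)
      return(classical_polynomial("schlafli_S", nr, z) / (2 * nr))
    }
  }
  # odd kappa+nu: Gegenbauer reduction, S_{k,2p+1-k} with p >= 0
  tot <- ka + abs(nu_r)
  if (is_int(tot) && round(tot) %% 2 == 1 && round(tot) >= 1) {
    p <- (round(tot) - 1) / 2
    if (!(is_int(1 + p - ka) && round(1 + p - ka) <= 0) && abs(2 * p + 1 - ka) > 1e-12) {
      val <- factorial(p) / (2^(1 - ka) * gamma(p + 1 - ka)) *
        as.complex(z)^ka / (2 * p + 1 - ka) * gegenbauer_A(2 * p, 1 - ka, z)
      return(if (is.numeric(z) && all(z > 0)) drop_imag(val, 1e-13) else val)
    }
  }
  NULL
}

lommel_series_ok <- function(kappa, nu) {
  !near_nonpos_int((1 + kappa - nu) / 2) && !near_nonpos_int((1 + kappa + nu) / 2) &&
    abs((kappa + 1)^2 - nu^2) > 1e-12 &&
    !near_nonpos_int((kappa - nu + 3) / 2) && !near_nonpos_int((kappa + nu + 3) / 2)
}

#' Lommel function S_{kappa,nu}
#'
#' The Lommel function of the second kind,
#' \deqn{S_{\kappa,\nu}(z) = s_{\kappa,\nu}(z) + 2^{\kappa-1}
#'   \Gamma\!\left(\tfrac{1+\kappa-\nu}{2}\right)
#'   \Gamma\!\left(\tfrac{1+\kappa+\nu}{2}\right)
#'   \left[\sin\!\big(\tfrac{\pi(\kappa-\nu)}{2}\big) J_\nu(z)
#'       - \cos\!\big(\tfrac{\pi(\kappa-\nu)}{2}\big) Y_\nu(z)\right].}
#'
#' Route selection (`route = "auto"`): the series form is used whenever the
#' Gamma factors and the \eqn{{}_1F_2} parameters are pole-free; otherwise a
#' registered closed form is used (Neumann/Schlafli polynomials for
#' \eqn{S_{1,2m}}, \eqn{S_{0,2m+1}}, \eqn{S_{-1,2m}}, and the Gegenbauer
#' reduction for odd \eqn{\kappa+\nu}); otherwise the index recurrence
#' \eqn{S_{\kappa,\nu} = (z^{\kappa+1} - S_{\kappa+2,\nu}) /
#' ((\kappa+1)^2-\nu^2)} shifts \eqn{\kappa} upward (at most 3 times) to a
#' resolvable pair.  The exceptional pair \eqn{S_{-1,0}} has no finite route
#' here and raises an error.  Complex \eqn{(\kappa,\nu)} are restricted to
#' the series route.
#'
#' @inheritParams lommel_s_small
#' @param route `"auto"`, `"series"`, `"closed_form"` or `"recurrence"`.
#' @param .depth internal recursion guard.
#' @export
lommel_S <- function(kappa, nu, z, route = c("auto", "series", "closed_form", "recurrence"),
                     .depth = 0L) {
  route <- match.arg(route)
  series_eval <- function() {
    zc <- as.complex(z)
    g <- pracma::gammaz((1 + kappa - nu) / 2) * pracma::gammaz((1 + kappa + nu) / 2)
    val <- as.complex(lommel_s_small(kappa, nu, z)) +
      2^(kappa - 1) * g * (sin(pi * (kappa - nu) / 2) * bessel_J(nu, zc) -
                             cos(pi * (kappa - nu) / 2) * bessel_Y(nu, zc))
    if (is_real_scalar(kappa) && is_real_scalar(nu) && is.numeric(z) && all(z > 0)) {
      drop_imag(val, 1e-10)
    } else {
      val
    }
  }
  if (route == "series") {
    if (!lommel_series_ok(kappa, nu)) {
      stop(sprintf("lommel_S: series route has a Gamma/1F2 pole at (kappa=%s, nu=%s)",
                   format(kappa), format(nu)))
    }
    return(series_eval())
  }
  if (route == "closed_form") {
    cf <- lommel_closed_form(kappa, nu, z)
    if (is.null(cf)) {
      stop(sprintf("lommel_S: no registered closed form for (kappa=%s, nu=%s)",
                   format(kappa), format(nu)))
    }
    return(cf)
  }
  if (route == "recurrence" || route == "auto") {
    if (route == "auto") {
      if (lommel_series_ok(kappa, nu)) return(series_eval())
      cf <- lommel_closed_form(kappa, nu, z)
      if (!is.null(cf)) return(cf)
    }
    den <- (kappa + 1)^2 - nu^2
    if (abs(den) < 1e-12 || .depth >= 3L) {
      stop(sprintf(
        "lommel_S: no finite evaluation route for (kappa=%s, nu=%s) (exceptional pair, e.g. S_{-1,0})",
        format(kappa), format(nu)))
    }
    up <- lommel_S(kappa + 2, nu, z, route = "auto", .depth = .depth + 1L)
    val <- (as.complex(z)^(kappa + 1) - as.complex(up)) / den
    if (is_real_scalar(kappa) && is_real_scalar(nu) && is.numeric(z) && all(z > 0)) {
      return(drop_imag(as.complex(val), 1e-10))
    }
    return(val)
  }
}

#' Derivative of the Lommel function S_{kappa,nu}
#'
#' Obtained from the two first-order recurrences
#' \eqn{S'_{\kappa,\nu} \pm (\nu/z) S_{\kappa,\nu} = (\kappa \pm \nu - 1)
#' S_{\kappa-1,\nu\mp1}} by averaging, which eliminates the \eqn{\nu/z} term:
#' \deqn{S'_{\kappa,\nu}(z) = \tfrac12\left[(\kappa+\nu-1)
#'   S_{\kappa-1,\nu-1}(z) + (\kappa-\nu-1) S_{\kappa-1,\nu+1}(z)\right].}
#' Terms with a vanishing prefactor are skipped, so e.g.
#' \eqn{S'_{1,0} = 0} (the constant \eqn{S_{1,0} = 1}) needs no evaluation
#' of an exceptional pair.
#'
#' @inheritParams lommel_s_small
#' @export
lommel_S_deriv <- function(kappa, nu, z) {
  c1 <- kappa + nu - 1
  c2 <- kappa - nu - 1
  t1 <- if (abs(c1) < 1e-14) 0 else c1 * lommel_S(kappa - 1, nu - 1, z)
  t2 <- if (abs(c2) < 1e-14) 0 else c2 * lommel_S(kappa - 1, nu + 1, z)
  (t1 + t2) / 2
}
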