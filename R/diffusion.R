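# Application layer: diffusion propagator in the shell, dipole-field
# expansion coefficients F^2, the frequency autocorrelation function K(t)
# and the closed-form sum rules that certify truncation accuracy.

#' Specification of a shell diffusion problem
#'
#' @param dim `"cyl"` (spins around a magnetized cylinder/capillary) or
#'   `"sph"` (around a magnetized sphere/alveolus).
#' @param geometry a [shell_geometry()]; `R` in any consistent length unit.
#' @param D diffusion coefficient (length^2/time), `D > 0`.
#' @param delta_omega dipole-field strength \eqn{\delta\omega} (rad/time).
#' @return object with the geometry, transport parameters and the shell
#'   volume \eqn{V = \pi R^2(\gamma^2-1)} (2-D, per unit length) or
#'   \eqn{V = \frac43\pi R^3(\gamma^3-1)} (3-D).
#' @export
diffusion_spec <- function(dim, geometry, D, delta_omega = 1) {
  dim <- match_dim(dim)
  if (!is.numeric(D) || D <= 0) stop("D must be > 0")
  R <- geometry$R; g <- geometry$gamma
  V <- if (dim == "cyl") pi * R^2 * (g^2 - 1) else 4 / 3 * pi * R^3 * (g^3 - 1)
  structure(list(dim = dim, geometry = geometry, D = D,
                 delta_omega = delta_omega, V = V),
            class = "diffusion_spec")
}

#' Dipole-field shape function
#'
#' The dimensionless local resonance-frequency shape around a magnetized
#' cylinder, \eqn{f(r,\phi) = (R/r)^2\cos(2\phi)}, or sphere,
#' \eqn{f(r,\theta) = (R/r)^3(3\cos^2\theta - 1)}.  The local frequency is
#' \eqn{\omega = \delta\omega\, f}.
#'
#' @param dim `"cyl"` or `"sph"`.
#' @param geometry a [shell_geometry()].
#' @param r radial coordinate(s), must lie in `[R, gamma*R]`.
#' @param angle azimuthal angle \eqn{\phi} (2-D) or polar angle
#'   \eqn{\theta} (3-D).
#' @export
dipole_shape <- function(dim, geometry, r, angle) {
  dim <- match_dim(dim)
  R <- geometry$R; g <- geometry$gamma
  if (any(r < R * (1 - 1e-12)) || any(r > g * R * (1 + 1e-12))) {
    stop("dipole_shape: coordinates outside the shell")
  }
  if (dim == "cyl") (R / r)^2 * cos(2 * angle) else (R / r)^3 * (3 * cos(angle)^2 - 1)
}

#' Dipole-field expansion coefficients F^2
#'
#' Projection of the dipole shape on the Neumann eigenbasis.  Only the
#' angular order \eqn{\nu = 2} couples, so the expansion runs over the
#' zeros \eqn{\lambda_{n,2}}.  Two printed closed forms are evaluated per
#' mode and cross-validated: in 2-D the derivative-ratio form and the
#' cleared form
#' \deqn{F_n^2 = \frac{8}{\gamma^2-1}\frac{1}{\lambda^2\gamma^4}
#'   \frac{[\gamma^3 J'_2(\gamma\lambda) - J'_2(\lambda)]^2}
#'        {\gamma^2(4-\lambda^2)J'_2(\gamma\lambda)^2 +
#'         (\gamma^2\lambda^2-4)J'_2(\lambda)^2};}
#' in 3-D the spherical-Bessel form and the trigonometric reduction of the
#' \eqn{j'_2} ratio.  (The derivative-ratio 2-D form is used with the
#' \eqn{1/\lambda^2} prefactor that re-deriving it from the Lommel integral
#' and the normalization constant gives; only then do the two routes and
#' all four sum rules agree.)
#'
#' @inheritParams bessel_cross
#' @param n_max number of modes.
#' @param modes optional precomputed `mode_table` for `nu = 2` (saves the
#'   eigenvalue solve); must match `dim` and `gamma`.
#' @param p grid size passed to [find_zeros()] when `modes` is missing.
#' @param cross_tol allowed relative disagreement between the two closed
#'   forms.
#' @return a `dipole_expansion`: data frame with columns `n`, `lambda`,
#'   `F2`, attributes `dim`, `gamma`, `max_route_diff`.
#' @export
expansion_coefficients <- function(dim, gamma, n_max, modes = NULL, p = 2000,
                                   cross_tol = 1e-8) {
  dim <- match_dim(dim)
  if (is.null(modes)) modes <- find_zeros(dim, 2, gamma, n_max, p = p)
  lam <- Re(modes$lambda)[seq_len(n_max)]
  g <- gamma
  if (dim == "cyl") {
    j1 <- bessel_Jp(2, lam); j2 <- bessel_Jp(2, g * lam)
    rr <- j1 / j2
    F2a <- 8 / (g^2 - 1) / lam^2 * (1 - rr / g^3)^2 /
      (4 - lam^2 + (lam^2 - 4 / g^2) * rr^2)
    F2b <- 8 / (g^2 - 1) / lam^2 / g^4 * (g^3 * j2 - j1)^2 /
      (g^2 * (4 - lam^2) * j2^2 + (g^2 * lam^2 - 4) * j1^2)
  } else {
    rr <- sph_jp(2, lam) / sph_jp(2, g * lam)
    F2a <- 216 / 5 / lam^2 / (g^3 - 1) * (1 - rr / g^4)^2 /
      ((g^2 * lam^2 - 6) / g^3 * rr^2 + 6 - lam^2)
    # trigonometric reduction of j2'(lam)/j2'(g lam)
    num <- (4 * lam^2 - 9) * sin(lam) + lam * (9 - lam^2) * cos(lam)
    den <- (4 * g^2 * lam^2 - 9) * sin(g * lam) + g * lam * (9 - g^2 * lam^2) * cos(g * lam)
    q <- num / den
    F2b <- 216 / 5 / lam^2 / (g^3 - 1) * (1 - q)^2 /
      (g^5 * q^2 * (g^2 * lam^2 - 6) + 6 - lam^2)
  }
  dmax <- max(abs(F2a - F2b) / pmax(abs(F2b), 1e-300))
  if (dmax > cross_tol) {
    stop(sprintf("expansion_coefficients: closed-form routes disagree (%.3e rel)", dmax))
  }
  if (any(F2b < -1e-14)) stop("expansion_coefficients: negative F^2")
  structure(data.frame(n = seq_along(lam), lambda = lam, F2 = pmax(F2b, 0)),
            dimension = dim, gamma = gamma, max_route_diff = dmax,
            class = c("dipole_expansion", "data.frame"))
}

#' Closed-form sum rules for the dipole expansion
#'
#' Exact values of weighted mode sums, used as accuracy certificates for
#' truncated expansions.  2-D:
#' \eqn{\sum F_n^2 = 1/(2\gamma^2)},
#' \eqn{\sum F_n^2\lambda_n^2 = 2(1+\gamma^2)/\gamma^4},
#' \eqn{\sum F_n^2/\lambda_n^2 = \ln\gamma / (4[\gamma^2-1])},
#' \eqn{\sum F_n^2/\lambda_n^4 = 1/32} (independent of \eqn{\gamma}).
#' 3-D: \eqn{\sum F_m^2 = 4/(5\gamma^3)},
#' \eqn{\sum F_m^2\lambda_m^2 = \frac{36}{5\gamma^5}\frac{\gamma^5-1}{\gamma^3-1}},
#' and the bracketed closed form for \eqn{\sum F_m^2/\lambda_m^2}.
#' Note that the \eqn{\sum F^2 \lambda^2} sums converge only like the
#' inverse of the number of modes (\eqn{F^2\lambda^2 \sim \lambda^{-2}}
#' with positive terms), reflecting the nonzero normal derivative of the
#' dipole field at the walls; the other sums converge fast.
#'
#' @inheritParams bessel_cross
#' @return data frame with columns `rule`, `weight`, `value`.
#' @export
sum_rules <- function(dim, gamma) {
  dim <- match_dim(dim)
  g <- gamma
  if (g <= 1) stop("sum_rules: gamma must be > 1 (pole at gamma = 1)")
  if (dim == "cyl") {
    data.frame(
      rule = c("sum_F2", "sum_F2_lam2", "sum_F2_over_lam2", "sum_F2_over_lam4"),
      weight = c("1", "lambda^2", "lambda^-2", "lambda^-4"),
      value = c(1 / (2 * g^2),
                2 * (1 + g^2) / g^4,
                log(g) / (4 * (g^2 - 1)),
                1 / 32))
  } else {
    data.frame(
      rule = c("sum_F2", "sum_F2_lam2", "sum_F2_over_lam2"),
      weight = c("1", "lambda^2", "lambda^-2"),
      value = c(4 / (5 * g^3),
                36 / (5 * g^5) * (g^5 - 1) / (g^3 - 1),
                2 / 5 / (g^3 - 1) *
                  (1 - 1 / g + (4 * (g^3 - 1)^2 + 9 * g * (2 * g^2 - 1 - g^4)) /
                     (36 * g * (1 - g^5)))))
  }
}

#' Frequency autocorrelation function K(t)
#'
#' \deqn{K(t) = \delta\omega^2 \sum_n F_n^2\,
#'   e^{-\lambda_{n,2}^2 D t / R^2},}
#' the autocorrelation of the local dipole-field frequency along diffusion
#' paths in the shell.  `K(0)` equals \eqn{\delta\omega^2} times the first
#' sum rule up to the truncation deficit; a warning is issued when the
#' estimated dropped tail (from the empirical \eqn{F^2 \sim c\lambda^{-4}}
#' decay) exceeds `1e-6` of `K(0)`.
#'
#' @param spec a [diffusion_spec()].
#' @param expansion a [expansion_coefficients()] result (matching `dim`).
#' @param times times (same time unit as `D`), `>= 0`.
#' @return data frame with columns `t`, `tau` (\eqn{Dt/R^2}), `K_rel`
#'   (\eqn{K/\delta\omega^2}) and `K` (rad^2/time^2).
#' @export
correlation_function <- function(spec, expansion, times) {
  stopifnot(inherits(spec, "diffusion_spec"), inherits(expansion, "dipole_expansion"))
  if (length(times) == 0) stop("correlation_function: empty time grid")
  if (any(times < 0)) stop("correlation_function: times must be >= 0")
  if (!identical(spec$dim, attr(expansion, "dimension"))) {
    stop("dimension mismatch between spec and expansion")
  }
  lam <- expansion$lambda
  F2 <- expansion$F2
  N <- length(lam)
  # tail estimate: F^2 ~ c/lambda^4 beyond the truncation
  cst <- mean(F2[max(1, N - 9):N] * lam[max(1, N - 9):N]^4)
  spacing <- pi / (attr(expansion, "gamma") - 1)
  tail_est <- cst / (3 * spacing * lam[N]^3)
  K0 <- sum(F2)
  if (tail_est > 1e-6 * K0) {
    warning(sprintf(
      "correlation_function: truncation tail ~%.2e exceeds 1e-6 of K(0); increase n_max",
      tail_est / K0))
  }
  tau <- spec$D * times / spec$geometry$R^2
  Krel <- vapply(tau, function(s) sum(F2 * exp(-lam^2 * s)), 0)
  data.frame(t = times, tau = tau, K_rel = Krel,
             K = spec$delta_omega^2 * Krel)
}

# cache of mode tables + normalizations for the propagator
mode_cache <- new.env(parent = emptyenv())

propagator_modes <- function(dim, gamma, nu, n_max, p) {
  key <- paste(dim, format(gamma, digits = 15), nu, n_max, p, sep = "|")
  if (!is.null(mode_cache[[key]])) return(mode_cache[[key]])
  mt <- find_zeros(dim, nu, gamma, n_max, p = p)
  lam <- Re(mt$lambda)
  out <- list(lam = lam,
              N = vapply(lam, function(l) Re(as.complex(
                normalization(dim, nu, l, gamma, check = FALSE))), 0))
  mode_cache[[key]] <- out
  out
}

legendre_P <- function(nmax, x) {
  # P_0..P_nmax(x) by upward recurrence
  out <- numeric(nmax + 1)
  out[1] <- 1
  if (nmax >= 1) out[2] <- x
  for (n in seq_len(max(nmax - 1, 0))) {
    out[n + 2] <- ((2 * n + 1) * x * out[n + 1] - n * out[n]) / (n + 1)
  }
  out
}

#' Diffusion propagator in the shell
#'
#' Eigenfunction expansion of the transition density for reflected Brownian
#' motion between the two shells.  2-D:
#' \deqn{p = \frac{1}{\pi R^2(\gamma^2-1)} + \frac{1}{2\pi R^2}
#'   \sum_{\nu\ge0}\sum_n \frac{e^{-\lambda^2 Dt/R^2}}{N_{n,\nu}}
#'   \Phi_{n,\nu}(\rho)\Phi_{n,\nu}(\rho_0)\,
#'   (2-\delta_{\nu0})\cos(\nu\Delta\phi),}
#' 3-D with \eqn{(2\nu+1)P_\nu(\cos\Omega)/(4\pi R^3)} and the constant
#' \eqn{3/[4\pi R^3(\gamma^3-1)]}; \eqn{\Omega} is the spherical angle
#' between initial and final direction (law of cosines).  Truncation is
#' adaptive: modes are included until \eqn{e^{-\lambda^2 Dt/R^2}} falls
#' below `cutoff`; a warning flags small times where the angular order
#' limit `nu_limit` is reached while terms are still significant.  The
#' long-time limit is \eqn{1/V}.
#'
#' @param spec a [diffusion_spec()].
#' @param r,r0 final and initial radial position (same unit as `R`).
#' @param angle angle between final and initial position: azimuthal
#'   difference \eqn{\phi-\phi_0} (2-D) or spherical angle \eqn{\Omega}
#'   (3-D).
#' @param t time, `t > 0`.
#' @param cutoff exponential damping threshold for dropping modes.
#' @param nu_limit hard cap on the angular order.
#' @param p grid size for the eigenvalue seeding.
#' @return the transition density, unit 1/length^2 (2-D, per unit length)
#'   or 1/length^3 (3-D).
#' @export
propagator <- function(spec, r, r0, angle, t, cutoff = 1e-12, nu_limit = 60L,
                       p = 1200) {
  stopifnot(inherits(spec, "diffusion_spec"))
  R <- spec$geometry$R; g <- spec$geometry$gamma
  if (r < R || r > g * R || r0 < R || r0 > g * R) stop("propagator: position outside the shell")
  if (t <= 0) stop("propagator: t must be > 0")
  tau <- spec$D * t / R^2
  lam_cut <- sqrt(-log(cutoff) / tau)
  rho <- r / R; rho0 <- r0 / R
  dim <- spec$dim
  acc <- 0
  truncated <- FALSE
  for (nu in 0:nu_limit) {
    # grow the mode list until the exponential cuts off
    n_max <- max(2L, ceiling(lam_cut * (g - 1) / pi) + 2L)
    md <- propagator_modes(dim, g, nu, n_max, p)
    keep <- md$lam <= lam_cut
    if (!any(keep)) {
      if (nu == 0) next else break
    }
    lam <- md$lam[keep]; Nn <- md$N[keep]
    ph <- radial_eigenfunction(dim, nu, lam, rho)
    ph0 <- radial_eigenfunction(dim, nu, lam, rho0)
    wgt <- exp(-lam^2 * tau) / Nn * ph * ph0
    acc <- acc + if (dim == "cyl") {
      sum(wgt) * (2 - (nu == 0)) * cos(nu * angle)
    } else {
      sum(wgt) * (2 * nu + 1) * legendre_P(nu, cos(angle))[nu + 1]
    }
    if (nu == nu_limit && any(keep)) truncated <- TRUE
  }
  if (truncated) {
    warning("propagator: angular-order cap reached while terms are still significant (t too small?)")
  }
  if (dim == "cyl") {
    1 / (pi * R^2 * (g^2 - 1)) + acc / (2 * pi * R^2)
  } else {
    (3 / (g^3 - 1) + acc) / (4 * pi * R^3)
  }
}

#' Residual of the nu = 2 spherical secular equation
#'
#' The transcendental equation equivalent to the vanishing of the spherical
#' cross product at \eqn{\nu = 2}:
#' \deqn{\frac{\tan(\lambda[\gamma-1])}{\lambda[\gamma-1]} =
#'   \frac{81 - 9\lambda^2[\gamma^2-3\gamma+1] + 4\gamma^2\lambda^4}
#'        {81 - 9\lambda^2[4\gamma^2-9\gamma+4] +
#'         \gamma\lambda^4[16\gamma-9\gamma^2-9] + \gamma^3\lambda^6}.}
#' Returns left minus right side; vanishes exactly at the \eqn{\nu = 2}
#' Neumann zeros.  Errors near tangent poles
#' (\eqn{\lambda[\gamma-1]} close to \eqn{\pi/2 + k\pi}).
#'
#' @param lam evaluation point (real).
#' @param gamma shell ratio.
#' @export
sph_secular_residual <- function(lam, gamma) {
  g <- gamma
  x <- lam * (g - 1)
  if (abs(cos(x)) < 1e-8) stop("sph_secular_residual: tan pole at lam*(gamma-1) = pi/2 + k*pi")
  lhs <- tan(x) / x
  rhs <- (81 - 9 * lam^2 * (g^2 - 3 * g + 1) + 4 * g^2 * lam^4) /
    (81 - 9 * lam^2 * (4 * g^2 - 9 * g + 4) +
       g * lam^4 * (16 * g - 9 * g^2 - 9) + g^3 * lam^6)
  lhs - rhs
}
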