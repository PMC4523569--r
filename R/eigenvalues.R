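# Location of the cross-product zeros lambda_{n,nu}: finite-difference
# discretization of the radial Laplacian with Neumann closure (the matrix
# eigenproblem provides globally reliable seeds), root polishing against the
# analytic cross product, and the printed literature approximations.

#' Shell geometry
#'
#' The radial domain `R <= r <= gamma*R`.
#'
#' @param R inner radius (any length unit), `R > 0`.
#' @param gamma outer/inner radius ratio, `gamma >= 1`.
#' @export
shell_geometry <- function(R = 1, gamma) {
  if (!is.numeric(R) || R <= 0) stop("R must be > 0")
  if (!is.numeric(gamma) || gamma < 1) stop("gamma must be >= 1")
  structure(list(R = R, gamma = gamma), class = "shell_geometry")
}

#' Uniform radial grid on the shell
#'
#' Nodes `r_j = R + (j-1) h`, `j = 1..p`, with spacing
#' `h = R (gamma-1)/(p-1)`, so `r_1 = R` and `r_p = gamma*R`.
#'
#' @param p number of nodes, `p >= 2`.
#' @param geometry a [shell_geometry()].
#' @export
build_grid <- function(p, geometry) {
  if (p < 2 || p != round(p)) stop("p must be an integer >= 2")
  p <- as.integer(p)
  h <- geometry$R * (geometry$gamma - 1) / (p - 1)
  structure(list(p = p, h = h, r = geometry$R + (seq_len(p) - 1) * h,
                 R = geometry$R, gamma = geometry$gamma),
            class = "radial_grid")
}

# tridiagonal representation of the discretized radial Laplacian:
# half-index radii r_{j+1/2} = R + (j - 1/2) h enter linearly (cyl) or
# squared (sph); first and last rows carry the factor-2 Neumann closure.
laplacian_tridiag <- function(dim, grid) {
  dim <- match_dim(dim)
  p <- grid$p; h <- grid$h; r <- grid$r
  rh <- grid$R + (seq_len(p - 1) - 0.5) * h       # r_{j+1/2}, j = 1..p-1
  pw <- if (dim == "cyl") 1 else 2
  a <- rh^pw
  sup <- a / r[seq_len(p - 1)]^pw / h^2           # entry (j, j+1)
  sub <- a / r[2:p]^pw / h^2                      # entry (j+1, j)
  sup[1] <- 2 * sup[1]
  sub[p - 1] <- 2 * sub[p - 1]
  dg <- numeric(p)
  dg[1] <- -sup[1]
  dg[p] <- -sub[p - 1]
  if (p > 2) {
    j <- 2:(p - 1)
    dg[j] <- -(a[j - 1] + a[j]) / r[j]^pw / h^2
  }
  list(sub = sub, diag = dg, sup = sup)
}

#' Discretized radial Laplacian with Neumann closure
#'
#' Dense `p x p` tridiagonal matrix of the radial part of the 2-D or 3-D
#' Laplace operator on the grid, conservative (every row sums to zero) with
#' interior diagonal exactly `-2/h^2` in the cylindrical case and a factor-2
#' closure in the first and last rows enforcing the reflecting boundary.
#'
#' @param dim `"cyl"` or `"sph"`.
#' @param grid a [build_grid()] result.
#' @export
build_discrete_laplacian <- function(dim, grid) {
  td <- laplacian_tridiag(dim, grid)
  p <- grid$p
  m <- diag(td$diag, p, p)
  m[cbind(seq_len(p - 1), 2:p)] <- td$sup
  m[cbind(2:p, seq_len(p - 1))] <- td$sub
  m
}

#' Radial Neumann eigenvalues from the matrix eigenproblem
#'
#' Solves the discretized eigenvalue problem
#' \eqn{[\nu^2 \mathrm{diag}(1/r_j^2) - \hat\Delta_r]\hat\Phi =
#' (\lambda^2/R^2)\hat\Phi} (with \eqn{\nu(\nu+1)} in 3-D) and returns the
#' `k` smallest eigenvalues as \eqn{\lambda} (principal square root).  For
#' real order the tridiagonal operator is diagonally similar to a symmetric
#' matrix and a symmetric solver is used; complex order falls back to a
#' dense complex eigendecomposition sorted lexicographically by (Re, Im).
#' Accuracy is second order in the grid spacing, so values are seeds for
#' [polish_zero()], not final answers.
#'
#' @inheritParams build_discrete_laplacian
#' @param nu Bessel order (real or complex scalar).
#' @param geometry a [shell_geometry()].
#' @param p number of grid nodes.
#' @param k number of eigenvalues to return, `k <= p`.
#' @export
matrix_modes <- function(dim, nu, geometry, p, k) {
  dim <- match_dim(dim)
  if (k > p) stop("k must be <= p")
  grid <- build_grid(p, geometry)
  td <- laplacian_tridiag(dim, grid)
  ord <- if (dim == "cyl") nu^2 else nu * (nu + 1)
  if (is_real_scalar(ord)) {
    d <- Re(ord) / grid$r^2 - td$diag
    e <- sqrt(td$sub * td$sup)      # symmetrizing similarity transform
    S <- diag(d, p, p)
    S[cbind(seq_len(p - 1), 2:p)] <- -e
    S[cbind(2:p, seq_len(p - 1))] <- -e
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    ev <- sort(ev)[seq_len(k)]
    grid$R * sqrt(pmax(ev, 0))
  } else {
    M <- diag(as.complex(ord / grid$r^2 - td$diag), p, p)
    M[cbind(seq_len(p - 1), 2:p)] <- -td$sup
    M[cbind(2:p, seq_len(p - 1))] <- -td$sub
    ev <- tryCatch(eigen(M, only.values = TRUE)$values,
                   error = function(e) stop("matrix_modes: complex eigensolver failed: ",
                                            conditionMessage(e)))
    lam <- grid$R * sqrt(as.complex(ev))
    lam[order(Re(lam), Im(lam))][seq_len(k)]
  }
}

# residual scale: the spherical cross product behaves like lambda^-3 near 0,
# so small-|lambda| residuals are measured on lambda^3 * g(lambda)
cross_residual <- function(dim, nu, gamma, lam) {
  sc <- if (dim == "sph") min(1, abs(lam)^3) else 1
  abs(bessel_cross(dim, nu, gamma, lam)) * sc
}

#' Polish a cross-product zero
#'
#' Refines a seed (typically from [matrix_modes()]) to a zero of
#' [bessel_cross()].  For real order and a real seed a bracketed
#' Brent/bisection search is used, which cannot jump roots; for complex
#' order an unconstrained secant iteration in the complex plane is used,
#' guarded against collapsing onto a different root (the polished value may
#' move at most half the local root spacing from the seed).
#'
#' @inheritParams bessel_cross
#' @param seed starting value, assumed within the basin of the target root.
#' @param spacing local root spacing used by the guards; defaults to the
#'   asymptotic spacing `pi/(gamma-1)`.
#' @param tol residual tolerance relative to `max(1, |f(seed)|)`.
#' @param max_iter secant iteration cap.
#' @return list with elements `lam`, `residual`, `iterations`.
#' @export
polish_zero <- function(dim, nu, gamma, seed, spacing = NULL, tol = 1e-12,
                        max_iter = 50L) {
  dim <- match_dim(dim)
  if (is.null(spacing)) spacing <- pi / max(gamma - 1, 1e-6)
  f0 <- bessel_cross(dim, nu, gamma, seed)
  target <- tol * max(1, abs(f0))
  if (cross_residual(dim, nu, gamma, seed) < target) {
    return(list(lam = seed, residual = cross_residual(dim, nu, gamma, seed),
                iterations = 0L))
  }
  if (is_real_scalar(nu) && is_real_scalar(seed)) {
    seed <- Re(as.complex(seed))
    f <- function(l) bessel_cross(dim, Re(as.complex(nu)), gamma, l)
    # expand around the seed until the cross product changes sign
    step <- spacing / 40
    lo <- seed; hi <- seed
    bracket <- NULL
    for (i in seq_len(24L)) {
      lo2 <- max(seed - i * step, 1e-12)
      hi2 <- seed + i * step
      if (f(lo2) * f(seed) < 0) { bracket <- c(lo2, seed); break }
      if (f(hi2) * f(seed) < 0) { bracket <- c(seed, hi2); break }
      if ((seed - lo2) > 0.6 * spacing && (hi2 - seed) > 0.6 * spacing) break
      lo <- lo2; hi <- hi2
    }
    if (is.null(bracket)) {
      stop("polish_zero: no sign change within half the local root spacing of the seed")
    }
    r <- uniroot(f, bracket, tol = .Machine$double.eps / 4)
    lam <- r$root
    it <- r$iter
  } else {
    # secant in the complex plane
    x0 <- as.complex(seed)
    x1 <- x0 * (1 + 1e-6) + 1e-6i
    fx0 <- as.complex(bessel_cross(dim, nu, gamma, x0))
    fx1 <- as.complex(bessel_cross(dim, nu, gamma, x1))
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("polish_zero: secant iteration did not converge")
      dx <- fx1 * (x1 - x0) / (fx1 - fx0)
      x0 <- x1; fx0 <- fx1
      x1 <- x1 - dx
      fx1 <- as.complex(bessel_cross(dim, nu, gamma, x1))
      if (abs(dx) < 1e-14 * max(1, abs(x1)) || abs(fx1) < target) break
    }
    lam <- x1
    if (abs(lam - as.complex(seed)) > 0.5 * spacing) {
      stop("polish_zero: root collapse (polished value moved more than half the root spacing)")
    }
  }
  res <- cross_residual(dim, nu, gamma, lam)
  if (res > target) {
    # the root location is machine-precision limited: accept a residual at
    # the level eps * |lam| * |f'(lam)| that rounding of lam alone implies
    del <- 1e-7 * max(1, abs(lam))
    fp <- abs(bessel_cross(dim, nu, gamma, lam + del) -
                bessel_cross(dim, nu, gamma, lam - del)) / (2 * del)
    floor_res <- 100 * .Machine$double.eps * max(1, abs(lam)) * fp
    if (res > max(target, floor_res)) {
      stop(sprintf("polish_zero: residual %.3e above tolerance %.3e", res, target))
    }
  }
  list(lam = lam, residual = res, iterations = it)
}

#' Closed-form approximations for the first (exceptional) zero
#'
#' The exceptional zero \eqn{\lambda_{1,\nu}} tends to \eqn{\nu} (annulus)
#' or \eqn{\sqrt{\nu(\nu+1)}} (spherical shell) as \eqn{\gamma \to 1},
#' unlike the higher zeros which scale as \eqn{\pi(n-1)/(\gamma-1)}.
#' Available methods: `"small_lambda"` (first zero of the small-\eqn{\lambda}
#' expansion of the cross product), `"small_nu"` (additional Taylor expansion
#' in \eqn{\nu}), and the literature results of Gottlieb, Grebenkov and (2-D
#' only) Buchholz.  All are expansions around \eqn{\gamma = 1}; their
#' accuracy degrades for thick shells and no validity window is enforced.
#' The 2-D `"small_lambda"` form has a pole at \eqn{\nu = \pm 1}.
#'
#' @inheritParams bessel_cross
#' @param method approximation to evaluate.
#' @export
approx_first <- function(dim, nu, gamma,
                         method = c("small_lambda", "small_nu", "gottlieb",
                                    "grebenkov", "buchholz")) {
  dim <- match_dim(dim)
  method <- match.arg(method)
  g <- gamma
  val <- if (dim == "cyl") {
    switch(method,
      small_lambda = {
        if (abs(nu^2 - 1) < 1e-12) stop("approx_first: pole at nu = +/-1 (cyl small-lambda form)")
        sqrt(4 * nu * (1 - nu^2) * (g^(2 * nu) - 1) /
               ((nu^2 + nu - 2) * (1 - g^2) * (1 + g^(2 * nu)) -
                  2 * nu * (g^(2 * nu) - g^2)))
      },
      small_nu = nu * sqrt(2 * log(g) / (g^2 - 1)),
      gottlieb = nu * (1 - (g - 1) / 2 + 7 * (g - 1)^2 / 24),
      grebenkov = nu * sqrt(2 - g + 5 / 6 * (1 - g)^2 + 2 / 3 * (1 - g)^3 -
                              (nu^2 - 16) / 30 * (1 - g)^4),
      buchholz = nu / (sqrt(g) * (1 + (g - 1)^2 / (12 * g) +
                                    (8 * nu^2 - 3) * (g - 1)^4 / (480 * g^2) -
                                    (144 * nu^2 - 103) * (g - 1)^6 / (120960 * g^3)))
    )
  } else {
    switch(method,
      small_lambda = sqrt(2 * nu * (nu + 1) * (4 * nu^2 + 4 * nu - 3) * (1 - g^(2 * nu + 1)) /
                            ((2 * nu^3 + 5 * nu^2 + nu - 2) * (1 - g^(2 * nu + 3)) +
                               nu * g^2 * (2 * nu^2 + nu - 3) * (g^(2 * nu - 1) - 1))),
      small_nu = sqrt(3 * nu / (1 + g + g^2)),
      gottlieb = sqrt(nu * (1 + nu)) * (1 - (g - 1) / 2 + 5 * (g - 1)^2 / 24 -
                                          (g - 1)^3 / 16 +
                                          (5 - 32 * nu * (nu + 1)) / 1920 * (g - 1)^4),
      grebenkov = sqrt(nu * (1 + nu)) *
        sqrt(2 - g + 2 / 3 * (1 - g)^2 + 1 / 3 * (1 - g)^3 -
               (3 * nu * (1 + nu) - 10) / 90 * (1 - g)^4),
      buchholz = stop("approx_first: the Buchholz first-zero form exists only for dim = 'cyl'")
    )
  }
  drop_imag(as.complex(val), 1e-12)
}

#' Asymptotic approximations for the higher zeros (n >= 2)
#'
#' McMahon's expansion, leading term \eqn{\pi(n-1)/(\gamma-1)} (labeling with
#' the exceptional zero as n = 1, i.e. without the Abramowitz--Stegun index
#' shift), with the printed higher-order corrections; and Buchholz's rational
#' form (2-D only).
#'
#' @inheritParams bessel_cross
#' @param n mode index, `n >= 2`.
#' @param method `"mcmahon"` or `"buchholz"`.
#' @export
approx_higher <- function(dim, nu, gamma, n, method = c("mcmahon", "buchholz")) {
  dim <- match_dim(dim)
  method <- match.arg(method)
  if (any(n < 2)) stop("approx_higher applies to n >= 2")
  g <- gamma
  b <- (g - 1) / (n - 1)
  val <- if (dim == "cyl") {
    if (method == "mcmahon") {
      pi / b + (4 * nu^2 + 3) / (8 * pi * g) * b +
        ((g^2 + g + 1) * (16 * nu^4 + 184 * nu^2 - 63) -
           6 * g * (4 * nu^2 + 3)^2) / (384 * pi^3 * g^3) * b^3
    } else {
      (pi / b) / (1 - (4 * nu^2 + 3) / (8 * g * pi^2) * b^2 +
                    (96 * nu^4 - 176 * nu^2 + 198) / (256 * g^2 * pi^4) * b^4)
    }
  } else {
    if (method == "buchholz") stop("approx_higher: Buchholz form exists only for dim = 'cyl'")
    pi / b + (nu^2 + nu + 2) / (2 * pi * g) * b
  }
  drop_imag(as.complex(val), 1e-12)
}

#' Locate and polish the cross-product zeros
#'
#' The workhorse: seeds from the discretized-Laplacian eigenproblem
#' ([matrix_modes()]) — supplemented by McMahon seeds for modes beyond the
#' resolution of the grid (`lambda * h > 0.25`) — polished against the
#' analytic cross product by [polish_zero()].  Indexing starts at the
#' smallest zero with `Re(lam) > tol_zero` (the exceptional zero); the
#' \eqn{\lambda = 0} constant mode that the Neumann operator always carries
#' for \eqn{\nu = 0} is excluded and reported in the `excluded` attribute.
#' For real order, consecutive gaps are checked against the asymptotic
#' spacing \eqn{\pi/(\gamma-1)}; a flagged hole is recovered by a dense
#' sign scan of the cross product, and duplicate roots raise an error.
#'
#' @inheritParams bessel_cross
#' @param n_max number of zeros requested.
#' @param p grid size for the matrix seeding (default 2000; the seeding is
#'   only second-order accurate, polishing always follows).
#' @param R inner radius carried into the returned metadata.
#' @param tol polishing tolerance, see [polish_zero()].
#' @return a `mode_table`: data frame with columns `n`, `lambda` (complex),
#'   `residual`, `source`, and attributes `dim`, `nu`, `gamma`, `p`,
#'   `excluded`.
#' @export
find_zeros <- function(dim, nu, gamma, n_max, p = 2000, R = 1, tol = 1e-12) {
  dim <- match_dim(dim)
  if (n_max < 1) stop("n_max must be >= 1")
  geometry <- shell_geometry(R = 1, gamma = gamma)
  spacing <- pi / max(gamma - 1, 1e-6)
  real_case <- is_real_scalar(nu)
  k_ask <- min(n_max + 2L, p)
  seeds <- matrix_modes(dim, nu, geometry, p, k_ask)
  h <- (gamma - 1) / (p - 1)

  # drop the lambda = 0 constant mode: it exists only when the order term
  # nu^2 (resp. nu(nu+1)) vanishes; the discrete operator returns it as a
  # numerical zero of size O(h)
  ord0 <- if (dim == "cyl") abs(as.complex(nu))^2 else abs(as.complex(nu) * (as.complex(nu) + 1))
  excluded <- if (is.numeric(seeds)) numeric(0) else complex(0)
  if (ord0 < 1e-12) {
    first_pos <- abs(seeds)[abs(seeds) > 10 * h][1]
    tol_zero <- max(10 * h^2, 1e-6 * first_pos)
    excluded <- seeds[abs(seeds) <= tol_zero]
    seeds <- seeds[abs(seeds) > tol_zero]
  }

  if (real_case) {
    seeds <- Re(as.complex(seeds))
    src <- rep("matrix", length(seeds))
    # replace / extend with McMahon seeds where the grid cannot resolve
    ok <- seeds * h < 0.25
    n_have <- max(which(ok), 1L)
    seeds <- seeds[seq_len(min(n_have, length(seeds)))]
    src <- src[seq_along(seeds)]
    if (length(seeds) < n_max) {
      extra_n <- (length(seeds) + 1L):n_max
      extra_n <- extra_n[extra_n >= 2]
      seeds <- c(seeds, Re(approx_higher(dim, Re(as.complex(nu)), gamma, extra_n,
                                         "mcmahon")))
      src <- c(src, rep("mcmahon", length(extra_n)))
    }
    seeds <- head(seeds, n_max)
    src <- head(src, n_max)
    pol <- lapply(seq_along(seeds), function(i)
      polish_zero(dim, nu, gamma, seeds[i], spacing = spacing, tol = tol))
    lam <- vapply(pol, function(x) Re(as.complex(x$lam)), 0)
    res <- vapply(pol, function(x) x$residual, 0)
    o <- order(lam)
    lam <- lam[o]; res <- res[o]; src <- src[o]
    if (any(diff(lam) < 1e-8)) stop("find_zeros: duplicate roots (seeds collapsed)")
    # missed-root check against the asymptotic spacing, with scan recovery
    repeat {
      gaps <- diff(lam)
      hole <- which(gaps > 1.6 * spacing)
      hole <- hole[gaps[hole] > 0]
      if (length(hole) == 0) break
      i <- hole[1]
      found <- scan_sign_changes(dim, nu, gamma, lam[i] + 1e-6, lam[i + 1] - 1e-6,
                                 step = spacing / 80)
      if (length(found) == 0) break   # genuine wide gap (e.g. after exceptional zero)
      newpol <- lapply(found, function(s)
        polish_zero(dim, nu, gamma, s, spacing = spacing, tol = tol))
      lam <- c(lam, vapply(newpol, function(x) Re(as.complex(x$lam)), 0))
      res <- c(res, vapply(newpol, function(x) x$residual, 0))
      src <- c(src, rep("scan", length(newpol)))
      o <- order(lam)
      lam <- lam[o]; res <- res[o]; src <- src[o]
      if (any(diff(lam) < 1e-8)) stop("find_zeros: duplicate roots after gap recovery")
      lam <- head(lam, n_max); res <- head(res, n_max); src <- head(src, n_max)
    }
    lam <- as.complex(head(lam, n_max))
    res <- head(res, n_max); src <- head(src, n_max)
  } else {
    seeds <- head(seeds, n_max)
    pol <- lapply(seeds, function(s)
      polish_zero(dim, nu, gamma, s, spacing = spacing, tol = tol))
    lam <- vapply(pol, function(x) as.complex(x$lam), complex(1))
    res <- vapply(pol, function(x) x$residual, 0)
    o <- order(Re(lam), Im(lam))
    lam <- lam[o]; res <- res[o]
    if (any(abs(diff(lam)) < 1e-8)) stop("find_zeros: duplicate roots (seeds collapsed)")
    src <- rep("matrix", length(lam))
  }
  if (length(lam) < n_max) {
    stop("find_zeros: could not locate the requested number of zeros")
  }
  structure(
    data.frame(n = seq_along(lam), lambda = lam, residual = res,
               source = factor(src, levels = c("matrix", "mcmahon", "scan"))),
    dimension = dim, nu = nu, gamma = gamma, p = p, R = R, tol = tol,
    excluded = excluded,
    class = c("mode_table", "data.frame"))
}

# dense sign scan: bracket sign changes of the (real) cross product
scan_sign_changes <- function(dim, nu, gamma, lo, hi, step) {
  if (hi <= lo) return(numeric(0))
  xs <- seq(lo, hi, by = step)
  if (length(xs) < 2) return(numeric(0))
  fs <- bessel_cross(dim, Re(as.complex(nu)), gamma, xs)
  i <- which(fs[-1] * fs[-length(fs)] < 0)
  (xs[i] + xs[i + 1]) / 2
}

#' @export
print.mode_table <- function(x, ...) {
  cat(sprintf("Neumann cross-product zeros: dim=%s, nu=%s, gamma=%g (%d modes, p=%d)\n",
              attr(x, "dimension"), format(attr(x, "nu")), attr(x, "gamma"),
              nrow(x), attr(x, "p")))
  ex <- attr(x, "excluded")
  if (length(ex)) {
    cat(sprintf("excluded constant mode(s): %s\n",
                paste(format(ex, digits = 3), collapse = ", ")))
  }
  print.data.frame(x, ...)
  invisible(x)
}
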