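# Independent oracles used across the suite.

# dense sign-scan + bisection root finder for the (real) cross product:
# deliberately ignorant of the matrix seeding / polishing pipeline
scan_zeros_oracle <- function(dim, nu, gamma, lo = 1e-3, hi = 12, step = 1e-4,
                              n_max = Inf) {
  xs <- seq(lo, hi, by = step)
  fs <- bessel_cross(dim, nu, gamma, xs)
  i <- which(fs[-1] * fs[-length(fs)] < 0)
  roots <- vapply(i, function(j) {
    uniroot(function(l) bessel_cross(dim, nu, gamma, l),
            c(xs[j], xs[j + 1]), tol = 1e-15)$root
  }, 0)
  head(roots, n_max)
}

# quadrature of a real integrand at oracle precision
quad_oracle <- function(f, lower, upper) {
  r <- integrate(f, lower, upper, rel.tol = 1e-12, abs.tol = 1e-14,
                 subdivisions = 500L, stop.on.error = FALSE)
  if (!(r$message %in% "OK") && !grepl("roundoff", r$message)) {
    stop("quad_oracle: ", r$message)
  }
  r$value
}

# Monte Carlo frequency autocorrelation for the annulus (nondimensional:
# R = 1, D = 1): reflected Brownian motion with Gaussian steps of width
# sigma = step_frac * (gamma - 1) and radial specular reflection at both
# shells; returns K/delta_omega^2 estimates with standard errors.
mc_correlation_cyl <- function(gamma, taus, n_walk = 1e5, seed = 1,
                               step_frac = 0.01) {
  set.seed(seed)
  sigma <- step_frac * (gamma - 1)
  dtau <- sigma^2 / 2            # per-coordinate variance 2*D*dt = sigma^2
  n_step <- ceiling(max(taus) / dtau)
  steps_at <- pmax(1L, round(taus / dtau))
  # area-uniform initial positions
  r <- sqrt(1 + runif(n_walk) * (gamma^2 - 1))
  phi <- runif(n_walk, 0, 2 * pi)
  x <- r * cos(phi); y <- r * sin(phi)
  fdip <- function(x, y) {
    r2 <- x^2 + y^2
    (x^2 - y^2) / r2^2           # cos(2*phi)/r^2
  }
  f0 <- fdip(x, y)
  est <- se <- numeric(length(taus))
  for (s in seq_len(n_step)) {
    x <- x + rnorm(n_walk, sd = sigma)
    y <- y + rnorm(n_walk, sd = sigma)
    rr <- sqrt(x^2 + y^2)
    for (k in 1:3) {             # resolve multiple reflections
      out_lo <- rr < 1
      out_hi <- rr > gamma
      if (!any(out_lo | out_hi)) break
      fac <- rep(1, n_walk)
      fac[out_lo] <- (2 - rr[out_lo]) / rr[out_lo]
      fac[out_hi] <- (2 * gamma - rr[out_hi]) / rr[out_hi]
      x <- x * fac; y <- y * fac
      rr <- sqrt(x^2 + y^2)
    }
    hit <- which(steps_at == s)
    for (j in hit) {
      prod <- f0 * fdip(x, y)
      est[j] <- mean(prod)
      se[j] <- sd(prod) / sqrt(n_walk)
    }
  }
  data.frame(tau = steps_at * dtau, K_rel = est, se = se)
}

first_polished_zero <- function(dim, nu, gamma, p = 800) {
  Re(find_zeros(dim, nu, gamma, 1, p = p)$lambda[1])
}
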