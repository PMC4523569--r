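---
title: "Neumann modes of the radial Laplacian on shells: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neumann modes of the radial Laplacian on shells: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellmodes)
```

## The eigenvalue problem

The package solves the radial Bessel eigenproblem on a shell
$R \le r \le \gamma R$ with reflecting (Neumann) walls,

$$\Big[\frac{\nu^2}{r^2} - \Delta_r\Big]\,\Phi_{n,\nu}(r)
  = \frac{\lambda_{n,\nu}^2}{R^2}\,\Phi_{n,\nu}(r),
  \qquad \Delta_r = \partial_{rr} + \tfrac{1}{r}\partial_r,$$

in two dimensions (annulus), and the analogue with $\nu(\nu+1)$ and
$\Delta_r = \partial_{rr} + \tfrac{2}{r}\partial_r$ in three dimensions
(spherical shell).  The eigenfunctions are cross combinations of Bessel
functions,
$\Phi_{n,\nu}(\rho) = Y'_\nu(\lambda)J_\nu(\lambda\rho) -
J'_\nu(\lambda)Y_\nu(\lambda\rho)$ with $\rho = r/R$, which satisfy
$\Phi'(1)=0$ by construction; the outer wall condition turns into the
secular equation
$f_\nu(\lambda) = Y'_\nu(\lambda)J'_\nu(\gamma\lambda) -
J'_\nu(\lambda)Y'_\nu(\gamma\lambda) = 0$, whose positive roots
$\lambda_{n,\nu}$ are the eigenvalues (`bessel_cross()`, `find_zeros()`).
Abel's identity pins the inner boundary values to $2/(\pi\lambda)$
(annulus) and $1/\lambda^2$ (shell), which the package uses both as a
cheap evaluation of boundary data (`boundary_value_outer()`) and as a
self-test.

Indexing follows the convention in which $n = 1$ labels the *exceptional
zero*: the root that tends to $\nu$ (annulus) or $\sqrt{\nu(\nu+1)}$
(shell) as $\gamma \to 1$, while all higher roots scale like
$\pi(n-1)/(\gamma-1)$.  This is deliberately *not* the Abramowitz–Stegun
labeling, which shifts the index by one.  For $\nu = 0$ the operator also
has the constant mode $\lambda = 0$; `find_zeros()` excludes it and
reports it in the `excluded` attribute.

## Root location: discretize, then polish

Generic 1-D root searches on $f_\nu$ miss or duplicate roots when started
poorly, and fail outright for complex order.  The package instead
discretizes the radial operator on a uniform grid
$r_j = R + (j-1)h$, $h = R(\gamma-1)/(p-1)$, as a conservative
tridiagonal matrix whose half-index radii enter linearly (2-D) or squared
(3-D) and whose first/last rows carry a factor-2 Neumann closure
(`build_discrete_laplacian()`); every row sums to zero, so constants are
annihilated exactly.  The matrix eigenvalues (`matrix_modes()`) are
globally complete — no root can be missed below the grid resolution — but
only $O(h^2)$ accurate (the suite verifies a fitted convergence order of
$2.0$), so each seed is then *polished* on the analytic cross product
(`polish_zero()`).

Numerical choices, all made once:

* default $p = 2000$ for seeding; the error of the first eigenvalue at
  $\gamma = 5$ is then a few parts in $10^8$, far inside the polishing
  basin;
* for real order the tridiagonal matrix is diagonally similar to a
  symmetric one, so a symmetric solver is used; for complex order a dense
  complex eigendecomposition is taken and roots are ordered
  lexicographically by (Re, Im) — the enumeration of genuinely complex
  roots is a package convention, since no canonical order exists;
* real-order polishing brackets the root (sign-preserving Brent), which
  cannot jump to a neighbour; complex-order polishing is a plain secant
  iteration with a guard rejecting moves larger than half the local root
  spacing $\pi/(\gamma-1)$;
* a polished residual is accepted either below
  $10^{-12}\max(1,|f(\mathrm{seed})|)$ or at the machine floor
  $\sim\varepsilon\,|\lambda|\,|f'(\lambda)|$ that rounding of $\lambda$
  alone implies (relevant for steep high-order roots);
* seeds for modes beyond the resolution of the grid
  ($\lambda h > 0.25$) are taken from McMahon's expansion instead of the
  matrix, and a spacing check against $\pi/(\gamma-1)$ triggers a dense
  sign-scan recovery if a hole remains;
* near $\lambda = 0$ the spherical cross product behaves like
  $\lambda^{-3}$, so residuals there are measured on
  $\lambda^3 g_\nu(\lambda)$.

The closed-form first-zero approximations (small-$\lambda$ expansion,
small-$\nu$ Taylor form, Gottlieb, Grebenkov, Buchholz) and the McMahon /
Buchholz forms for $n \ge 2$ are exposed verbatim in `approx_first()` and
`approx_higher()`.  They are thin-shell expansions; no validity window in
$\gamma$ is enforced, and the 2-D small-$\lambda$ form has a genuine pole
at $\nu = \pm 1$.

## Bessel functions at complex order

Standard double-precision libraries do not accept complex order.  The
package evaluates $J_\nu(z)$ for complex $\nu$ by Miller's backward
recurrence, normalized with the Neumann-series identity
$(z/2)^\nu = \sum_k (\nu+2k)\,\Gamma(\nu+k)/k!\; J_{\nu+2k}(z)$
(complex $\Gamma$ from **pracma**).  That normalization is
well-conditioned for $\mathrm{Re}\,\nu \ge 0$ but catastrophically
cancelled at mirrored orders, where $(z/2)^{-|\nu|}$ is exponentially
small against the summands; the mirrored sequence is therefore scaled
through the Wronskian
$J_\mu J'_{-\mu} - J'_\mu J_{-\mu} = -2\sin(\mu\pi)/(\pi z)$ against the
well-conditioned positive-order values, and $Y_\nu$ follows from the
connection formula.  The route reaches $\sim 10^{-13}$ relative accuracy
over the whole in-scope $(\nu, z)$ range — verified against the base
routines at real order and against the Wronskian at complex order — which
out-precises every tolerance in the package, so no arbitrary-precision
fallback is carried.  The connection formula degenerates at (near-)
integer complex order ($|\sin \pi\nu| \to 0$); such orders are rejected
rather than approximated.  Derivatives always use the exact three-term
relation $J'_\nu = (J_{\nu-1}-J_{\nu+1})/2$, never finite differences, so
all Wronskian identities hold to machine precision.

Negative real arguments (needed only for symmetry checks) follow the
principal-branch continuation
$J_\nu(ze^{i\pi}) = e^{i\pi\nu}J_\nu(z)$.

## Normalization constants and Lommel integrals

At a polished zero the closed forms

$$N_{n,\nu} = \frac{2}{\pi^2\lambda^2}
  \Big[1-\frac{\nu^2}{\gamma^2\lambda^2}\Big]
  \Big[\frac{J'_\nu(\lambda)}{J'_\nu(\gamma\lambda)}\Big]^2
  - \frac{2}{\pi^2\lambda^2}\Big[1-\frac{\nu^2}{\lambda^2}\Big]$$

(and the 3-D analogue) give $R^{-2}\int r\,\Phi^2\,dr$ without quadrature
(`normalization()`), and the power moments
$R^{-(\alpha+1)}\int r^\alpha \Phi\,dr$ come from boundary terms involving
Lommel functions $S_{\kappa,\nu}$ (`lommel_integral()`).  All integrals
are formed in $\rho = r/R$; the inner radius only re-enters at I/O.
Quadrature appears solely as a *verification oracle*
(`orthogonality_gram()`, the test suite) with tolerances
$10^{-12}$/$10^{-10}$ — tighter than every claim it checks.  Lommel
derivatives are never taken numerically: averaging the two first-order
index recurrences eliminates the $\nu/z$ term and expresses
$S'_{\kappa,\nu}$ through $S_{\kappa-1,\nu\mp1}$.

`lommel_S()` selects its route automatically: the
${}_1F_2$ series (truncated at $10^{-16}$ relative, 500 terms, with a
range warning beyond $|z| \approx 40$ — no asymptotic expansion is
carried since all in-scope arguments are moderate) whenever the
$\Gamma$ factors and lower series parameters are pole-free; otherwise a
registered closed form (Neumann polynomials for $S_{1,2m}$ and
$S_{0,2m+1}$, Schläfli polynomials for $S_{-1,2m}$, the Gegenbauer
reduction when $\kappa+\nu$ is an odd positive integer); otherwise an
upward $\kappa$-shift by the second-order recurrence, at most three
times.  Pairs with $\kappa-\nu$ an odd negative integer — the family
containing the classical exceptional case $S_{-1,0}$ — have no finite
route here: both the $\Gamma$ factor and the series parameter degenerate
simultaneously and the shift dead-ends on $(\kappa+1)^2=\nu^2$.  These
raise a named error; the logarithmic/digamma limit formulas are out of
scope.  The spherical weight-$r$ moment hits this family at odd integer
$\nu$, which is why the verification grid uses $\alpha = 0$ there.  For
complex $(\kappa,\nu)$ only the series route is allowed, since the
branch conventions of the complement term are otherwise ambiguous.

One printed form required correction: re-deriving the 2-D dipole
expansion coefficient from the Lommel integral and the normalization
constant gives a $1/\lambda^2$ prefactor in the derivative-ratio form of
$F_n^2$ (not $1/\lambda$); only with that power do the two printed routes
agree per mode (the package cross-validates them to $10^{-10}$) and do
all four sum rules come out.  A second numerical subtlety: deep evanescent
modes ($\nu \gg \lambda$) make $J'_\nu(\gamma\lambda)$ a catastrophically
cancelled difference, while at a zero the $J'$- and $Y'$-ratios are
identical; `normalization()` therefore picks whichever ratio has the
better-conditioned denominator.  Without this the propagator's
high-angular-order terms are garbage.

## The diffusion layer

For spins diffusing with coefficient $D$ in the shell around a magnetized
cylinder or sphere, the local resonance frequency is
$\omega = \delta\omega\, f$ with the dipole shapes
$f = (R/r)^2\cos 2\phi$ and $f = (R/r)^3(3\cos^2\theta - 1)$.  The
transition density is the Neumann eigenfunction expansion
(`propagator()`), with long-time limit $1/V$,
$V = \pi R^2(\gamma^2-1)$ or $\tfrac43\pi R^3(\gamma^3-1)$.  Truncation
is adaptive: radial modes are kept while
$e^{-\lambda^2 Dt/R^2}$ exceeds $10^{-12}$, angular orders until their
first zero passes that cut (with a hard cap and a small-time warning).
Projecting $f$ on the basis, only the angular order $\nu = 2$ survives,
giving the frequency autocorrelation function

$$K(t) = \delta\omega^2 \sum_n F_n^2\,
  e^{-\lambda_{n,2}^2\, Dt/R^2}$$

(`expansion_coefficients()`, `correlation_function()`), reported both in
$\delta\omega^2$ units and absolutely, with the nondimensional time
$\tau = Dt/R^2$ alongside.

The closed-form sum rules (`sum_rules()`) serve as accuracy
certificates.  Their convergence classes differ fundamentally:
$\sum F^2$, $\sum F^2/\lambda^2$ and $\sum F^2/\lambda^4$ converge like
$N^{-3}$ or faster (empirically $F^2\lambda^4 \to$ const, e.g.
$0.0863$ at $\gamma = 5$), and 500 modes reach them to $10^{-7}$ or
better.  But $\sum F^2\lambda^2$ has strictly positive terms decaying
only like $\lambda^{-2}$ — the dipole field violates the Neumann
condition at the walls, so its expansion cannot converge faster — and a
500-mode partial sum still sits $\sim 3\times10^{-3}$ (relative) below
the closed form; reaching $10^{-6}$ would need $\sim 10^6$ modes.  The
suite asserts this sum at the same tolerance as the others and the
assertion fails by design; it documents a property of the expansion, not
a defect of the code.  The truncation policy for $K(t)$ estimates the
dropped $\sum F^2$ tail from the empirical $c\lambda^{-4}$ decay and
warns when it exceeds $10^{-6}$ of $K(0)$.

A similar physical limit holds for the propagator at $\gamma = 8$: the
slowest surviving mode is $\lambda_{1,1} = 0.2229$, so at
$\tau = 100$ the series still deviates pointwise from $1/V$ by
$e^{-\lambda_{1,1}^2\tau} \approx 7\times10^{-3}$ weighted by the local
eigenfunctions (measured $\sim 1\%$); the constant itself,
$1/(\pi R^2[\gamma^2-1]) = 5.05254\times10^9\,\mathrm{m}^{-2}$ for
$R = 1\,\mu\mathrm{m}$, is exact.

## Independent validation

Beyond closed-form/quadrature cross-checks, the test suite validates
$K(t)$ against reflected Brownian motion: $10^5$ walkers with Gaussian
steps of width $0.01\,R(\gamma-1)$ (giving $\Delta\tau = 8\times10^{-4}$
at $\gamma = 5$) and radial specular reflection at both walls, seeded
deterministically; agreement is required within three standard errors at
$\tau \in \{0.05, 0.2, 1\}$.  The walker emulates ideal reflected
diffusion only — no permeable walls, surface relaxation, susceptibility
distribution or field inhomogeneity beyond the pure dipole — so passing
it supports the mathematics of the expansion, not the fidelity of the
dipole model to any particular tissue.  Mode tables are verified against
an exhaustive bisection scan of the cross product (step $10^{-4}$), and
the $\nu = 2$ spherical zeros against the independent trigonometric
secular equation.

Problem sizes in the default test run are chosen to keep the full suite
around two minutes on one core: grids up to $p = 2000$, 500-mode sum-rule
checks, $10^5$ Monte Carlo walkers, and tensor-product quadratures
(48-point Gauss–Legendre × 96 angles) for propagator mass conservation at
$10^{-6}$.

## Known limitations

* No uniform asymptotics: Bessel evaluation beyond $|z| \sim 10^4$ and
  ${}_1F_2$ beyond $|z| \approx 40$ are out of validated range.
* Near-integer complex orders (within $10^{-8}$ of an integer in the
  imaginary-free sense) are rejected by the connection formula.
* Exceptional Lommel pairs ($\kappa-\nu$ an odd negative integer) error
  instead of evaluating the digamma limit.
* The bracketed closed form of the third spherical sum rule is verified
  only against the numerically summed series (to $10^{-6}$); no second
  independent derivation is carried.
* Mixed (Robin) boundary conditions and Dirichlet cross products are not
  implemented.
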