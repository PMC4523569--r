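Package: shellmodes
Title: Neumann Eigenmodes of the Radial Laplacian on Annuli and
    Spherical Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-product zeros of (spherical) Bessel function derivatives,
    which are the Neumann eigenvalues of the radial Laplace operator on an
    annulus or spherical shell R <= r <= gamma*R, for real and complex Bessel
    order.  Provides the radial eigenfunctions, closed-form normalization
    constants and Lommel integrals (via Lommel functions S_{kappa,nu}
    evaluated through a 1F2 hypergeometric series, recurrences and classical
    polynomial special cases), a tridiagonal finite-difference discretization
    of the radial Laplacian for robust eigenvalue seeding, root polishing,
    and the printed literature approximations (McMahon, Buchholz, Gottlieb,
    Grebenkov).  On top of the eigenbasis it implements the diffusion
    propagator in the shell and the frequency autocorrelation function K(t)
    of spins dephasing around magnetized cylinders (capillaries) and spheres
    (alveoli), with dipole-field expansion coefficients and closed-form sum
    rules as accuracy certificates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
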