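# Table serialization, run metadata and regression fixtures.  The CSV
# dialect is fixed: comma separator, '.' decimal, header row, complex
# numbers as paired re_/im_ columns.

#' Parse a complex number written as "a+bi"
#'
#' Accepts plain reals (`"2"`, `"-0.5"`), pure imaginary (`"1i"`) and
#' `"a+bi"` / `"a-bi"` forms.
#'
#' @param x character scalar.
#' @export
parse_complex <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  if (!grepl("^[0-9eE.+i-]+$", x)) stop("parse_complex: malformed complex literal: ", x)
  val <- tryCatch(eval(parse(text = x)[[1]], envir = baseenv()),
                  error = function(e) stop("parse_complex: cannot parse: ", x))
  if (!is.numeric(val) && !is.complex(val)) stop("parse_complex: not a number: ", x)
  if (is.numeric(val)) val else val
}

format_complex <- function(z) {
  sprintf("%.15g%+.15gi", Re(z), Im(z))
}

#' Write a mode table to CSV with JSON metadata
#'
#' Columns `n, re_lambda, im_lambda, residual, source`; a sidecar
#' `<path>.meta.json` records everything needed to reproduce the run
#' (dimension, order, gamma, grid size, tolerances, excluded modes).
#'
#' @param modes a `mode_table` from [find_zeros()].
#' @param path output CSV path.
#' @export
write_mode_table <- function(modes, path) {
  df <- data.frame(n = modes$n,
                   re_lambda = Re(modes$lambda),
                   im_lambda = Im(modes$lambda),
                   residual = modes$residual,
                   source = as.character(modes$source))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(dim = attr(modes, "dimension"),
               nu = format_complex(as.complex(attr(modes, "nu"))),
               gamma = attr(modes, "gamma"),
               p = attr(modes, "p"),
               R = attr(modes, "R"),
               tol = attr(modes, "tol"),
               n_max = nrow(modes),
               excluded = Re(as.complex(attr(modes, "excluded"))),
               package_version = as.character(utils::packageVersion("shellmodes")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(df)
}

#' Compute and export cross-product zeros
#'
#' Thin driver over [find_zeros()] + [write_mode_table()], used by the
#' command-line front end `inst/cli/shellmodes.R`.
#'
#' @inheritParams find_zeros
#' @param n number of zeros.
#' @param out output CSV path.
#' @export
run_zeros <- function(dim, nu, gamma, n, p = 2000, out, tol = 1e-12) {
  modes <- find_zeros(dim, nu, gamma, n, p = p, tol = tol)
  write_mode_table(modes, out)
  message(sprintf("wrote %d zeros (max residual %.3e, p = %d) to %s",
                  nrow(modes), max(modes$residual), p, out))
  invisible(modes)
}

#' Compute and export a correlation curve with its sum-rule report
#'
#' Writes `(t, tau, K_rel, K)` rows to `out` and a JSON report
#' (`<out>.report.json`) comparing the truncated mode sums against their
#' closed-form sum rules.
#'
#' @inheritParams find_zeros
#' @param times time grid (same unit as `D`); must be non-empty.
#' @param D diffusion coefficient (length^2/time).
#' @param R inner radius.
#' @param delta_omega dipole field strength (rad/time).
#' @param n_max number of modes in the expansion.
#' @param out output CSV path.
#' @export
run_correlation <- function(dim, gamma, times, D = 1, R = 1, delta_omega = 1,
                            n_max = 200, p = 2000, out) {
  if (length(times) == 0) stop("run_correlation: the time grid is empty")
  spec <- diffusion_spec(dim, shell_geometry(R = R, gamma = gamma), D = D,
                         delta_omega = delta_omega)
  expn <- expansion_coefficients(dim, gamma, n_max, p = p)
  curve <- correlation_function(spec, expn, times)
  write.csv(curve, out, row.names = FALSE, quote = FALSE)
  rules <- sum_rules(dim, gamma)
  partial <- c(sum(expn$F2), sum(expn$F2 * expn$lambda^2),
               sum(expn$F2 / expn$lambda^2))
  if (dim == "cyl") partial <- c(partial, sum(expn$F2 / expn$lambda^4))
  report <- list(dim = dim, gamma = gamma, n_max = n_max,
                 rules = data.frame(rule = rules$rule,
                                    partial_sum = partial[seq_len(nrow(rules))],
                                    closed_form = rules$value))
  jsonlite::write_json(report, paste0(out, ".report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  message(sprintf("wrote K(t) with %d modes to %s; sum-rule report in %s",
                  n_max, out, paste0(out, ".report.json")))
  invisible(curve)
}

#' Deterministic regression fixtures
#'
#' Writes small reference artifacts (mode tables for both geometries, a
#' Gram matrix, a K(t) curve) plus a manifest with versions, tolerances
#' and the seed.  Outputs are deterministic: the same seed produces
#' byte-identical files.
#'
#' @param seed integer recorded in the manifest (the quantities themselves
#'   are deterministic; the seed fixes any future stochastic additions).
#' @param dir output directory, created if needed.
#' @export
make_fixtures <- function(seed, dir) {
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fz_cyl <- find_zeros("cyl", 2, 5, 6, p = 600)
  fz_sph <- find_zeros("sph", 2, 5, 6, p = 600)
  write_mode_table(fz_cyl, file.path(dir, "zeros_cyl_nu2_gamma5.csv"))
  write_mode_table(fz_sph, file.path(dir, "zeros_sph_nu2_gamma5.csv"))
  G <- orthogonality_gram("cyl", 2, 5, fz_cyl[1:3, ])
  write.csv(data.frame(G), file.path(dir, "gram_cyl_nu2_gamma5.csv"),
            row.names = FALSE, quote = FALSE)
  spec <- diffusion_spec("cyl", shell_geometry(R = 1, gamma = 5), D = 1)
  expn <- expansion_coefficients("cyl", 5, 200, modes = find_zeros("cyl", 2, 5, 200, p = 600))
  curve <- correlation_function(spec, expn, times = seq(0, 1, by = 0.1))
  write.csv(curve, file.path(dir, "correlation_cyl_gamma5.csv"),
            row.names = FALSE, quote = FALSE)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("shellmodes")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   polish_tol = 1e-12,
                   files = c("zeros_cyl_nu2_gamma5.csv", "zeros_sph_nu2_gamma5.csv",
                             "gram_cyl_nu2_gamma5.csv", "correlation_cyl_gamma5.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
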