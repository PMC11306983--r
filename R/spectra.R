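#' Frequency grid validation
#'
#' THz spectra in this package live on a wavenumber grid in cm^-1.  A valid
#' grid is strictly increasing, strictly positive, finite, and has at least
#' two points.
#'
#' @param wavenumber numeric vector of wavenumbers (cm^-1).
#' @return the validated numeric vector, invisibly usable as a grid.
#' @export
frequency_grid <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2L)
    stop("a frequency grid needs at least two numeric wavenumbers", call. = FALSE)
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumbers must be finite and non-missing", call. = FALSE)
  if (any(wavenumber <= 0))
    stop("wavenumbers must be strictly positive (cm^-1)", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  as.numeric(wavenumber)
}

#' Optical-constant spectrum
#'
#' Instrument-facing representation of a THz spectrum: refractive index
#' \eqn{n(\nu)} and Napierian (natural-log) absorption coefficient
#' \eqn{\alpha(\nu)} in cm^-1 on a common wavenumber grid.
#'
#' @param wavenumber wavenumber grid, cm^-1 (strictly increasing, > 0).
#' @param n refractive index, dimensionless, > 0.
#' @param alpha absorption coefficient, cm^-1, >= 0 (natural-log base).
#' @return a data frame of class `"optical_spectrum"` with columns
#'   `wavenumber`, `n`, `alpha`.
#' @seealso [dielectric_spectrum()], [permittivity_from_optical()]
#' @export
optical_spectrum <- function(wavenumber, n, alpha) {
  wavenumber <- frequency_grid(wavenumber)
  if (length(n) != length(wavenumber) || length(alpha) != length(wavenumber))
    stop("n and alpha must have the same length as the wavenumber grid",
         call. = FALSE)
  if (any(!is.finite(n)) || any(!is.finite(alpha)))
    stop("n and alpha must be finite", call. = FALSE)
  if (any(n <= 0))
    stop("refractive index must be strictly positive", call. = FALSE)
  if (any(alpha < 0))
    stop("absorption coefficient must be non-negative", call. = FALSE)
  structure(
    data.frame(wavenumber = wavenumber, n = as.numeric(n),
               alpha = as.numeric(alpha)),
    class = c("optical_spectrum", "data.frame"))
}

#' Complex dielectric permittivity spectrum
#'
#' The universal currency of the package: per-frequency real and imaginary
#' permittivity on a wavenumber grid.  The complex value is assembled as
#' \eqn{\epsilon^* = \epsilon' + i\epsilon''} under the \eqn{e^{-i\omega t}}
#' time convention, so a passive medium has \eqn{\epsilon'' \ge 0}.
#'
#' @param wavenumber wavenumber grid, cm^-1.
#' @param eps_re real part \eqn{\epsilon'}.
#' @param eps_im imaginary part \eqn{\epsilon''} (dielectric loss).
#' @param check_passive require `eps_im >= 0` (default `TRUE`).  Extraction
#'   from noisy data can produce small negative excursions; those are carried
#'   with `check_passive = FALSE` and flagged downstream, never silently
#'   clamped.  With `check_passive = FALSE`, `NA` values are also admitted
#'   to mark frequencies where a per-frequency solve failed.
#' @return a data frame of class `"dielectric_spectrum"` with columns
#'   `wavenumber`, `eps_re`, `eps_im`.
#' @export
dielectric_spectrum <- function(wavenumber, eps_re, eps_im,
                                check_passive = TRUE) {
  wavenumber <- frequency_grid(wavenumber)
  if (length(eps_re) != length(wavenumber) ||
      length(eps_im) != length(wavenumber))
    stop("eps_re and eps_im must have the same length as the grid",
         call. = FALSE)
  if (check_passive) {
    if (any(!is.finite(eps_re)) || any(!is.finite(eps_im)))
      stop("permittivity values must be finite", call. = FALSE)
    if (any(eps_im < 0))
      stop("eps_im < 0 is off the passive branch; use check_passive = FALSE ",
           "to carry flagged negative-loss values", call. = FALSE)
  } else {
    if (any(is.infinite(eps_re)) || any(is.infinite(eps_im)))
      stop("permittivity values must be finite or NA", call. = FALSE)
  }
  structure(
    data.frame(wavenumber = wavenumber, eps_re = as.numeric(eps_re),
               eps_im = as.numeric(eps_im)),
    class = c("dielectric_spectrum", "data.frame"))
}

#' Complex permittivity vector of a dielectric spectrum
#'
#' @param spec a [dielectric_spectrum()].
#' @return complex vector `eps_re + 1i * eps_im`.
#' @export
eps_complex <- function(spec) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  complex(real = spec$eps_re, imaginary = spec$eps_im)
}

#' @export
print.optical_spectrum <- function(x, ...) {
  cat(sprintf("<optical_spectrum> %d frequencies, %.6g-%.6g cm^-1\n",
              nrow(x), min(x$wavenumber), max(x$wavenumber)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("<dielectric_spectrum> %d frequencies, %.6g-%.6g cm^-1\n",
              nrow(x), min(x$wavenumber), max(x$wavenumber)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Absorption coefficient from a transmission spectrum
#'
#' Beer-Lambert in natural-log form: \eqn{\alpha(\nu) = -\ln(Tr(\nu))/d},
#' with the layer thickness `d` in cm so that alpha comes out in cm^-1.
#'
#' @param tr per-frequency transmittance, in (0, 1].
#' @param thickness_cm layer thickness in cm, > 0.
#' @return numeric vector of absorption coefficients (cm^-1).
#' @examples
#' absorption_from_transmission(exp(-1), 1)        # 1 cm^-1 by definition
#' absorption_from_transmission(0.5, 50.48e-4)     # ~137.3 cm^-1
#' @export
absorption_from_transmission <- function(tr, thickness_cm) {
  if (!is.numeric(thickness_cm) || length(thickness_cm) != 1L ||
      !is.finite(thickness_cm) || thickness_cm <= 0)
    stop("thickness_cm must be a single positive number", call. = FALSE)
  bad <- which(!is.finite(tr) | tr <= 0 | tr > 1)
  if (length(bad))
    stop(sprintf(
      "transmittance must lie in (0, 1]; offending index %d (value %g)",
      bad[1L], tr[bad[1L]]), call. = FALSE)
  # ln(1) underflows to -0 on some platforms; keep alpha exactly 0 there
  a <- -log(tr) / thickness_cm
  a[tr == 1] <- 0
  a
}

#' Convert optical constants to complex permittivity
#'
#' Standard THz ratios with wavenumber nu and Napierian alpha both in cm^-1:
#' \deqn{\epsilon' = n^2 - \left(\frac{\alpha}{4\pi\nu}\right)^2, \qquad
#'       \epsilon'' = \frac{n\,\alpha}{2\pi\nu}.}
#'
#' @param opt an [optical_spectrum()].
#' @return a [dielectric_spectrum()] on the same grid.
#' @examples
#' opt <- optical_spectrum(c(10, 30), c(2.2, 2.2), c(100, 100))
#' permittivity_from_optical(opt)
#' @export
permittivity_from_optical <- function(opt) {
  stopifnot(inherits(opt, "optical_spectrum"))
  kappa <- opt$alpha / (4 * pi * opt$wavenumber)
  dielectric_spectrum(opt$wavenumber,
                      eps_re = opt$n^2 - kappa^2,
                      eps_im = opt$n * opt$alpha / (2 * pi * opt$wavenumber))
}

#' Convert complex permittivity to optical constants
#'
#' Exact inverse of [permittivity_from_optical()]:
#' \eqn{n = \sqrt{(|\epsilon^*| + \epsilon')/2}},
#' \eqn{\kappa = \sqrt{(|\epsilon^*| - \epsilon')/2}},
#' \eqn{\alpha = 4\pi\nu\kappa}.  Requires the passive branch
#' (\eqn{\epsilon'' \ge 0}); valid also for \eqn{\epsilon' < 0}
#' (metallic-like), where \eqn{|\epsilon^*| \ge -\epsilon'} guarantees real
#' non-negative n and kappa.
#'
#' @param diel a [dielectric_spectrum()] with `eps_im >= 0`.
#' @return an [optical_spectrum()] on the same grid.
#' @export
optical_from_permittivity <- function(diel) {
  stopifnot(inherits(diel, "dielectric_spectrum"))
  if (any(diel$eps_im < 0))
    stop("eps_im < 0: unphysical branch, cannot form optical constants",
         call. = FALSE)
  mod <- sqrt(diel$eps_re^2 + diel$eps_im^2)
  n <- sqrt(pmax(mod + diel$eps_re, 0) / 2)
  kappa <- sqrt(pmax(mod - diel$eps_re, 0) / 2)
  optical_spectrum(diel$wavenumber, n = n,
                   alpha = 4 * pi * diel$wavenumber * kappa)
}

# Canonical CSV headers for the two on-disk dialects.
.diel_cols <- c("wavenumber_cm-1", "eps_real", "eps_imag")
.opt_cols  <- c("wavenumber_cm-1", "n", "alpha_cm-1")

#' Read a THz spectrum from a delimited text file
#'
#' Comma-separated UTF-8 text with a header row; comment lines start with
#' `#`.  The dialect is inferred from the header: columns
#' `wavenumber_cm-1,eps_real,eps_imag` give a [dielectric_spectrum()];
#' `wavenumber_cm-1,n,alpha_cm-1` give an [optical_spectrum()].
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"dielectric"` or `"optical"`; a
#'   non-auto value asserts the expected dialect.
#' @return a typed spectrum with validated invariants.
#' @export
read_spectrum <- function(path, dialect = c("auto", "dielectric", "optical")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        strip.white = TRUE)
  have <- names(df)
  kind <-
    if (all(.diel_cols %in% have)) "dielectric"
    else if (all(.opt_cols %in% have)) "optical"
    else stop(sprintf(
      "unrecognized spectrum header in %s: found [%s]; expected [%s] or [%s]",
      path, paste(have, collapse = ","),
      paste(.diel_cols, collapse = ","),
      paste(.opt_cols, collapse = ",")), call. = FALSE)
  if (dialect != "auto" && dialect != kind)
    stop(sprintf("%s holds a %s spectrum, not %s", path, kind, dialect),
         call. = FALSE)
  for (cn in if (kind == "dielectric") .diel_cols else .opt_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1L]
      stop(sprintf("non-numeric value in column '%s' of %s (data row %s)",
                   cn, path, ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
  }
  if (kind == "dielectric")
    dielectric_spectrum(df[["wavenumber_cm-1"]], df[["eps_real"]],
                        df[["eps_imag"]])
  else
    optical_spectrum(df[["wavenumber_cm-1"]], df[["n"]], df[["alpha_cm-1"]])
}

#' Write a THz spectrum to CSV
#'
#' Writes the dialect matching the spectrum class (see [read_spectrum()] for
#' the two headers).
#'
#' @param spec an [optical_spectrum()] or [dielectric_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  if (inherits(spec, "dielectric_spectrum")) {
    out <- stats::setNames(as.data.frame(spec), .diel_cols)
  } else if (inherits(spec, "optical_spectrum")) {
    out <- stats::setNames(as.data.frame(spec), .opt_cols)
  } else stop("spec must be an optical_spectrum or dielectric_spectrum",
              call. = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Put spectra on a common wavenumber grid
#'
#' Restricts all spectra to the intersection of their wavenumber intervals
#' and linearly interpolates every spectrum onto the points of the first
#' spectrum that fall inside that interval.  Extrapolation is never
#' performed: spectra are smooth relaxational curves and values outside the
#' measured interval would be fabricated.
#'
#' @param ... two or more spectra ([optical_spectrum()] or
#'   [dielectric_spectrum()]), or a single list of them.
#' @return a list of spectra, all on the identical common grid.
#' @export
align_grids <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !inherits(specs[[1L]], "data.frame"))
    specs <- specs[[1L]]
  if (length(specs) < 1L) stop("no spectra supplied", call. = FALSE)
  ok <- vapply(specs, function(s)
    inherits(s, "optical_spectrum") || inherits(s, "dielectric_spectrum"),
    logical(1L))
  if (!all(ok)) stop("all inputs must be typed spectra", call. = FALSE)
  lo <- max(vapply(specs, function(s) min(s$wavenumber), numeric(1L)))
  hi <- min(vapply(specs, function(s) max(s$wavenumber), numeric(1L)))
  if (lo > hi)
    stop("spectra have no overlapping wavenumber interval", call. = FALSE)
  grid <- specs[[1L]]$wavenumber
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L)
    stop("fewer than two common wavenumbers after intersection", call. = FALSE)
  lapply(specs, function(s) {
    cols <- setdiff(names(s), "wavenumber")
    vals <- lapply(cols, function(cn)
      stats::approx(s$wavenumber, s[[cn]], xout = grid, rule = 1)$y)
    names(vals) <- cols
    if (inherits(s, "dielectric_spectrum"))
      dielectric_spectrum(grid, vals$eps_re, vals$eps_im,
                          check_passive = FALSE)
    else
      optical_spectrum(grid, vals$n, vals$alpha)
  })
}
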