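#' Lineal-energy spectrum
#'
#' Builds a frequency probability density f(y) of lineal energy y (keV/um)
#' over a micrometre-scale site.  The density is renormalised to unit
#' integral on construction; a warning is issued when the supplied values
#' were off by more than 1%.  A spectrum may be continuous (density on a
#' grid, integrated by the trapezoidal rule) or discrete (point masses,
#' e.g. a single-event "Dirac" spectrum used in closed-form checks).
#'
#' @param y Lineal-energy grid, keV/um.  Strictly increasing, finite,
#'   positive.  A length-1 or length-2 `y` is treated as discrete unless
#'   `discrete` says otherwise.
#' @param f Non-negative frequency density (continuous) or weights
#'   (discrete), same length as `y`.
#' @param label Optional free-text label carried through summaries.
#' @param discrete Logical; force discrete (point-mass) interpretation.
#' @return A tibble of class `lineal_spectrum` with columns `y` and `f`.
#' @examples
#' sp <- lineal_spectrum(c(1, 2, 3), c(0.5, 0.5, 0.5))
#' y_dose_mean(sp)
#' @export
lineal_spectrum <- function(y, f, label = NULL, discrete = length(y) < 3) {
  y <- as.numeric(y)
  f <- as.numeric(f)
  if (length(y) == 0 || length(y) != length(f)) {
    abort("`y` and `f` must be non-empty vectors of equal length.")
  }
  if (!all(is.finite(y)) || any(y <= 0)) {
    abort("lineal-energy values must be finite and positive.")
  }
  if (is.unsorted(y, strictly = TRUE)) {
    abort("`y` must be strictly increasing.")
  }
  if (!all(is.finite(f)) || any(f < 0)) {
    abort("densities must be finite and non-negative.")
  }
  total <- if (discrete) sum(f) else trapz(y, f)
  if (total <= 0) {
    abort("degenerate spectrum: density integrates to zero.")
  }
  if (abs(total - 1) > 0.01) {
    warn(sprintf("renormalising spectrum density (integral was %.4g).", total))
  }
  out <- tibble::tibble(y = y, f = f / total)
  structure(out,
    class = c("lineal_spectrum", class(out)),
    label = label, discrete = discrete, renorm = 1 / total
  )
}

#' @export
print.lineal_spectrum <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf(
    "<lineal_spectrum%s: %d %s points, y in [%g, %g] keV/um>\n",
    if (is.null(lbl)) "" else paste0(" '", lbl, "'"),
    nrow(x), if (attr(x, "discrete")) "discrete" else "grid",
    min(x$y), max(x$y)
  ))
  cat(sprintf(
    "  y_F = %.4g, y_D = %.4g, y* = %.4g keV/um\n",
    y_freq_mean(x), y_dose_mean(x), y_saturation_corrected(x)
  ))
  invisible(x)
}

# integral of g(y) against the frequency density
spec_integral <- function(spec, g) {
  if (attr(spec, "discrete")) sum(spec$f * g) else trapz(spec$y, spec$f * g)
}

#' Dose probability density d(y)
#'
#' The dose density is proportional to y f(y): events of higher lineal
#' energy deposit proportionally more dose.  Returned as a new
#' `lineal_spectrum`-shaped object normalised to unit integral.
#'
#' @param spec A [lineal_spectrum()].
#' @return A `lineal_spectrum` holding d(y) in its `f` column.
#' @export
dose_density <- function(spec) {
  stopifnot(inherits(spec, "lineal_spectrum"))
  g <- spec$y * spec$f
  norm <- if (attr(spec, "discrete")) sum(g) else trapz(spec$y, g)
  lineal_spectrum(spec$y, g / norm,
    label = paste0(attr(spec, "label") %||% "", " [dose density]"),
    discrete = attr(spec, "discrete")
  )
}

#' Frequency-mean lineal energy y_F
#' @param spec A [lineal_spectrum()].
#' @return y_F in keV/um.
#' @export
y_freq_mean <- function(spec) {
  stopifnot(inherits(spec, "lineal_spectrum"))
  spec_integral(spec, spec$y)
}

#' Dose-mean lineal energy y_D
#'
#' y_D = int y^2 f(y) dy / int y f(y) dy, the first moment of the dose
#' density d(y).  Always >= y_F.
#'
#' @param spec A [lineal_spectrum()].
#' @return y_D in keV/um.
#' @export
y_dose_mean <- function(spec) {
  stopifnot(inherits(spec, "lineal_spectrum"))
  spec_integral(spec, spec$y^2) / spec_integral(spec, spec$y)
}

#' Saturation-corrected dose-mean lineal energy y*
#'
#' Applies the overkill (saturation) correction with parameter y0:
#' y* = y0^2 int (1 - exp(-y^2/y0^2)) f(y) dy / int y f(y) dy.
#' For spectra concentrated well below y0 (low-LET photons) y* is
#' indistinguishable from y_D; for very high lineal energies the
#' correction saturates the effectiveness per unit dose.
#'
#' @param spec A [lineal_spectrum()].
#' @param geom A [domain_geometry()] (only `y0` is used) or a numeric y0.
#' @return y* in keV/um, with 0 < y* <= y_D.
#' @export
y_saturation_corrected <- function(spec, geom = domain_geometry()) {
  stopifnot(inherits(spec, "lineal_spectrum"))
  y0 <- if (is.numeric(geom)) geom else geom$y0
  if (!is.finite(y0) || y0 <= 0) abort("saturation parameter y0 must be > 0.")
  num <- y0^2 * spec_integral(spec, -expm1(-(spec$y / y0)^2))
  num / spec_integral(spec, spec$y)
}

#' Sensitive-site geometry for microdosimetric conversion
#'
#' The site ("domain") over which specific energy is scored: a sphere of
#' radius `rd` um and density `rho` g/cm^3.  `y0` is the saturation
#' parameter of the overkill correction.
#'
#' @param rd Domain radius, um (default 0.5, i.e. a 1 um diameter sphere).
#' @param rho Density, g/cm^3.
#' @param y0 Saturation parameter, keV/um.
#' @return A list of class `domain_geometry`.
#' @export
domain_geometry <- function(rd = 0.5, rho = 1.0, y0 = 150) {
  if (!is.finite(rd) || rd <= 0) abort("`rd` must be > 0.")
  if (!is.finite(rho) || rho <= 0) abort("`rho` must be > 0.")
  if (!is.finite(y0) || y0 <= 0) abort("`y0` must be > 0.")
  structure(list(rd = rd, rho = rho, y0 = y0), class = "domain_geometry")
}

#' Mix spectra by dose weight
#'
#' Combines component spectra into the spectrum of the mixed field.  The
#' weights are dose fractions, so the mixture is formed at the level of
#' the dose densities d(y) (of which y_D and y* are linear functionals)
#' and converted back to a frequency density.  Components on different
#' grids are linearly interpolated onto the union grid.
#'
#' @param specs List of [lineal_spectrum()] objects.
#' @param weights Non-negative dose weights, one per spectrum.
#' @return A `lineal_spectrum` for the mixed field.
#' @export
mix_spectra <- function(specs, weights) {
  stopifnot(is.list(specs), all(vapply(specs, inherits, TRUE, "lineal_spectrum")))
  weights <- as.numeric(weights)
  if (length(weights) != length(specs) || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be non-negative dose weights, one per spectrum, not all zero.")
  }
  weights <- weights / sum(weights)
  discrete <- vapply(specs, attr, TRUE, which = "discrete")
  if (any(discrete) && !all(discrete)) {
    abort("cannot mix discrete and continuous spectra.")
  }
  dens <- lapply(specs, dose_density)
  if (all(discrete)) {
    y_all <- sort(unique(unlist(lapply(dens, function(d) d$y))))
    d_mix <- Reduce(`+`, Map(function(d, w) {
      w * approx(d$y, d$f, xout = y_all, yleft = 0, yright = 0, ties = "ordered")$y *
        as.numeric(y_all %in% d$y)
    }, dens, weights))
  } else {
    y_all <- sort(unique(unlist(lapply(dens, function(d) d$y))))
    d_mix <- Reduce(`+`, Map(function(d, w) {
      w * approx(d$y, d$f, xout = y_all, yleft = 0, yright = 0, ties = "ordered")$y
    }, dens, weights))
  }
  # back to a frequency density: f(y) proportional to d(y) / y
  f_raw <- d_mix / y_all
  norm <- if (all(discrete)) sum(f_raw) else trapz(y_all, f_raw)
  lineal_spectrum(y_all, f_raw / norm, label = "mixture", discrete = all(discrete))
}

#' Read a lineal-energy spectrum from a text file
#'
#' Two columns (y in keV/um, frequency density), whitespace- or
#' comma-delimited; lines starting with `#` are comments.  The density is
#' renormalised on load with a warning when it is off by more than 1%.
#'
#' @param path File path.
#' @param label Optional label; defaults to the file name.
#' @return A [lineal_spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  raw <- readr::read_table(path,
    comment = "#", col_names = c("y", "f"),
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0) abort("spectrum file is empty.")
  # tolerate comma delimiters inside the two-column layout
  if (all(grepl(",", raw$y)) && all(is.na(suppressWarnings(as.numeric(raw$y))))) {
    parts <- strsplit(raw$y, ",")
    raw <- tibble::tibble(
      y = vapply(parts, `[`, "", 1),
      f = vapply(parts, `[`, "", 2)
    )
  }
  lineal_spectrum(as.numeric(raw$y), as.numeric(raw$f), label = label)
}

#' @export
autoplot.lineal_spectrum <- function(object, ...) {
  dd <- dose_density(object)
  df <- dplyr::bind_rows(
    tibble::tibble(y = object$y, density = object$f, which = "f(y)"),
    tibble::tibble(y = dd$y, density = dd$f, which = "d(y)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$density, colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "lineal energy y (keV/μm)", y = "probability density",
      colour = NULL, title = attr(object, "label")
    )
}
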