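#' Radiation-quality components of a boron-loaded neutron field
#'
#' Describes the mixed field seen by a cell during thermal-neutron
#' irradiation with a 10B carrier: a background component (neutrons plus
#' secondary photons, independent of boron) and a boron-capture component
#' whose dose rate scales linearly with the 10B concentration, because the
#' capture-reaction rate is proportional to the 10B number density at
#' fixed fluence.
#'
#' @param background_dose_rate Background dose rate, Gy/min.
#' @param background_y_star Saturation-corrected dose-mean lineal energy
#'   of the background component, keV/um.
#' @param boron_dose_rate_per_ppm Capture-product dose rate per ppm of
#'   10B, Gy/min/ppm.
#' @param boron_y_star y* of the capture-product component, keV/um.
#' @return A list of class `quality_components`.
#' @seealso [calibrate_components()], [mix_quality()]
#' @export
quality_components <- function(background_dose_rate, background_y_star,
                               boron_dose_rate_per_ppm, boron_y_star) {
  vals <- c(
    background_dose_rate = background_dose_rate,
    background_y_star = background_y_star,
    boron_dose_rate_per_ppm = boron_dose_rate_per_ppm,
    boron_y_star = boron_y_star
  )
  if (!all(is.finite(vals)) || any(vals < 0)) {
    abort("all quality-component values must be finite and non-negative.")
  }
  if (boron_dose_rate_per_ppm <= 0) {
    abort("`boron_dose_rate_per_ppm` must be > 0 for a boron component.")
  }
  structure(as.list(vals), class = "quality_components")
}

#' @export
print.quality_components <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<quality_components>\n",
      "  background: %.4g Gy/min at y* = %.4g keV/um\n",
      "  boron:      %.4g Gy/min/ppm at y* = %.4g keV/um\n"
    ),
    x$background_dose_rate, x$background_y_star,
    x$boron_dose_rate_per_ppm, x$boron_y_star
  ))
  invisible(x)
}

#' Calibrate field components from two measured operating points
#'
#' Given the neutron-only field (zero boron) and the full field at a
#' known reference concentration, solves for the per-ppm boron dose-rate
#' coefficient and the boron-component y*.  The boron y* comes from the
#' dose-weighted mixing identity
#' `mixed_y* . total_rate = bg_y* . bg_rate + boron_y* . boron_rate`.
#'
#' @param neutron_rate,neutron_y_star Neutron-only dose rate (Gy/min) and
#'   y* (keV/um).
#' @param bnct_rate,bnct_y_star Full-field dose rate and mixed y* at the
#'   reference concentration.
#' @param ppm_ref Reference 10B concentration, ppm.
#' @return A [quality_components()] object; [mix_quality()] at `ppm_ref`
#'   reproduces the calibration inputs exactly.
#' @examples
#' comp <- calibrate_components(1.0, 41.36, 3.75, 68.50, 10)
#' mix_quality(comp, c(0, 10))
#' @export
calibrate_components <- function(neutron_rate, neutron_y_star,
                                 bnct_rate, bnct_y_star, ppm_ref) {
  stopifnot(
    is_scalar_num(neutron_rate), is_scalar_num(neutron_y_star),
    is_scalar_num(bnct_rate), is_scalar_num(bnct_y_star),
    is_scalar_num(ppm_ref)
  )
  if (ppm_ref <= 0) abort("`ppm_ref` must be > 0.")
  if (bnct_rate <= neutron_rate) {
    abort("`bnct_rate` must exceed `neutron_rate`: no boron dose to calibrate.")
  }
  boron_rate <- bnct_rate - neutron_rate
  boron_y_star <- (bnct_y_star * bnct_rate - neutron_y_star * neutron_rate) / boron_rate
  if (boron_y_star < 0) {
    abort("calibration yields a negative boron-component y*; check inputs.")
  }
  quality_components(
    background_dose_rate = neutron_rate,
    background_y_star = neutron_y_star,
    boron_dose_rate_per_ppm = boron_rate / ppm_ref,
    boron_y_star = boron_y_star
  )
}

#' Mixed field at a given boron concentration
#'
#' Total dose rate is background plus the linear boron term; the mixed y*
#' is the dose-weighted average of the component y* values (y* is a
#' linear functional of the dose density, so dose-weighted mixing is
#' exact).
#'
#' @param components A [quality_components()] object.
#' @param ppm 10B concentration(s), ppm (vectorised).
#' @return A tibble with columns `ppm`, `dose_rate` (Gy/min), `y_star`
#'   (keV/um).
#' @export
mix_quality <- function(components, ppm) {
  stopifnot(inherits(components, "quality_components"))
  ppm <- as.numeric(ppm)
  if (any(!is.finite(ppm)) || any(ppm < 0)) abort("`ppm` must be non-negative.")
  boron_rate <- ppm * components$boron_dose_rate_per_ppm
  rate <- components$background_dose_rate + boron_rate
  y_star <- (components$background_y_star * components$background_dose_rate +
    components$boron_y_star * boron_rate) / rate
  tibble::tibble(ppm = ppm, dose_rate = rate, y_star = y_star)
}
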