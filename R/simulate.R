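#' Simulate a clonogenic survival dataset
#'
#' Generates survival records with the exact statistical structure the
#' fitter assumes: the observed -ln S is the model value plus independent
#' N(0, sigma^2) noise, clipped so that the surviving fraction does not
#' exceed 1.  The default design crosses doses of 1-8 Gy with dose rates
#' spanning the protraction transition for repair rates near 9 h^-1.
#'
#' @param params True [cell_params()].
#' @param doses Dose levels, Gy.
#' @param dose_rates Dose-rate levels, Gy/min.
#' @param y_star Radiation quality, keV/um (single value or one per
#'   dose-rate level).
#' @param sigma Noise SD on -ln S (> 0).
#' @param seed Integer seed (required; same seed, same dataset).
#' @param geom A [domain_geometry()].
#' @return A tibble with columns `dose`, `dose_rate`, `y_star`,
#'   `surviving_fraction`, `neg_log_sf`, `quality`.
#' @export
sim_survival_data <- function(params, doses = c(1, 2, 4, 6, 8),
                              dose_rates = c(10, 1, 0.1, 0.01),
                              y_star = 2.26, sigma = 0.15, seed,
                              geom = domain_geometry()) {
  stopifnot(inherits(params, "cell_params"))
  if (missing(seed)) abort("`seed` is required.")
  if (!is_scalar_num(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  if (length(y_star) == 1) y_star <- rep(y_star, length(dose_rates))
  stopifnot(length(y_star) == length(dose_rates))
  design <- tidyr::crossing(
    dose = doses,
    tibble::tibble(dose_rate = dose_rates, y_star = y_star)
  )
  truth <- neg_log_survival(params, design$dose, design$dose_rate,
    design$y_star, geom
  )
  obs <- withr::with_seed(seed, truth + rnorm(nrow(design), 0, sigma))
  design |>
    dplyr::mutate(
      neg_log_sf = pmax(obs, 0),
      surviving_fraction = exp(-.data$neg_log_sf),
      quality = sprintf("y*=%.4g", .data$y_star)
    )
}

#' Synthetic multi-peak lineal-energy spectrum
#'
#' A phenomenological stand-in for a simulated microdosimetric spectrum:
#' the dose density d(y) is a mixture of log-normal bumps centred near
#' 0.3 keV/um (photon/electron events), 20 keV/um (recoil protons) and
#' 200 keV/um (boron-capture ions), combined with the supplied dose
#' weights and converted to a frequency density.  Deterministic: no
#' random numbers involved.
#'
#' @param weights Length-3 non-negative dose weights
#'   (photon, proton, heavy ion), not all zero.
#' @param n_grid Number of logarithmic grid points.
#' @return A [lineal_spectrum()].
#' @export
sim_lineal_spectrum <- function(weights = c(1, 0, 0), n_grid = 400) {
  weights <- as.numeric(weights)
  if (length(weights) != 3 || any(!is.finite(weights)) || any(weights < 0) ||
    sum(weights) <= 0) {
    abort("`weights` must be 3 non-negative values, not all zero.")
  }
  weights <- weights / sum(weights)
  y <- exp(seq(log(0.01), log(2000), length.out = n_grid))
  modes <- c(0.3, 20, 200)
  sdlog <- c(0.8, 0.5, 0.35)
  d <- Reduce(`+`, Map(function(w, m, s) {
    w * dlnorm(y, meanlog = log(m), sdlog = s)
  }, weights, modes, sdlog))
  f_raw <- d / y
  lineal_spectrum(y, f_raw / trapz(y, f_raw), label = "synthetic mixture")
}

#' Synthetic boron-concentration timeline
#'
#' Rise-then-decay kinetics of a boron carrier in tumour cells after
#' injection: a saturating rise to a peak near `peak_time_min`, then
#' first-order washout at `decay_per_min`.  Sampled at 1-minute knots.
#'
#' @param peak_ppm Peak concentration, ppm.
#' @param peak_time_min Time of the peak, minutes.
#' @param decay_per_min Washout rate after the peak, 1/min (0 gives a
#'   plateau).
#' @param duration_min Timeline length, minutes.
#' @return A [boron_timeline()].
#' @export
sim_boron_timeline <- function(peak_ppm = 25, peak_time_min = 10,
                               decay_per_min = 0.005, duration_min = 160) {
  stopifnot(
    is_scalar_num(peak_ppm), peak_ppm > 0,
    is_scalar_num(peak_time_min), peak_time_min > 0,
    is_scalar_num(decay_per_min), decay_per_min >= 0,
    is_scalar_num(duration_min), duration_min > 0
  )
  t <- seq(0, duration_min, by = 1)
  rise <- -expm1(-3 * t / peak_time_min)
  wash <- exp(-decay_per_min * pmax(t - peak_time_min, 0))
  boron_timeline(t, peak_ppm * rise * wash)
}
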