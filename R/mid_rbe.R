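#' Mean inactivation dose
#'
#' The mean dose needed to inactivate a cell, obtained by treating the
#' survival curve as a complementary distribution function and
#' integrating it over dose: Dbar = int_0^Inf S(D) dD.  The curve is
#' evaluated at a fixed dose rate, so the delivery time T = D / rate
#' grows along the integrand and protraction is fully accounted for.
#' Adaptive quadrature at relative tolerance `rel_tol`, with the upper
#' limit placed where -ln S reaches 46 (S ~ 1e-20).
#'
#' @param params A [cell_params()].
#' @param y_star Radiation quality, keV/um.
#' @param dose_rate Dose rate, Gy/min; `Inf` gives the acute curve.
#' @param geom A [domain_geometry()].
#' @param rel_tol Relative quadrature tolerance.
#' @return Dbar in Gy.
#' @examples
#' mean_inactivation_dose(cell_params(0.5, 0, 10), dose_rate = Inf) # 1/0.5
#' @export
mean_inactivation_dose <- function(params, y_star = 2.26, dose_rate = 10,
                                   geom = domain_geometry(), rel_tol = 1e-8) {
  stopifnot(inherits(params, "cell_params"))
  gam <- gamma_factor(y_star, geom)
  if (params$alpha0 + gam * params$beta0 <= 0 && params$beta0 <= 0) {
    abort("non-integrable survival curve: both alpha and beta are zero.")
  }
  nls <- function(D) neg_log_survival(params, D, dose_rate, y_star, geom)
  upper <- 10
  while (nls(upper) < 46 && upper < 1e12) upper <- upper * 2
  d46 <- uniroot(function(D) nls(D) - 46, c(0, upper), tol = 1e-6)$root
  integrate(function(D) exp(-nls(D)), 0, d46,
    rel.tol = rel_tol, subdivisions = 500L
  )$value
}

#' RBE at the mean-inactivation-dose endpoint
#'
#' Relative biological effectiveness defined as the ratio of the photon
#' reference MID to the test-radiation MID, both computed with the same
#' cell-line parameters.  The reference is 60Co-quality photons
#' (y* = 2.26 keV/um) delivered at an effectively acute 10 Gy/min,
#' evaluated with the full protraction factor.
#'
#' @param params A [cell_params()].
#' @param y_star,dose_rate Test radiation quality (keV/um) and dose rate
#'   (Gy/min).
#' @param ref_y_star,ref_dose_rate Reference radiation, default 2.26
#'   keV/um at 10 Gy/min.
#' @param geom A [domain_geometry()].
#' @return RBE (dimensionless, > 0).
#' @export
rbe_at_mid <- function(params, y_star, dose_rate,
                       ref_y_star = 2.26, ref_dose_rate = 10,
                       geom = domain_geometry()) {
  ref <- mean_inactivation_dose(params, ref_y_star, ref_dose_rate, geom)
  test <- mean_inactivation_dose(params, y_star, dose_rate, geom)
  ref / test
}

#' Draw parameter sets from marginal summaries
#'
#' When only per-parameter means and SDs are available (published
#' posterior summaries rather than samples), draws are taken from
#' independent normal distributions truncated at zero.  Correlations of
#' the underlying joint posterior are necessarily lost; see the methods
#' vignette for the consequences when a marginal sits close to zero.
#'
#' @param params A [cell_params()] with SDs set.
#' @param n Number of draws.
#' @param seed Integer seed (required; draws are reproducible).
#' @return A tibble with columns `alpha0`, `beta0`, `repair_rate`.
#' @export
draw_cell_params <- function(params, n, seed) {
  stopifnot(inherits(params, "cell_params"), is_scalar_num(n), n >= 1)
  if (anyNA(c(params$alpha0_sd, params$beta0_sd, params$repair_rate_sd))) {
    abort("`params` must carry SDs to draw from.")
  }
  withr::with_seed(seed, tibble::tibble(
    alpha0 = rtruncnorm(n, params$alpha0, params$alpha0_sd),
    beta0 = rtruncnorm(n, params$beta0, params$beta0_sd),
    repair_rate = rtruncnorm(n, params$repair_rate, params$repair_rate_sd)
  ))
}

as_draws_tibble <- function(x, n_draws, seed) {
  if (inherits(x, "imk_fit")) {
    draws <- x$samples[, c("alpha0", "beta0", "repair_rate")]
    if (!is.null(n_draws) && n_draws < nrow(draws)) {
      idx <- withr::with_seed(seed, sample.int(nrow(draws), n_draws))
      draws <- draws[idx, ]
    }
    draws
  } else if (inherits(x, "cell_params")) {
    draw_cell_params(x, n_draws, seed)
  } else if (is.data.frame(x)) {
    stopifnot(all(c("alpha0", "beta0", "repair_rate") %in% names(x)))
    tibble::as_tibble(x)
  } else {
    abort("expected a cell_params, imk_fit, or data frame of parameter draws.")
  }
}

draw_rbe <- function(draws, y_star, dose_rate, ref_y_star, ref_dose_rate, geom) {
  purrr::pmap_dbl(
    draws[c("alpha0", "beta0", "repair_rate")],
    function(alpha0, beta0, repair_rate) {
      p <- cell_params(alpha0, beta0, repair_rate)
      tryCatch(
        rbe_at_mid(p, y_star, dose_rate, ref_y_star, ref_dose_rate, geom),
        error = function(e) NA_real_
      )
    }
  )
}

#' RBE as a function of dose rate, with uncertainty band
#'
#' For each dose rate on the grid, computes the per-draw RBE at the MID
#' endpoint over a set of parameter draws (posterior samples, or
#' truncated-normal draws from published summaries) and summarises the
#' mean and the 16th/84th percentiles (a 68% band).  Draws with
#' non-integrable survival curves are dropped and counted.
#'
#' @param params A [cell_params()] with SDs, an `imk_fit`, or a data
#'   frame of draws.
#' @param dose_rate_grid Test dose rates, Gy/min.
#' @param y_star Test radiation quality, keV/um.
#' @param n_draws Number of parameter draws (default 5000).
#' @param seed Integer seed for the draws.
#' @param ref_y_star,ref_dose_rate Reference radiation.
#' @param geom A [domain_geometry()].
#' @return A tibble of class `rbe_sweep` with columns `dose_rate`,
#'   `rbe_mean`, `rbe_lo`, `rbe_hi`.
#' @export
rbe_dose_rate_sweep <- function(params, dose_rate_grid, y_star = 2.26,
                                n_draws = 5000, seed = 1,
                                ref_y_star = 2.26, ref_dose_rate = 10,
                                geom = domain_geometry()) {
  draws <- as_draws_tibble(params, n_draws, seed)
  ref_mid <- purrr::pmap_dbl(
    draws[c("alpha0", "beta0", "repair_rate")],
    function(alpha0, beta0, repair_rate) {
      p <- cell_params(alpha0, beta0, repair_rate)
      tryCatch(mean_inactivation_dose(p, ref_y_star, ref_dose_rate, geom),
        error = function(e) NA_real_
      )
    }
  )
  res <- purrr::map(dose_rate_grid, function(rate) {
    test_mid <- purrr::pmap_dbl(
      draws[c("alpha0", "beta0", "repair_rate")],
      function(alpha0, beta0, repair_rate) {
        p <- cell_params(alpha0, beta0, repair_rate)
        tryCatch(mean_inactivation_dose(p, y_star, rate, geom),
          error = function(e) NA_real_
        )
      }
    )
    rbe <- ref_mid / test_mid
    ok <- is.finite(rbe)
    tibble::tibble(
      dose_rate = rate,
      rbe_mean = mean(rbe[ok]),
      rbe_lo = unname(quantile(rbe[ok], 0.16)),
      rbe_hi = unname(quantile(rbe[ok], 0.84)),
      n_dropped = sum(!ok)
    )
  })
  out <- dplyr::bind_rows(res)
  structure(out,
    class = c("rbe_sweep", class(out)),
    n_draws = nrow(draws), seed = seed,
    reference = list(y_star = ref_y_star, dose_rate = ref_dose_rate)
  )
}

#' RBE versus boron concentration
#'
#' For each concentration, the mixed field (dose rate and y*) comes from
#' [mix_quality()]; the RBE at the MID endpoint is then taken against the
#' photon reference.  With point parameters a single curve is returned;
#' with draws a 68% band is added.
#'
#' @param params A [cell_params()] (point values used unless `n_draws`
#'   is given and SDs are present), an `imk_fit`, or a draw data frame.
#' @param components A calibrated [quality_components()].
#' @param ppm_grid Concentrations, ppm.
#' @param n_draws Number of draws for the band, or `NULL` for the
#'   point-estimate curve.
#' @param seed Seed for the draws.
#' @inheritParams rbe_dose_rate_sweep
#' @return A tibble with columns `ppm`, `dose_rate`, `y_star`, `rbe`
#'   (and `rbe_lo`, `rbe_hi` when draws are used).
#' @export
rbe_vs_ppm <- function(params, components, ppm_grid, n_draws = NULL, seed = 1,
                       ref_y_star = 2.26, ref_dose_rate = 10,
                       geom = domain_geometry()) {
  mixed <- mix_quality(components, ppm_grid)
  if (is.null(n_draws) && inherits(params, "cell_params")) {
    mixed$rbe <- purrr::map2_dbl(
      mixed$y_star, mixed$dose_rate,
      ~ rbe_at_mid(params, .x, .y, ref_y_star, ref_dose_rate, geom)
    )
    return(mixed)
  }
  draws <- as_draws_tibble(params, n_draws %||% 1000, seed)
  stats_tbl <- purrr::map2(mixed$y_star, mixed$dose_rate, function(ys, rate) {
    per_draw <- draw_rbe(draws, ys, rate, ref_y_star, ref_dose_rate, geom)
    per_draw <- per_draw[is.finite(per_draw)]
    tibble::tibble(
      rbe = mean(per_draw),
      rbe_lo = unname(quantile(per_draw, 0.16)),
      rbe_hi = unname(quantile(per_draw, 0.84))
    )
  })
  dplyr::bind_cols(mixed, dplyr::bind_rows(stats_tbl))
}

#' @export
autoplot.rbe_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dose_rate, .data$rbe_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$rbe_lo, ymax = .data$rbe_hi),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "dose rate (Gy/min)", y = "RBE at mean inactivation dose",
      title = sprintf("%d parameter draws, 68%% band", attr(object, "n_draws"))
    )
}
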