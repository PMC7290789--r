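#' Conversion constant from lineal energy to specific energy
#'
#' 1 keV = 1.602e-16 J; dividing by the mass of the spherical site in
#' water (rho * pi * rd^2 per unit chord, with rd in um and rho in
#' g/cm^3) gives specific energy in Gy as `0.1602 * y / (rho * pi * rd^2)`.
#'
#' @format A length-1 numeric, 0.1602.
#' @export
KEV_UM_TO_GY <- 0.1602

#' Single-event dose-mean specific energy (quality factor gamma*)
#'
#' Converts a saturation-corrected dose-mean lineal energy y* into the
#' dose-mean specific energy per event in the sensitive site,
#' gamma* = 0.1602 y* / (rho pi rd^2) in Gy.  gamma* multiplies `beta0`
#' in the linear term of the survival model and is how radiation quality
#' enters the model.
#'
#' @param y_star y* in keV/um (vectorised, >= 0).
#' @param geom A [domain_geometry()].
#' @return gamma* in Gy.
#' @examples
#' gamma_factor(2.26) # 60Co gamma-rays, ~0.461 Gy
#' @export
gamma_factor <- function(y_star, geom = domain_geometry()) {
  stopifnot(inherits(geom, "domain_geometry"))
  y_star <- as.numeric(y_star)
  if (any(!is.finite(y_star)) || any(y_star < 0)) abort("`y_star` must be >= 0.")
  KEV_UM_TO_GY * y_star / (geom$rho * pi * geom$rd^2)
}

#' Dose-protraction factor q(T)
#'
#' The Lea-Catcheside-type factor that scales the quadratic coefficient
#' for a delivery time T at constant dose rate:
#' q(T) = 2 ((a+c) T + exp(-(a+c) T) - 1) / ((a+c) T)^2.
#' q -> 1 for acute exposure and -> 0 as the delivery becomes long
#' compared with the sub-lethal damage repair time 1/(a+c).  For
#' (a+c) T < 1e-4 a series expansion is used to avoid cancellation.
#'
#' @param T_h Delivery time, hours (vectorised, >= 0).
#' @param repair_rate Combined repair rate (a+c), h^-1.
#' @return q in (0, 1]; q(0) = 1 by the analytic limit.
#' @export
protraction_factor <- function(T_h, repair_rate) {
  stopifnot(is_scalar_num(repair_rate), repair_rate > 0)
  T_h <- as.numeric(T_h)
  if (any(!is.finite(T_h) & !is.infinite(T_h)) || any(T_h < 0)) {
    abort("`T_h` must be >= 0.")
  }
  x <- repair_rate * T_h
  q <- ifelse(x < 1e-4,
    1 - x / 3 + x^2 / 12,
    2 * (x + exp(-x) - 1) / x^2
  )
  ifelse(is.infinite(T_h), 0, q)
}

#' Negative log survival at constant dose rate and quality
#'
#' Closed form of the time-sectioned survival model in the limit of
#' infinitely fine time sectioning:
#' -ln S = (alpha0 + gamma* beta0) D + beta0 q(D / rate) D^2,
#' i.e. a linear-quadratic response whose quadratic coefficient is
#' reduced by the protraction factor over the delivery time T = D / rate.
#'
#' @param params A [cell_params()].
#' @param dose Absorbed dose(s), Gy.
#' @param dose_rate Dose rate, Gy/min; `Inf` gives the acute limit.
#' @param y_star Radiation quality as y*, keV/um (default 2.26, 60Co
#'   gamma-rays).
#' @param geom A [domain_geometry()].
#' @return -ln S, same length as `dose`.
#' @export
neg_log_survival <- function(params, dose, dose_rate, y_star = 2.26,
                             geom = domain_geometry()) {
  stopifnot(inherits(params, "cell_params"))
  dose <- as.numeric(dose)
  if (any(!is.finite(dose)) || any(dose < 0)) abort("`dose` must be >= 0.")
  if (any(dose_rate <= 0) || any(is.na(dose_rate))) {
    abort("`dose_rate` must be > 0 (delivery time undefined otherwise).")
  }
  gam <- gamma_factor(y_star, geom)
  T_h <- dose / gy_min_to_gy_h(dose_rate) # Inf rate => T = 0, q = 1
  q <- protraction_factor(T_h, params$repair_rate)
  (params$alpha0 + gam * params$beta0) * dose + params$beta0 * q * dose^2
}

#' Surviving fraction
#'
#' `S = exp(-(-ln S))`; the mean number of lethal lesions per nucleus is
#' Poisson-distributed, so survival is the probability of zero lesions.
#'
#' @inheritParams neg_log_survival
#' @param schedule Alternatively, an [irradiation_schedule()]; when given,
#'   `dose`/`dose_rate`/`y_star` are ignored.
#' @return S in (0, 1].
#' @export
survival_fraction <- function(params, dose = NULL, dose_rate = NULL,
                              y_star = 2.26, geom = domain_geometry(),
                              schedule = NULL) {
  nls <- if (!is.null(schedule)) {
    neg_log_survival_schedule(params, schedule)
  } else {
    neg_log_survival(params, dose, dose_rate, y_star, geom)
  }
  exp(-nls)
}

#' Piecewise-constant irradiation schedule
#'
#' A delivery split into N equal sub-intervals of length `dt_min`, each
#' with its own absorbed dose rate and radiation quality.  This is the
#' input of the time-sectioned survival sum and is how time-varying
#' boron concentrations enter the model.
#'
#' @param dose_rate Per-interval dose rates, Gy/min (length N, >= 0).
#' @param y_star Per-interval y*, keV/um (length N or 1).
#' @param dt_min Sub-interval length, minutes (> 0).
#' @param geom A [domain_geometry()] used to convert y* to gamma*.
#' @return A tibble of class `irradiation_schedule` with columns
#'   `t_start_min`, `dose_rate`, `y_star`; the total dose and `dt_min`
#'   are carried as attributes.
#' @export
irradiation_schedule <- function(dose_rate, y_star, dt_min,
                                 geom = domain_geometry()) {
  dose_rate <- as.numeric(dose_rate)
  y_star <- as.numeric(y_star)
  if (length(y_star) == 1) y_star <- rep(y_star, length(dose_rate))
  if (length(y_star) != length(dose_rate)) {
    abort("`dose_rate` and `y_star` must have equal length.")
  }
  if (!is_scalar_num(dt_min) || dt_min <= 0) abort("`dt_min` must be > 0.")
  if (any(!is.finite(dose_rate)) || any(dose_rate < 0)) {
    abort("dose rates must be finite and >= 0.")
  }
  n <- length(dose_rate)
  out <- tibble::tibble(
    t_start_min = (seq_len(n) - 1) * dt_min,
    dose_rate = dose_rate,
    y_star = y_star
  )
  structure(out,
    class = c("irradiation_schedule", class(out)),
    dt_min = dt_min, geom = geom,
    total_dose = sum(dose_rate) * dt_min
  )
}

#' @export
print.irradiation_schedule <- function(x, ...) {
  cat(sprintf(
    "<irradiation_schedule: %d x %.3g min intervals, total %.4g Gy>\n",
    nrow(x), attr(x, "dt_min"), attr(x, "total_dose")
  ))
  NextMethod()
}

#' Negative log survival for a piecewise-constant schedule
#'
#' Evaluates the time-sectioned survival sum
#' \deqn{-\ln S = \sum_n [(\alpha_0 + \gamma_n^* \beta_0) D_n + \beta_0 D_n^2]
#'   + 2 \beta_0 \sum_{n<m} e^{-(m-n)(a+c)\Delta T} D_n D_m,}
#' with per-interval doses D_n = rate_n * dt.  Radiation quality enters
#' only the linear term; the quadratic and cross terms carry `beta0`
#' alone, damped between intervals by first-order sub-lethal damage
#' repair.  The double sum is evaluated in O(N) by the running-sum
#' recursion S_m = e^{-(a+c) dt} (S_{m-1} + D_{m-1}) (a linear recursive
#' filter).
#'
#' @param params A [cell_params()].
#' @param schedule An [irradiation_schedule()].
#' @return -ln S (non-negative scalar).
#' @export
neg_log_survival_schedule <- function(params, schedule) {
  stopifnot(inherits(params, "cell_params"), inherits(schedule, "irradiation_schedule"))
  pieces <- schedule_neg_log_pieces(params, schedule)
  sum(pieces$increment)
}

# per-interval increments of -ln S; cumulative sums give the truncated-
# schedule value at every interval boundary in one O(N) pass
schedule_neg_log_pieces <- function(params, schedule) {
  dt_h <- min_to_h(attr(schedule, "dt_min"))
  d <- gy_min_to_gy_h(schedule$dose_rate) * dt_h # per-interval dose, Gy
  gam <- gamma_factor(schedule$y_star, attr(schedule, "geom"))
  n <- length(d)
  decay <- exp(-params$repair_rate * dt_h)
  # running cross sum: s_m = sum_{k<m} d_k decay^(m-k)
  s <- if (n > 1) {
    as.numeric(stats::filter(c(0, decay * d[-n]), decay, method = "recursive"))
  } else {
    0
  }
  increment <- (params$alpha0 + gam * params$beta0) * d +
    params$beta0 * d^2 + 2 * params$beta0 * d * s
  list(dose = d, increment = increment)
}
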