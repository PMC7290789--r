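#' Prior specifications
#'
#' Priors for the sampled parameters: a uniform box or a normal
#' truncated below (at zero by default, enforcing positivity).
#'
#' @param min,max Bounds of the uniform prior (finite, `min < max`).
#' @return A list of class `mk_prior`.
#' @export
prior_uniform <- function(min, max) {
  stopifnot(is_scalar_num(min), is_scalar_num(max))
  if (min >= max) abort("`min` must be < `max`.")
  structure(
    list(
      type = "uniform", min = min, max = max,
      logd = function(x) ifelse(x > min & x <= max, -log(max - min), -Inf)
    ),
    class = "mk_prior"
  )
}

#' @param mean,sd Centre and spread of the normal prior (`sd > 0`).
#' @param lower Truncation point (default 0).
#' @rdname prior_uniform
#' @export
prior_normal <- function(mean, sd, lower = 0) {
  stopifnot(is_scalar_num(mean), is_scalar_num(sd))
  if (sd <= 0) abort("`sd` must be > 0.")
  lognorm <- log1p(-pnorm(lower, mean, sd))
  structure(
    list(
      type = "normal", mean = mean, sd = sd, lower = lower,
      logd = function(x) {
        ifelse(x >= lower, dnorm(x, mean, sd, log = TRUE) - lognorm, -Inf)
      }
    ),
    class = "mk_prior"
  )
}

#' @export
print.mk_prior <- function(x, ...) {
  if (x$type == "uniform") {
    cat(sprintf("<prior: uniform(%g, %g)>\n", x$min, x$max))
  } else {
    cat(sprintf("<prior: normal(%g, %g) truncated at %g>\n", x$mean, x$sd, x$lower))
  }
  invisible(x)
}

#' Default priors for the survival-model fit
#'
#' Uniform boxes generous relative to published melanoma-scale values:
#' alpha0 in \[0, 3\] Gy^-1, beta0 in \[0, 1\] Gy^-2, repair rate (a+c)
#' in \[0, 50\] h^-1, and 1/sigma in (0, 100\].
#'
#' @return Named list of [prior_uniform()]/[prior_normal()] objects.
#' @export
default_priors <- function() {
  list(
    alpha0 = prior_uniform(0, 3),
    beta0 = prior_uniform(0, 1),
    repair_rate = prior_uniform(0, 50),
    inv_sigma = prior_uniform(0, 100)
  )
}

#' Posterior-based prior update
#'
#' Sequential Bayesian updating across datasets: the marginal posterior
#' of a parameter from one fit becomes a truncated-normal prior for the
#' next (e.g. carrying the repair rate estimated from one cell line's
#' dose-rate data over to cell lines measured only acutely).
#'
#' @param fit An `imk_fit`, or a [cell_params()] carrying SDs.
#' @param parameter One of `"alpha0"`, `"beta0"`, `"repair_rate"`.
#' @return A [prior_normal()] truncated at zero.
#' @export
update_prior_from <- function(fit, parameter = "repair_rate") {
  parameter <- match.arg(parameter, c("alpha0", "beta0", "repair_rate"))
  if (inherits(fit, "imk_fit")) {
    x <- fit$samples[[parameter]]
    m <- mean(x)
    s <- sd(x)
  } else if (inherits(fit, "cell_params")) {
    m <- fit[[parameter]]
    s <- fit[[paste0(parameter, "_sd")]]
  } else {
    abort("`fit` must be an imk_fit or a cell_params with SDs.")
  }
  if (!is.finite(s) || s <= 0) abort("source posterior has zero or missing spread.")
  prior_normal(m, s, lower = 0)
}

# Component-wise random-walk Metropolis with burn-in width adaptation.
# `log_post` takes a named list; proposal widths are adapted every 50
# sweeps during burn-in toward ~30% acceptance, then frozen so the
# retained draws form a valid Markov chain.  Uses the caller's RNG state.
mk_metropolis <- function(log_post, init, widths, n_samples, burn_in) {
  par_names <- names(init)
  theta <- init
  lp_cur <- log_post(as.list(theta))
  if (!is.finite(lp_cur)) stop("initial point has zero posterior density.")
  n_iter <- burn_in + n_samples
  samples <- matrix(NA_real_, n_iter, length(init),
    dimnames = list(NULL, par_names)
  )
  acc <- acc_window <- setNames(numeric(length(init)), par_names)
  n_window <- 0
  for (it in seq_len(n_iter)) {
    for (p in par_names) {
      cand <- theta
      cand[[p]] <- theta[[p]] + rnorm(1, 0, widths[[p]])
      lp_cand <- log_post(as.list(cand))
      if (is.finite(lp_cand) && runif(1) < exp(lp_cand - lp_cur)) {
        theta <- cand
        lp_cur <- lp_cand
        if (it > burn_in) acc[[p]] <- acc[[p]] + 1
        acc_window[[p]] <- acc_window[[p]] + 1
      }
    }
    n_window <- n_window + 1
    if (it <= burn_in && n_window == 50) {
      # nudge each width toward the 20-50% acceptance window
      widths <- widths * exp(acc_window / n_window - 0.3)
      acc_window[] <- 0
      n_window <- 0
    }
    samples[it, ] <- theta
  }
  list(
    samples = samples[(burn_in + 1):n_iter, , drop = FALSE],
    acceptance = acc / n_samples,
    widths = widths
  )
}

validate_survival_data <- function(data) {
  req <- c("dose", "dose_rate", "surviving_fraction")
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    abort(paste0("survival data lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"y_star" %in% names(data)) data$y_star <- 2.26
  if (nrow(data) < 4) abort("need at least 4 records to fit.")
  if (any(data$dose < 0)) abort("doses must be >= 0.")
  if (any(data$dose_rate <= 0)) abort("dose rates must be > 0.")
  sf <- data$surviving_fraction
  if (any(!is.finite(sf)) || any(sf <= 0) || any(sf > 1)) {
    abort("surviving fractions must lie in (0, 1].")
  }
  tibble::as_tibble(data)
}

# precompute the per-record pieces the likelihood reuses at every step
likelihood_context <- function(data, geom) {
  data <- validate_survival_data(data)
  list(
    D = data$dose,
    D2 = data$dose^2,
    gamD = gamma_factor(data$y_star, geom) * data$dose,
    T_h = data$dose / gy_min_to_gy_h(data$dose_rate),
    obs = -log(data$surviving_fraction),
    n = nrow(data)
  )
}

model_neg_log_s <- function(theta, ctx) {
  x <- theta[["repair_rate"]] * ctx$T_h
  q <- ifelse(x < 1e-4, 1 - x / 3 + x^2 / 12, 2 * (x + exp(-x) - 1) / x^2)
  theta[["alpha0"]] * ctx$D + theta[["beta0"]] * (ctx$gamD + q * ctx$D2)
}

#' Gaussian log-likelihood on -ln S
#'
#' The measurement model: the observed -ln S of each record deviates
#' from the model prediction by independent N(0, sigma^2) noise, i.e.
#' sum_i \[ -ln(sqrt(2 pi) sigma) - (lnS_mod_i - lnS_obs_i)^2 / (2 sigma^2) \].
#'
#' @param theta Named vector/list with `alpha0`, `beta0`, `repair_rate`,
#'   and either `sigma` or `inv_sigma`.
#' @param data Survival data (columns `dose` Gy, `dose_rate` Gy/min,
#'   `surviving_fraction`, optional `y_star`).
#' @param geom A [domain_geometry()].
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(theta, data, geom = domain_geometry()) {
  ctx <- likelihood_context(data, geom)
  sigma <- if (!is.null(theta[["sigma"]])) theta[["sigma"]] else 1 / theta[["inv_sigma"]]
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  sum(dnorm(ctx$obs, model_neg_log_s(theta, ctx), sigma, log = TRUE))
}

#' Fit the survival model by random-walk Metropolis
#'
#' Samples theta = (alpha0, beta0, a+c, 1/sigma) from the posterior under
#' the Gaussian likelihood on -ln S.  Parameters are updated one at a
#' time with Gaussian random-walk proposals whose widths adapt toward a
#' 20-50% acceptance rate during burn-in and are then frozen, so the
#' retained chain is a valid Metropolis sample.  The chain starts from
#' the posterior mode (found by Nelder-Mead).
#'
#' @param data Survival data (see [log_likelihood()]).
#' @param priors Named prior list as from [default_priors()]; replace
#'   entries (e.g. `repair_rate`) with [update_prior_from()] output to
#'   carry information across datasets.
#' @param n_samples Retained draws after burn-in (default 10^4).
#' @param burn_in Discarded initial sweeps (default 10^3).
#' @param seed Integer seed (required; same seed gives an identical chain).
#' @param geom A [domain_geometry()].
#' @param init Optional named start values; default posterior mode.
#' @return An object of class `imk_fit`: a list with `samples` (tibble of
#'   `alpha0`, `beta0`, `repair_rate`, `inv_sigma`, `sigma`),
#'   `acceptance`, `burn_in`, `seed`, `priors`, `data`.
#' @export
fit_imk_mcmc <- function(data, priors = default_priors(),
                         n_samples = 10000, burn_in = 1000, seed,
                         geom = domain_geometry(), init = NULL) {
  if (missing(seed)) abort("`seed` is required for a reproducible chain.")
  stopifnot(
    is_scalar_num(n_samples), n_samples >= 1,
    is_scalar_num(burn_in), burn_in >= 0
  )
  if (!setequal(names(priors), c("alpha0", "beta0", "repair_rate", "inv_sigma"))) {
    abort("`priors` must name alpha0, beta0, repair_rate and inv_sigma.")
  }
  ctx <- likelihood_context(data, geom)
  par_names <- c("alpha0", "beta0", "repair_rate", "inv_sigma")

  log_post <- function(theta) {
    lp <- sum(vapply(par_names, function(p) priors[[p]]$logd(theta[[p]]), 0))
    if (!is.finite(lp)) return(-Inf)
    sigma <- 1 / theta[["inv_sigma"]]
    mod <- model_neg_log_s(theta, ctx)
    lp + sum(dnorm(ctx$obs, mod, sigma, log = TRUE))
  }

  run <- withr::with_seed(seed, {
    theta <- c(alpha0 = 0.2, beta0 = 0.05, repair_rate = 10, inv_sigma = 5)
    if (!is.null(init)) theta[names(init)] <- unlist(init)
    mode_try <- tryCatch(
      optim(theta, function(v) -log_post(as.list(v)), method = "Nelder-Mead",
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(mode_try) && is.finite(mode_try$value)) theta <- mode_try$par
    if (!is.finite(log_post(as.list(theta)))) {
      theta <- c(alpha0 = 0.2, beta0 = 0.05, repair_rate = 10, inv_sigma = 5)
    }
    widths <- pmax(abs(theta) * 0.2, c(0.02, 0.005, 0.5, 0.3))
    mk_metropolis(log_post, theta, widths, n_samples, burn_in)
  })
  kept <- run$samples
  acc_rate <- run$acceptance
  widths <- run$widths
  if (any(acc_rate < 0.05) || any(acc_rate > 0.8)) {
    warn(sprintf(
      "acceptance rate outside [0.05, 0.8] for: %s",
      paste(par_names[acc_rate < 0.05 | acc_rate > 0.8], collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(as.data.frame(kept))
  out$sigma <- 1 / out$inv_sigma
  structure(
    list(
      samples = out, acceptance = acc_rate, burn_in = burn_in,
      n_samples = n_samples, seed = seed, priors = priors,
      proposal_widths = widths, data = tibble::as_tibble(data)
    ),
    class = "imk_fit"
  )
}

#' @export
print.imk_fit <- function(x, ...) {
  cat(sprintf(
    "<imk_fit: %d samples after %d burn-in, seed %d>\n",
    x$n_samples, x$burn_in, x$seed
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted survival model
#'
#' @param x An `imk_fit`.
#' @param ... Unused.
#' @return One row per parameter: posterior mean (`estimate`), SD
#'   (`std.error`) and the 16th/84th percentiles (`conf.low`,
#'   `conf.high`, a 68% credible interval).
#' @export
tidy.imk_fit <- function(x, ...) {
  x$samples |>
    dplyr::select("alpha0", "beta0", "repair_rate", "sigma") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      std.error = sd(.data$value),
      conf.low = unname(quantile(.data$value, 0.16)),
      conf.high = unname(quantile(.data$value, 0.84)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$term, c("alpha0", "beta0", "repair_rate", "sigma")))
}

#' @rdname tidy.imk_fit
#' @export
glance.imk_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$data),
    n_samples = x$n_samples,
    burn_in = x$burn_in,
    mean_acceptance = mean(x$acceptance),
    sigma = mean(x$samples$sigma),
    seed = x$seed
  )
}

#' Posterior predictive mean parameters
#' @param fit An `imk_fit`.
#' @return A [cell_params()] at the posterior means with posterior SDs.
#' @export
as_cell_params <- function(fit) {
  stopifnot(inherits(fit, "imk_fit"))
  s <- fit$samples
  cell_params(
    mean(s$alpha0), mean(s$beta0), mean(s$repair_rate),
    sd(s$alpha0), sd(s$beta0), sd(s$repair_rate)
  )
}

#' @export
autoplot.imk_fit <- function(object, ...) {
  object$samples |>
    dplyr::select("alpha0", "beta0", "repair_rate", "sigma") |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter") |>
    ggplot2::ggplot(ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration (post burn-in)", y = NULL)
}
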