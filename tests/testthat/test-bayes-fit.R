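test_that("log-likelihood matches the Gaussian form on -ln S", {
  theta <- list(alpha0 = 0.263, beta0 = 0.047, repair_rate = 8.857, sigma = 0.15)
  data <- sim_survival_data(hx34, sigma = 1e-12, seed = 1)
  # on-curve data: residual term vanishes, leaving -N log(sqrt(2 pi) sigma)
  expect_equal(
    log_likelihood(theta, data),
    -nrow(data) * log(sqrt(2 * pi) * 0.15),
    tolerance = 1e-6
  )
  # single record, hand-computed density
  one <- tibble::tibble(
    dose = c(2, 2, 2, 2), dose_rate = 10,
    surviving_fraction = c(0.2, 0.2, 0.2, 0.2), y_star = 2.26
  )
  mod <- neg_log_survival(hx34, 2, 10)
  expect_equal(
    log_likelihood(theta, one),
    4 * dnorm(-log(0.2), mod, 0.15, log = TRUE),
    tolerance = 1e-12
  )
  # growing any residual at fixed sigma lowers the likelihood
  worse <- one
  worse$surviving_fraction[1] <- 0.05
  expect_lt(log_likelihood(theta, worse), log_likelihood(theta, one))
  expect_error(log_likelihood(c(theta[1:3], sigma = -1), one), "sigma")
  expect_error(
    log_likelihood(theta, dplyr::mutate(one, surviving_fraction = 1.5)),
    "\\(0, 1\\]"
  )
})

test_that("the Metropolis kernel targets its stationary distribution", {
  # prior recovery: flat target over a box -> uniform marginals
  log_box <- function(th) {
    if (th$a < 0 || th$a > 2 || th$b < -1 || th$b > 1) -Inf else 0
  }
  run <- withr::with_seed(11, microkin:::mk_metropolis(
    log_box, c(a = 1, b = 0), c(a = 1.5, b = 1.5), 20000, 500
  ))
  # thin to roughly independent draws before the distributional test
  thin <- seq(1, 20000, by = 20)
  expect_gt(
    suppressWarnings(ks.test(run$samples[thin, "a"], "punif", 0, 2))$p.value, 0.01
  )
  expect_gt(
    suppressWarnings(ks.test(run$samples[thin, "b"], "punif", -1, 1))$p.value, 0.01
  )

  # chain correctness on a correlated bivariate normal with known moments
  mu <- c(x = 1, y = -2)
  rho <- 0.6
  log_mvn <- function(th) {
    dx <- th$x - 1
    dy <- (th$y + 2) / 2
    -(dx^2 - 2 * rho * dx * dy + dy^2) / (2 * (1 - rho^2))
  }
  run2 <- withr::with_seed(12, microkin:::mk_metropolis(
    log_mvn, c(x = 1, y = -2), c(x = 1, y = 2), 20000, 1000
  ))
  x <- run2$samples[, "x"]
  y <- run2$samples[, "y"]
  # MC standard error estimated from batch means (serially correlated chain)
  bse <- function(v) {
    m <- matrix(v[1:(100 * floor(length(v) / 100))], nrow = 100)
    sd(colMeans(m)) / sqrt(ncol(m))
  }
  expect_lt(abs(mean(x) - 1), 3 * bse(x))
  expect_lt(abs(mean(y) + 2), 3 * bse(y))
  expect_equal(sd(x), 1, tolerance = 0.1)
  expect_equal(sd(y), 2, tolerance = 0.1)
  expect_equal(cor(x, y), rho, tolerance = 0.1)
})

test_that("the fitter recovers known parameters from synthetic data", {
  truth <- cell_params(0.263, 0.047, 8.857)
  data <- sim_survival_data(truth,
    doses = c(1, 2, 3, 4, 6, 8),
    sigma = 0.15, seed = 202
  )
  expect_equal(nrow(data), 24)
  fit <- fit_imk_mcmc(data, n_samples = 3000, burn_in = 600, seed = 303)
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha0", "beta0", "repair_rate", "sigma"))
  tru <- c(alpha0 = 0.263, beta0 = 0.047, repair_rate = 8.857, sigma = 0.15)
  for (p in names(tru)) {
    row <- td[td$term == p, ]
    expect_lt(abs(row$estimate - tru[[p]]), 3 * row$std.error)
  }
  # positivity of every stored sample
  expect_true(all(as.matrix(fit$samples) > 0))
  # determinism under the seed
  fit2 <- fit_imk_mcmc(data, n_samples = 3000, burn_in = 600, seed = 303)
  expect_identical(fit$samples, fit2$samples)
  # a different seed gives a different chain
  fit3 <- fit_imk_mcmc(data, n_samples = 100, burn_in = 100, seed = 304)
  expect_false(identical(fit$samples$alpha0[1:100], fit3$samples$alpha0))
  expect_equal(glance(fit)$n_obs, 24)
  expect_true(all(glance(fit)$mean_acceptance > 0.05))
})

test_that("posterior summaries become truncated-normal priors for the next fit", {
  pr <- update_prior_from(hx34, "repair_rate")
  expect_equal(pr$mean, 8.857)
  expect_equal(pr$sd, 2.175)
  expect_identical(pr$logd(-0.1), -Inf)
  # proper truncated density: integrates to 1 on the support
  expect_equal(
    integrate(function(x) exp(pr$logd(x)), 0, Inf)$value, 1,
    tolerance = 1e-6
  )
  # degenerate source rejected
  degenerate <- cell_params(0.2, 0.05, 9, 0.01, 0.01, 0)
  expect_error(update_prior_from(degenerate, "repair_rate"), "spread")
  # round trip through a fit object preserves the posterior mean
  data <- sim_survival_data(hx34, sigma = 0.1, seed = 5)
  fit <- fit_imk_mcmc(data, n_samples = 500, burn_in = 200, seed = 6)
  pr2 <- update_prior_from(fit, "repair_rate")
  expect_equal(pr2$mean, mean(fit$samples$repair_rate))
  expect_equal(pr2$type, "normal")
})

test_that("validation rejects unusable survival records", {
  bad <- tibble::tibble(dose = 1:4, dose_rate = 1, surviving_fraction = c(0.5, 0.4, 0, 0.2))
  expect_error(fit_imk_mcmc(bad, seed = 1), "\\(0, 1\\]")
  expect_error(
    fit_imk_mcmc(bad[1:3, ] |> dplyr::mutate(surviving_fraction = 0.5), seed = 1),
    "at least 4"
  )
  expect_error(
    fit_imk_mcmc(dplyr::rename(bad, d = dose), seed = 1),
    "lack column"
  )
})
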