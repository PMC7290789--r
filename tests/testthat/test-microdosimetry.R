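test_that("spectra are validated and renormalised on construction", {
  expect_warning(
    sp <- lineal_spectrum(c(1, 2, 3), c(1, 1, 1)),
    "renormalising"
  )
  expect_equal(trapz_test(sp$y, sp$f), 1, tolerance = 1e-6)
  expect_equal(attr(sp, "renorm"), 1 / 2)

  expect_error(lineal_spectrum(c(1, 2), c(0, 0)), "degenerate")
  expect_error(lineal_spectrum(c(-1, 2, 3), c(1, 1, 1)), "positive")
  expect_error(lineal_spectrum(c(2, 1, 3), c(1, 1, 1)), "increasing")
  expect_error(lineal_spectrum(c(1, 2, 3), c(1, -1, 1)), "non-negative")
})

test_that("dose density is proportional to y f(y) and normalised", {
  # uniform f on [1, 3]: d(y) = y / int_1^3 y dy = y / 4
  sp <- suppressWarnings(lineal_spectrum(seq(1, 3, by = 0.01), rep(0.5, 201)))
  dd <- dose_density(sp)
  expect_equal(trapz_test(dd$y, dd$f), 1, tolerance = 1e-6)
  expect_equal(dd$f, dd$y / 4, tolerance = 1e-4)

  # single-support case: the Dirac spectrum maps to itself
  dirac <- lineal_spectrum(10, 1)
  expect_equal(dose_density(dirac)$f, 1)
})

test_that("Dirac spectra match closed forms for y_F, y_D and y*", {
  sp <- lineal_spectrum(10, 1)
  expect_equal(y_freq_mean(sp), 10)
  expect_equal(y_dose_mean(sp), 10)
  # y* = y0^2 (1 - exp(-y^2/y0^2)) / y
  expect_equal(
    y_saturation_corrected(sp),
    150^2 * (1 - exp(-100 / 150^2)) / 10
  )
  # two equal-weight masses at 1 and 3: y_D = (1 + 9)/(1 + 3)
  two <- lineal_spectrum(c(1, 3), c(0.5, 0.5))
  expect_equal(y_dose_mean(two), 2.5)
  expect_equal(y_freq_mean(two), 2)
})

test_that("saturation correction has the right limits and ordering", {
  specs <- list(
    sim_lineal_spectrum(c(1, 0, 0)),
    sim_lineal_spectrum(c(0, 1, 0)),
    sim_lineal_spectrum(c(0, 0, 1)),
    sim_lineal_spectrum(c(0.2, 0.5, 0.3))
  )
  for (sp in specs) {
    yd <- y_dose_mean(sp)
    yf <- y_freq_mean(sp)
    ystar <- y_saturation_corrected(sp)
    expect_lte(yf, yd)
    expect_gt(ystar, 0)
    expect_lte(ystar, yd * (1 + 1e-12))
    # y0 -> Inf recovers y_D
    expect_equal(y_saturation_corrected(sp, domain_geometry(y0 = 1e9)), yd,
      tolerance = 1e-6
    )
    # monotone: y* non-increasing as y0 decreases
    y0s <- c(300, 150, 75, 30)
    vals <- vapply(y0s, function(y0) {
      y_saturation_corrected(sp, domain_geometry(y0 = y0))
    }, 0)
    expect_true(all(diff(vals) <= 1e-12))
  }
  # overkill limit: a mass far above y0 gives y* ~ y0^2 / y -> 0
  hi <- lineal_spectrum(1e6, 1)
  expect_equal(y_saturation_corrected(hi), 150^2 / 1e6, tolerance = 1e-6)
  expect_error(domain_geometry(y0 = -1), "y0")
})

test_that("dose-weighted mixtures are linear in y_D and y* (merged-spectrum oracle)", {
  y <- exp(seq(log(0.05), log(800), length.out = 300))
  set.seed(42)
  for (rep in 1:5) {
    f1 <- dlnorm(y, log(sample(c(0.3, 1, 5), 1)), 0.7) + runif(1, 0, 0.01)
    f2 <- dlnorm(y, log(sample(c(30, 100, 300), 1)), 0.4) + runif(1, 0, 0.01)
    s1 <- suppressWarnings(lineal_spectrum(y, f1))
    s2 <- suppressWarnings(lineal_spectrum(y, f2))
    w <- runif(2)
    w <- w / sum(w)
    mixed <- mix_spectra(list(s1, s2), w)
    expect_equal(
      y_dose_mean(mixed),
      w[1] * y_dose_mean(s1) + w[2] * y_dose_mean(s2),
      tolerance = 1e-10
    )
    expect_equal(
      y_saturation_corrected(mixed),
      w[1] * y_saturation_corrected(s1) + w[2] * y_saturation_corrected(s2),
      tolerance = 1e-10
    )
  }
})

test_that("spectrum files round-trip through the two-column text format", {
  sp <- sim_lineal_spectrum(c(0.3, 0.4, 0.3), n_grid = 50)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(
    c(
      "# synthetic spectrum, y keV/um and frequency density",
      sprintf("%.10g %.10g", sp$y, sp$f)
    ),
    path
  )
  sp2 <- read_spectrum(path)
  expect_equal(sp2$y, sp$y, tolerance = 1e-9)
  expect_equal(sp2$f, sp$f, tolerance = 1e-9)
  expect_error(read_spectrum(withr::local_tempfile(fileext = ".t")), "empty|exist")
})

test_that("component calibration and mixing reproduce their inputs", {
  comp <- calibrate_components(1.0, 41.36, 3.75, 68.50, 10)
  expect_equal(comp$boron_dose_rate_per_ppm, 0.275)
  expect_equal(comp$boron_y_star, (68.50 * 3.75 - 41.36 * 1.0) / 2.75)

  at10 <- mix_quality(comp, 10)
  expect_equal(at10$dose_rate, 3.75)
  expect_equal(at10$y_star, 68.50)
  at0 <- mix_quality(comp, 0)
  expect_equal(at0$dose_rate, 1.0)
  expect_equal(at0$y_star, 41.36)

  # hand-mixed synthetic components: y* = (40*1 + 80*3) / 4
  syn <- quality_components(1, 40, 3, 80)
  expect_equal(mix_quality(syn, 1)$y_star, 70)

  # identical qualities stay identical under calibration
  same <- calibrate_components(1.0, 40, 2.0, 40, 10)
  expect_equal(same$boron_y_star, 40)

  # monotone non-decreasing in ppm when the boron component is harder
  curve <- mix_quality(comp, seq(0, 40, by = 5))
  expect_true(all(diff(curve$y_star) > 0))

  expect_error(mix_quality(comp, -1), "non-negative")
  expect_error(calibrate_components(1.0, 41.36, 0.9, 68.50, 10), "exceed")
})
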