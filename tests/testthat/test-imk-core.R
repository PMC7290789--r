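test_that("gamma factor converts lineal to specific energy", {
  expect_equal(gamma_factor(2.26), 0.1602 * 2.26 / (pi * 0.25))
  expect_equal(gamma_factor(0), 0)
  expect_equal(gamma_factor(4.52), 2 * gamma_factor(2.26))
  # scales with the site geometry
  expect_equal(
    gamma_factor(10, domain_geometry(rd = 1)),
    gamma_factor(10) / 4
  )
})

test_that("protraction factor has the analytic limits and monotone decay", {
  k <- 8.857
  expect_equal(protraction_factor(0, k), 1)
  expect_equal(protraction_factor(1, k), 2 * (k + exp(-k) - 1) / k^2)
  expect_equal(protraction_factor(Inf, k), 0)
  # acute limit: |q - 1| is bounded by x/3 and vanishes smoothly
  xs <- c(1e-9, 1e-6, 1e-4, 1e-3, 1e-2)
  qs <- protraction_factor(xs / k, k)
  expect_true(all(abs(qs - 1) <= xs / 3 + 1e-12))
  # series branch (x < 1e-4) tracks the expansion to machine accuracy;
  # the direct branch is cancellation-limited but still well inside 1e-6
  expect_equal(qs[1:2], 1 - xs[1:2] / 3 + xs[1:2]^2 / 12, tolerance = 1e-12)
  expect_equal(qs[3:4], 1 - xs[3:4] / 3 + xs[3:4]^2 / 12, tolerance = 1e-6)
  expect_equal(
    protraction_factor(0.01 / k, k),
    2 * (0.01 + exp(-0.01) - 1) / 0.01^2,
    tolerance = 1e-10
  )
  # strictly decreasing in T
  grid <- protraction_factor(10^seq(-3, 2, by = 0.25), k)
  expect_true(all(diff(grid) < 0))
  expect_error(protraction_factor(-1, k), ">= 0")
})

test_that("constant-rate survival matches the closed form and its limits", {
  expect_equal(neg_log_survival(m8, 0, 1), 0)
  # frozen hand chain: M8 at 2 Gy, 10 Gy/min, 60Co quality
  gam <- 0.1602 * 2.26 / (pi * 0.25)
  x <- 8.769 * (2 / 600)
  q <- 2 * (x + exp(-x) - 1) / x^2
  expect_equal(
    neg_log_survival(m8, 2, 10),
    (0.612 + gam * 0.066) * 2 + 0.066 * q * 4
  )
  expect_equal(neg_log_survival(m8, 2, 10), 1.546296, tolerance = 1e-6)
  # acute limit: infinite dose rate gives alpha D + beta0 D^2 exactly
  d <- c(1, 3.5, 8)
  expect_equal(
    neg_log_survival(m8, d, Inf),
    (0.612 + gam * 0.066) * d + 0.066 * d^2
  )
  expect_equal(survival_fraction(m8, 2, 10), exp(-1.546296), tolerance = 1e-6)
  # monotone non-increasing in dose at fixed rate
  s <- survival_fraction(m8, seq(0, 10, by = 0.5), 1)
  expect_true(all(diff(s) < 0))
  expect_error(neg_log_survival(m8, 2, 0), "> 0")
  expect_error(neg_log_survival(m8, -2, 1), ">= 0")
})

test_that("sparing: -ln S is non-increasing as the dose rate decreases", {
  rates <- c(100, 10, 1, 0.1, 0.01, 0.001)
  for (p in list(m8, hx34, melj)) {
    for (ys in c(0, 2.26, 68.5)) {
      vals <- neg_log_survival(p, rep(5, length(rates)), rates, ys)
      expect_true(all(diff(vals) <= 1e-12))
    }
  }
})

test_that("schedule sum reduces to the closed form as dt -> 0", {
  # N = 2000 equal intervals at constant rate, several rates and doses
  for (rate in c(0.01, 0.1, 1, 10)) {
    for (dose in c(1, 5, 10)) {
      dur_min <- dose / rate
      sched <- irradiation_schedule(rep(rate, 2000), 2.26, dur_min / 2000)
      expect_equal(
        neg_log_survival_schedule(m8, sched),
        neg_log_survival(m8, dose, rate),
        tolerance = 1e-3
      )
    }
  }
  # convergence order >= 1: halving dt at least halves the error
  err <- vapply(c(50, 100, 200, 400), function(n) {
    sched <- irradiation_schedule(rep(1, n), 2.26, 10 / n)
    abs(neg_log_survival_schedule(m8, sched) - neg_log_survival(m8, 10, 1))
  }, 0)
  expect_true(all(err[-1] / err[-length(err)] <= 0.5 + 1e-6))
})

test_that("O(N) recursion equals the literal double sum on random schedules", {
  set.seed(7)
  for (rep in 1:6) {
    n <- sample(2:200, 1)
    rates <- runif(n, 0, 3)
    ys <- runif(n, 2, 80)
    dt <- runif(1, 0.05, 2)
    sched <- irradiation_schedule(rates, ys, dt)
    expect_equal(
      neg_log_survival_schedule(m8, sched),
      brute_force_neg_log_s(
        0.612, 0.066, 8.769, gamma_factor(ys), rates, dt
      ),
      tolerance = 1e-12
    )
  }
  expect_equal(
    neg_log_survival_schedule(m8, irradiation_schedule(rep(0, 10), 2.26, 1)),
    0
  )
  expect_error(irradiation_schedule(c(1, 1), c(1, 2, 3), 1), "equal length")
})

test_that("split doses: the cross term decays with the gap (repair between fractions)", {
  # two acute-ish pulses separated by a growing gap
  nls_gap <- function(gap_min) {
    n_gap <- round(gap_min)
    rates <- c(5, rep(0, n_gap), 5) # 5 Gy/min for 1 min each
    sched <- irradiation_schedule(rates, 2.26, 1)
    neg_log_survival_schedule(m8, sched)
  }
  gaps <- c(0, 15, 30, 60, 120, 480)
  vals <- vapply(gaps, nls_gap, 0)
  expect_true(all(diff(vals) < 0))
  # the limit of full separation is the sum of two independent fractions
  single <- neg_log_survival_schedule(
    m8, irradiation_schedule(5, 2.26, 1)
  )
  expect_gt(vals[1], 2 * single)
  expect_equal(vals[length(gaps)], 2 * single, tolerance = 1e-3)
  # cross term between two pulses decays as exp(-(a+c) gap)
  cross <- vals - 2 * single
  gap_h <- (gaps[2:5] + 1) / 60 # centre-to-centre spacing
  expect_equal(
    cross[2:5] / cross[1],
    exp(-8.769 * gap_h) / exp(-8.769 * 1 / 60),
    tolerance = 1e-2
  )
})
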