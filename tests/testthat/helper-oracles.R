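# Independent oracles used across the suite; these deliberately avoid the
# package's own code paths.

trapz_test <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1))) / 2
}

# literal O(N^2) evaluation of the time-sectioned survival sum
brute_force_neg_log_s <- function(alpha0, beta0, repair_rate, gam,
                                  dose_rate_gy_min, dt_min) {
  dt_h <- dt_min / 60
  d <- dose_rate_gy_min * 60 * dt_h
  n <- length(d)
  if (length(gam) == 1) gam <- rep(gam, n)
  total <- sum((alpha0 + gam * beta0) * d + beta0 * d^2)
  if (n > 1) {
    for (nn in 1:(n - 1)) {
      for (mm in (nn + 1):n) {
        total <- total + 2 * beta0 * exp(-(mm - nn) * repair_rate * dt_h) *
          d[nn] * d[mm]
      }
    }
  }
  total
}

# acute linear-quadratic mean inactivation dose, via the complementary
# error function: Dbar = sqrt(pi/(4 beta)) exp(alpha^2/(4 beta)) erfc(alpha/(2 sqrt(beta)))
erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
acute_lq_mid <- function(alpha, beta) {
  if (beta == 0) {
    return(1 / alpha)
  }
  sqrt(pi / (4 * beta)) * exp(alpha^2 / (4 * beta)) * erfc(alpha / (2 * sqrt(beta)))
}

m8 <- microkin::melanoma_params("M8")
hx34 <- microkin::melanoma_params("HX34")
melj <- microkin::melanoma_params("Mel-J")
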