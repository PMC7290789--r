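# trapezoidal rule on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(if (n == 1) y else 0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# draws from a normal truncated below at `lower` (inverse-CDF method)
rtruncnorm <- function(n, mean, sd, lower = 0) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

# dose rates are quoted in Gy/min at the interface; the kinetics run in
# hours, so internal computations use Gy/h
gy_min_to_gy_h <- function(rate) rate * 60
min_to_h <- function(t) t / 60

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
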