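# default generating rates used across tests: kapp = 3.08e4 M^-1 s^-1,
# half-saturation at 0.81 uM (inside the 0.1-2.5 uM design)
default_rates <- function() rate_constants(4e5, 0.3, 0.025)

# independent brute-force oracle for the monoexponential association fit:
# dense grid over kobs, with (offset, amplitude) solved exactly by linear
# least squares at each candidate rate
grid_search_fp <- function(t, y, kobs_range, n_grid = 400) {
  ks <- exp(seq(log(kobs_range[1]), log(kobs_range[2]), length.out = n_grid))
  best <- list(rss = Inf)
  for (k in ks) {
    basis <- cbind(1, 1 - exp(-k * t))
    cf <- qr.solve(basis, y)
    rss <- sum((y - basis %*% cf)^2)
    if (rss < best$rss) {
      best <- list(rss = rss, kobs = k, offset = cf[1], amplitude = cf[2])
    }
  }
  best
}

# strip the warning that pfo_trajectory emits at low protein excess
quiet_pfo <- function(...) suppressWarnings(pfo_trajectory(...))

# Cramer-Rao lower bound on the relative standard error of the rate in the
# floating-plateau monoexponential fit y = y0 + A(1 - exp(-kt)) under
# multiplicative noise of coefficient of variation cv: the information-bound
# oracle for half-life recovery
crlb_halflife_relse <- function(t_half, cv, window = 40, pitch = 2, A = 2) {
  t <- seq(0, window, pitch)
  k <- log(2) / t_half
  y <- 1 + A * (1 - exp(-k * t))
  J <- cbind(1, 1 - exp(-k * t), A * t * exp(-k * t))
  W <- diag(1 / (cv * y)^2)
  V <- solve(t(J) %*% W %*% J)
  sqrt(V[3, 3]) / k
}
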