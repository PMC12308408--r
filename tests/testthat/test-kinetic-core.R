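test_that("rate constants enforce their domain", {
  expect_error(rate_constants(0, 1, 1), class = "tagkin_invalid_rates")
  expect_error(rate_constants(1e6, 0, 1), class = "tagkin_invalid_rates")
  expect_error(rate_constants(1e6, 1, -1), class = "tagkin_invalid_rates")
  expect_error(rate_constants(Inf, 1, 1), class = "tagkin_invalid_rates")
  expect_silent(rate_constants(1e6, 1, 0))  # binding-only control
})

test_that("the rate equations have the mass-action form", {
  r <- rate_constants(1e6, 2, 0.5)
  # no complex yet: covalent flux zero, P and S consumed at the binding rate
  d <- ode_rhs(species_state(P = 1e-6, S = 5e-8, PS = 0), r)
  expect_identical(d[["PSstar"]], 0)
  expect_equal(d[["P"]], -1e6 * 1e-6 * 5e-8)
  expect_equal(d[["S"]], d[["P"]])
  # complex only: decays at k_minus1 + k2
  c0 <- 3e-8
  d2 <- ode_rhs(c(P = 0, S = 0, PS = c0, PSstar = 0), r)
  expect_equal(d2[["PS"]], -(2 + 0.5) * c0)
  # conservation of the derivative field
  st <- species_state(P = 8e-7, S = 3e-8, PS = 1e-8, PSstar = 5e-9)
  d3 <- ode_rhs(st, r)
  expect_equal(d3[["P"]] + d3[["PS"]] + d3[["PSstar"]], 0)
  expect_equal(d3[["S"]] + d3[["PS"]] + d3[["PSstar"]], 0)
  expect_error(ode_rhs(c(P = NaN, S = 0, PS = 0, PSstar = 0), r),
               class = "tagkin_bad_state")
})

test_that("rate equations agree with finite differences of the trajectory", {
  r <- rate_constants(1e6, 2, 0.5)
  st <- species_state(P = 1e-6, S = 2.5e-8, PS = 4e-9, PSstar = 2e-9)
  h <- 2e-4
  traj <- simulate_timecourse(r, st, times = c(0, h, 2 * h),
                              rtol = 1e-12, atol = 1e-18)
  fd <- (unlist(traj[3, c("P", "S", "PS", "PSstar")]) -
           unlist(traj[1, c("P", "S", "PS", "PSstar")])) / (2 * h)
  mid <- species_state(P = traj$P[2], S = traj$S[2], PS = traj$PS[2],
                       PSstar = traj$PSstar[2])
  d <- ode_rhs(mid, r)
  expect_equal(unname(fd), unname(d), tolerance = 1e-6)
})

test_that("simulated trajectories conserve mass and reach the right limits", {
  r <- default_rates()
  atol <- 1e-12
  times <- seq(0, 2000, by = 10)
  P0 <- 5e-7; S0 <- 2.5e-8
  traj <- simulate_timecourse(r, species_state(P = P0, S = S0), times,
                              atol = atol)
  expect_true(all(abs(traj$P + traj$PS + traj$PSstar - P0) <= 10 * atol))
  expect_true(all(abs(traj$S + traj$PS + traj$PSstar - S0) <= 10 * atol))
  # covalent product never decreases
  expect_true(all(diff(traj$PSstar) >= -10 * atol))
  # substrate in deficit is fully converted at long times
  expect_equal(traj$PSstar[length(times)], S0, tolerance = 1e-3)
  # grid validation
  expect_error(simulate_timecourse(r, species_state(1e-6, 1e-8), c(1, 2)),
               class = "tagkin_bad_grid")
  expect_error(simulate_timecourse(r, species_state(1e-6, 1e-8), c(0, 2, 2)),
               class = "tagkin_bad_grid")
})

test_that("with the covalent step off the system settles at the binding isotherm", {
  r <- rate_constants(1e6, 1, 0)
  P0 <- 2e-6; S0 <- 2.5e-8
  traj <- simulate_timecourse(r, species_state(P = P0, S = S0),
                              times = seq(0, 100, 0.5))
  expect_true(all(traj$PSstar == 0))
  n <- nrow(traj)
  # equilibrium complex ratio PS/(P*S) = 1/Kd
  Kd <- derived_kd(r)
  expect_equal(traj$PS[n] / (traj$P[n] * traj$S[n]), 1 / Kd,
               tolerance = 1e-5)
})

test_that("Kd and kapp follow from the rate constants", {
  expect_equal(derived_kd(rate_constants(1e6, 1, 0.5)), 1e-6)
  r <- rate_constants(3e5, 0.2, 0.2)
  expect_equal(derived_kapp(r), r$k1 / 2)        # k2 = k_minus1
  big <- rate_constants(3e5, 1e-6, 1)            # k2 >> k_minus1
  expect_equal(derived_kapp(big), big$k1, tolerance = 1e-5)
  small <- rate_constants(3e5, 1, 1e-6)          # rapid equilibrium
  expect_equal(derived_kapp(small), small$k2 / derived_kd(small),
               tolerance = 1e-5)
  expect_lt(derived_kapp(r), r$k1)
})

test_that("kapp matches the fitted rate of a simulated pseudo-first-order trace", {
  # unsaturated regime: [P] well below (k_minus1 + k2)/k1 = 5.05 uM, so the
  # observed rate is within ~1% of kapp * [P]
  r <- rate_constants(1e6, 5, 0.05)
  P0 <- 2e-8; S0 <- 2e-10
  times <- seq(0, 5 * log(2) / (derived_kapp(r) * P0), length.out = 300)
  traj <- simulate_timecourse(r, species_state(P = P0, S = S0), times)
  fit <- grid_search_fp(traj$time_s, traj$PSstar,
                        kobs_range = derived_kapp(r) * P0 * c(0.5, 2),
                        n_grid = 2000)
  expect_equal(fit$kobs / P0, derived_kapp(r), tolerance = 0.02)
})

test_that("half-time reproduces the published polarization half-times", {
  # the five printed (kapp, t_half) pairs whose rounding is self-consistent
  expect_identical(round(half_time(6.8e4, 200e-9)), 51)
  expect_identical(round(half_time(4.3e4, 200e-9)), 81)
  expect_identical(round(half_time(1.5e4, 200e-9)), 231)
  expect_identical(round(half_time(4.6e4, 200e-9)), 75)
  expect_identical(round(half_time(3.0e4, 200e-9)), 116)
  # doubling the protein concentration halves the half-time
  expect_equal(half_time(5e4, 4e-7), half_time(5e4, 2e-7) / 2)
  expect_error(half_time(-1, 2e-7), class = "tagkin_bad_arg")
})

test_that("closed-form solution matches the ODE within its accuracy domain", {
  r <- default_rates()
  S0 <- 2.5e-8
  times <- seq(0, 600, by = 2)
  # model discrepancy scales with substrate/protein ratio; bounds frozen
  # from high-precision reference runs
  for (case in list(list(P0 = 5e-7, tol = 1e-2),     # 20-fold excess
                    list(P0 = 2e-6, tol = 2e-3),     # 80-fold excess
                    list(P0 = 5e-5, tol = 1e-4))) {  # 2000-fold excess
    ode <- simulate_timecourse(r, species_state(P = case$P0, S = S0), times,
                               rtol = 1e-10, atol = 1e-14)
    cf <- pfo_trajectory(r, case$P0, S0, times)
    expect_lt(max(abs(ode$PSstar - cf$PSstar)) / S0, case$tol)
  }
})

test_that("closed-form solution has the correct limiting observed rates", {
  S0 <- 2.5e-8; P0 <- 2e-6
  times <- seq(0, 5000, by = 5)
  # rapid-equilibrium limit: labeling rate -> kapp * P0 = (k1 k2 / k_minus1) P0
  r_eq <- rate_constants(1e6, 1000, 1)
  traj <- pfo_trajectory(r_eq, P0, S0, times)
  expected <- S0 * (1 - exp(-derived_kapp(r_eq) * P0 * times))
  expect_lt(max(abs(traj$PSstar - expected)) / S0, 0.01)
  # binding-limited limit: labeling rate -> k1 * P0
  r_fast <- rate_constants(1e6, 1, 1e6)
  times2 <- seq(0, 5 / (1e6 * P0), length.out = 500)
  traj2 <- pfo_trajectory(r_fast, P0, S0, times2)
  expected2 <- S0 * (1 - exp(-r_fast$k1 * P0 * times2))
  expect_lt(max(abs(traj2$PSstar - expected2)) / S0, 0.01)
  # observed-rate helper agrees with Eq-8 style limits
  expect_equal(pfo_observed_rate(r_eq, P0), derived_kapp(r_eq) * P0,
               tolerance = 5e-3)
})

test_that("confluent eigenvalue branch is finite and continuous", {
  # a = k1 P0, b = k_minus1, c = k2 chosen near the double root of the
  # 2x2 system; the confluent t*exp branch must not divide by zero
  P0 <- 1e-6; S0 <- 1e-8
  k1 <- 1e6; a <- k1 * P0
  # discriminant (a+b+c)^2 - 4ac -> 0 requires b ~ 0: use tiny b
  b <- 1e-20 * a
  r <- rate_constants(k1, b, a * (1 + 1e-12))
  traj <- quiet_pfo(r, P0, S0, seq(0, 10, 0.1))
  expect_true(all(is.finite(traj$PSstar)))
  expect_true(all(diff(traj$PSstar) >= -1e-20))
  # continuity: a nearby non-degenerate parameter point gives nearly the
  # same trajectory
  r2 <- rate_constants(k1, b, a * 1.001)
  traj2 <- quiet_pfo(r2, P0, S0, seq(0, 10, 0.1))
  expect_lt(max(abs(traj$PSstar - traj2$PSstar)) / S0, 0.01)
})

test_that("low protein excess triggers the pseudo-first-order warning", {
  r <- default_rates()
  expect_warning(pfo_trajectory(r, 1e-7, 5e-8, seq(0, 10, 1)),
                 class = "tagkin_pfo_excess_warning")
  expect_silent(pfo_trajectory(r, 2e-6, 5e-8, seq(0, 10, 1)))
})

test_that("product formation is monotone in time and in the rate constants", {
  base <- default_rates()
  times <- seq(0, 400, by = 4)
  st <- species_state(P = 5e-7, S = 2.5e-8)
  ref <- simulate_timecourse(base, st, times)
  expect_true(all(diff(ref$PSstar) >= -1e-14))
  for (bump in list(rate_constants(base$k1 * 2, base$k_minus1, base$k2),
                    rate_constants(base$k1, base$k_minus1, base$k2 * 2))) {
    up <- simulate_timecourse(bump, st, times)
    expect_true(all(up$PSstar - ref$PSstar >= -1e-12 * 2.5e-8))
  }
})
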