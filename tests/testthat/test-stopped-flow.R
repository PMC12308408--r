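test_that("replicate averaging is idempotent, linear, and reduces noise", {
  t <- seq(0, 10, 0.1)
  y <- sin(t) + 2
  one <- sf_trace(t, y, 5e-7, trace_id = "a", replicate = 1)
  two <- dplyr::bind_rows(one, sf_trace(t, y, 5e-7, trace_id = "a",
                                        replicate = 2))
  avg <- average_traces(two)
  expect_equal(avg$fluorescence, y)
  expect_equal(avg$n_averaged[1], 2)
  # traces y and -y average to zero
  pm <- dplyr::bind_rows(sf_trace(t, y, 5e-7, trace_id = "a", replicate = 1),
                         sf_trace(t, -y, 5e-7, trace_id = "a", replicate = 2))
  expect_equal(max(abs(average_traces(pm)$fluorescence)), 0)
  # averaging 8 replicates shrinks residual SD by ~sqrt(8)
  withr::with_seed(99, {
    reps <- purrr::map(1:8, function(r)
      sf_trace(t, y + rnorm(length(t), 0, 0.05), 5e-7,
               trace_id = "a", replicate = r)) |> purrr::list_rbind()
  })
  avg8 <- average_traces(reps)
  sd_single <- sd(reps$fluorescence[reps$replicate == 1] - y)
  sd_avg <- sd(avg8$fluorescence - y)
  expect_equal(sd_avg, sd_single / sqrt(8), tolerance = 0.2)
  # mismatched concentrations across replicates are an error
  bad <- dplyr::bind_rows(one, sf_trace(t, y, 9e-7, trace_id = "a",
                                        replicate = 2))
  expect_error(average_traces(bad), class = "tagkin_metadata_mismatch")
})

test_that("baseline subtraction removes the substrate-only signal", {
  t <- seq(0, 10, 0.1)
  y <- 1 - exp(-t)
  trc <- sf_trace(t, y, 5e-7, trace_id = "a")
  # a trace minus itself is zero
  self <- trc; self$protein_conc_M <- 0
  expect_equal(max(abs(baseline_subtract(trc, self)$fluorescence)), 0)
  # constant baseline shifts by -c
  const <- sf_trace(t, rep(0.3, length(t)), 0, trace_id = "b")
  expect_equal(baseline_subtract(trc, const)$fluorescence, y - 0.3)
  # generator composes signal + drifting baseline; subtraction recovers truth
  fam <- gen_sf_family(noise_sd = 0, baseline_level = 0.05,
                       baseline_drift = 1e-4, seed = 1)
  clean <- baseline_subtract(fam$traces, fam$baseline)
  pred <- predict_sf_trace(fam$truth$rates, clean$protein_conc_M[1],
                           25e-9, clean$time_s[clean$trace_id == clean$trace_id[1]],
                           fam$truth$mixing_delay, fam$truth$offsets[1],
                           fam$truth$response)
  got <- clean$fluorescence[clean$trace_id == clean$trace_id[1]]
  expect_lt(max(abs(got - pred$fluorescence)), 1e-12)
  # protein-containing baseline is rejected
  expect_error(baseline_subtract(trc, trc), class = "tagkin_bad_baseline")
})

test_that("predicted traces have the two-step signal structure", {
  r <- default_rates()
  t <- seq(0, 400, 2)
  # zero response coefficient: flat at offset
  flat <- predict_sf_trace(r, 2e-6, 25e-9, t, offset = 0.4,
                           response_coeff = 0)
  expect_true(all(flat$fluorescence == 0.4))
  # protein excess: plateau at offset + response * S0
  pl <- predict_sf_trace(r, 2.5e-6, 25e-9, seq(0, 2000, 10), offset = 0.1,
                         response_coeff = 1e7)
  expect_equal(tail(pl$fluorescence, 1), 0.1 + 1e7 * 25e-9, tolerance = 1e-3)
  # matches the closed-form bound species at 80-fold excess (bound frozen
  # from high-precision reference runs; the constant-[P] linearization
  # differs from the full system at order S0/P0)
  cf <- pfo_trajectory(r, 2e-6, 25e-9, t)
  pred <- predict_sf_trace(r, 2e-6, 25e-9, t, mixing_delay = 0, offset = 0.1,
                           response_coeff = 1e7)
  expect_lt(max(abs(pred$fluorescence - (0.1 + 1e7 * (cf$PS + cf$PSstar)))) /
              (1e7 * 25e-9), 2e-3)
  # signal is blanked to the offset during the mixing delay
  del <- predict_sf_trace(r, 2e-6, 25e-9, c(0, 0.001, 0.002, 1),
                          mixing_delay = 0.0015, offset = 0.2,
                          response_coeff = 1e7)
  expect_equal(del$fluorescence[1:2], c(0.2, 0.2))
  expect_gt(del$fluorescence[4], 0.2)
})

test_that("zero-noise global fit recovers the generating constants", {
  fam <- gen_sf_family(seed = 2, noise_sd = 0, baseline_level = 0)
  fit <- fit_sf_global(fam$traces)
  expect_true(fit$converged)
  truth <- fam$truth$rates
  expect_equal(fit$rates$k1, truth$k1, tolerance = 1e-4)
  expect_equal(fit$rates$k_minus1, truth$k_minus1, tolerance = 1e-4)
  expect_equal(fit$rates$k2, truth$k2, tolerance = 1e-4)
  expect_equal(fit$response, fam$truth$response, tolerance = 1e-4)
  expect_equal(fit$offsets$offset, fam$truth$offsets, tolerance = 1e-4)
  # derived values are recomputed from the fitted rates
  expect_identical(fit$derived$kapp, derived_kapp(fit$rates))
  expect_identical(fit$derived$Kd, derived_kd(fit$rates))
})

test_that("global fit requires concentration dependence", {
  fam <- gen_sf_family(protein_concs = c(5e-7, 5e-7), seed = 3)
  expect_error(fit_sf_global(fam$traces), class = "tagkin_underdetermined")
  fam2 <- gen_sf_family(protein_concs = c(5e-7, 1e-6), seed = 3)
  expect_warning(fit_sf_global(baseline_subtract(fam2$traces, fam2$baseline)),
                 class = "tagkin_rank_deficiency_warning")
})

test_that("kapp stays identifiable when k2 >> k_minus1 makes the steps sloppy", {
  # binding-limited: kapp ~ k1, individual k2 / k_minus1 poorly constrained
  r <- rate_constants(4e5, 0.01, 1)
  fam <- gen_sf_family(rates = r, seed = 5, baseline_level = 0)
  fit <- fit_sf_global(fam$traces)
  expect_equal(fit$derived$kapp, derived_kapp(r), tolerance = 0.1)
  fit <- mc_errors(fit, n_reps = 40, seed = 9)
  rel_sd <- fit$mc$sd / c(k1 = fit$rates$k1, k_minus1 = fit$rates$k_minus1,
                          k2 = fit$rates$k2, response = fit$response,
                          Kd = fit$derived$Kd, kapp = fit$derived$kapp)
  expect_lt(rel_sd[["kapp"]], 0.1)
  expect_gt(max(rel_sd[["k2"]], rel_sd[["k_minus1"]]), 3 * rel_sd[["kapp"]])
})

test_that("per-trace offsets absorb constant shifts", {
  fam <- gen_sf_family(seed = 6, baseline_level = 0)
  d <- fam$traces
  fit1 <- fit_sf_global(d)
  shifted <- d
  first <- shifted$trace_id == shifted$trace_id[1]
  shifted$fluorescence[first] <- shifted$fluorescence[first] + 5
  fit2 <- fit_sf_global(shifted)
  expect_equal(fit2$rates$k1, fit1$rates$k1, tolerance = 1e-3)
  expect_equal(fit2$rates$k2, fit1$rates$k2, tolerance = 1e-3)
  expect_equal(fit2$offsets$offset[1], fit1$offsets$offset[1] + 5,
               tolerance = 1e-3)
})

test_that("the fixed mixing delay is honored, not ignored", {
  fast <- rate_constants(2e6, 5, 1)
  fam <- gen_sf_family(rates = fast, mixing_delay = 0.05, noise_sd = 0,
                       baseline_level = 0, seed = 1)
  f_ok <- fit_sf_global(fam$traces, mixing_delay = 0.05)
  f_wrong <- suppressWarnings(fit_sf_global(fam$traces, mixing_delay = 0))
  expect_lt(abs(f_ok$rates$k1 / fast$k1 - 1), 0.01)
  expect_gt(abs(f_wrong$rates$k1 / fast$k1 - 1), 0.05)
})

test_that("Monte-Carlo uncertainties are seeded, finite and near zero without noise", {
  fam <- gen_sf_family(seed = 3, noise_sd = 0, baseline_level = 0)
  fit <- fit_sf_global(fam$traces)
  expect_error(mc_errors(fit, n_reps = 0), class = "tagkin_bad_arg")
  fit0 <- mc_errors(fit, n_reps = 5, seed = 4)
  expect_lt(fit0$mc$sd[["kapp"]] / fit0$derived$kapp, 1e-6)
  # same seed reproduces the draws exactly
  fam2 <- gen_sf_family(seed = 8)
  fit2 <- fit_sf_global(baseline_subtract(fam2$traces, fam2$baseline))
  a <- mc_errors(fit2, n_reps = 10, seed = 11)
  b <- mc_errors(fit2, n_reps = 10, seed = 11)
  expect_identical(a$mc$draws, b$mc$draws)
  expect_true(all(a$mc$sd >= 0))
  td <- tidy(a)
  expect_true("mc_sd" %in% names(td))
})
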