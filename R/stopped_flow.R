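#' Build a stopped-flow trace table
#'
#' Tidy format: one row per time point, with per-trace metadata repeated.
#' A family of traces at different protein concentrations shares one table,
#' distinguished by `trace_id`; replicate recordings of the same condition
#' carry a `replicate` column until averaged.
#'
#' @param time_s Time since trigger (s).
#' @param fluorescence Fluorescence signal (arbitrary units).
#' @param protein_conc_M Final protein concentration in the observation cell
#'   (M). 0 marks a substrate-plus-buffer baseline trace.
#' @param substrate_conc_M Final substrate concentration (M), 25 nM standard.
#' @param trace_id Condition identifier.
#' @param replicate Replicate number within a condition.
#' @return A tibble, one row per time point.
#' @export
sf_trace <- function(time_s, fluorescence, protein_conc_M,
                     substrate_conc_M = 25e-9, trace_id = "trace",
                     replicate = 1L) {
  if (any(diff(time_s) <= 0)) {
    abort("time must be strictly increasing", class = "tagkin_nonmonotone_time")
  }
  if (protein_conc_M > 0 && protein_conc_M < substrate_conc_M) {
    warn("protein below substrate concentration: not pseudo-first-order",
         class = "tagkin_not_pfo_warning")
  }
  tibble(time_s = time_s, fluorescence = fluorescence,
         protein_conc_M = protein_conc_M,
         substrate_conc_M = substrate_conc_M,
         trace_id = as.character(trace_id), replicate = as.integer(replicate))
}

# shared-grid check: grids must agree to within one sample pitch
check_grid <- function(t_ref, t_new, what = "replicate") {
  if (length(t_ref) != length(t_new)) {
    abort(sprintf("%s grids differ in length", what),
          class = "tagkin_grid_mismatch")
  }
  pitch <- median(diff(t_ref))
  if (max(abs(t_ref - t_new)) > pitch) {
    abort(sprintf("%s time grids differ by more than one sample", what),
          class = "tagkin_grid_mismatch")
  }
  invisible(TRUE)
}

#' Average replicate stopped-flow traces
#'
#' Replicates of each condition (same `trace_id`) are averaged pointwise on
#' the grid of the first replicate; replicate grids must agree to within one
#' sample (they are linearly resampled onto the first grid if they differ by
#' less). Concentration metadata must match across replicates.
#'
#' @param data A trace table with a `replicate` column ([sf_trace()] rows
#'   bound together).
#' @return A trace table with one averaged trace per `trace_id` and an
#'   `n_averaged` column.
#' @export
average_traces <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "fluorescence", "trace_id") %in% names(data)))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  split(data, factor(data$trace_id, levels = unique(data$trace_id))) |>
    purrr::map(function(d) {
      reps <- split(d, d$replicate)
      ref <- reps[[1]]
      if (length(unique(purrr::map_dbl(reps, ~ .x$protein_conc_M[1]))) > 1 ||
          length(unique(purrr::map_dbl(reps, ~ .x$substrate_conc_M[1]))) > 1) {
        abort("replicates of one condition must share concentrations",
              class = "tagkin_metadata_mismatch")
      }
      ys <- purrr::map(reps, function(r) {
        check_grid(ref$time_s, r$time_s)
        if (identical(r$time_s, ref$time_s)) r$fluorescence
        else approx(r$time_s, r$fluorescence, xout = ref$time_s, rule = 2)$y
      })
      tibble(time_s = ref$time_s,
             fluorescence = Reduce(`+`, ys) / length(ys),
             protein_conc_M = ref$protein_conc_M[1],
             substrate_conc_M = ref$substrate_conc_M[1],
             trace_id = ref$trace_id[1],
             n_averaged = length(ys))
    }) |>
    purrr::list_rbind()
}

#' Subtract a substrate-only baseline from stopped-flow traces
#'
#' The baseline (substrate mixed with buffer only) is interpolated onto each
#' trace's grid and subtracted pointwise; metadata are preserved.
#'
#' @param data A trace table (one or more traces).
#' @param baseline A single baseline trace recorded with matching substrate
#'   and no protein.
#' @return The trace table with baseline-corrected `fluorescence`.
#' @export
baseline_subtract <- function(data, baseline) {
  stopifnot(is.data.frame(baseline),
            all(c("time_s", "fluorescence") %in% names(baseline)))
  if ("protein_conc_M" %in% names(baseline) &&
      any(baseline$protein_conc_M > 0)) {
    abort("baseline must be protein-free", class = "tagkin_bad_baseline")
  }
  pitch <- median(diff(baseline$time_s))
  split(data, factor(data$trace_id, levels = unique(data$trace_id))) |>
    purrr::map(function(d) {
      if (min(d$time_s) < min(baseline$time_s) - pitch ||
          max(d$time_s) > max(baseline$time_s) + pitch) {
        abort("trace grid extends beyond the baseline grid",
              class = "tagkin_grid_mismatch")
      }
      b <- approx(baseline$time_s, baseline$fluorescence,
                  xout = d$time_s, rule = 2)$y
      d$fluorescence <- d$fluorescence - b
      d
    }) |>
    purrr::list_rbind()
}

# species trajectory as a plain matrix (fast path for fitting)
sim_species <- function(rates, P0, S0, times, rtol = 1e-8, atol = 1e-12) {
  k1 <- rates$k1; km1 <- rates$k_minus1; k2 <- rates$k2
  deriv <- function(t, y, parms) {
    bind <- k1 * y[1] * y[2]
    unbind <- km1 * y[3]
    react <- k2 * y[3]
    list(c(-bind + unbind, -bind + unbind, bind - unbind - react, react))
  }
  deSolve::lsoda(y = c(P0, S0, 0, 0), times = times, func = deriv,
                 parms = NULL, rtol = rtol, atol = atol)
}

# bound species (PS + PS*) at times t for a trace observed with a mixing
# delay d: species evolve from mixing, observation starts d later, and the
# signal is flat at the offset for t <= d
bound_species <- function(rates, P0, S0, t, mixing_delay,
                          rtol = 1e-8, atol = 1e-12) {
  g <- numeric(length(t))
  after <- t > mixing_delay
  if (!any(after)) return(g)
  tau <- t[after] - mixing_delay
  grid <- sort(unique(c(0, tau)))
  sol <- sim_species(rates, P0, S0, grid, rtol, atol)
  if (nrow(sol) < length(grid)) {
    abort(sprintf("ODE solver failed at t = %.4g s", sol[nrow(sol), 1]),
          class = "tagkin_solver_failure")
  }
  bound <- sol[, 4] + sol[, 5]
  g[after] <- bound[match(tau, grid)]
  g
}

#' Predict a stopped-flow fluorescence trace from the two-step model
#'
#' The observed signal is modelled as
#' `F(t) = offset + response_coeff * ([PS](t - d) + [PS*](t - d))`
#' with `d` the instrument mixing delay (fixed, not fitted) and the species
#' from the two-step scheme started at the freshly mixed concentrations.
#' The complex and the covalent conjugate are taken to contribute equally to
#' the signal change (a single shared response coefficient). For `t <= d`
#' the prediction is flat at `offset`.
#'
#' @param rates A [rate_constants()] object.
#' @param protein_conc,substrate_conc Mixed (final) concentrations (M).
#' @param times Observation time grid (s).
#' @param mixing_delay Instrument mixing delay (s).
#' @param offset Signal offset (free-dye fluorescence), signal units.
#' @param response_coeff Signal change per molar of bound substrate.
#' @param rtol,atol Solver tolerances.
#' @return A tibble `time_s`, `fluorescence`.
#' @export
predict_sf_trace <- function(rates, protein_conc, substrate_conc, times,
                             mixing_delay = 0.0015, offset = 0,
                             response_coeff = 1, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(rates, "rate_constants"))
  g <- bound_species(rates, protein_conc, substrate_conc, times,
                     mixing_delay, rtol, atol)
  tibble(time_s = times, fluorescence = offset + response_coeff * g)
}

# per-trace noise estimate from the high-frequency component
noise_sd <- function(y) {
  s <- sd(diff(y)) / sqrt(2)
  if (!is.finite(s) || s <= 0) 1 else s
}

# initial guesses for (k1, k_minus1, k2) from per-trace monoexponential
# rates: kobs(P) ~ k2 P / (K + P) with K = (k_minus1 + k2)/k1, linearized
# as 1/kobs = K/(k2 P) + 1/k2; the k_minus1/k1 split starts at k_minus1 = k2
sf_initial_guess <- function(traces) {
  kobs <- purrr::map_dbl(traces, function(tr) {
    k0 <- guess_kobs(tr$t, tr$y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ o + a * (1 - exp(-k * t)),
                        data = list(t = tr$t, y = tr$y),
                        start = list(o = tr$y[1], a = tail(tr$y, 1) - tr$y[1],
                                     k = k0),
                        lower = c(-Inf, -Inf, 0)),
      error = function(e) NULL)
    if (is.null(fit)) k0 else coef(fit)[["k"]]
  })
  P <- purrr::map_dbl(traces, "P0")
  ok <- is.finite(kobs) & kobs > 0
  k2_0 <- NA_real_; K_0 <- NA_real_
  if (sum(ok) >= 3) {
    lb <- lm(I(1 / kobs[ok]) ~ I(1 / P[ok]))
    ic <- unname(coef(lb)[1]); sl <- unname(coef(lb)[2])
    if (is.finite(ic) && ic > 0 && sl > 0) {
      k2_0 <- 1 / ic
      K_0 <- sl * k2_0
    }
  }
  if (!is.finite(k2_0) || k2_0 <= 0) k2_0 <- 2 * max(kobs[ok], 1e-3)
  if (!is.finite(K_0) || K_0 <= 0) K_0 <- median(P)
  km1_0 <- k2_0
  k1_0 <- (km1_0 + k2_0) / K_0
  c(k1 = k1_0, k_minus1 = km1_0, k2 = k2_0)
}

# weighted residual vector with the response coefficient and per-trace
# offsets profiled out exactly (linear in the signal model)
sf_residuals <- function(theta, traces, mixing_delay, weights,
                         rtol, atol, return_linear = FALSE) {
  rates <- list(k1 = exp(theta[1]), k_minus1 = exp(theta[2]),
                k2 = exp(theta[3]))
  g <- vector("list", length(traces))
  for (j in seq_along(traces)) {
    tr <- traces[[j]]
    gj <- tryCatch(
      suppressWarnings(
        bound_species(rates, tr$P0, tr$S0, tr$t, mixing_delay, rtol, atol)),
      error = function(e) NULL)
    if (is.null(gj) || !all(is.finite(gj))) {
      # solver blow-up at an extreme parameter point: return a large finite
      # penalty that grows with |theta| so the optimizer backs off smoothly
      n_all <- sum(lengths(purrr::map(traces, "t")))
      res <- rep(1e3 * (1 + sqrt(sum(theta^2))), n_all)
      return(if (return_linear) list(resid = res) else res)
    }
    g[[j]] <- gj
  }
  num <- 0; den <- 0
  yc <- gc_ <- vector("list", length(traces))
  for (j in seq_along(traces)) {
    yj <- traces[[j]]$y
    yc[[j]] <- yj - mean(yj)
    gc_[[j]] <- g[[j]] - mean(g[[j]])
    w2 <- weights[j]^2
    num <- num + w2 * sum(yc[[j]] * gc_[[j]])
    den <- den + w2 * sum(gc_[[j]]^2)
  }
  r_coef <- if (den > 0) num / den else 0
  res <- unlist(purrr::map2(yc, gc_, ~ .x - r_coef * .y), use.names = FALSE)
  res <- res * rep(weights, times = lengths(yc))
  if (return_linear) {
    offsets <- purrr::map2_dbl(traces, g,
                               ~ mean(.x$y) - r_coef * mean(.y))
    list(resid = res, response = r_coef, offsets = offsets, g = g)
  } else {
    res
  }
}

#' Globally fit a stopped-flow trace family to the two-step model
#'
#' All traces of a concentration series are fitted jointly: the rate
#' constants `k1`, `k_minus1`, `k2` and one response coefficient are shared
#' across traces, each trace keeps its own signal offset, and the instrument
#' mixing delay is held fixed (never fitted). Rate constants are optimized in
#' log space (enforcing positivity and improving conditioning) by
#' Levenberg-Marquardt least squares; the response coefficient and offsets,
#' linear in the model, are profiled out exactly at each step. Traces are
#' inverse-variance weighted using a per-trace noise estimate from the
#' high-frequency signal component. Derived `Kd` and `kapp` are recomputed
#' from the fitted rates.
#'
#' @param data A trace table covering >= 2 traces at distinct protein
#'   concentrations (identifiability of the binding and covalent steps
#'   requires concentration dependence). Baseline rows
#'   (`protein_conc_M == 0`) must be removed / subtracted beforehand.
#' @param mixing_delay Instrument mixing delay (s), fixed during fitting.
#' @param start Optional named vector `c(k1=, k_minus1=, k2=)` of initial
#'   guesses; by default derived from per-trace monoexponential rates.
#' @param lower,upper Bounds on `(k1, k_minus1, k2)`, natural scale.
#' @param weights `"auto"` (inverse noise SD per trace) or `"none"`.
#' @param rtol,atol ODE solver tolerances used inside the objective.
#' @return An object of class `sf_fit` with [tidy()], [glance()],
#'   [augment()] and [autoplot()] methods; pass to [mc_errors()] for
#'   Monte-Carlo parameter uncertainties.
#'
#' @examples
#' \donttest{
#' fam <- gen_sf_family(seed = 1, noise_sd = 0)
#' fit <- fit_sf_global(fam$traces)
#' glance(fit)
#' }
#' @export
fit_sf_global <- function(data, mixing_delay = 0.0015, start = NULL,
                          lower = c(1, 1e-6, 1e-6),
                          upper = c(1e9, 1e3, 1e3),
                          weights = c("auto", "none"),
                          rtol = 1e-8, atol = 1e-12) {
  stopifnot(is.data.frame(data),
            all(c("time_s", "fluorescence", "trace_id",
                  "protein_conc_M") %in% names(data)))
  weights <- match.arg(weights)
  ids <- unique(data$trace_id)
  traces <- purrr::map(ids, function(id) {
    d <- data[data$trace_id == id, ]
    list(id = id, t = d$time_s, y = d$fluorescence,
         P0 = d$protein_conc_M[1], S0 = d$substrate_conc_M[1])
  })
  P <- purrr::map_dbl(traces, "P0")
  if (length(unique(P)) < 2) {
    abort(paste("global fitting needs >= 2 traces at distinct protein",
                "concentrations"), class = "tagkin_underdetermined")
  }
  if (max(P) / min(P) < 4) {
    warn(paste("protein concentration series spans < 4-fold:",
               "k1/k2 separation may be rank-deficient"),
         class = "tagkin_rank_deficiency_warning")
  }
  w <- if (weights == "auto") {
    purrr::map_dbl(traces, ~ 1 / noise_sd(.x$y))
  } else rep(1, length(traces))
  w <- w / mean(w)

  if (is.null(start)) start <- sf_initial_guess(traces)
  run_lm <- function(theta0) {
    minpack.lm::nls.lm(
      par = theta0,
      lower = log(lower), upper = log(upper),
      fn = sf_residuals, traces = traces, mixing_delay = mixing_delay,
      weights = w, rtol = rtol, atol = atol,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-10))
  }
  clamp <- function(x) log(pmin(pmax(x, lower), upper))
  theta0 <- clamp(unname(start[c("k1", "k_minus1", "k2")]))
  lm_fit <- run_lm(theta0)
  # the heuristic initial guess occasionally lands in a local minimum;
  # detectable because the residual scale then exceeds the per-trace noise
  # estimate. Restart from a coarse grid of rescaled starts and keep the
  # best weighted RSS.
  noise_bar <- mean(purrr::map_dbl(traces, ~ noise_sd(.x$y)))
  fit_sigma <- function(f) sqrt(f$deviance / length(f$fvec))
  if (fit_sigma(lm_fit) > 1.5 * noise_bar * mean(w)) {
    s0 <- exp(theta0)
    for (fac in list(c(0.1, 0.1, 0.1), c(0.1, 1, 0.01), c(0.03, 1, 0.03),
                     c(1, 10, 1), c(10, 1, 1), c(0.01, 0.1, 0.01))) {
      cand <- run_lm(clamp(s0 * fac))
      if (cand$deviance < lm_fit$deviance) lm_fit <- cand
      if (fit_sigma(lm_fit) <= 1.5 * noise_bar * mean(w)) break
    }
  }
  theta <- lm_fit$par
  lin <- sf_residuals(theta, traces, mixing_delay, w, rtol, atol,
                      return_linear = TRUE)
  rates <- rate_constants(exp(theta[1]), exp(theta[2]), exp(theta[3]))
  n_pts <- sum(lengths(purrr::map(traces, "t")))
  n_par <- 3 + 1 + length(traces)
  resid_raw <- unlist(purrr::map2(
    traces, seq_along(traces),
    function(tr, j) tr$y - lin$offsets[j] - lin$response * lin$g[[j]]),
    use.names = FALSE)
  out <- list(
    rates = rates,
    response = lin$response,
    offsets = tibble(trace_id = purrr::map_chr(traces, "id"),
                     protein_conc_M = P,
                     offset = lin$offsets),
    derived = derived_params(rates),
    mixing_delay = mixing_delay,
    weights = setNames(w, purrr::map_chr(traces, "id")),
    sigma = sqrt(sum(resid_raw^2) / (n_pts - n_par)),
    trace_sigma = purrr::map_dbl(traces, ~ noise_sd(.x$y)),
    rss = sum(resid_raw^2),
    n_traces = length(traces), n_points = n_pts,
    converged = lm_fit$info %in% 1:4,
    info = lm_fit$info, message = lm_fit$message,
    niter = lm_fit$niter,
    start = start, lower = lower, upper = upper,
    rtol = rtol, atol = atol,
    data = data, traces = traces,
    mc = NULL
  )
  if (!out$converged) {
    warn(sprintf("global fit did not converge (%s); best point returned",
                 lm_fit$message), class = "tagkin_fit_warning")
  }
  class(out) <- "sf_fit"
  out
}

#' @export
print.sf_fit <- function(x, ...) {
  cat("Global two-step fit of", x$n_traces, "stopped-flow traces\n")
  cat(sprintf("  k1       = %.4g M^-1 s^-1\n", x$rates$k1))
  cat(sprintf("  k_minus1 = %.4g s^-1\n", x$rates$k_minus1))
  cat(sprintf("  k2       = %.4g s^-1\n", x$rates$k2))
  cat(sprintf("  Kd = %.4g M, kapp = %.4g M^-1 s^-1\n",
              x$derived$Kd, x$derived$kapp))
  cat(sprintf("  response = %.4g per M, residual sigma = %.3g\n",
              x$response, x$sigma))
  if (!is.null(x$mc)) {
    cat(sprintf("  Monte-Carlo SDs (%d replicates): k1 %.2g, k_minus1 %.2g, k2 %.2g, kapp %.2g\n",
                x$mc$n_ok, x$mc$sd[["k1"]], x$mc$sd[["k_minus1"]],
                x$mc$sd[["k2"]], x$mc$sd[["kapp"]]))
  }
  invisible(x)
}

#' @method tidy sf_fit
#' @export
tidy.sf_fit <- function(x, ...) {
  est <- c(k1 = x$rates$k1, k_minus1 = x$rates$k_minus1, k2 = x$rates$k2,
           response = x$response, Kd = x$derived$Kd, kapp = x$derived$kapp)
  out <- tibble(term = names(est), estimate = unname(est))
  if (!is.null(x$mc)) {
    out$mc_sd <- unname(x$mc$sd[out$term])
  }
  out
}

#' @method glance sf_fit
#' @export
glance.sf_fit <- function(x, ...) {
  tibble(k1 = x$rates$k1, k_minus1 = x$rates$k_minus1, k2 = x$rates$k2,
         Kd = x$derived$Kd, kapp = x$derived$kapp,
         response = x$response, sigma = x$sigma,
         n_traces = x$n_traces, n_points = x$n_points,
         converged = x$converged)
}

#' @method augment sf_fit
#' @export
augment.sf_fit <- function(x, ...) {
  purrr::map2(x$traces, seq_along(x$traces), function(tr, j) {
    g <- bound_species(x$rates, tr$P0, tr$S0, tr$t, x$mixing_delay,
                       x$rtol, x$atol)
    fitted <- x$offsets$offset[j] + x$response * g
    tibble(trace_id = tr$id, time_s = tr$t, fluorescence = tr$y,
           protein_conc_M = tr$P0, .fitted = fitted,
           .resid = tr$y - fitted)
  }) |> purrr::list_rbind()
}

#' @method autoplot sf_fit
#' @export
autoplot.sf_fit <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fluorescence),
                        size = 0.3, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "firebrick") +
    ggplot2::facet_wrap(~ protein_conc_M, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  title = "Global two-step fit",
                  subtitle = sprintf(
                    "k1 = %.3g M⁻¹s⁻¹, k₋₁ = %.3g s⁻¹, k2 = %.3g s⁻¹, kapp = %.3g M⁻¹s⁻¹",
                    object$rates$k1, object$rates$k_minus1, object$rates$k2,
                    object$derived$kapp))
}

#' Monte-Carlo standard deviations for a global stopped-flow fit
#'
#' Parametric Monte Carlo: `n_reps` synthetic datasets are drawn from the
#' fitted model with Gaussian noise at each trace's residual SD, each is
#' refit (warm-started at the point estimate), and the SD of every parameter
#' across replicates is reported. Replicate fits that fail are counted; if
#' more than 20% fail the SDs are invalidated (returned as `NA`).
#'
#' @param fit A converged `sf_fit`.
#' @param n_reps Number of Monte-Carlo replicates (default 500).
#' @param seed Integer seed; the procedure is reproducible given a seed.
#' @return The `sf_fit` with an `mc` element: `sd` (named vector over `k1`,
#'   `k_minus1`, `k2`, `response`, `Kd`, `kapp`, offsets), `draws` (tibble of
#'   replicate estimates), `n_ok`, `n_fail`.
#' @export
mc_errors <- function(fit, n_reps = 500, seed = NULL) {
  stopifnot(inherits(fit, "sf_fit"))
  if (n_reps < 1) {
    abort("n_reps must be >= 1", class = "tagkin_bad_arg")
  }
  if (!fit$converged) {
    abort("Monte-Carlo errors need a converged fit",
          class = "tagkin_not_converged")
  }
  aug <- augment(fit)
  pred <- split(aug$.fitted, aug$trace_id)[unique(aug$trace_id)]
  resid_sd <- purrr::map_dbl(
    split(aug$.resid, aug$trace_id)[unique(aug$trace_id)], sd)
  theta_hat <- log(c(fit$rates$k1, fit$rates$k_minus1, fit$rates$k2))

  run <- function() {
    draws <- purrr::map(seq_len(n_reps), function(i) {
      traces_i <- purrr::map2(fit$traces, seq_along(fit$traces),
        function(tr, j) {
          tr$y <- pred[[j]] + rnorm(length(tr$y), 0, resid_sd[j])
          tr
        })
      lm_i <- tryCatch(
        minpack.lm::nls.lm(
          par = theta_hat, lower = log(fit$lower), upper = log(fit$upper),
          fn = sf_residuals, traces = traces_i,
          mixing_delay = fit$mixing_delay, weights = unname(fit$weights),
          rtol = fit$rtol, atol = fit$atol,
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(lm_i) || !(lm_i$info %in% 1:4)) return(NULL)
      th <- lm_i$par
      lin <- sf_residuals(th, traces_i, fit$mixing_delay,
                          unname(fit$weights), fit$rtol, fit$atol,
                          return_linear = TRUE)
      k1 <- exp(th[1]); km1 <- exp(th[2]); k2 <- exp(th[3])
      tibble(rep = i, k1 = k1, k_minus1 = km1, k2 = k2,
             response = lin$response,
             Kd = km1 / k1, kapp = k1 * k2 / (k2 + km1))
    })
    purrr::compact(draws) |> purrr::list_rbind()
  }
  draws <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  n_ok <- nrow(draws)
  n_fail <- n_reps - n_ok
  sds <- purrr::map_dbl(draws[c("k1", "k_minus1", "k2", "response",
                                "Kd", "kapp")], sd)
  if (n_fail > 0.2 * n_reps) {
    warn(sprintf("%d/%d Monte-Carlo replicate fits failed: SDs invalidated",
                 n_fail, n_reps), class = "tagkin_mc_warning")
    sds[] <- NA_real_
  }
  fit$mc <- list(sd = sds, draws = draws, n_ok = n_ok, n_fail = n_fail,
                 n_reps = n_reps, seed = seed, resid_sd = resid_sd)
  fit
}
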