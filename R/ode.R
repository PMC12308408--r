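#' Species state of the two-step labeling reaction
#'
#' Concentrations (M) of free protein `P`, free substrate `S`, noncovalent
#' complex `PS` and covalent conjugate `PSstar`.
#'
#' @param P,S,PS,PSstar Concentrations in molar, all >= 0.
#' @return A named numeric vector of class `species_state`.
#' @export
species_state <- function(P, S, PS = 0, PSstar = 0) {
  x <- c(P = P, S = S, PS = PS, PSstar = PSstar)
  if (!all(is.finite(x))) {
    abort("species concentrations must be finite", class = "tagkin_bad_state")
  }
  if (any(x < 0)) {
    abort("species concentrations must be non-negative",
          class = "tagkin_bad_state")
  }
  structure(x, class = c("species_state", "numeric"))
}

#' Time derivatives of the two-step reaction scheme
#'
#' The mass-action rate equations of the scheme
#' P + S <-> PS -> PS*:
#' \deqn{d[P]/dt = -k_1 [P][S] + k_{-1} [PS]}
#' \deqn{d[S]/dt = -k_1 [P][S] + k_{-1} [PS]}
#' \deqn{d[PS]/dt = k_1 [P][S] - k_{-1} [PS] - k_2 [PS]}
#' \deqn{d[PS^*]/dt = k_2 [PS]}
#'
#' @param state A [species_state()] (or named numeric with `P`, `S`, `PS`,
#'   `PSstar`), concentrations in M.
#' @param rates A [rate_constants()] object.
#' @return Named numeric vector of derivatives (M/s) in the same order.
#' @export
ode_rhs <- function(state, rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (!all(is.finite(state))) {
    abort("non-finite species state", class = "tagkin_bad_state")
  }
  P <- state[["P"]]; S <- state[["S"]]; PS <- state[["PS"]]
  bind <- rates$k1 * P * S
  unbind <- rates$k_minus1 * PS
  react <- rates$k2 * PS
  c(P = -bind + unbind,
    S = -bind + unbind,
    PS = bind - unbind - react,
    PSstar = react)
}

#' Simulate a labeling trajectory of the two-step scheme
#'
#' Integrates the mass-action rate equations with an adaptive-step solver
#' (`deSolve::lsoda`). The system conserves total protein (`P + PS + PSstar`)
#' and total substrate (`S + PS + PSstar`); both are preserved to within
#' solver tolerance.
#'
#' @param rates A [rate_constants()] object.
#' @param initial A [species_state()] giving concentrations at `times[1]`.
#' @param times Strictly increasing time grid (s), starting at 0.
#' @param rtol,atol Relative / absolute solver tolerances. The default
#'   `atol = 1e-12` M resolves nanomolar species to ~1e-5 relative.
#' @return A tibble with columns `time_s`, `P`, `S`, `PS`, `PSstar` (M).
#'
#' @examples
#' rates <- rate_constants(4e5, 0.3, 0.025)
#' traj <- simulate_timecourse(rates, species_state(P = 2e-6, S = 25e-9),
#'                             times = seq(0, 300, by = 2))
#' @export
simulate_timecourse <- function(rates, initial, times,
                                rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(rates, "rate_constants"))
  if (length(times) < 2 || any(diff(times) <= 0)) {
    abort("times must be strictly increasing with at least 2 points",
          class = "tagkin_bad_grid")
  }
  if (times[1] != 0) {
    abort("time grid must start at 0", class = "tagkin_bad_grid")
  }
  y0 <- c(P = initial[["P"]], S = initial[["S"]],
          PS = initial[["PS"]], PSstar = initial[["PSstar"]])
  deriv <- function(t, y, parms) list(ode_rhs(y, rates))
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (nrow(sol) < length(times)) {
    abort(sprintf("ODE solver failed at t = %.4g s", sol[nrow(sol), "time"]),
          class = "tagkin_solver_failure")
  }
  tibble(time_s = sol[, "time"],
         P = sol[, "P"], S = sol[, "S"],
         PS = sol[, "PS"], PSstar = sol[, "PSstar"])
}

#' Closed-form pseudo-first-order solution of the two-step scheme
#'
#' With protein in large excess, `[P]` stays effectively constant at `P0` and
#' the substrate species obey a linear two-compartment system
#' \deqn{dS/dt = -k_1 P_0 S + k_{-1} PS}
#' \deqn{dPS/dt = k_1 P_0 S - (k_{-1} + k_2) PS}
#' whose solution is biexponential in the two eigenvalues of the 2x2 rate
#' matrix; `PS*(t) = S_0 - S(t) - PS(t)`. When the eigenvalues coincide the
#' confluent (`t e^{lambda t}`) form is used. The slow eigenvalue reduces to
#' `kapp * P0` whenever binding pre-equilibrates or the covalent step is
#' rate-limiting.
#'
#' @param rates A [rate_constants()] object.
#' @param P0 Excess protein concentration (M), held constant.
#' @param S0 Initial free substrate concentration (M).
#' @param times Time grid (s).
#' @return A tibble with columns `time_s`, `P`, `S`, `PS`, `PSstar` (M);
#'   `P` is the constant `P0`.
#' @export
pfo_trajectory <- function(rates, P0, S0, times) {
  stopifnot(inherits(rates, "rate_constants"))
  if (P0 <= 0 || S0 <= 0) {
    abort("P0 and S0 must be positive", class = "tagkin_bad_arg")
  }
  if (P0 < 4 * S0) {
    warn(paste("protein excess below 4-fold: the pseudo-first-order",
               "approximation may be poor"),
         class = "tagkin_pfo_excess_warning")
  }
  a <- rates$k1 * P0          # pseudo-first-order binding rate
  b <- rates$k_minus1
  c2 <- rates$k2
  tr <- -(a + b + c2)
  det <- a * c2
  disc <- tr^2 - 4 * det      # = (a - b - c2)^2 + 4*a*b > 0
  sq <- sqrt(max(disc, 0))
  l1 <- (tr + sq) / 2         # slow eigenvalue (closer to 0)
  l2 <- (tr - sq) / 2
  t <- times

  if (abs(l1 - l2) < 1e-9 * abs(l1 + l2) / 2 || sq == 0) {
    # confluent case: exp(Mt) = e^{lt} (I + t(M - lI))
    l <- tr / 2
    e <- exp(l * t)
    S <- e * (S0 + t * (-a - l) * S0)
    PS <- e * (t * a * S0)
  } else {
    # exp(Mt) x0 via Lagrange interpolation of the matrix exponential
    e1 <- exp(l1 * t); e2 <- exp(l2 * t)
    # first column of (M - l2 I) and (M - l1 I) applied to (S0, 0)
    S <- (e1 * (-a - l2) - e2 * (-a - l1)) * S0 / (l1 - l2)
    PS <- (e1 * a - e2 * a) * S0 / (l1 - l2)
  }
  PSstar <- S0 - S - PS
  tibble(time_s = t, P = rep(P0, length(t)), S = S, PS = PS,
         PSstar = pmax(PSstar, 0))
}

#' Slow observed rate of the pseudo-first-order two-step system
#'
#' The magnitude of the slow eigenvalue of the linearized system; this is the
#' observed single-exponential labeling rate when the two eigenvalues are
#' well separated, and approaches `kapp * P0` in the usual regimes.
#'
#' @inheritParams pfo_trajectory
#' @return Observed rate (s^-1).
#' @export
pfo_observed_rate <- function(rates, P0) {
  a <- rates$k1 * P0
  b <- rates$k_minus1
  c2 <- rates$k2
  tr <- a + b + c2
  (tr - sqrt(tr^2 - 4 * a * c2)) / 2
}
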