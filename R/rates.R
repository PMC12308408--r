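#' Rate constants of the two-step self-labeling scheme
#'
#' A self-labeling tag reacts with its substrate in two steps: reversible
#' binding of substrate S to protein P forming the noncovalent complex PS
#' (association rate `k1`, dissociation rate `k_minus1`), followed by the
#' irreversible covalent transfer producing the conjugate PS* (rate `k2`):
#'
#' \deqn{P + S \rightleftharpoons PS \rightarrow PS^{*}}
#'
#' @param k1 Bimolecular association rate constant (M^-1 s^-1).
#' @param k_minus1 Dissociation rate constant (s^-1).
#' @param k2 Irreversible covalent-step rate constant (s^-1). May be 0,
#'   representing a binding-only (no covalent transfer) control.
#'
#' @return An object of class `rate_constants`: a named list with elements
#'   `k1`, `k_minus1`, `k2`.
#'
#' @examples
#' rates <- rate_constants(k1 = 4e5, k_minus1 = 0.3, k2 = 0.025)
#' derived_kd(rates)
#' derived_kapp(rates)
#' @export
rate_constants <- function(k1, k_minus1, k2) {
  vals <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2)
  if (!all(is.finite(vals)) || k1 <= 0 || k_minus1 <= 0 || k2 < 0) {
    abort(paste("rate constants must be finite with k1, k_minus1 > 0",
                "and k2 >= 0"),
          class = "tagkin_invalid_rates")
  }
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Two-step self-labeling rate constants\n")
  cat(sprintf("  k1      = %.4g M^-1 s^-1\n", x$k1))
  cat(sprintf("  k_minus1= %.4g s^-1\n", x$k_minus1))
  cat(sprintf("  k2      = %.4g s^-1\n", x$k2))
  cat(sprintf("  Kd      = %.4g M, kapp = %.4g M^-1 s^-1\n",
              derived_kd(x), derived_kapp(x)))
  invisible(x)
}

#' Dissociation constant of the binding step
#'
#' `Kd = k_minus1 / k1`, the equilibrium dissociation constant of the
#' noncovalent protein-substrate complex.
#'
#' @param rates A [rate_constants()] object.
#' @return Kd in molar.
#' @export
derived_kd <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  rates$k_minus1 / rates$k1
}

#' Apparent second-order labeling rate constant
#'
#' Under pseudo-first-order conditions the two-step scheme labels with an
#' apparent second-order rate constant
#' \deqn{k_{app} = \frac{k_1 k_2}{k_2 + k_{-1}},}
#' the rate at which substrate is committed to the covalent product per molar
#' of excess protein. `kapp` is bounded above by `k1` (binding-limited) and
#' approaches `k2 / Kd` in the rapid-equilibrium limit.
#'
#' @param rates A [rate_constants()] object.
#' @return kapp in M^-1 s^-1.
#' @export
derived_kapp <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  rates$k1 * rates$k2 / (rates$k2 + rates$k_minus1)
}

#' Labeling half-time at a given protein concentration
#'
#' Under pseudo-first-order conditions (protein in excess over substrate) the
#' covalent product rises as a single exponential with observed rate
#' `kapp * [P]`, so the half-time of labeling is
#' \deqn{t_{1/2} = \ln 2 / (k_{app} [P]).}
#' The relation assumes at least ~4-fold protein excess; at lower excess the
#' observed curve is no longer a clean single exponential.
#'
#' @param kapp Apparent second-order labeling rate (M^-1 s^-1).
#' @param protein_conc Protein concentration (M).
#' @return Half-time in seconds.
#'
#' @examples
#' half_time(6.8e4, 200e-9)  # ~51 s
#' @export
half_time <- function(kapp, protein_conc) {
  stopifnot(is.numeric(kapp), is.numeric(protein_conc))
  if (any(kapp <= 0) || any(protein_conc <= 0)) {
    abort("kapp and protein_conc must be positive", class = "tagkin_bad_arg")
  }
  log(2) / (kapp * protein_conc)
}

#' Apparent rate constant from an observed pseudo-first-order rate
#'
#' Divides the observed single-exponential rate by the (excess) protein
#' concentration: `kapp = kobs / [P]`.
#'
#' @param kobs Observed first-order rate (s^-1).
#' @param protein_conc Protein concentration (M).
#' @return kapp in M^-1 s^-1.
#' @export
kapp_from_kobs <- function(kobs, protein_conc) {
  stopifnot(is.numeric(kobs), is.numeric(protein_conc))
  if (any(kobs <= 0) || any(protein_conc <= 0)) {
    abort("kobs and protein_conc must be positive", class = "tagkin_bad_arg")
  }
  kobs / protein_conc
}

#' Derived kinetic parameters from rate constants
#'
#' @param rates A [rate_constants()] object.
#' @param protein_conc Optional protein concentration (M) at which to report
#'   the labeling half-time.
#' @return A one-row tibble with `Kd`, `kapp`, and (if `protein_conc` is
#'   given) `t_half`.
#' @export
derived_params <- function(rates, protein_conc = NULL) {
  kapp <- derived_kapp(rates)
  out <- tibble(
    Kd = derived_kd(rates),
    kapp = kapp
  )
  if (!is.null(protein_conc)) {
    out$t_half <- half_time(kapp, protein_conc)
    out$protein_conc_M <- protein_conc
  }
  out
}
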