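#' Reference-normalize a labeling time course
#'
#' Divides the signal-channel integrated density by the reference channel
#' frame by frame (cancelling shared photobleaching and illumination drift),
#' then rescales so the first frame equals 1. Subtraction of the reference is
#' available as an option since division is a modelling choice, not a law.
#'
#' @param data A tibble with columns `time_min`, `signal`, `reference`
#'   (integrated densities), e.g. from [gen_cell_timecourse()] or
#'   [read_trace_table()].
#' @param method `"divide"` (default) or `"subtract"`.
#' @return The tibble with a `normalized` column (first frame = 1).
#' @export
normalize_timecourse <- function(data, method = c("divide", "subtract")) {
  stopifnot(is.data.frame(data),
            all(c("time_min", "signal", "reference") %in% names(data)))
  method <- match.arg(method)
  if (any(data$reference <= 0)) {
    abort("reference channel must be positive in every frame",
          class = "tagkin_bad_reference")
  }
  corrected <- switch(method,
    divide = data$signal / data$reference,
    subtract = data$signal - data$reference)
  if (corrected[1] == 0) {
    abort("first frame is zero after correction: cannot rescale",
          class = "tagkin_bad_reference")
  }
  data$normalized <- corrected / corrected[1]
  data
}

#' Fold increase of a normalized labeling time course
#'
#' The last-frame value of a series normalized to 1 at the first frame,
#' together with a plateau flag: the curve is considered still rising
#' (plateau = FALSE) when both of the last two inter-frame increments exceed
#' 5% of the observed range.
#'
#' @param data A tibble with a `normalized` column (see
#'   [normalize_timecourse()]), or a bare numeric series.
#' @return A one-row tibble: `fold_increase`, `plateau`.
#' @export
fold_increase <- function(data) {
  y <- if (is.data.frame(data)) data$normalized else as.numeric(data)
  if (is.null(y)) {
    abort("normalize the time course first (no `normalized` column)",
          class = "tagkin_bad_arg")
  }
  if (length(y) < 3) {
    abort("fold increase needs at least 3 frames", class = "tagkin_bad_arg")
  }
  rng <- diff(range(y))
  inc <- diff(tail(y, 3))
  still_rising <- rng > 0 && all(inc > 0.05 * rng)
  tibble(fold_increase = tail(y, 1), plateau = !still_rising)
}

#' Fit a labeling half-life to a normalized cell time course
#'
#' Fits a monoexponential association with floating plateau,
#' `y(t) = y0 + A * (1 - exp(-k t))`, to the reference-normalized integrated
#' density, with `t = 0` defined by the decaging light pulse. The labeling
#' half-life is `ln 2 / k`. Fits are flagged unreliable when the half-life
#' exceeds 5x the observation window (rate not resolved) or when the fitted
#' intercept deviates more than 10% of the amplitude from the first frame
#' (suggesting the time origin is off).
#'
#' @param data A tibble with `time_min` and `normalized` columns (run
#'   [normalize_timecourse()] first if needed); >= 5 frames. If several
#'   replicates are present (`replicate` column), they are averaged framewise
#'   before fitting.
#' @return An object of class `labeling_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods; key fields `t_half` (min), `plateau`, `reliable`.
#'
#' @examples
#' tc <- gen_cell_timecourse(t_half = 4.6, seed = 1)
#' fit <- fit_labeling_halflife(normalize_timecourse(tc))
#' glance(fit)
#' @export
fit_labeling_halflife <- function(data) {
  stopifnot(is.data.frame(data), "time_min" %in% names(data))
  if (!"normalized" %in% names(data)) {
    if (all(c("signal", "reference") %in% names(data))) {
      data <- normalize_timecourse(data)
    } else {
      abort("need a `normalized` column or `signal` + `reference`",
            class = "tagkin_bad_arg")
    }
  }
  if ("replicate" %in% names(data) && length(unique(data$replicate)) > 1) {
    data <- data |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(normalized = mean(.data$normalized), .groups = "drop")
  }
  t <- data$time_min
  y <- data$normalized
  if (length(t) < 5) {
    abort("labeling fit needs at least 5 frames", class = "tagkin_bad_arg")
  }
  if (t[1] < 0) {
    abort("time must start at the decaging event (t >= 0)",
          class = "tagkin_bad_arg")
  }
  window <- max(t) - min(t)
  k0 <- guess_kobs(t, y)
  # relative least squares (weights 1/y^2): the maximum-likelihood weighting
  # for the multiplicative noise of ratio-normalized intensity data
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A * (1 - exp(-k * t)),
                      data = list(t = t, y = y),
                      start = list(y0 = y[1], A = tail(y, 1) - y[1],
                                   k = if (is.finite(k0)) k0 else log(2) / window),
                      weights = 1 / pmax(y, 0.05 * max(abs(y)))^2,
                      lower = c(-Inf, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  out <- list(data = tibble(time_min = t, normalized = y), window = window,
              n = length(t))
  class(out) <- "labeling_fit"
  if (is.null(fit) || coef(fit)[["k"]] <= 0) {
    out$converged <- FALSE
    out$t_half <- out$rate <- out$plateau <- out$intercept <- NA_real_
    out$reliable <- FALSE
    out$flags <- "non-convergence"
    return(out)
  }
  cf <- coef(fit)
  out$converged <- TRUE
  out$rate <- cf[["k"]]
  out$t_half <- log(2) / cf[["k"]]
  out$intercept <- cf[["y0"]]
  out$amplitude <- cf[["A"]]
  out$plateau <- cf[["y0"]] + cf[["A"]]
  out$sigma <- sqrt(sum(residuals(fit)^2) / max(1, length(t) - 3))
  out$model <- fit
  flags <- character()
  if (out$t_half > 5 * window) flags <- c(flags, "half-life beyond 5x window")
  if (abs(out$intercept - y[1]) > 0.1 * max(abs(out$amplitude),
                                            .Machine$double.eps)) {
    flags <- c(flags, "intercept deviates >10% from first frame")
  }
  out$flags <- if (length(flags)) paste(flags, collapse = "; ") else NA_character_
  out$reliable <- length(flags) == 0
  out
}

#' @export
print.labeling_fit <- function(x, ...) {
  cat("Labeling half-life fit\n")
  if (!isTRUE(x$converged)) {
    cat("  fit did not converge\n")
  } else {
    cat(sprintf("  t1/2 = %.2f min (rate %.4g min^-1), plateau %.2f\n",
                x$t_half, x$rate, x$plateau))
    if (!x$reliable) cat("  flagged unreliable:", x$flags, "\n")
  }
  invisible(x)
}

#' @method tidy labeling_fit
#' @export
tidy.labeling_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble(term = c("y0", "A", "k"), estimate = NA_real_,
                  std.error = NA_real_))
  }
  cf <- coef(x$model)
  se <- tryCatch(sqrt(diag(vcov(x$model))),
                 error = function(e) rep(NA_real_, length(cf)))
  tibble(term = names(cf), estimate = unname(cf), std.error = unname(se))
}

#' @method glance labeling_fit
#' @export
glance.labeling_fit <- function(x, ...) {
  tibble(t_half = x$t_half, rate = x$rate,
         plateau = if (isTRUE(x$converged)) x$plateau else NA_real_,
         reliable = isTRUE(x$reliable), sigma = x$sigma %||% NA_real_,
         n = x$n, converged = isTRUE(x$converged))
}

#' @method autoplot labeling_fit
#' @export
autoplot.labeling_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$normalized)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time after decaging (min)",
                  y = "normalized integrated density",
                  subtitle = if (isTRUE(object$converged)) {
                    sprintf("t½ = %.1f min", object$t_half)
                  } else "fit did not converge")
  if (isTRUE(object$converged)) {
    tt <- seq(min(d$time_min), max(d$time_min), length.out = 200)
    fit_d <- tibble(time_min = tt,
                    normalized = object$intercept +
                      object$amplitude * (1 - exp(-object$rate * tt)))
    p <- p + ggplot2::geom_line(data = fit_d, colour = "firebrick")
  }
  p
}

check_region_table <- function(data) {
  need <- c("cell_id", "region", "channel", "mean_intensity",
            "integrated_density")
  if (!all(need %in% names(data))) {
    abort(paste("region table needs columns:", paste(need, collapse = ", ")),
          class = "tagkin_missing_columns")
  }
  if (any(data$integrated_density < 0)) {
    abort("integrated density must be >= 0", class = "tagkin_bad_table")
  }
  invisible(data)
}

#' Per-cell nuclear intensity ratio between two channels
#'
#' For each cell, the mean nuclear intensity of the signal channel divided by
#' the mean nuclear intensity of the reference channel (e.g. SNAP over
#' HaloTag, so that expression level cancels). The cohort is summarized by
#' the median and interquartile range, robust to the long-tailed per-cell
#' expression distribution.
#'
#' @param data A region table: columns `cell_id`, `region`, `channel`,
#'   `mean_intensity`, `integrated_density` (long format).
#' @param signal_channel,reference_channel Channel names (defaults "SNAP",
#'   "HT7").
#' @return A list with `per_cell` (tibble `cell_id`, `ratio`) and `summary`
#'   (one-row tibble: `median`, `iqr`, `q25`, `q75`, `n`).
#' @export
nuclear_ratio <- function(data, signal_channel = "SNAP",
                          reference_channel = "HT7") {
  check_region_table(data)
  nuc <- data[data$region == "nucleus", ]
  wide <- nuc |>
    dplyr::select("cell_id", "channel", "mean_intensity") |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = "mean_intensity")
  if (!all(c(signal_channel, reference_channel) %in% names(wide))) {
    abort("both channels must be present for every nucleus",
          class = "tagkin_missing_channel")
  }
  ref <- wide[[reference_channel]]
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    abort("reference-channel nuclear intensity must be positive",
          class = "tagkin_bad_reference")
  }
  per_cell <- tibble(cell_id = wide$cell_id,
                     ratio = wide[[signal_channel]] / ref)
  qs <- quantile(per_cell$ratio, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_cell = per_cell,
       summary = tibble(median = qs[2], iqr = qs[3] - qs[1],
                        q25 = qs[1], q75 = qs[3], n = nrow(per_cell)))
}

#' Amber-suppression efficiency from nuclear / whole-cell partitioning
#'
#' For each cell, the fraction of the reference-tag (HaloTag) integrated
#' density found in the nucleus relative to the whole cell. With the
#' full-length read-through product carrying a nuclear localization signal
#' and the prematurely terminated fragment staying cytosolic, this fraction
#' estimates the amber-suppression efficiency per cell. Values lie in [0, 1];
#' the cohort is summarized as mean +/- SD.
#'
#' @param data A region table with `nucleus` and `whole_cell` rows per cell.
#' @param channel Channel to use (default "HT7").
#' @return A list with `per_cell` (tibble `cell_id`, `efficiency`) and
#'   `summary` (one-row tibble: `mean`, `sd`, `n`).
#' @export
amber_suppression_efficiency <- function(data, channel = "HT7") {
  check_region_table(data)
  d <- data[data$channel == channel, ]
  wide <- d |>
    dplyr::select("cell_id", "region", "integrated_density") |>
    tidyr::pivot_wider(names_from = "region",
                       values_from = "integrated_density")
  if (!all(c("nucleus", "whole_cell") %in% names(wide))) {
    abort("need nucleus and whole_cell rows for every cell",
          class = "tagkin_missing_region")
  }
  if (any(wide$nucleus > wide$whole_cell * (1 + 1e-12))) {
    abort("nuclear integrated density exceeds whole-cell value",
          class = "tagkin_bad_table")
  }
  per_cell <- tibble(cell_id = wide$cell_id,
                     efficiency = wide$nucleus / wide$whole_cell)
  list(per_cell = per_cell,
       summary = tibble(mean = mean(per_cell$efficiency),
                        sd = sd(per_cell$efficiency),
                        n = nrow(per_cell)))
}
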