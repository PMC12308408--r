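with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# normal draw truncated to [lo, hi] by rejection (cheap at these scales)
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic fluorescence-polarization association trace
#'
#' Emulates the standard polarization assay design: 50 nM fluorescent
#' benzylguanine substrate mixed with 200 nM tag protein, signal sampled
#' every 2 s. The polarization rises monoexponentially with observed rate
#' `kobs = kapp * active_fraction * [P]`. `active_fraction` models incomplete
#' photoactivation (caged or photochemically dead protein); 0 yields the flat
#' trace of a fully caged variant.
#'
#' @param kapp True apparent labeling rate (M^-1 s^-1).
#' @param protein_conc,substrate_conc Concentrations (M).
#' @param active_fraction Fraction of reactive (decaged) protein in [0, 1].
#' @param amplitude,offset Polarization amplitude and starting level.
#' @param noise_sd Additive Gaussian noise SD, polarization units (default
#'   2% of the amplitude).
#' @param window Measurement duration (s).
#' @param pitch Sampling interval (s).
#' @param label Trace label.
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A trace tibble (see [fp_trace()]).
#' @export
gen_fp_trace <- function(kapp = 6.8e4, protein_conc = 200e-9,
                         substrate_conc = 50e-9, active_fraction = 1,
                         amplitude = 0.15, offset = 0.05,
                         noise_sd = 0.02 * amplitude,
                         window = 1500, pitch = 2,
                         label = "synthetic", seed = NULL) {
  stopifnot(active_fraction >= 0, active_fraction <= 1)
  t <- seq(0, window, by = pitch)
  kobs <- kapp * active_fraction * protein_conc
  y_true <- if (kobs > 0) offset + amplitude * (1 - exp(-kobs * t))
            else rep(offset, length(t))
  with_seed_maybe(seed, {
    y <- y_true + rnorm(length(t), 0, noise_sd)
    fp_trace(t, y, protein_conc, substrate_conc, label)
  })
}

#' Generate a synthetic stopped-flow trace family with baseline
#'
#' Emulates the stopped-flow design: 25 nM substrate mixed 1:1 with excess
#' protein at a series of final concentrations (0.1-2.5 uM standard), signal
#' `F(t) = offset_j + response * ([PS] + [PS*])` with species from the
#' two-step scheme, an instrument mixing delay blanking the first
#' milliseconds, replicate recordings per condition, and a protein-free
#' substrate baseline (optionally drifting) added to every trace.
#'
#' @param rates True [rate_constants()]. The default (`k1 = 4e5` M^-1 s^-1,
#'   `k_minus1 = 0.3` s^-1, `k2 = 0.025` s^-1, so `kapp = 3.1e4` M^-1 s^-1)
#'   sits in the middle of the reported self-labeling range with
#'   half-saturation inside the concentration series.
#' @param protein_concs Final protein concentrations (M).
#' @param substrate_conc Final substrate concentration (M).
#' @param active_fraction Fraction of reactive protein (scales the effective
#'   protein concentration).
#' @param mixing_delay Instrument mixing delay (s).
#' @param response Response coefficient (signal per molar bound substrate).
#' @param offsets Per-trace signal offsets (recycled); small random values
#'   by default.
#' @param baseline_level,baseline_drift Free-substrate baseline level and
#'   linear drift (signal units, units/s) added to every trace and returned
#'   as the baseline recording.
#' @param noise_sd Additive Gaussian noise SD in signal units (default 2% of
#'   the full amplitude `response * substrate_conc`).
#' @param n_replicates Replicate recordings per condition (5-8 typical).
#' @param times Shared time grid (s); by default 161 points covering ~4
#'   half-lives of the slowest trace.
#' @param seed Integer seed.
#' @return A list: `traces` (tidy trace table, replicates marked),
#'   `baseline` (protein-free trace), `truth` (generating parameters).
#' @export
gen_sf_family <- function(rates = rate_constants(4e5, 0.3, 0.025),
                          protein_concs = c(0.1, 0.25, 0.5, 1, 2.5) * 1e-6,
                          substrate_conc = 25e-9, active_fraction = 1,
                          mixing_delay = 0.0015, response = 1e7,
                          offsets = NULL, baseline_level = 0.02,
                          baseline_drift = 0,
                          noise_sd = 0.02 * response * substrate_conc,
                          n_replicates = 1, times = NULL, seed = NULL) {
  stopifnot(inherits(rates, "rate_constants"), length(protein_concs) >= 2)
  P_eff <- protein_concs * active_fraction
  if (is.null(times)) {
    # logarithmic sampling from just past the mixing delay out to ~4
    # half-lives of the slowest trace, covering every trace's rise on one
    # shared grid (standard stopped-flow acquisition)
    slow <- pfo_observed_rate(rates, min(P_eff))
    t_start <- max(2 * mixing_delay, 2e-3)
    times <- c(0, exp(seq(log(t_start), log(4 / slow), length.out = 160)))
  }
  with_seed_maybe(seed, {
    if (is.null(offsets)) {
      offsets <- runif(length(protein_concs), 0, 0.1 * response * substrate_conc)
    }
    offsets <- rep_len(offsets, length(protein_concs))
    base_true <- baseline_level + baseline_drift * times
    traces <- purrr::imap(protein_concs, function(P, j) {
      clean <- predict_sf_trace(rates, P_eff[j], substrate_conc, times,
                                mixing_delay, offsets[j], response)
      purrr::map(seq_len(n_replicates), function(r) {
        y <- clean$fluorescence + base_true +
          rnorm(length(times), 0, noise_sd)
        sf_trace(times, y, P, substrate_conc,
                 trace_id = sprintf("P%g_nM", P * 1e9), replicate = r)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    baseline <- sf_trace(times,
                         base_true + rnorm(length(times), 0, noise_sd),
                         protein_conc_M = 0, substrate_conc = substrate_conc,
                         trace_id = "baseline")
    list(traces = traces, baseline = baseline,
         truth = list(rates = rates, response = response, offsets = offsets,
                      mixing_delay = mixing_delay,
                      active_fraction = active_fraction,
                      kapp = derived_kapp(rates), noise_sd = noise_sd,
                      baseline_level = baseline_level,
                      baseline_drift = baseline_drift))
  })
}

#' Generate a synthetic live-cell labeling time course
#'
#' Emulates wash-free time-lapse labeling after a decaging light pulse
#' (t = 0): the signal-channel integrated density rises monoexponentially
#' with the configured half-life on top of a reference channel, both
#' optionally decaying with a shared photobleaching factor (which cancels on
#' normalization) and carrying independent multiplicative noise.
#'
#' @param t_half True labeling half-life (min).
#' @param amplitude Amplitude of the normalized rise (plateau = 1 +
#'   amplitude; the default 2 gives the ~3-fold signal increase seen for
#'   nuclear labeling over 30 min).
#' @param sampling Frame interval (min), 2 or 4 in the standard designs.
#' @param window Observation window (min).
#' @param reference_level Reference-channel integrated density scale.
#' @param noise_cv Multiplicative (lognormal) noise CV per frame on the
#'   signal channel.
#' @param ref_noise_cv Independent noise CV on the reference channel
#'   (defaults to `noise_cv`).
#' @param bleach_rate Shared photobleaching rate (min^-1) applied to both
#'   channels.
#' @param n_replicates Number of replicate cells/fields.
#' @param time_shift Delay (min) between the decaging event and the first
#'   recorded frame: frames are stamped with their true (absolute) times
#'   starting at `time_shift`, emulating a recording that started late
#'   (0 = recording starts at the light pulse).
#' @param seed Integer seed.
#' @return A tibble: `time_min`, `signal`, `reference`, `replicate`.
#' @export
gen_cell_timecourse <- function(t_half = 4.6, amplitude = 2, sampling = 2,
                                window = 40, reference_level = 1e6,
                                noise_cv = 0.05, ref_noise_cv = noise_cv,
                                bleach_rate = 0, n_replicates = 1,
                                time_shift = 0, seed = NULL) {
  stopifnot(t_half > 0, sampling > 0, window > sampling, time_shift >= 0)
  t <- seq(time_shift, window, by = sampling)
  k <- log(2) / t_half
  y_true <- 1 + amplitude * (1 - exp(-k * t))
  bleach <- exp(-bleach_rate * t)
  sdlog <- sqrt(log(1 + noise_cv^2))
  sdlog_ref <- sqrt(log(1 + ref_noise_cv^2))
  with_seed_maybe(seed, {
    purrr::map(seq_len(n_replicates), function(r) {
      ref <- reference_level * bleach *
        rlnorm(length(t), -sdlog_ref^2 / 2, sdlog_ref)
      sig <- reference_level * y_true * bleach *
        rlnorm(length(t), -sdlog^2 / 2, sdlog)
      tibble(time_min = t, signal = sig, reference = ref, replicate = r)
    }) |> purrr::list_rbind()
  })
}

#' Generate a synthetic per-cell region intensity table
#'
#' Emulates the per-cell measurements exported from segmented time-lapse /
#' endpoint images: for each cell, nucleus and whole-cell rows with area,
#' mean intensity and integrated density in a labeling channel ("SNAP") and
#' an orthogonal expression-control channel ("HT7"). Per-cell expression is
#' lognormal and shared between channels; the fraction of the control
#' channel's integrated density in the nucleus is drawn from a truncated
#' normal (the amber-suppression efficiency observable); `caged_fraction`
#' scales the labeling channel down per cell, emulating incomplete decaging
#' (1 = fully caged, labeling at background).
#'
#' @param n_cells Number of cells (cohort sizes of 40-136 typical).
#' @param nuclear_fraction_mean,nuclear_fraction_sd Mean and SD of the
#'   per-cell nuclear fraction of the control channel (defaults 0.64, 0.11).
#' @param expression_meanlog,expression_sdlog Lognormal per-cell expression.
#' @param snap_per_ht7 Labeling-channel mean intensity per unit
#'   control-channel mean intensity at full decaging.
#' @param caged_fraction Fraction of labeling signal lost to caging in
#'   [0, 1].
#' @param background Background mean intensity, both channels.
#' @param noise_cv Multiplicative per-measurement noise CV.
#' @param whole_area,nucleus_area_fraction Cell geometry (pixels, fraction).
#' @param seed Integer seed.
#' @return A long tibble: `cell_id`, `region`, `channel`, `area`,
#'   `mean_intensity`, `integrated_density`.
#' @export
gen_region_table <- function(n_cells = 40, nuclear_fraction_mean = 0.64,
                             nuclear_fraction_sd = 0.11,
                             expression_meanlog = log(1e3),
                             expression_sdlog = 0.5,
                             snap_per_ht7 = 1, caged_fraction = 0,
                             background = 1, noise_cv = 0.05,
                             whole_area = 400, nucleus_area_fraction = 0.3,
                             seed = NULL) {
  stopifnot(caged_fraction >= 0, caged_fraction <= 1, n_cells >= 1)
  sdlog <- sqrt(log(1 + noise_cv^2))
  mnoise <- function(n) rlnorm(n, -sdlog^2 / 2, sdlog)
  with_seed_maybe(seed, {
    expr <- rlnorm(n_cells, expression_meanlog, expression_sdlog)
    nf <- rtruncnorm(n_cells, nuclear_fraction_mean, nuclear_fraction_sd)
    nuc_area <- whole_area * nucleus_area_fraction
    # control channel: whole-cell integrated density = expression;
    # nuclear share = nf exactly (the generating observable)
    ht7_whole_int <- expr * whole_area
    ht7_nuc_int <- nf * ht7_whole_int
    ht7_nuc_mean <- ht7_nuc_int / nuc_area
    ht7_whole_mean <- ht7_whole_int / whole_area
    # labeling channel tracks the nuclear control signal, scaled by decaging
    snap_nuc_mean <- background +
      (1 - caged_fraction) * snap_per_ht7 * ht7_nuc_mean * mnoise(n_cells)
    snap_nuc_int <- snap_nuc_mean * nuc_area
    # whole cell = nuclear signal + cytosolic background (keeps the
    # whole-cell >= nucleus invariant)
    snap_whole_int <- snap_nuc_int +
      background * (whole_area - nuc_area) * mnoise(n_cells)
    snap_whole_mean <- snap_whole_int / whole_area
    cell_id <- sprintf("cell_%03d", seq_len(n_cells))
    rows <- list(
      tibble(cell_id = cell_id, region = "nucleus", channel = "HT7",
             area = nuc_area, mean_intensity = ht7_nuc_mean,
             integrated_density = ht7_nuc_int),
      tibble(cell_id = cell_id, region = "whole_cell", channel = "HT7",
             area = whole_area, mean_intensity = ht7_whole_mean,
             integrated_density = ht7_whole_int),
      tibble(cell_id = cell_id, region = "nucleus", channel = "SNAP",
             area = nuc_area, mean_intensity = snap_nuc_mean,
             integrated_density = snap_nuc_int),
      tibble(cell_id = cell_id, region = "whole_cell", channel = "SNAP",
             area = whole_area, mean_intensity = snap_whole_mean,
             integrated_density = snap_whole_int)
    )
    purrr::list_rbind(rows) |> dplyr::arrange(.data$cell_id, .data$region)
  })
}
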