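detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a kinetic trace table from delimited text
#'
#' Reads comma- or tab-delimited text (dialect auto-detected) with a header
#' whose column names carry unit suffixes (`time_s` or `time_min`; signal
#' columns such as `polarization`, `fluorescence`, `signal`, `reference`;
#' concentrations as `*_conc_M` or `*_M`). Validation failures raise named
#' conditions: `tagkin_missing_columns`, `tagkin_nonmonotone_time`,
#' `tagkin_missing_units`.
#'
#' @param path File path.
#' @return A tibble of validated records, as written by [write_trace_table()]
#'   or produced by the generators.
#' @export
read_trace_table <- function(path) {
  d <- readr::read_delim(path, delim = detect_delim(path),
                         show_col_types = FALSE, progress = FALSE)
  time_col <- intersect(c("time_s", "time_min"), names(d))
  if (length(time_col) == 0) {
    if (any(grepl("^time($|_)", names(d)))) {
      abort("time column lacks a unit suffix (expected time_s or time_min)",
            class = "tagkin_missing_units")
    }
    abort("no time column (time_s or time_min) found",
          class = "tagkin_missing_columns")
  }
  sig_cols <- intersect(c("polarization", "fluorescence", "signal",
                          "normalized"), names(d))
  if (length(sig_cols) == 0) {
    abort("no signal column (polarization / fluorescence / signal) found",
          class = "tagkin_missing_columns")
  }
  grp <- intersect(c("trace_id", "replicate", "label"), names(d))
  check_one <- function(x) {
    if (any(diff(x[[time_col[1]]]) <= 0)) {
      abort("time column is not strictly increasing",
            class = "tagkin_nonmonotone_time")
    }
  }
  if (length(grp)) {
    invisible(lapply(split(d, d[grp], drop = TRUE), check_one))
  } else {
    check_one(d)
  }
  as_tibble(d)
}

#' Read a per-cell region intensity table from delimited text
#'
#' Expects the long region-table layout: `cell_id`, `region`
#' (nucleus / whole_cell), `channel`, `area`, `mean_intensity`,
#' `integrated_density`.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_region_table <- function(path) {
  d <- readr::read_delim(path, delim = detect_delim(path),
                         show_col_types = FALSE, progress = FALSE)
  check_region_table(d)
  as_tibble(d)
}

#' Write a trace or region table as delimited text
#'
#' @param data A tibble from the generators or readers.
#' @param path Output path; `.tsv` extension selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(data, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Write a fit report: parameter table plus plain-text summary
#'
#' Collects fit results (any mix of `fp_fit`, `sf_fit`, `labeling_fit`) into
#' one delimited parameter table (one row per fit; "n.d." printed where a
#' rate was not determinable) and a short human-readable summary, with a
#' provenance header (package version, date, seed if supplied).
#'
#' @param results A list of fit objects (possibly named).
#' @param path Output path for the parameter table (a `.txt` summary is
#'   written alongside).
#' @param seed Optional seed to record in the provenance header.
#' @return The report tibble, invisibly.
#' @export
write_fit_report <- function(results, path, seed = NULL) {
  stopifnot(is.list(results))
  rows <- purrr::imap(results, function(r, nm) {
    label <- if (is.character(nm) && nzchar(nm)) nm else NA_character_
    if (inherits(r, "fp_fit")) {
      g <- glance(r)
      tibble(label = label %||% g$label, type = "fp",
             kobs = g$kobs, kapp = g$kapp, t_half_s = g$t_half,
             k1 = NA_real_, k_minus1 = NA_real_, k2 = NA_real_,
             Kd = NA_real_, determinable = g$determinable)
    } else if (inherits(r, "sf_fit")) {
      g <- glance(r)
      tibble(label = label, type = "stopped_flow",
             kobs = NA_real_, kapp = g$kapp,
             t_half_s = NA_real_, k1 = g$k1, k_minus1 = g$k_minus1,
             k2 = g$k2, Kd = g$Kd, determinable = g$converged)
    } else if (inherits(r, "labeling_fit")) {
      g <- glance(r)
      tibble(label = label, type = "cell_timecourse",
             kobs = g$rate / 60, kapp = NA_real_,
             t_half_s = g$t_half * 60, k1 = NA_real_, k_minus1 = NA_real_,
             k2 = NA_real_, Kd = NA_real_, determinable = g$reliable)
    } else {
      abort("unsupported result type in report", class = "tagkin_bad_arg")
    }
  })
  report <- purrr::list_rbind(rows)
  if (nrow(report) == 0) {
    report <- tibble(label = character(), type = character(),
                     kobs = numeric(), kapp = numeric(),
                     t_half_s = numeric(), k1 = numeric(),
                     k_minus1 = numeric(), k2 = numeric(), Kd = numeric(),
                     determinable = logical())
  }
  printable <- report
  num <- vapply(printable, is.numeric, logical(1))
  printable[num] <- lapply(printable[num], function(x) {
    out <- ifelse(is.finite(x), formatC(x, digits = 4, format = "g"), "n.d.")
    ifelse(is.na(x), "n.d.", out)
  })
  header <- c(
    sprintf("# tagkin %s fit report", as.character(utils::packageVersion("tagkin"))),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(seed)) sprintf("# seed: %d", seed))
  writeLines(header, path)
  suppressWarnings(
    readr::write_delim(printable, path, delim = "\t", append = TRUE,
                       col_names = TRUE))
  summary_path <- sub("\\.[a-z]+$", "", path)
  writeLines(c(header, "",
               utils::capture.output(print(as.data.frame(printable)))),
             paste0(summary_path, "_summary.txt"))
  invisible(report)
}

#' Published self-labeling kinetics of SNAP variants (polarization assay)
#'
#' The reference grid of apparent labeling rate constants and half-times for
#' SNAP, its photocaged Y114/Y158 variants and their HaloTag fusions, with
#' BG-OG and SBG-OG substrates, before ("-") and after ("+") irradiation, as
#' determined by fluorescence-polarization association at 200 nM protein and
#' 50 nM substrate. `kapp` is `NA` where the association was too slow to fit
#' ("n.d.").
#'
#' @return A tibble: `variant`, `substrate`, `irradiated`, `kapp`
#'   (M^-1 s^-1), `t_half` (s), `determinable`.
#' @export
fp_reference_kinetics <- function() {
  variants <- c("SNAP", "SNAP-Y114ONBY", "SNAP-Y158ONBY",
                "SNAP-HT7", "SNAP-Y114ONBY-HT7", "SNAP-Y158ONBY-HT7")
  grid <- tibble(
    substrate = rep(c("BG-OG", "BG-OG", "SBG-OG", "SBG-OG"), each = 6),
    irradiated = rep(c("-", "+", "-", "+"), each = 6),
    variant = rep(variants, 4),
    kapp = c(6.8e4, NA, NA, 4.3e4, NA, NA,
             4.6e4, 2.3e4, 1.6e4, 3.0e4, 1.3e4, 0.5e4,
             1.5e4, NA, NA, 0.9e4, NA, NA,
             1.1e4, 0.6e4, 0.4e4, 0.8e4, 0.7e4, 0.4e4),
    t_half = c(51, NA, NA, 81, NA, NA,
               75, 148, 212, 116, 275, 636,
               231, NA, NA, 398, NA, NA,
               321, 533, 821, 420, 521, 904)
  )
  grid$determinable <- !is.na(grid$kapp)
  grid
}

# rounding interval of a printed kapp value: one unit in the last printed
# digit (values are printed as multiples of 0.1e4)
kapp_print_interval <- function(kapp, step = 0.1e4) {
  c(lo = kapp - step / 2, hi = kapp + step / 2)
}

#' Consistency of printed kapp / half-time pairs
#'
#' Checks every determinable (kapp, t_half) pair of a reference grid against
#' the pseudo-first-order relation `t_half = ln 2 / (kapp [P])`, respecting
#' the precision both numbers are printed at. Each cell is classified:
#' * `exact` - `ln 2 / (kapp [P])` rounded to the nearest second equals the
#'   printed half-time;
#' * `consistent` - not exact, but some kapp within the printed value's
#'   rounding interval reproduces the printed half-time (the mismatch is
#'   printing precision, not arithmetic);
#' * `inconsistent` - otherwise.
#'
#' @param reference A grid as from [fp_reference_kinetics()].
#' @param protein_conc Protein concentration of the assay (M).
#' @param kapp_step Printing resolution of kapp (default 0.1e4 M^-1 s^-1).
#' @return The grid with `t_half_implied`, `rel_dev` and `status` columns.
#' @export
halftime_consistency <- function(reference = fp_reference_kinetics(),
                                 protein_conc = 200e-9, kapp_step = 0.1e4) {
  d <- reference[reference$determinable, ]
  d$t_half_implied <- half_time(d$kapp, protein_conc)
  d$rel_dev <- abs(d$t_half_implied - d$t_half) / d$t_half
  d$status <- purrr::map2_chr(d$kapp, d$t_half, function(k, th) {
    if (round(half_time(k, protein_conc)) == th) return("exact")
    iv <- kapp_print_interval(k, kapp_step)
    # half-time is decreasing in kapp: the attainable printed range is
    # [round(t(hi)), round(t(lo))]
    lo_t <- round(half_time(iv[["hi"]], protein_conc))
    hi_t <- round(half_time(iv[["lo"]], protein_conc))
    if (th >= lo_t && th <= hi_t) "consistent" else "inconsistent"
  })
  d
}
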