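#' Fit log-log power-law calibration curves
#'
#' ELSD response is a power law in concentration, `A = 10^b * C^F`, so the
#' calibration model is an ordinary least-squares straight line in log-log
#' coordinates: `lg A = F * lg C + b` with `lg` the base-10 logarithm. One
#' curve is fitted per analyte.
#'
#' @param data A data frame of calibration levels with columns `analyte_id`,
#'   `concentration` (mass concentration, ug/mL, > 0) and `area` (detector
#'   peak area, > 0). A `level_index` column is optional; when absent, row
#'   order within each analyte defines it.
#' @param min_levels Minimum number of calibration levels per analyte
#'   (default 3). The reference five-point design dilutes a mixed standard
#'   1, 1.5, 2.2, 4 and 10 times.
#'
#' @return A tibble of class `qams_calibration` with one row per analyte:
#'   `analyte_id`, `slope` (F), `intercept` (b), `r_squared`, `range_low`,
#'   `range_high` (ug/mL, the span of the fitted levels) and `n_levels`.
#'
#' @examples
#' cal <- make_calibration_series(detector_model("GF3", 1.82, -1.67), 1180.4)
#' fit_calibration(cal)
#' @export
fit_calibration <- function(data, min_levels = 3) {
  data <- as_calibration_data(data)
  counts <- dplyr::count(data, .data$analyte_id)
  short <- counts$analyte_id[counts$n < min_levels]
  if (length(short) > 0) {
    abort(sprintf(
      "fewer than %d calibration levels for: %s",
      min_levels, paste(short, collapse = ", ")
    ), class = "qams_insufficient_data_error")
  }
  degen <- data |>
    dplyr::summarise(spread = diff(range(.data$concentration)),
                     .by = "analyte_id") |>
    dplyr::filter(.data$spread == 0)
  if (nrow(degen) > 0) {
    abort(sprintf("all concentrations identical for: %s",
                  paste(degen$analyte_id, collapse = ", ")),
          class = "qams_degenerate_design_error")
  }
  out <- data |>
    tidyr::nest(.by = "analyte_id") |>
    dplyr::mutate(fit = purrr::map(.data$data, fit_one_series)) |>
    dplyr::select(!"data") |>
    tidyr::unnest("fit")
  structure(out, class = c("qams_calibration", class(tibble::tibble())))
}

# One analyte: OLS of lg(area) on lg(concentration).
fit_one_series <- function(levels) {
  fit <- lm(log10(area) ~ log10(concentration), data = levels)
  # coefficient of determination computed directly; summary.lm() warns on
  # noiseless (exact power-law) data
  y <- log10(levels$area)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    range_low = min(levels$concentration),
    range_high = max(levels$concentration),
    n_levels = nrow(levels)
  )
}

# Validate and normalise a calibration-level table.
as_calibration_data <- function(data, what = "calibration data") {
  data <- tibble::as_tibble(data)
  if (!"analyte_id" %in% names(data) && all(c("concentration", "area") %in% names(data))) {
    data$analyte_id <- "analyte"
  }
  check_columns(data, c("analyte_id", "concentration", "area"), what)
  for (col in c("concentration", "area")) {
    bad <- which(!is.finite(data[[col]]) | data[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("%s: nonpositive or missing `%s` at row %d",
                    what, col, bad[1]),
            class = "qams_domain_error")
    }
  }
  if (!"level_index" %in% names(data)) {
    data <- data |>
      dplyr::mutate(level_index = dplyr::row_number(), .by = "analyte_id")
  }
  dup <- data |>
    dplyr::count(.data$analyte_id, .data$level_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicated level_index %s for analyte %s",
                  dup$level_index[1], dup$analyte_id[1]),
          class = "qams_schema_error")
  }
  data
}

# Pull the single curve row for one analyte out of a curve table.
curve_for <- function(curves, analyte_id) {
  if (is.null(analyte_id)) {
    if (nrow(curves) != 1) {
      abort("`analyte` must be given when the curve table has several rows",
            class = "qams_lookup_error")
    }
    return(curves)
  }
  row <- curves[curves$analyte_id == analyte_id, , drop = FALSE]
  if (nrow(row) != 1) {
    abort(sprintf("no calibration curve for analyte '%s'", analyte_id),
          class = "qams_lookup_error")
  }
  row
}

#' Inverse-predict concentration from peak area
#'
#' Inverts the fitted power law: `C = 10^((lg A - b) / F)`. Results outside
#' the calibrated concentration range are returned as-is with a warning
#' (extrapolation is flagged, not forbidden).
#'
#' @param curves A `qams_calibration` table (or any one-row data frame with
#'   `slope` and `intercept`).
#' @param area Peak area(s), > 0.
#' @param analyte Analyte id selecting the curve when `curves` has several
#'   rows.
#' @return Numeric vector of concentrations (ug/mL).
#' @examples
#' curves <- tibble::tibble(analyte_id = "GF3", slope = 1.82, intercept = -1.67)
#' predict_concentration(curves, 500)
#' @export
predict_concentration <- function(curves, area, analyte = NULL) {
  curve <- curve_for(curves, analyte)
  check_positive(area, "area")
  if (curve$slope == 0) {
    abort("calibration slope is zero; concentration is not identifiable",
          class = "qams_degenerate_curve_error")
  }
  conc <- 10^((log10(area) - curve$intercept) / curve$slope)
  flag_out_of_range(conc, curve)
  conc
}

flag_out_of_range <- function(conc, curve) {
  if (all(c("range_low", "range_high") %in% names(curve))) {
    out <- conc < curve$range_low | conc > curve$range_high
    if (any(out)) {
      warn(sprintf(
        "%d value(s) outside calibrated range [%.4g, %.4g] for '%s'",
        sum(out), curve$range_low, curve$range_high,
        curve$analyte_id %||% "analyte"
      ), class = "qams_range_warning")
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward-predict peak area from concentration
#'
#' Evaluates the fitted power law `A = 10^(F * lg C + b)`; the exact inverse
#' of [predict_concentration()].
#'
#' @inheritParams predict_concentration
#' @param concentration Concentration(s) in ug/mL, > 0.
#' @return Numeric vector of peak areas.
#' @export
predict_area <- function(curves, concentration, analyte = NULL) {
  curve <- curve_for(curves, analyte)
  check_positive(concentration, "concentration")
  10^(curve$slope * log10(concentration) + curve$intercept)
}

#' Estimate LOD and LOQ by the signal-to-noise convention
#'
#' The limit of detection (quantification) is the concentration whose
#' predicted area equals 3 (10) times the baseline noise standard deviation,
#' read back through the power-law curve.
#'
#' @param curves A `qams_calibration` table.
#' @param noise_sd Baseline peak-area noise SD (scalar, or one value per
#'   curve row), > 0.
#' @return A tibble with `analyte_id`, `lod` and `loq` in ug/mL.
#' @export
estimate_lod_loq <- function(curves, noise_sd) {
  check_positive(noise_sd, "noise_sd")
  inv <- function(a) 10^((log10(a) - curves$intercept) / curves$slope)
  tibble::tibble(
    analyte_id = curves$analyte_id,
    lod = inv(3 * noise_sd),
    loq = inv(10 * noise_sd)
  )
}

#' @export
tidy.qams_calibration <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.qams_calibration <- function(x, ...) {
  tibble::tibble(
    n_analytes = nrow(x),
    min_r_squared = min(x$r_squared),
    slope_range = diff(range(x$slope)),
    total_levels = sum(x$n_levels)
  )
}

#' @export
print.qams_calibration <- function(x, ...) {
  cat(sprintf("<qams_calibration: %d analyte(s), log-log OLS>\n", nrow(x)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
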