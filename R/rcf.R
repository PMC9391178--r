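#' Relative correction factors for single-marker ELSD quantification
#'
#' A relative correction factor (RCF) relates an analyte's detector response
#' to that of the single marker, so the marker's calibration curve can stand
#' in for the analyte's. Because ELSD response is nonlinear, several
#' competing RCF definitions circulate; the six implemented here are:
#'
#' * **A** — apparent-concentration ratio: read the analyte's area through
#'   the *marker's* curve, `C_detected = 10^((lg A_k - b_s)/F_s)`, and take
#'   `RCF = C_detected / C_k`, averaged over calibration levels.
#' * **B** — slope ratio `F_k / F_s` of the two log-log curves.
#' * **C** — `(C_s / lg A_s) / (C_k / lg A_k)`, averaged over paired levels.
#' * **D** — `(lg C_k / lg A_k) / (lg C_s / lg A_s)`, averaged over paired
#'   levels.
#' * **E** — response-factor ratio `(A_s / C_s) / (A_k / C_k)`, averaged
#'   over paired levels.
#' * **F** — unity: every analyte is quantified as if it were the marker.
#'
#' Methods C, D and E pair the marker's and the analyte's series by
#' `level_index` (the shared dilution event in a co-diluted mixed standard);
#' method A needs only the analyte's own levels and the marker's curve.
#' Only method A carries the marker's intercept into the correction, which
#' is why it alone compensates a detector response that differs in
#' intercept but not slope.
#'
#' @param marker_curve One-row curve table for the marker (see
#'   [fit_calibration()]).
#' @param analyte_series Calibration levels for one analyte: columns
#'   `concentration`, `area` (and optionally `level_index`, `analyte_id`).
#' @param analyte_curve One-row curve table for the analyte (method B).
#' @param marker_series Calibration levels for the marker (methods C-E).
#' @param analyte_id Analyte label (method F).
#'
#' @return A one-row tibble of class `qams_rcf_entry`: `analyte_id`,
#'   `method`, `rcf`, with a `per_level` attribute (tibble of `level_index`,
#'   `rcf`) for the level-averaged methods A, C, D and E and an empty one
#'   for B and F.
#' @name rcf_methods
NULL

rcf_entry <- function(analyte_id, method, value, per_level = NULL) {
  if (is.null(per_level)) {
    per_level <- tibble::tibble(level_index = integer(), rcf = double())
  }
  out <- tibble::tibble(analyte_id = analyte_id, method = method, rcf = value)
  structure(out, per_level = per_level,
            class = c("qams_rcf_entry", class(tibble::tibble())))
}

series_id <- function(series, fallback = "analyte") {
  if ("analyte_id" %in% names(series)) series$analyte_id[1] else fallback
}

#' @rdname rcf_methods
#' @export
rcf_method_a <- function(marker_curve, analyte_series) {
  analyte_series <- as_calibration_data(analyte_series, "analyte series")
  detected <- suppressWarnings(
    predict_concentration(marker_curve, analyte_series$area)
  )
  per <- tibble::tibble(
    level_index = analyte_series$level_index,
    rcf = detected / analyte_series$concentration
  )
  rcf_entry(series_id(analyte_series), "A", mean(per$rcf), per)
}

#' @rdname rcf_methods
#' @export
rcf_method_b <- function(marker_curve, analyte_curve) {
  if (marker_curve$slope == 0) {
    abort("marker calibration slope is zero", class = "qams_degenerate_curve_error")
  }
  rcf_entry(analyte_curve$analyte_id %||% "analyte", "B",
            analyte_curve$slope / marker_curve$slope)
}

# Shared level pairing for the per-level ratio methods C, D, E.
paired_levels <- function(marker_series, analyte_series) {
  m <- as_calibration_data(marker_series, "marker series")
  k <- as_calibration_data(analyte_series, "analyte series")
  if (!setequal(m$level_index, k$level_index)) {
    abort("marker and analyte series have different level_index sets",
          class = "qams_pairing_error")
  }
  dplyr::inner_join(
    dplyr::select(m, "level_index", c_s = "concentration", a_s = "area"),
    dplyr::select(k, "level_index", c_k = "concentration", a_k = "area"),
    by = "level_index"
  ) |>
    dplyr::arrange(.data$level_index)
}

check_log_area_domain <- function(areas, method) {
  if (any(areas == 1)) {
    abort(sprintf("method %s divides by lg(area); area = 1 at some level", method),
          class = "qams_domain_error")
  }
  if (any(areas < 1)) {
    warn(sprintf(
      "method %s: area < 1 makes lg(area) negative; the formula changes sign",
      method
    ), class = "qams_log_domain_warning")
  }
}

#' @rdname rcf_methods
#' @export
rcf_method_c <- function(marker_series, analyte_series) {
  p <- paired_levels(marker_series, analyte_series)
  check_log_area_domain(c(p$a_s, p$a_k), "C")
  per <- tibble::tibble(
    level_index = p$level_index,
    rcf = (p$c_s / log10(p$a_s)) / (p$c_k / log10(p$a_k))
  )
  rcf_entry(series_id(analyte_series), "C", mean(per$rcf), per)
}

#' @rdname rcf_methods
#' @export
rcf_method_d <- function(marker_series, analyte_series) {
  p <- paired_levels(marker_series, analyte_series)
  check_log_area_domain(c(p$a_s, p$a_k), "D")
  if (any(p$c_s == 1 | p$c_k == 1)) {
    warn("method D: concentration = 1 makes lg(C) zero; level is degenerate",
         class = "qams_log_domain_warning")
  }
  per <- tibble::tibble(
    level_index = p$level_index,
    rcf = (log10(p$c_k) / log10(p$a_k)) / (log10(p$c_s) / log10(p$a_s))
  )
  rcf_entry(series_id(analyte_series), "D", mean(per$rcf), per)
}

#' @rdname rcf_methods
#' @export
rcf_method_e <- function(marker_series, analyte_series) {
  p <- paired_levels(marker_series, analyte_series)
  per <- tibble::tibble(
    level_index = p$level_index,
    rcf = (p$a_s / p$c_s) / (p$a_k / p$c_k)
  )
  rcf_entry(series_id(analyte_series), "E", mean(per$rcf), per)
}

#' @rdname rcf_methods
#' @export
rcf_method_f <- function(analyte_id) {
  rcf_entry(analyte_id, "F", 1.00)
}

#' Build an RCF table for a panel against a single marker
#'
#' Dispatches one of the six RCF methods (see [rcf_methods]) across every
#' analyte of a calibration panel, the marker included (whose RCF is 1 by
#' construction before rounding).
#'
#' @param data Calibration levels for the whole panel (columns `analyte_id`,
#'   `concentration`, `area`, optional `level_index`), or a fitted
#'   `qams_calibration` table for method B.
#' @param marker Analyte id of the single marker, e.g. `"GF3"`.
#' @param method One of `"A"` to `"F"`.
#' @param digits Decimal places for the reported `rcf` column (default 2,
#'   the conventional reporting precision); `NULL` to disable. Full
#'   precision is always kept in `rcf_full`.
#' @param curves Optional pre-fitted `qams_calibration` table; fitted from
#'   `data` when omitted.
#'
#' @return A tibble of class `qams_rcf` with columns `analyte_id`, `method`,
#'   `rcf` (rounded) and `rcf_full`, plus attributes `marker` and
#'   `per_level` (long tibble `analyte_id`, `method`, `level_index`, `rcf`).
#'
#' @examples
#' panel <- gfn_detector_models()
#' cal <- make_calibration_series(panel)
#' build_rcf_table(cal, marker = "GF3", method = "A")
#' @export
build_rcf_table <- function(data, marker, method = "A", digits = 2,
                            curves = NULL) {
  method <- match.arg(toupper(method), LETTERS[1:6])
  is_curves <- inherits(data, "qams_calibration") ||
    (all(c("analyte_id", "slope", "intercept") %in% names(data)) &&
       !"area" %in% names(data))
  if (is_curves) {
    curves <- data
    data <- NULL
    analytes <- curves$analyte_id
  } else {
    data <- as_calibration_data(data, "panel data")
    analytes <- unique(data$analyte_id)
  }
  if (!marker %in% analytes) {
    abort(sprintf("marker '%s' not present in the panel", marker),
          class = "qams_lookup_error")
  }
  if (method %in% c("A", "B") && is.null(curves)) {
    curves <- fit_calibration(data)
  }
  if (method %in% c("A", "C", "D", "E") && is.null(data)) {
    abort(sprintf("method %s needs calibration levels, not only fitted curves",
                  method), class = "qams_schema_error")
  }
  marker_curve <- if (!is.null(curves)) curve_for(curves, marker)
  marker_series <- if (!is.null(data)) data[data$analyte_id == marker, ]

  entries <- purrr::map(analytes, function(id) {
    series <- if (!is.null(data)) data[data$analyte_id == id, ]
    switch(method,
      A = rcf_method_a(marker_curve, series),
      B = rcf_method_b(marker_curve, curve_for(curves, id)),
      C = rcf_method_c(marker_series, series),
      D = rcf_method_d(marker_series, series),
      E = rcf_method_e(marker_series, series),
      F = rcf_method_f(id)
    )
  })
  per_level <- purrr::map_dfr(entries, function(e) {
    lv <- attr(e, "per_level")
    if (nrow(lv) == 0) return(NULL)
    tibble::tibble(analyte_id = e$analyte_id, method = method,
                   level_index = lv$level_index, rcf = lv$rcf)
  })
  out <- purrr::map_dfr(entries, tibble::as_tibble) |>
    dplyr::rename(rcf_full = "rcf") |>
    dplyr::mutate(rcf = if (is.null(digits)) .data$rcf_full
                  else round(.data$rcf_full, digits),
                  .after = "method")
  structure(out, marker = marker, per_level = per_level,
            class = c("qams_rcf", class(tibble::tibble())))
}

#' Compute RCF tables for several methods at once
#'
#' @inheritParams build_rcf_table
#' @param methods Character vector of method codes (default all six).
#' @return A long tibble binding [build_rcf_table()] results, with the
#'   `marker` attribute and combined `per_level` detail preserved.
#' @export
build_rcf_tables <- function(data, marker, methods = LETTERS[1:6],
                             digits = 2, curves = NULL) {
  tabs <- purrr::map(methods, function(m)
    build_rcf_table(data, marker, method = m, digits = digits, curves = curves))
  out <- dplyr::bind_rows(tabs)
  structure(out, marker = marker,
            per_level = purrr::map_dfr(tabs, attr, "per_level"),
            class = c("qams_rcf", class(tibble::tibble())))
}

#' @export
print.qams_rcf <- function(x, ...) {
  cat(sprintf("<qams_rcf: marker %s>\n", attr(x, "marker")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Reshape an RCF table to the conventional wide report
#'
#' Rows are methods, columns are analytes, mirroring the way RCF panels are
#' reported in monographs.
#'
#' @param rcf A `qams_rcf` table (possibly multi-method).
#' @return A tibble with a `method` column and one column per analyte.
#' @export
rcf_wide <- function(rcf) {
  tibble::as_tibble(rcf) |>
    dplyr::select("method", "analyte_id", "rcf") |>
    tidyr::pivot_wider(names_from = "analyte_id", values_from = "rcf")
}
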