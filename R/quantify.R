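#' External-standard quantification of a sample batch
#'
#' Each analyte's peak area is read back through its *own* calibration
#' curve (the external standard method, ESM).
#'
#' @param samples Long sample table: one row per (sample, analyte) with
#'   columns `sample_id`, `analyte_id`, `area` and the solution metadata
#'   `mass_g`, `volume_ml`, `dilution` (a `group` column is carried through
#'   when present).
#' @param curves A `qams_calibration` table covering every analyte present.
#' @return The input tibble with a `conc_esm` column (ug/mL) appended.
#' @export
esm_quantify <- function(samples, curves) {
  samples <- as_sample_data(samples)
  missing <- setdiff(unique(samples$analyte_id), curves$analyte_id)
  if (length(missing) > 0) {
    abort(sprintf("no calibration curve for: %s", paste(missing, collapse = ", ")),
          class = "qams_lookup_error")
  }
  samples |>
    dplyr::mutate(
      conc_esm = suppressWarnings(
        predict_concentration(curve_for(curves, .data$analyte_id[1]), .data$area)
      ),
      .by = "analyte_id"
    )
}

#' Single-marker (QAMS) quantification of a sample batch
#'
#' Every analyte's area is read through the *marker's* calibration curve as
#' an apparent concentration, then corrected by the analyte's relative
#' correction factor: `C_k = C_detected / RCF_k`. The same inversion is
#' applied to whichever method's RCFs are supplied, so the six methods are
#' compared on an identical pipeline (method F's unit RCF then means
#' "quantify everything as if it were the marker").
#'
#' @inheritParams esm_quantify
#' @param rcf A single-method `qams_rcf` table (see [build_rcf_table()])
#'   covering every analyte present.
#' @param marker Marker analyte id; defaults to the table's `marker`
#'   attribute.
#' @return The input tibble with a `conc_qams` column (ug/mL) appended.
#' @export
qams_quantify <- function(samples, curves, rcf, marker = attr(rcf, "marker")) {
  samples <- as_sample_data(samples)
  if (length(unique(rcf$method)) != 1) {
    abort("`rcf` must hold a single method; filter or rebuild it",
          class = "qams_schema_error")
  }
  missing <- setdiff(unique(samples$analyte_id), rcf$analyte_id)
  if (length(missing) > 0) {
    abort(sprintf("no RCF entry for: %s", paste(missing, collapse = ", ")),
          class = "qams_lookup_error")
  }
  if (any(rcf$rcf_full <= 0)) {
    abort("RCF values must be positive", class = "qams_domain_error")
  }
  marker_curve <- curve_for(curves, marker)
  rcf_map <- setNames(rcf$rcf_full, rcf$analyte_id)
  samples |>
    dplyr::mutate(
      conc_qams = suppressWarnings(
        predict_concentration(marker_curve, .data$area)
      ) / unname(rcf_map[.data$analyte_id])
    )
}

#' Convert a solution concentration to sample content
#'
#' Standard assay arithmetic: the analyte mass in the extract divided by
#' the sample mass, as a percentage w/w of the as-weighed sample.
#'
#' @param conc Solution concentration(s), ug/mL, >= 0.
#' @param mass_g Sample mass weighed (g), > 0.
#' @param volume_ml Extraction volume (mL), > 0.
#' @param dilution Dilution factor applied before injection (>= 1,
#'   default 1).
#' @return Content in percent w/w: `conc * volume_ml * dilution /
#'   (mass_g * 1e6) * 100`.
#' @examples
#' content_percent(500, mass_g = 0.25, volume_ml = 25) # 5 %
#' @export
content_percent <- function(conc, mass_g, volume_ml, dilution = 1) {
  if (any(conc < 0)) abort("`conc` must be >= 0", class = "qams_domain_error")
  check_positive(mass_g, "mass_g")
  check_positive(volume_ml, "volume_ml")
  check_positive(dilution, "dilution")
  conc * volume_ml * dilution / (mass_g * 1e6) * 100
}

#' Relative error between QAMS and external-standard contents
#'
#' `RE% = (QAMS - ESM) / ESM * 100`, the signed criterion used to judge how
#' closely single-marker quantification tracks the external-standard
#' reference.
#'
#' @param qams,esm Contents (or concentrations) on the same scale; `esm`
#'   must be > 0.
#' @return Signed percentage(s).
#' @export
relative_error <- function(qams, esm) {
  if (any(esm <= 0)) {
    abort("`esm` must be > 0 to define a relative error",
          class = "qams_domain_error")
  }
  (qams - esm) / esm * 100
}

#' Full content table under ESM and QAMS
#'
#' Runs [esm_quantify()] and [qams_quantify()] on a batch and converts both
#' concentration sets to percent-w/w contents with the per-sample solution
#' metadata, appending the relative error of QAMS against ESM.
#'
#' @inheritParams qams_quantify
#' @return A tibble with one row per (sample, analyte): identifiers, areas,
#'   `conc_esm`, `conc_qams`, `content_esm_pct`, `content_qams_pct`,
#'   `re_pct`.
#' @export
quantify_contents <- function(samples, curves, rcf,
                              marker = attr(rcf, "marker")) {
  samples |>
    esm_quantify(curves) |>
    qams_quantify(curves, rcf, marker = marker) |>
    dplyr::mutate(
      content_esm_pct = content_percent(.data$conc_esm, .data$mass_g,
                                        .data$volume_ml, .data$dilution),
      content_qams_pct = content_percent(.data$conc_qams, .data$mass_g,
                                         .data$volume_ml, .data$dilution),
      re_pct = relative_error(.data$content_qams_pct, .data$content_esm_pct)
    )
}

#' Rank the six RCF methods by QAMS-vs-ESM relative error
#'
#' For each RCF method, quantifies the batch by QAMS and by the external
#' standard method and summarises the distribution of per-analyte relative
#' errors. Methods are ordered by mean absolute RE (ascending); the first
#' is the selected method.
#'
#' @inheritParams esm_quantify
#' @param data Calibration levels for the panel (see [fit_calibration()]).
#' @param marker Marker analyte id.
#' @param methods Method codes to compare (default all six).
#' @return A tibble of class `qams_method_ranking`, ordered best-first,
#'   with `method`, `mean_abs_re`, `median_abs_re`, `max_abs_re`,
#'   `mean_re`, `n`; the selected method code is in the `selected`
#'   attribute and the per-record errors in the `detail` attribute.
#' @examples
#' panel <- gfn_detector_models(noise_cv = 0.01)
#' set.seed(1)
#' cal <- make_calibration_series(panel)
#' batch <- make_sample_batch(batch_design(), panel)
#' rank_rcf_methods(batch$samples, cal, marker = "GF3")
#' @export
rank_rcf_methods <- function(samples, data, marker, methods = LETTERS[1:6]) {
  samples <- as_sample_data(samples)
  if (nrow(samples) == 0) {
    abort("empty sample batch", class = "qams_insufficient_data_error")
  }
  curves <- fit_calibration(data)
  detail <- purrr::map_dfr(methods, function(m) {
    rcf <- build_rcf_table(data, marker, method = m, curves = curves)
    quantify_contents(samples, curves, rcf) |>
      dplyr::mutate(method = m, .before = 1)
  })
  out <- detail |>
    dplyr::summarise(
      mean_abs_re = mean(abs(.data$re_pct)),
      median_abs_re = median(abs(.data$re_pct)),
      max_abs_re = max(abs(.data$re_pct)),
      mean_re = mean(.data$re_pct),
      n = dplyr::n(),
      .by = "method"
    ) |>
    dplyr::arrange(.data$mean_abs_re)
  structure(out, selected = out$method[1], detail = detail,
            class = c("qams_method_ranking", class(tibble::tibble())))
}

#' @export
print.qams_method_ranking <- function(x, ...) {
  cat(sprintf("<qams_method_ranking: selected method %s>\n",
              attr(x, "selected")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @export
tidy.qams_method_ranking <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.qams_method_ranking <- function(x, ...) {
  tibble::tibble(
    selected = attr(x, "selected"),
    best_mean_abs_re = x$mean_abs_re[1],
    worst_mean_abs_re = x$mean_abs_re[nrow(x)],
    n_methods = nrow(x)
  )
}

#' Content ratios of processed samples to their raw counterparts
#'
#' Lot-to-lot variation of the raw material is removed by expressing each
#' processed sample's per-analyte content relative to the raw sample it was
#' prepared from; the resulting ratio matrix is what downstream
#' chemometrics consumes.
#'
#' @param contents Content table with `sample_id`, `analyte_id` and a
#'   content column.
#' @param pairing A data frame mapping `sample_id` (processed) to `raw_id`.
#' @param value Which content column to ratio: `"qams"`
#'   (`content_qams_pct`), `"esm"`, or the name of any numeric column.
#' @param exclude Character vector of sample ids to drop before pairing
#'   (manual outlier exclusion).
#' @return A tibble `sample_id`, `raw_id`, `analyte_id`, `ratio`. A raw
#'   content of zero yields `NA` with a warning.
#' @export
ratio_to_raw <- function(contents, pairing, value = c("qams", "esm"),
                         exclude = character()) {
  col <- if (is.character(value) && length(value) == 1 &&
             value %in% names(contents)) {
    value
  } else {
    switch(match.arg(value), qams = "content_qams_pct", esm = "content_esm_pct")
  }
  check_columns(contents, c("sample_id", "analyte_id", col), "content table")
  check_columns(pairing, c("sample_id", "raw_id"), "pairing table")
  contents <- dplyr::filter(contents, !.data$sample_id %in% exclude)
  processed <- dplyr::filter(contents, .data$sample_id %in% pairing$sample_id)
  unpaired <- setdiff(pairing$sample_id, contents$sample_id)
  if (length(unpaired) > 0) {
    abort(sprintf("pairing refers to absent sample(s): %s",
                  paste(head(unpaired, 5), collapse = ", ")),
          class = "qams_pairing_error")
  }
  raw <- contents |>
    dplyr::filter(.data$sample_id %in% pairing$raw_id) |>
    dplyr::select("sample_id", "analyte_id", raw_content = dplyr::all_of(col))
  out <- processed |>
    dplyr::inner_join(pairing, by = "sample_id") |>
    dplyr::inner_join(raw, by = c(raw_id = "sample_id", "analyte_id")) |>
    dplyr::mutate(ratio = .data[[col]] / .data$raw_content) |>
    dplyr::select("sample_id", "raw_id", "analyte_id", "ratio")
  zero <- !is.finite(out$ratio)
  if (any(zero)) {
    warn(sprintf("%d ratio(s) undefined (raw content zero); set to NA",
                 sum(zero)), class = "qams_zero_raw_warning")
    out$ratio[zero] <- NA_real_
  }
  out
}

# Validate a long-format sample table.
as_sample_data <- function(samples) {
  samples <- tibble::as_tibble(samples)
  check_columns(samples,
                c("sample_id", "analyte_id", "area", "mass_g", "volume_ml"),
                "sample table")
  if (!"dilution" %in% names(samples)) samples$dilution <- 1
  bad <- which(!is.finite(samples$area) | samples$area <= 0)
  if (length(bad) > 0) {
    abort(sprintf("sample table: nonpositive `area` at row %d", bad[1]),
          class = "qams_domain_error")
  }
  samples
}
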