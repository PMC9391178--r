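#' Relative standard deviation of replicate measurements
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, in
#' percent — the universal precision metric of chromatographic method
#' validation.
#'
#' @param values Numeric vector of >= 2 replicate measurements with a
#'   nonzero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(95.72, 97.82, 99.24)) # ~1.81
#' @export
rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("at least 2 replicate values are needed for an RSD",
          class = "qams_insufficient_data_error")
  }
  m <- mean(values)
  if (m == 0) abort("mean of replicates is zero", class = "qams_domain_error")
  sd(values) / m * 100
}

#' Spike recovery rate
#'
#' `recovery = (detected - origin) / spiked * 100`: the fraction of a known
#' spike found on re-assay, after subtracting the analyte already present
#' in the sample.
#'
#' @param origin_mg Analyte amount already present (mg).
#' @param spike_mg Analyte amount added (mg), > 0.
#' @param detected_mg Total amount found (mg), >= 0.
#' @return Recovery in percent (vectorised).
#' @examples
#' recovery_rate(4.892, 2.5, 7.285) # 95.72
#' @export
recovery_rate <- function(origin_mg, spike_mg, detected_mg) {
  check_positive(spike_mg, "spike_mg")
  if (any(detected_mg < 0)) {
    abort("`detected_mg` must be >= 0", class = "qams_domain_error")
  }
  (detected_mg - origin_mg) / spike_mg * 100
}

#' Summarise a spike-recovery experiment
#'
#' Computes per-row recoveries and the per-level mean and RSD for a
#' three-level (Low/Medium/High) spike design.
#'
#' @param data Data frame with columns `level`, `origin_mg`, `spike_mg`,
#'   `detected_mg` (extra columns such as `mass_g` are carried through).
#' @return A list with `rows` (input plus `recovery_pct`) and `summary`
#'   (per level: `n`, `mean_recovery_pct`, `rsd_pct`).
#' @export
summarize_recovery <- function(data) {
  check_columns(data, c("level", "origin_mg", "spike_mg", "detected_mg"),
                "recovery table")
  rows <- data |>
    dplyr::mutate(recovery_pct = recovery_rate(.data$origin_mg,
                                               .data$spike_mg,
                                               .data$detected_mg))
  summary <- rows |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_recovery_pct = mean(.data$recovery_pct),
      rsd_pct = rsd(.data$recovery_pct),
      .by = "level"
    )
  list(rows = rows, summary = summary)
}

#' Summarise replicate tables into validation statistics
#'
#' Collapses grouped replicates (precision injections, stability time
#' points, repeatability preparations, ...) into per-(metric, analyte) RSD
#' summaries. Repeatability designs that deliberately vary the sample mass
#' should supply content values rather than raw areas, so the replicates
#' are commensurable.
#'
#' @param runs Long data frame with columns `metric`, `analyte_id`,
#'   `replicate_id`, `value`.
#' @param min_n Minimum replicates per group (default 2).
#' @return A tibble with `metric`, `analyte_id`, `n`, `mean`, `rsd_pct`.
#' @export
summarize_validation <- function(runs, min_n = 2) {
  check_columns(runs, c("metric", "analyte_id", "replicate_id", "value"),
                "replicate table")
  out <- runs |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      .by = c("metric", "analyte_id")
    )
  short <- out[out$n < min_n, ]
  if (nrow(short) > 0) {
    abort(sprintf("group below %d replicates: %s / %s", min_n,
                  short$metric[1], short$analyte_id[1]),
          class = "qams_insufficient_data_error")
  }
  runs |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      rsd_pct = rsd(.data$value),
      .by = c("metric", "analyte_id")
    )
}

#' Cross-instrument system suitability of RCFs
#'
#' An RCF is only usable as a transferable constant if independent
#' instruments reproduce it. Given per-instrument RCF tables computed with
#' the same method and marker, returns each analyte's mean RCF and the
#' between-instrument RSD.
#'
#' @param rcf_tables List of >= 2 single-method `qams_rcf` tables (one per
#'   instrument).
#' @param digits Decimal places for the reported mean (default 2,
#'   `NULL` to disable); RSDs are computed on full precision.
#' @return A tibble with `analyte_id`, `n_instruments`, `mean_rcf`,
#'   `rsd_pct`.
#' @export
system_suitability_rcf <- function(rcf_tables, digits = 2) {
  if (length(rcf_tables) < 2) {
    abort("at least 2 instruments are needed",
          class = "qams_insufficient_data_error")
  }
  markers <- unique(purrr::map_chr(rcf_tables, attr, "marker"))
  methods <- unique(purrr::map_chr(rcf_tables, function(x) x$method[1]))
  if (length(markers) > 1 || length(methods) > 1) {
    abort("RCF tables disagree on marker or method",
          class = "qams_consistency_error")
  }
  dplyr::bind_rows(lapply(rcf_tables, tibble::as_tibble)) |>
    dplyr::summarise(
      n_instruments = dplyr::n(),
      mean_rcf = if (is.null(digits)) mean(.data$rcf_full)
                 else round(mean(.data$rcf_full), digits),
      rsd_pct = rsd(.data$rcf_full),
      .by = "analyte_id"
    )
}
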