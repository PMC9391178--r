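#' Plot fitted calibration curves in log-log coordinates
#'
#' @param object A `qams_calibration` table.
#' @param data Optional calibration levels to overlay as points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qams_calibration <- function(object, data = NULL, ...) {
  lines <- tibble::as_tibble(object) |>
    dplyr::reframe(
      log_conc = seq(log10(.data$range_low), log10(.data$range_high),
                     length.out = 25),
      log_area = .data$slope * .data$log_conc + .data$intercept,
      .by = "analyte_id"
    )
  p <- ggplot2::ggplot(lines, ggplot2::aes(.data$log_conc, .data$log_area,
                                           colour = .data$analyte_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lg concentration (µg/mL)", y = "lg peak area",
                  colour = "analyte",
                  title = "Log-log ELSD calibration curves")
  if (!is.null(data)) {
    data <- as_calibration_data(data)
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(data, log_conc = log10(.data$concentration),
                           log_area = log10(.data$area)),
      ggplot2::aes(.data$log_conc, .data$log_area, colour = .data$analyte_id)
    )
  }
  p
}

#' Compare RCF values across methods and analytes
#'
#' @param rcf A (possibly multi-method) `qams_rcf` table.
#' @return A ggplot: one point per (analyte, method), a reference line at
#'   RCF = 1.
#' @export
plot_rcf_methods <- function(rcf) {
  ggplot2::ggplot(tibble::as_tibble(rcf),
                  ggplot2::aes(.data$analyte_id, .data$rcf_full,
                               colour = .data$method, group = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "RCF against marker", colour = "method",
                  title = sprintf("Relative correction factors (marker %s)",
                                  attr(rcf, "marker")))
}

#' Plot the QAMS-vs-ESM relative-error distribution per RCF method
#'
#' @param object A `qams_method_ranking`.
#' @param ... Unused.
#' @return A ggplot boxplot of per-record RE by method, ordered best-first.
#' @export
autoplot.qams_method_ranking <- function(object, ...) {
  detail <- attr(object, "detail") |>
    dplyr::mutate(method = factor(.data$method, levels = object$method))
  ggplot2::ggplot(detail, ggplot2::aes(.data$method, .data$re_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "RCF method", y = "RE (QAMS vs ESM, %)",
                  title = sprintf("Method %s tracks the external standard best",
                                  attr(object, "selected")))
}
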