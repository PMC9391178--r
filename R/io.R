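#' Read and write calibration-level tables
#'
#' The interchange format is comma-separated UTF-8 text with a header.
#' Calibration tables carry `analyte_id`, `level_index` (optional on
#' read), `concentration_ug_per_ml` and `area`; rows with nonpositive or
#' nonnumeric values are rejected with the offending row named.
#'
#' @param path File path.
#' @return `read_calibration_table()` returns a validated calibration
#'   tibble (internal column names `concentration`, `area`);
#'   `write_calibration_table()` returns `path` invisibly.
#' @export
read_calibration_table <- function(path) {
  raw <- read_csv_strict(path)
  names(raw)[names(raw) == "concentration_ug_per_ml"] <- "concentration"
  check_columns(raw, c("analyte_id", "concentration", "area"),
                sprintf("'%s'", path))
  for (col in c("concentration", "area")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | vals <= 0)
    if (length(bad) > 0) {
      abort(sprintf("'%s': column `%s`, row %d is not a positive number",
                    path, col, bad[1]),
            class = "qams_schema_error")
    }
    raw[[col]] <- vals
  }
  as_calibration_data(raw, sprintf("'%s'", path))
}

#' @rdname read_calibration_table
#' @param data A calibration tibble.
#' @export
write_calibration_table <- function(data, path) {
  out <- as_calibration_data(data) |>
    dplyr::select("analyte_id", "level_index",
                  concentration_ug_per_ml = "concentration", "area")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write long-format sample tables
#'
#' Columns: `sample_id`, `group`, `mass_g`, `volume_ml`, `dilution`,
#' `analyte_id`, `area`.
#'
#' @param path File path.
#' @return A validated sample tibble, or (writer) `path` invisibly.
#' @export
read_sample_table <- function(path) {
  raw <- read_csv_strict(path)
  as_sample_data(raw)
}

#' @rdname read_sample_table
#' @param data A sample tibble.
#' @export
write_sample_table <- function(data, path) {
  readr::write_csv(as_sample_data(data), path)
  invisible(path)
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "qams_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a fitted-curve report
#'
#' One row per analyte with slope, intercept, R^2 (4 decimals, the
#' conventional reporting precision), linear range and, when a baseline
#' noise SD is supplied, LOD/LOQ. Rounding happens only here, at
#' serialisation.
#'
#' @param curves A `qams_calibration` table.
#' @param path File path.
#' @param noise_sd Optional baseline noise SD for LOD/LOQ columns.
#' @export
write_curve_table <- function(curves, path, noise_sd = NULL) {
  out <- tibble::as_tibble(curves) |>
    dplyr::mutate(r_squared = round(.data$r_squared, 4))
  if (!is.null(noise_sd)) {
    out <- dplyr::left_join(out, estimate_lod_loq(curves, noise_sd),
                            by = "analyte_id")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Write an RCF table (wide report plus per-level audit)
#'
#' @param rcf A `qams_rcf` table.
#' @param path Path for the wide methods-by-analytes report.
#' @param levels_path Optional path for the long per-level audit table.
#' @export
write_rcf_table <- function(rcf, path, levels_path = NULL) {
  readr::write_csv(rcf_wide(rcf), path)
  if (!is.null(levels_path)) {
    readr::write_csv(attr(rcf, "per_level"), levels_path)
  }
  invisible(path)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param calibration_path,sample_path Input CSV paths.
#' @param out_dir Output directory (created if absent).
#' @param marker Single-marker analyte id.
#' @param rcf_method Method whose RCFs drive the reported QAMS contents.
#' @param digits Rounding for reported RCFs.
#' @param seed Optional RNG seed recorded with the run.
#' @return A `qams_run_config` list.
#' @export
run_config <- function(calibration_path, sample_path, out_dir,
                       marker = "GF3", rcf_method = "A", digits = 2,
                       seed = NULL) {
  rcf_method <- match.arg(toupper(rcf_method), LETTERS[1:6])
  structure(list(calibration_path = calibration_path,
                 sample_path = sample_path, out_dir = out_dir,
                 marker = marker, rcf_method = rcf_method,
                 digits = digits, seed = seed),
            class = "qams_run_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognised keys
#' match the arguments of [run_config()].
#'
#' @param path File path.
#' @return A `qams_run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(sprintf("config line not of the form key = value: '%s'",
                  lines[which(bad)[1]]), class = "qams_schema_error")
  }
  vals <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  for (k in c("digits", "seed")) {
    if (!is.null(vals[[k]])) vals[[k]] <- as.integer(vals[[k]])
  }
  do.call(run_config, vals)
}

#' Run the full single-marker quantification pipeline
#'
#' Calibrate, compute RCFs by all six methods, quantify the batch by ESM
#' and by QAMS under the configured method, rank the methods by relative
#' error, and write every artifact: `curves.csv`, `rcf_table.csv`,
#' `rcf_levels.csv`, `contents.csv`, `method_ranking.csv`.
#'
#' @param config A [run_config()] (or a path to a key=value config file).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the written `paths`, the `selected`
#'   method from the ranking, and the in-memory results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "qams_run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$seed)) set.seed(config$seed)

  cal <- read_calibration_table(config$calibration_path)
  if (!config$marker %in% cal$analyte_id) {
    abort(sprintf("marker '%s' not present in calibration data", config$marker),
          class = "qams_lookup_error")
  }
  samples <- read_sample_table(config$sample_path)
  say("calibration: %d analytes, %d levels", dplyr::n_distinct(cal$analyte_id),
      nrow(cal))
  curves <- fit_calibration(cal)

  rcf_all <- build_rcf_tables(cal, config$marker, digits = config$digits,
                              curves = curves)
  say("rcf: 6 methods x %d analytes against %s",
      dplyr::n_distinct(rcf_all$analyte_id), config$marker)

  rcf_sel <- build_rcf_table(cal, config$marker, method = config$rcf_method,
                             digits = config$digits, curves = curves)
  contents <- quantify_contents(samples, curves, rcf_sel)
  say("quantify: %d samples by ESM and QAMS (method %s)",
      dplyr::n_distinct(samples$sample_id), config$rcf_method)

  ranking <- rank_rcf_methods(samples, cal, config$marker)
  say("rank: selected method %s (mean |RE| %.3g%%)", attr(ranking, "selected"),
      ranking$mean_abs_re[1])

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    curves = file.path(config$out_dir, "curves.csv"),
    rcf = file.path(config$out_dir, "rcf_table.csv"),
    rcf_levels = file.path(config$out_dir, "rcf_levels.csv"),
    contents = file.path(config$out_dir, "contents.csv"),
    ranking = file.path(config$out_dir, "method_ranking.csv")
  )
  write_curve_table(curves, paths$curves)
  write_rcf_table(rcf_all, paths$rcf, paths$rcf_levels)
  readr::write_csv(contents, paths$contents)
  readr::write_csv(tibble::as_tibble(ranking), paths$ranking)
  say("wrote %d artifacts to %s", length(paths), config$out_dir)

  invisible(list(paths = paths, selected = attr(ranking, "selected"),
                 curves = curves, rcf = rcf_all, contents = contents,
                 ranking = ranking))
}
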