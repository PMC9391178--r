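#' Ground-truth detector models for simulation
#'
#' A detector model is the hidden truth behind a synthetic ELSD: a
#' power-law response `A = 10^(F lg C + b)` plus multiplicative
#' (signal-proportional, lognormal) and additive (baseline) noise.
#'
#' @param analyte_id Analyte label(s).
#' @param slope Power-law exponent F (> 0); ELSD slopes for
#'   oligosaccharide assays typically fall around 1.8-1.95.
#' @param intercept Log10 intercept b; typically about -1.9 to -1.55.
#' @param noise_cv Relative SD of the multiplicative area noise (0 = none).
#' @param baseline_sd SD of the additive baseline noise, in area units.
#' @param top_concentration Highest calibration level (ug/mL), used by
#'   [make_calibration_series()].
#' @return A tibble with one row per analyte.
#' @export
detector_model <- function(analyte_id, slope, intercept, noise_cv = 0,
                           baseline_sd = 0, top_concentration = 1000) {
  check_positive(slope, "slope")
  if (any(noise_cv < 0) || any(baseline_sd < 0)) {
    abort("noise parameters must be >= 0", class = "qams_domain_error")
  }
  tibble::tibble(
    analyte_id = analyte_id, slope = slope, intercept = intercept,
    noise_cv = noise_cv, baseline_sd = baseline_sd,
    top_concentration = top_concentration
  )
}

#' Reference detector panel: eight fructooligosaccharides
#'
#' Published HILIC-HPLC-ELSD calibration parameters for the eight
#' fructooligosaccharides of *Morinda officinalis* (GF1 = sucrose through
#' GF8; nystose GF3 is the pharmacopoeial single marker), usable both as a
#' realistic simulation ground truth and as the printed-slope input for
#' slope-ratio RCFs.
#'
#' @param noise_cv,baseline_sd Noise settings applied to every analyte
#'   (default noiseless).
#' @return A detector-model tibble (see [detector_model()]) with an
#'   `is_marker` column flagging GF3.
#' @export
gfn_detector_models <- function(noise_cv = 0, baseline_sd = 0) {
  panel <- detector_model(
    analyte_id = paste0("GF", 1:8),
    slope = c(1.88, 1.94, 1.82, 1.80, 1.81, 1.81, 1.83, 1.86),
    intercept = c(-1.70, -1.90, -1.67, -1.56, -1.66, -1.76, -1.77, -1.91),
    noise_cv = noise_cv, baseline_sd = baseline_sd,
    top_concentration = c(934.128, 730.422, 1180.400, 950.40,
                          1130.920, 1212.154, 1162.394, 1035.752)
  )
  dplyr::mutate(panel, is_marker = .data$analyte_id == "GF3")
}

#' Dilution arithmetic for standard solutions
#'
#' Concentration of an aliquot brought to a final volume:
#' `conc * aliquot_ml / final_ml`.
#'
#' @param conc Stock concentration (ug/mL), > 0.
#' @param aliquot_ml Volume of stock drawn (mL), > 0.
#' @param final_ml Final volume (mL), > 0.
#' @return The working concentration (ug/mL).
#' @examples
#' dilute_concentration(1043.46, 3.5, 5) # 730.422
#' @export
dilute_concentration <- function(conc, aliquot_ml, final_ml) {
  check_positive(conc, "conc")
  check_positive(aliquot_ml, "aliquot_ml")
  check_positive(final_ml, "final_ml")
  conc * aliquot_ml / final_ml
}

#' Simulate ELSD peak areas
#'
#' Draws `area = 10^(F lg C + b) * exp(e_mult) + e_add` with
#' `e_mult ~ N(0, log(1 + noise_cv))` and `e_add ~ N(0, baseline_sd)`.
#' With both noise terms zero the output is deterministic and no random
#' numbers are consumed. Randomness comes from R's global RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param model A one-row detector model, or one row per concentration.
#' @param concentration Concentration(s), ug/mL, > 0.
#' @return Numeric vector of peak areas.
#' @export
simulate_area <- function(model, concentration) {
  check_positive(concentration, "concentration")
  n <- length(concentration)
  if (nrow(model) == 1) {
    model <- model[rep(1, n), ]
  } else if (nrow(model) != n) {
    abort("`model` must have 1 row or one row per concentration",
          class = "qams_schema_error")
  }
  area <- 10^(model$slope * log10(concentration) + model$intercept)
  if (any(model$noise_cv > 0)) {
    area <- area * exp(rnorm(n, 0, log(1 + model$noise_cv)))
  }
  if (any(model$baseline_sd > 0)) {
    area <- area + rnorm(n, 0, model$baseline_sd)
  }
  area
}

#' Generate a calibration dilution series
#'
#' Builds the standard five-point design by diluting each analyte's top
#' standard by the given factors (default 1, 1.5, 2.2, 4 and 10), or uses
#' explicitly supplied concentrations, and simulates the detector response
#' at every level. Level 1 is the most dilute standard.
#'
#' @param models Detector-model tibble (one row per analyte).
#' @param top_concentration Optional override of the models'
#'   `top_concentration` (scalar or per-analyte).
#' @param dilution_factors Distinct dilution factors >= 1.
#' @param concentrations Optional long tibble (`analyte_id`,
#'   `concentration`) replacing the factor rule for the analytes it names,
#'   e.g. a separately prepared single-standard series.
#' @return A calibration-level tibble (`analyte_id`, `level_index`,
#'   `concentration`, `area`) ready for [fit_calibration()].
#' @examples
#' make_calibration_series(detector_model("GF3", 1.82, -1.67, top_concentration = 1180.4))
#' @export
make_calibration_series <- function(models, top_concentration = NULL,
                                    dilution_factors = c(1, 1.5, 2.2, 4, 10),
                                    concentrations = NULL) {
  if (anyDuplicated(dilution_factors)) {
    abort("dilution factors must be distinct", class = "qams_design_error")
  }
  if (any(dilution_factors < 1)) {
    abort("dilution factors must be >= 1", class = "qams_design_error")
  }
  if (!is.null(top_concentration)) {
    models$top_concentration <- top_concentration
  }
  grid <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
    id <- models$analyte_id[i]
    conc <- if (!is.null(concentrations) && id %in% concentrations$analyte_id) {
      concentrations$concentration[concentrations$analyte_id == id]
    } else {
      models$top_concentration[i] / dilution_factors
    }
    tibble::tibble(
      analyte_id = id,
      level_index = seq_along(conc),
      concentration = sort(conc)
    )
  })
  grid |>
    dplyr::mutate(
      area = simulate_area(models[models$analyte_id == .data$analyte_id[1], ],
                           .data$concentration),
      .by = "analyte_id"
    )
}

#' Describe a synthetic sample-batch design
#'
#' The default design mirrors a processing study of *Morinda officinalis*:
#' three raw lots, each processed three ways (steamed `St`, licorice-boiled
#' `L`, salt-steamed `S`) in triplicate — 30 samples in all. Default
#' contents put the marker near 5 % w/w with the eight analytes totalling
#' about 45 %, and the default group multipliers encode the expected
#' processing chemistry: high-polymer analytes (GF7/GF8) hydrolyse during
#' steaming while GF1/GF2 rise, with only mild shifts for the boiled
#' product.
#'
#' @param n_raw Number of raw lots.
#' @param processes Character vector of processed-group codes.
#' @param n_replicates Replicates per (lot, process).
#' @param base_content Named vector of per-analyte raw content (% w/w).
#' @param group_multipliers Named list (per process) of named multiplier
#'   vectors; analytes not named keep multiplier 1.
#' @param mass_g,volume_ml,dilution Assay solution metadata.
#' @param lot_cv Lognormal CV of content between raw lots.
#' @param rep_cv Lognormal CV between replicate preparations.
#' @param outlier Optional `list(sample_id =, factor =)` degrading one
#'   sample's true contents, for testing exclusion workflows.
#' @return A `qams_batch_design` list.
#' @export
batch_design <- function(n_raw = 3,
                         processes = c("St", "L", "S"),
                         n_replicates = 3,
                         base_content = c(GF1 = 4.5, GF2 = 4.8, GF3 = 5.0,
                                          GF4 = 5.6, GF5 = 6.0, GF6 = 6.3,
                                          GF7 = 6.6, GF8 = 6.2),
                         group_multipliers = list(
                           St = c(GF1 = 1.30, GF2 = 1.50, GF7 = 0.70, GF8 = 0.60),
                           S  = c(GF1 = 1.35, GF2 = 1.60, GF7 = 0.65, GF8 = 0.55),
                           L  = c(GF1 = 1.05, GF2 = 1.10, GF3 = 1.05, GF8 = 0.95)
                         ),
                         mass_g = 0.25, volume_ml = 25, dilution = 1,
                         lot_cv = 0.10, rep_cv = 0.02, outlier = NULL) {
  if (any(base_content <= 0)) {
    abort("base contents must be > 0", class = "qams_domain_error")
  }
  if (any(unlist(group_multipliers) <= 0)) {
    abort("group multipliers must be > 0", class = "qams_domain_error")
  }
  if (n_replicates < 1 || n_raw < 1) {
    abort("replicate and lot counts must be >= 1", class = "qams_design_error")
  }
  structure(
    list(n_raw = n_raw, processes = processes, n_replicates = n_replicates,
         base_content = base_content, group_multipliers = group_multipliers,
         mass_g = mass_g, volume_ml = volume_ml, dilution = dilution,
         lot_cv = lot_cv, rep_cv = rep_cv, outlier = outlier),
    class = "qams_batch_design"
  )
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) rep(1, n) else exp(rnorm(n, 0, log(1 + cv)))
}

#' Simulate a sample batch with known ground truth
#'
#' Builds one raw sample per lot plus every (lot, process, replicate)
#' combination. True contents are the design's base contents times lot
#' jitter (shared between a raw lot and its processed descendants), a
#' per-group multiplier and replicate jitter; solution concentrations
#' follow from the assay metadata and areas from the detector models.
#'
#' @param design A [batch_design()].
#' @param models Detector-model tibble covering every analyte of the
#'   design.
#' @return A list: `samples` (long observable table, ready for
#'   [quantify_contents()]), `truth` (`sample_id`, `analyte_id`,
#'   `true_content_pct`, `true_conc`), and `pairing` (processed
#'   `sample_id` to `raw_id`) for [ratio_to_raw()].
#' @export
make_sample_batch <- function(design, models) {
  stopifnot(inherits(design, "qams_batch_design"))
  analytes <- names(design$base_content)
  missing <- setdiff(analytes, models$analyte_id)
  if (length(missing) > 0) {
    abort(sprintf("no detector model for: %s", paste(missing, collapse = ", ")),
          class = "qams_lookup_error")
  }
  lots <- sprintf("%02d", seq_len(design$n_raw))
  # lot-level content jitter, shared by the raw sample and its products
  lot_factor <- matrix(
    lognormal_factor(design$n_raw * length(analytes), design$lot_cv),
    nrow = design$n_raw, dimnames = list(lots, analytes)
  )
  mult_for <- function(group) {
    m <- setNames(rep(1, length(analytes)), analytes)
    g <- design$group_multipliers[[group]]
    g <- g[intersect(names(g), analytes)]
    if (length(g) > 0) m[names(g)] <- g
    m
  }
  plan <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("Raw_", lots), group = "Raw", lot = lots),
    tidyr::expand_grid(group = design$processes, lot = lots,
                       rep = seq_len(design$n_replicates)) |>
      dplyr::mutate(sample_id = sprintf("%s_%s-%d", .data$group, .data$lot,
                                        .data$rep)) |>
      dplyr::select("sample_id", "group", "lot")
  )
  truth <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    g <- plan$group[i]
    content <- design$base_content * lot_factor[plan$lot[i], ] * mult_for(g)
    if (g != "Raw") {
      content <- content * lognormal_factor(length(analytes), design$rep_cv)
    }
    tibble::tibble(sample_id = plan$sample_id[i], group = g,
                   analyte_id = analytes, true_content_pct = unname(content))
  })
  if (!is.null(design$outlier)) {
    hit <- truth$sample_id == design$outlier$sample_id
    truth$true_content_pct[hit] <- truth$true_content_pct[hit] *
      design$outlier$factor
  }
  truth <- truth |>
    dplyr::mutate(true_conc = .data$true_content_pct / 100 * design$mass_g *
                    1e6 / (design$volume_ml * design$dilution))
  samples <- truth |>
    dplyr::mutate(
      mass_g = design$mass_g, volume_ml = design$volume_ml,
      dilution = design$dilution,
      area = simulate_area(models[models$analyte_id == .data$analyte_id[1], ],
                           .data$true_conc),
      .by = "analyte_id"
    ) |>
    dplyr::select("sample_id", "group", "mass_g", "volume_ml", "dilution",
                  "analyte_id", "area")
  pairing <- plan |>
    dplyr::filter(.data$group != "Raw") |>
    dplyr::mutate(raw_id = paste0("Raw_", .data$lot)) |>
    dplyr::select("sample_id", "raw_id")
  list(samples = samples,
       truth = dplyr::select(truth, "sample_id", "group", "analyte_id",
                             "true_content_pct", "true_conc"),
       pairing = pairing)
}
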