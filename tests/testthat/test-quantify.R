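make_batch_fixture <- function(models, design = batch_design()) {
  cal <- make_calibration_series(models)
  batch <- make_sample_batch(design, models)
  list(cal = cal, curves = fit_calibration(cal), batch = batch)
}

test_that("external-standard quantification inverts each analyte's own curve", {
  curves <- bare_curve(1, 0, "X")
  samples <- tibble::tibble(sample_id = "s1", analyte_id = "X", area = 42,
                            mass_g = 0.25, volume_ml = 25, dilution = 1)
  expect_equal(esm_quantify(samples, curves)$conc_esm, 42)

  # zero-noise closure: simulate -> calibrate -> ESM returns ground truth
  fx <- make_batch_fixture(gfn_detector_models(),
                           batch_design(lot_cv = 0, rep_cv = 0))
  got <- esm_quantify(fx$batch$samples, fx$curves) |>
    dplyr::inner_join(fx$batch$truth, by = c("sample_id", "analyte_id"))
  expect_equal(got$conc_esm, got$true_conc, tolerance = 1e-9)

  expect_error(esm_quantify(samples, bare_curve(1, 0, "other")),
               class = "qams_lookup_error")
})

test_that("QAMS equals ESM for the marker and for marker-like analytes", {
  fx <- make_batch_fixture(gfn_detector_models())
  rcf <- build_rcf_table(fx$cal, "GF3", method = "A", curves = fx$curves)
  both <- fx$batch$samples |>
    esm_quantify(fx$curves) |>
    qams_quantify(fx$curves, rcf)
  marker_rows <- both[both$analyte_id == "GF3", ]
  expect_equal(marker_rows$conc_qams, marker_rows$conc_esm, tolerance = 1e-10)

  # an analyte sharing the marker's response has RCF 1 and identical readouts
  twins <- detector_model(c("M", "T"), 1.82, -1.67, top_concentration = 1000)
  fx2 <- make_batch_fixture(
    twins, batch_design(base_content = c(M = 5, T = 5), lot_cv = 0, rep_cv = 0)
  )
  rcf2 <- build_rcf_table(fx2$cal, "M", method = "A", curves = fx2$curves)
  both2 <- fx2$batch$samples |>
    esm_quantify(fx2$curves) |>
    qams_quantify(fx2$curves, rcf2)
  expect_equal(both2$conc_qams, both2$conc_esm, tolerance = 1e-10)
})

test_that("with equal slopes, method-A QAMS reproduces ground truth exactly", {
  fx <- make_batch_fixture(equal_slope_models(),
                           batch_design(lot_cv = 0, rep_cv = 0))
  rcf <- build_rcf_table(fx$cal, "GF3", method = "A", curves = fx$curves)
  got <- qams_quantify(fx$batch$samples, fx$curves, rcf) |>
    dplyr::inner_join(fx$batch$truth, by = c("sample_id", "analyte_id"))
  expect_equal(got$conc_qams, got$true_conc, tolerance = 1e-9)
})

test_that("QAMS input validation catches bad RCF tables", {
  fx <- make_batch_fixture(gfn_detector_models())
  rcf <- build_rcf_table(fx$cal, "GF3", method = "A", curves = fx$curves)
  partial <- rcf[rcf$analyte_id != "GF5", ]
  attr(partial, "marker") <- "GF3"
  expect_error(qams_quantify(fx$batch$samples, fx$curves, partial),
               class = "qams_lookup_error")
  multi <- build_rcf_tables(fx$cal, "GF3", curves = fx$curves)
  expect_error(qams_quantify(fx$batch$samples, fx$curves, multi),
               class = "qams_schema_error")
})

test_that("content arithmetic is the standard assay formula", {
  expect_equal(content_percent(500, mass_g = 0.25, volume_ml = 25), 5.0)
  expect_equal(content_percent(0, 0.25, 25), 0)
  # linear in conc, volume and dilution; inverse-linear in mass
  base <- content_percent(200, 0.25, 25, 1)
  expect_equal(content_percent(400, 0.25, 25, 1), 2 * base)
  expect_equal(content_percent(200, 0.25, 50, 1), 2 * base)
  expect_equal(content_percent(200, 0.25, 25, 2), 2 * base)
  expect_equal(content_percent(200, 0.5, 25, 1), base / 2)
  expect_error(content_percent(1, 0, 25), class = "qams_domain_error")
  expect_error(content_percent(1, 0.25, -1), class = "qams_domain_error")
})

test_that("relative error is the signed QAMS-vs-ESM percentage", {
  expect_equal(relative_error(5, 5), 0)
  expect_equal(relative_error(1.05, 1.00), 5)
  expect_equal(relative_error(0.95, 1.00), -5)
  expect_error(relative_error(1, 0), class = "qams_domain_error")
  # literal contract against direct evaluation on random pairs
  set.seed(21)
  q <- runif(25, 0.5, 2); e <- runif(25, 0.5, 2)
  expect_equal(relative_error(q, e), (q - e) / e * 100)
})

test_that("method ranking prefers the apparent-concentration RCF", {
  # degenerate panel: every analyte is the marker, all methods tie at zero
  twins <- detector_model(c("M", "T"), 1.82, -1.67, top_concentration = 1000)
  cal <- make_calibration_series(twins)
  batch <- make_sample_batch(
    batch_design(base_content = c(M = 5, T = 5), lot_cv = 0, rep_cv = 0), twins
  )
  ranking <- rank_rcf_methods(batch$samples, cal, "M")
  expect_true(all(ranking$mean_abs_re < 1e-9))

  # equal-slope, unequal-intercept panel: only method A tracks the shift
  models <- equal_slope_models()
  cal <- make_calibration_series(models)
  batch <- make_sample_batch(batch_design(lot_cv = 0, rep_cv = 0), models)
  ranking <- rank_rcf_methods(batch$samples, cal, "GF3")
  expect_equal(attr(ranking, "selected"), "A")
  expect_lt(ranking$mean_abs_re[ranking$method == "A"], 1e-6)
  expect_gt(ranking$mean_abs_re[ranking$method == "F"], 1)

  expect_error(rank_rcf_methods(batch$samples[0, ], cal, "GF3"),
               class = "qams_insufficient_data_error")
})

test_that("content ratios to the raw lot recover designed multipliers", {
  contents <- tibble::tibble(
    sample_id = rep(c("Raw_01", "St_01-1"), each = 2),
    analyte_id = rep(c("GF2", "GF8"), 2),
    content_qams_pct = c(4, 6, 8, 6)
  )
  pairing <- tibble::tibble(sample_id = "St_01-1", raw_id = "Raw_01")
  ratios <- ratio_to_raw(contents, pairing)
  expect_equal(ratios$ratio, c(2, 1))

  expect_error(
    ratio_to_raw(contents, tibble::tibble(sample_id = "nope", raw_id = "Raw_01")),
    class = "qams_pairing_error"
  )
  zero <- dplyr::mutate(contents,
                        content_qams_pct = replace(.data$content_qams_pct,
                                                   .data$sample_id == "Raw_01", 0))
  expect_warning(out <- ratio_to_raw(zero, pairing),
                 class = "qams_zero_raw_warning")
  expect_true(all(is.na(out$ratio)))

  # seeded noisy batch: external-standard ratios sit within 3x the area noise
  set.seed(17)
  models <- gfn_detector_models(noise_cv = 0.01)
  design <- batch_design(
    group_multipliers = list(S = c(GF2 = 1.5, GF8 = 0.6)), rep_cv = 0
  )
  fx <- make_batch_fixture(models, design)
  rcf <- build_rcf_table(fx$cal, "GF3", method = "A", curves = fx$curves)
  contents <- quantify_contents(fx$batch$samples, fx$curves, rcf)
  ratios <- ratio_to_raw(contents, fx$batch$pairing, value = "esm") |>
    dplyr::filter(startsWith(.data$sample_id, "S_")) |>
    dplyr::summarise(ratio = mean(.data$ratio), .by = "analyte_id")
  expect_equal(ratios$ratio[ratios$analyte_id == "GF2"], 1.5, tolerance = 0.03)
  expect_equal(ratios$ratio[ratios$analyte_id == "GF8"], 0.6, tolerance = 0.03)
})

test_that("manual exclusion drops flagged outlier replicates", {
  contents <- tibble::tibble(
    sample_id = c("Raw_01", "L_01-1", "L_01-2"),
    analyte_id = "GF3",
    content_qams_pct = c(5, 5.2, 3.0)
  )
  pairing <- tibble::tibble(sample_id = c("L_01-1", "L_01-2"),
                            raw_id = "Raw_01")
  kept <- ratio_to_raw(contents, dplyr::filter(pairing, sample_id != "L_01-2"),
                       exclude = "L_01-2")
  expect_equal(kept$sample_id, "L_01-1")
})
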