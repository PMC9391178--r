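test_that("method A averages the apparent-concentration ratio over levels", {
  # analyte responding exactly like the marker: RCF 1 at every level
  marker_series <- power_law_series("GF3", 1.82, -1.67)
  marker_curve <- fit_calibration(marker_series)
  clone <- dplyr::mutate(marker_series, analyte_id = "X")
  entry <- rcf_method_a(marker_curve, clone)
  expect_equal(entry$rcf, 1, tolerance = 1e-10)
  expect_equal(attr(entry, "per_level")$rcf, rep(1, 5), tolerance = 1e-10)

  # identity marker curve: C_detected = area
  twofold <- tibble::tibble(analyte_id = "Y", concentration = c(10, 100),
                            area = c(20, 200))
  entry <- rcf_method_a(bare_curve(1, 0, "GF3"), twofold)
  expect_equal(attr(entry, "per_level")$rcf, c(2, 2))
  expect_equal(entry$rcf, 2)
})

test_that("method B is the slope ratio of the two log-log curves", {
  gf3 <- bare_curve(1.82, -1.67, "GF3")
  expect_equal(round(rcf_method_b(gf3, bare_curve(1.88, -1.70, "GF1"))$rcf, 2), 1.03)
  expect_equal(round(rcf_method_b(gf3, bare_curve(1.94, -1.90, "GF2"))$rcf, 2), 1.07)
  expect_equal(rcf_method_b(gf3, gf3)$rcf, 1)
  expect_equal(nrow(attr(rcf_method_b(gf3, gf3), "per_level")), 0)
  expect_error(rcf_method_b(bare_curve(0, 0), gf3),
               class = "qams_degenerate_curve_error")
})

test_that("per-level ratio methods C, D and E match hand evaluation", {
  marker <- power_law_series("GF3", 1.82, -1.67)
  for (f in list(rcf_method_c, rcf_method_d, rcf_method_e)) {
    entry <- f(marker, dplyr::mutate(marker, analyte_id = "X"))
    expect_equal(entry$rcf, 1, tolerance = 1e-12)
  }

  one <- function(analyte_id, conc, area) {
    tibble::tibble(analyte_id = analyte_id, level_index = 1,
                   concentration = conc, area = area)
  }
  # C: (C_s/lgA_s)/(C_k/lgA_k)
  expect_equal(rcf_method_c(one("S", 10, 100), one("K", 20, 100))$rcf, 0.5)
  # D: (lgC_k/lgA_k)/(lgC_s/lgA_s)
  expect_equal(rcf_method_d(one("S", 10, 10), one("K", 100, 10))$rcf, 2)
  # E: (A_s/C_s)/(A_k/C_k)
  expect_equal(rcf_method_e(one("S", 100, 200), one("K", 100, 100))$rcf, 2)

  # mismatched level sets cannot be paired
  short <- dplyr::filter(marker, level_index < 5) |>
    dplyr::mutate(analyte_id = "X")
  expect_error(rcf_method_c(marker, short), class = "qams_pairing_error")

  # lg(area) degeneracies
  expect_error(rcf_method_c(one("S", 10, 1), one("K", 10, 100)),
               class = "qams_domain_error")
  expect_warning(rcf_method_c(one("S", 10, 0.5), one("K", 10, 100)),
                 class = "qams_log_domain_warning")
  expect_warning(rcf_method_d(one("S", 1, 10), one("K", 10, 10)),
                 class = "qams_log_domain_warning")
})

test_that("method F is unity for any analyte", {
  entry <- rcf_method_f("GF7")
  expect_equal(entry$rcf, 1)
  expect_equal(nrow(attr(entry, "per_level")), 0)
})

test_that("the marker's RCF against itself is 1 under every method", {
  # noiseless: exactly 1 before rounding
  cal <- make_calibration_series(gfn_detector_models())
  for (m in LETTERS[1:6]) {
    tab <- build_rcf_table(cal, "GF3", method = m, digits = NULL)
    expect_equal(tab$rcf_full[tab$analyte_id == "GF3"], 1, tolerance = 1e-10)
  }
  # noisy data: 1.00 at reporting precision
  set.seed(5)
  noisy <- make_calibration_series(gfn_detector_models(noise_cv = 0.01))
  for (m in LETTERS[1:6]) {
    tab <- build_rcf_table(noisy, "GF3", method = m)
    expect_equal(tab$rcf[tab$analyte_id == "GF3"], 1.00)
  }
})

test_that("a panel sharing the marker's response gives RCF 1.00 everywhere", {
  models <- detector_model(paste0("GF", 1:4), slope = 1.82, intercept = -1.67,
                           top_concentration = 1000)
  cal <- make_calibration_series(models)
  for (m in LETTERS[1:6]) {
    tab <- build_rcf_table(cal, "GF1", method = m)
    expect_equal(tab$rcf, rep(1, 4), tolerance = 1e-10)
  }
})

test_that("assembled tables carry per-level detail consistent with the mean", {
  set.seed(3)
  cal <- make_calibration_series(gfn_detector_models(noise_cv = 0.02))
  for (m in c("A", "C", "D", "E")) {
    tab <- build_rcf_table(cal, "GF3", method = m, digits = NULL)
    per <- attr(tab, "per_level")
    expect_equal(dplyr::n_distinct(per$level_index), 5)
    means <- per |>
      dplyr::summarise(m = mean(.data$rcf), .by = "analyte_id")
    expect_equal(tab$rcf_full[match(means$analyte_id, tab$analyte_id)],
                 means$m, tolerance = 1e-12)
  }
  tab_f <- build_rcf_table(cal, "GF3", method = "F")
  expect_equal(tab_f$rcf, rep(1, 8))
  expect_equal(nrow(attr(tab_f, "per_level")), 0)
})

test_that("unknown markers and methods are rejected", {
  cal <- make_calibration_series(gfn_detector_models())
  expect_error(build_rcf_table(cal, "GF99"), class = "qams_lookup_error")
  expect_error(build_rcf_table(cal, "GF3", method = "Z"))
})

test_that("scaling analyte areas shifts method-A RCFs as the curve predicts", {
  marker_series <- power_law_series("GF3", 1.82, -1.67)
  marker_curve <- fit_calibration(marker_series)
  analyte <- power_law_series("X", 1.82, -1.80)
  base <- rcf_method_a(marker_curve, analyte)
  for (delta in c(-0.3, 0.1, 0.5)) {
    shifted <- dplyr::mutate(analyte, area = .data$area * 10^delta)
    got <- rcf_method_a(marker_curve, shifted)
    # oracle: direct per-level recomputation of C_detected/C
    oracle <- mean(10^((log10(shifted$area) - marker_curve$intercept) /
                         marker_curve$slope) / shifted$concentration)
    expect_equal(got$rcf, oracle, tolerance = 1e-12)
    expect_equal(got$rcf, base$rcf * 10^(delta / marker_curve$slope),
                 tolerance = 1e-10)
  }
})

test_that("equal slopes make method A level-independent and method B blind", {
  # same exponent, different intercepts: the detector shift that only the
  # apparent-concentration method can see
  marker_series <- power_law_series("GF3", 1.82, -1.67)
  marker_curve <- fit_calibration(marker_series)
  analyte <- power_law_series("X", 1.82, -1.95)
  entry_a <- rcf_method_a(marker_curve, analyte)
  per <- attr(entry_a, "per_level")$rcf
  expect_equal(diff(range(per)), 0, tolerance = 1e-12)
  expect_equal(entry_a$rcf, 10^((-1.95 + 1.67) / 1.82), tolerance = 1e-10)

  entry_b <- rcf_method_b(marker_curve, fit_calibration(analyte))
  expect_equal(entry_b$rcf, 1, tolerance = 1e-10)
})

test_that("the wide report has methods as rows and analytes as columns", {
  cal <- make_calibration_series(gfn_detector_models())
  wide <- rcf_wide(build_rcf_tables(cal, "GF3"))
  expect_equal(wide$method, LETTERS[1:6])
  expect_named(wide, c("method", paste0("GF", 1:8)))
  expect_equal(wide$GF3, rep(1, 6))
})
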