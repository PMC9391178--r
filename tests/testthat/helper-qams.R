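# Shared fixtures and independent oracles.

# Closed-form OLS via the normal equations, written from sums so it shares
# no code path with lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  list(slope = slope, intercept = (sum(y) - slope * sum(x)) / n)
}

# A noiseless calibration series from explicit power-law parameters.
power_law_series <- function(analyte_id, slope, intercept,
                             conc = c(100, 250, 500, 750, 1000)) {
  tibble::tibble(
    analyte_id = analyte_id,
    level_index = seq_along(conc),
    concentration = conc,
    area = 10^(slope * log10(conc) + intercept)
  )
}

# Panel with identical slopes but different intercepts: the configuration
# where only the apparent-concentration RCF (method A) can be exact.
equal_slope_models <- function(noise_cv = 0) {
  detector_model(
    analyte_id = paste0("GF", 1:8),
    slope = 1.82,
    intercept = c(-1.70, -1.90, -1.67, -1.56, -1.66, -1.76, -1.77, -1.91),
    noise_cv = noise_cv,
    top_concentration = 1000
  )
}

# One-row curve table without ranges (no extrapolation warnings).
bare_curve <- function(slope, intercept, analyte_id = "X") {
  tibble::tibble(analyte_id = analyte_id, slope = slope, intercept = intercept)
}
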