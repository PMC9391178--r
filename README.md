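# qams

Single-marker quantification of multiple analytes for nonlinear
evaporative light scattering detection (ELSD).

## The problem

Quantitative analysis of multi-components by a single marker (QAMS) prices
an assay at one reference standard instead of many: each analyte's
concentration is read off the *marker's* calibration curve and corrected by
a relative correction factor (RCF). With a UV detector, whose response is
linear, the RCF is simply a slope ratio. An ELSD, however, responds as a
power law,

```
A = 10^b · C^F        i.e.   lg A = F · lg C + b
```

with per-analyte exponent `F` (typically 1.8–1.95 for oligosaccharide
assays) and log-intercept `b`. In that nonlinear regime at least six RCF
definitions circulate, and they disagree. This package implements all six
and the machinery to decide between them:

* **calibration** — per-analyte OLS fits of `lg A` on `lg C`, bidirectional
  area ↔ concentration prediction, R², linear range, and S/N-based LOD/LOQ;
* **RCF methods A–F** — (A) the apparent-concentration ratio
  `C_detected/C_k` averaged over calibration levels, where `C_detected` is
  the analyte's area read through the marker's curve; (B) the slope ratio
  `F_k/F_s`; (C) `(C_s/lg A_s)/(C_k/lg A_k)`; (D)
  `(lg C_k/lg A_k)/(lg C_s/lg A_s)`; (E) `(A_s/C_s)/(A_k/C_k)`; (F) unity;
* **quantification** — external-standard (ESM, each analyte on its own
  curve) and QAMS (`C_k = C_detected / RCF_k`) contents in % w/w, and the
  selection criterion `RE% = (QAMS − ESM)/ESM × 100` that ranks the six
  methods by mean |RE| across a sample batch;
* **validation** — RSD, spike recovery `(detected − origin)/spiked × 100`,
  precision/stability/repeatability summaries, and cross-instrument RCF
  system suitability;
* **simulation** — a synthetic ELSD with known ground truth (power-law
  response, lognormal multiplicative noise, additive baseline noise) and a
  batch generator emulating a raw-vs-processed botanical study, so the
  whole pipeline is testable without instrument data.

Only method A carries the marker's intercept into the correction; when two
analytes share a response exponent but differ in intercept, methods B and F
are blind to the shift while A compensates it exactly. The ranking
machinery makes that observable on synthetic batches.

Intended users: analytical chemists developing or validating LC-ELSD
single-marker assays, and anyone needing a reproducible peak-table-to-content
pipeline with the audit trail regulators expect.

## Worked example

Simulate an eight-fructooligosaccharide panel (GF1–GF8, marker GF3 =
nystose) with 1 % area noise, calibrate, compute all six RCF tables, and
rank the methods on a 30-sample batch:

```r
library(qams)

panel <- gfn_detector_models(noise_cv = 0.01)  # published slopes/intercepts
set.seed(42)
cal    <- make_calibration_series(panel)       # 5-point dilution series
curves <- fit_calibration(cal)
curves
#> <qams_calibration: 8 analyte(s), log-log OLS>
#> # A tibble: 8 × 7
#>   analyte_id slope intercept r_squared range_low range_high n_levels
#> 1 GF1         1.88     -1.69     1.000      93.4       934.        5
#> 2 GF2         1.94     -1.90     1.000      73.0       730.        5
#> 3 GF3         1.81     -1.64     1.000     118.       1180.        5
#> # i 5 more rows

rcf_wide(build_rcf_tables(cal, marker = "GF3"))
#> # A tibble: 6 × 9
#>   method   GF1   GF2   GF3   GF4   GF5   GF6   GF7   GF8
#> 1 A       1.17  1.08     1  1.07  0.98  0.86  0.91  0.83
#> 2 B       1.04  1.07     1  0.99  1.01  1     1.01  1.03
#> ...
#> 6 F       1     1        1  1     1     1     1     1

batch <- make_sample_batch(batch_design(), panel)
rank_rcf_methods(batch$samples, cal, marker = "GF3")
#> <qams_method_ranking: selected method A>
#> # A tibble: 6 × 6
#>   method mean_abs_re median_abs_re max_abs_re mean_re     n
#> 1 A             1.11         0.297       8.00   0.979   240
#> 2 B             9.24         9.26       19.4   -2.03    240
#> 3 C             9.46         8.40       22.6   -9.46    240
#> 4 F            10.2         10.4        19.5   -0.146   240
#> 5 D            11.4         11.3        22.3   -1.88    240
#> 6 E            19.3         18.5        46.4  -11.5     240
```

Reading the numbers: every RCF table has 1.00 in the marker's own column;
the ranking says that quantifying via method A's RCFs stays within about
1 % of the external-standard result on average (pure measurement noise),
while every other definition leaves 9–19 % systematic error — so method A
is the one a monograph should adopt. `autoplot(curves, cal)`,
`plot_rcf_methods(...)` and `autoplot(ranking)` draw the corresponding
figures, and `quantify_contents()` returns the per-sample content table
(ESM, QAMS, RE%) behind the summary.

A command-line surface wraps the same functions:

```sh
exec/qams simulate --out simdata --seed 3
exec/qams pipeline --calibration simdata/calibration.csv \
                   --samples simdata/samples.csv --marker GF3 --out results
```

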