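---
title: "Single-marker quantification on a nonlinear detector: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification on a nonlinear detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qams)
```

## The detector model

An evaporative light scattering detector is mass-dependent and nonlinear:
over its working range the peak area follows a power law in concentration,

$$A = 10^{b}\,C^{F}, \qquad \lg A = F \lg C + b,$$

with a per-analyte exponent $F$ and log-intercept $b$. All logarithms in
this package are base 10 (`lg`), the convention under which published
ELSD regression equations such as $y = 1.82x - 1.67$ are stated; a natural
log would rescale every intercept. Calibration is therefore ordinary
least squares of $\lg A$ on $\lg C$. The fit is **unweighted**: with five
levels spanning one decade and multiplicative (constant-CV) noise, the
log transform already variance-stabilises the residuals, and no weighting
scheme is part of the published convention. A minimum of three levels is
enforced (`min_levels`); the reference design has five, produced by
diluting a mixed standard 1, 1.5, 2.2, 4 and 10 times, so every analyte's
level $i$ shares a physical dilution event.

Inverse prediction is the exact algebraic inverse,
$C = 10^{(\lg A - b)/F}$. Readouts outside the calibrated range are
**flagged with a warning, never refused**: assay practice quantifies
unknowns first and judges range compliance second, and a hard error would
make the flag untestable downstream.

### LOD and LOQ

The package reports limits of detection and quantification by the
signal-to-noise convention: LOD (LOQ) is the concentration whose
*predicted* area equals $3\sigma$ ($10\sigma$) for a user-supplied
baseline-noise SD $\sigma$, inverted through the power law. This is a
declared choice among the three common procedures (S/N, calibration-curve
SD, dilution to extinction); published limit values for this assay class
do not come with a stated procedure, so the package makes the most widely
used one explicit and parameterises the only free quantity, $\sigma$.

## The six relative correction factors

With nystose-like marker $s$ and analyte $k$, the implemented definitions
are

| method | formula | per-level? |
|---|---|---|
| A | $C_{k\text{-detected}}/C_k$, with $C_{k\text{-detected}} = 10^{(\lg A_k - b_s)/F_s}$ | yes |
| B | $F_k/F_s$ | no |
| C | $(C_s/\lg A_s)\,/\,(C_k/\lg A_k)$ | yes |
| D | $(\lg C_k/\lg A_k)\,/\,(\lg C_s/\lg A_s)$ | yes |
| E | $(A_s/C_s)\,/\,(A_k/C_k)$ | yes |
| F | $1.00$ | no |

Per-level methods are averaged with the **arithmetic mean** across
calibration levels (the stated convention is "average", unqualified), and
the per-level values are kept as an audit attribute. Pairing for C, D and
E is by `level_index`, justified by the co-dilution of the mixed
standard; a separately prepared series (as for sucrose here) pairs by
ordinal position, which these formulas accommodate because both $C_k$ and
$C_s$ appear explicitly. Reported RCFs round to two decimals — the
precision at which such factors are published and transferred — while all
computation keeps full precision (`rcf_full`), with rounding applied only
at the reporting/serialisation boundary.

Two degeneracies of the log-containing formulas are handled explicitly:
an area of exactly 1 makes $\lg A = 0$ and is an error (division by
zero); areas between 0 and 1 make $\lg A$ negative, silently flipping the
sign of methods C and D, so they are computed as-is but warned about.
Real ELSD areas are far above 1, so the warning marks data that should
not occur.

### Why only method A can track an intercept shift

Method A is the only definition that carries the *marker's intercept*
into the correction. If analyte and marker share the exponent
($F_k = F_s = F$) but differ in intercept, the apparent concentration is
$C_{k\text{-detected}} = C\,10^{(b_k - b_s)/F}$ at every level: the
per-level RCFs are constant, and dividing by the averaged RCF recovers
the truth exactly. Method B returns $F_k/F_s = 1$ regardless of the
intercepts, and method F is 1 by fiat — both then mis-state the content
by the factor $10^{(b_k-b_s)/F}$. This asymmetry is the mechanism behind
the package's ranking experiments, which reproduce it as a synthetic
end-to-end property.

## Quantification and method selection

The external-standard method (ESM) reads each analyte off its own curve;
QAMS reads everything off the marker's curve and corrects:
$C_k = C_{k\text{-detected}} / \mathrm{RCF}_k$. This inversion — the
exact inverse of method A's definition — is applied **uniformly to
whichever method's RCFs are supplied**. That is a design decision: the
six definitions are only comparable if they feed one and the same content
pipeline, and it is the only reading under which method F means "quantify
everything as if it were the marker". Contents are reported on an
as-weighed basis,

$$\text{content \%} = \frac{C \cdot V \cdot D}{m \cdot 10^6} \times 100,$$

with no moisture correction (none is part of the modelled procedure).

The selection criterion is the relative error
$\mathrm{RE}\% = (\mathrm{QAMS} - \mathrm{ESM})/\mathrm{ESM} \times 100$
per (sample, analyte). Methods are ranked by the **mean of |RE| pooled
over analytes and samples**; the reference account shows RE
distributions and says "closest to zero" without fixing an aggregate, so
the package picks the simplest one and also reports median and maximum
|RE| so a user can check the ranking is not an artifact of pooling.
Whether per-analyte errors should be signed or absolute before pooling is
genuinely open; pooling signed errors would let opposite biases cancel,
which is why the ranking key is |RE|.

Outlier replicates (a degraded preparation, say) are removed only through
an explicit `exclude` list in `ratio_to_raw()` — the judgment "this
replicate is significantly lower" has no published threshold, so the
package refuses to automate it.

## Validation statistics

RSD uses the sample ($n-1$) standard deviation; that convention, and no
other, reproduces the published low-level recovery RSD of 1.81 % from its
own printed triplicate. Spike recovery is
$(\text{detected} - \text{origin})/\text{spiked} \times 100$ with the
origin content taken from a prior assay of the same lot, not re-estimated.
Repeatability across a deliberate three-mass design (0.125, 0.250,
0.375 g) must be computed on *content*, not raw area — the masses differ
by design, so areas are incommensurable; `summarize_validation()`
documents and assumes this. Cross-instrument suitability of RCFs is the
column-wise mean and RSD across per-instrument RCF tables computed with
the same marker and method, and is required (and tested) to coincide with
`rsd()` applied per analyte.

## What the simulator emulates — and what it does not

`detector_model()` + `simulate_area()` generate
$A = 10^{F \lg C + b}\,e^{\varepsilon}\!+\!\eta$ with lognormal
multiplicative noise $\varepsilon \sim N(0, \ln(1+\mathrm{cv}))$ and
additive baseline noise $\eta \sim N(0, \sigma)$. Multiplicative noise is
the dominant ELSD term (nebulisation noise scales with signal); the
additive term exists mainly to give LOD/LOQ a physical anchor. No
published noise magnitude exists for this assay, so the default working
value (`noise_cv` 0.01–0.02) was chosen once to land replicate-precision
RSDs in the low single-digit percent range typical of validated ELSD
methods, and is not revisited.

`batch_design()`/`make_sample_batch()` emulate a raw-vs-processed
botanical study: 3 raw lots, each processed by steaming (`St`),
licorice boiling (`L`) and salt steaming (`S`) in triplicate — 30 samples
of 8 analytes. Defaults put the marker near 5 % w/w with the panel
totalling about 45 %, lot-to-lot content jitter is lognormal with CV
10 % (shared between a raw lot and its processed descendants, so content
*ratios* cancel it), replicate jitter 2 %, and the group multipliers
encode the expected processing chemistry — high-polymer analytes
(GF7/GF8) hydrolysing downward and GF1/GF2 rising under steaming, mild
shifts for the boiled product. The generator returns the hidden truth
table alongside the observable batch, which is what makes parameter-
recovery tests possible.

What it deliberately does **not** emulate: chromatographic reality
(retention times, peak shape, co-elution, integration error), carryover,
drift within a sequence, matrix effects on the response exponent, or
moisture differences between samples. Passing tests therefore demonstrate
the *arithmetic* of calibration, correction and ranking under a faithful
response model — not robustness to the failure modes of real
chromatograms, which enter this pipeline only as already-integrated peak
areas.

## Numerical choices and degenerate inputs

* $R^2$ is computed directly as $1 - \mathrm{RSS}/\mathrm{TSS}$ (exact
  1 on noiseless data, where `summary.lm()` would warn) and reported to
  four decimals at serialisation, matching the precision of published
  linearity tables.
* Exactness tolerances used in the test suite: parameter recovery and
  OLS-oracle agreement to 1e-10 relative, roundtrip
  `predict_concentration(predict_area(C))` to 1e-9, noiseless
  pipeline-closure to 1e-9.
* Fewer than 3 levels, nonpositive concentrations/areas, an all-equal
  concentration design, a zero marker slope, nonpositive RCFs, and an
  empty batch are all typed errors (`qams_*_error` condition classes);
  out-of-range readouts and sub-unity areas are typed warnings.
* Randomness flows through R's global RNG only; a design with all noise
  terms zero consumes no random numbers, so seeded and unseeded runs of
  a noiseless pipeline are bit-identical.
* Problem sizes in the shipped tests: 5-level calibrations, panels of 8
  analytes, batches of 30 samples (240 determinations), and one
  10,000-draw Monte-Carlo check of the noise model's CV — sizes chosen
  to mirror the reference study design while keeping the full suite
  under half a minute.

## Known limitations

* The RCF inversion assumes areas are positive and well above 1; assays
  whose raw areas approach unity need rescaled units before methods C/D
  are meaningful.
* Method-A RCFs are concentration-averaged; when exponents differ
  between analyte and marker the correction is exact only near the
  geometric centre of the calibration, and content *ratios* taken from
  QAMS values inherit a small exponent-mismatch bias (use ESM contents
  for ratio analyses, as the tests do).
* LOD/LOQ depend entirely on the supplied baseline SD; the package does
  not estimate $\sigma$ from data.
* Multivariate chemometrics (HCA, PCA, OPLS-DA, VIP) on the content
  matrix is out of scope by design; `ratio_to_raw()` emits the matrix
  such tools consume.
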