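---
title: "Model-based film calibration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based film calibration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmcal)
```

## The problem

Radiographic film is an attractive dosimeter for radiotherapy quality
assurance: it is convenient, has excellent spatial resolution, and measures a
whole plane at once. Its weakness is that the dose response drifts with the
film emulsion batch, with the day-to-day state of the processor chemistry,
and with the photon scatter environment (field size and depth in phantom).
The classical remedy — a fresh calibration curve of 5–15 films for every
measurement session and every irradiation condition — is accurate but
expensive in film and time.

`filmcal` implements the model-based alternative: describe the calibration
curve with a three-parameter saturation model, learn which parameters move
with which physical cause, and exploit that structure so that one to three
exposed films suffice to calibrate a new session or a new geometry.

## The response model

The scanned pixel value of a film exposed to dose $D$ (cGy) follows the
single-target single-hit response

$$P(D) = P_0 + P_s\left(1 - e^{-mD/P_s}\right),$$

where

* $P_0$ (counts) is the **background**: fog plus base-layer signal of
  unexposed film. It is re-measured from an unexposed film of the batch and
  varies little (≈2% relative, 1σ).
* $P_s$ (counts) is the **saturation** value of the *net* signal: the
  asymptote of $P - P_0$ when every silver grain is developable. It is a
  property of the emulsion batch (grain concentration). Note the convention:
  the *total* pixel value saturates at $P_0 + P_s$.
* $m$ (counts/cGy) is the **sensitivity slope**, the initial slope of the
  curve. It carries the film-processing state and the energy-spectrum
  dependence, and factorizes as $m = m_E(\text{field size}, \text{depth})
  \cdot m_{FP}(\text{processing})$.

The dose inverse is closed-form,

$$D = -\frac{P_s}{m}\,\ln\!\left(1 - \frac{P - P_0}{P_s}\right),$$

defined for $P_0 \le P < P_0 + P_s$. `dose_from_pixel()` refuses pixels
within $10^{-9} P_s$ of saturation instead of returning an enormous dose:
the scanner-saturation regime is outside the model's validity, and a
numerical answer there would be noise amplified without bound.

All pixel values in the package are real numbers (ROI averages), never
integer counts.

## Fitting strategies

`fit_full()` is the reference strategy: unweighted least squares on eight
(or more) points by Levenberg–Marquardt, with $P_0$ fixed to the
unexposed-film value when available. We use unweighted residuals because
readout noise is roughly proportional to the pixel value but the calibrated
dose range (16–128 cGy) spans less than a factor of three in pixel value;
the weighting question is moot at that dynamic range.

The reduced-point strategies trade dose points for prior knowledge:

* **Method I** — universal $P_0$ *and* $P_s$; one or two points give $m$.
  With one point the slope is closed-form.
* **Method II** — universal $P_s$, measured background; one or two points
  give $m$.
* **Method III** — measured background only; two points determine
  $(P_s, m)$ exactly, three by least squares.

Exactly-determined cases are solved deterministically, not by general
optimization. For the two-point Method III system we reparameterize by
$u = m/P_s$: the net-pixel ratio $n_1/n_2 = (1-e^{-uD_1})/(1-e^{-uD_2})$ is
strictly increasing in $u$ from $D_1/D_2$ (no bending) to 1 (hard
saturation), so a bracketed root search on $u \in (10^{-9}/D_2,\; 50/D_1)$
cannot miss or multiply count the solution. Data whose net pixels are
proportional to dose (or grow super-linearly) have no positive solution and
fail loudly as unidentifiable/infeasible rather than returning an extreme
$P_s$.

Initialization for the iterative fits: $m_0$ from the secant through the
lowest-dose point and $P_{s,0} = 1.2\times$ the largest net pixel, which
keeps the model feasible from the first iteration. Positivity is enforced by
box constraints; a fit pressed against them errors instead of silently
clipping. Convergence: relative parameter/objective change below $10^{-8}$
or 200 iterations.

**Saturation identifiability.** When the data never reach ≈5% of
saturation, the curvature term of the model (quadratic in $mD/P_s$) is
smaller than typical 1% readout noise and $P_s$ is effectively
unconstrained. `fit_full()` flags such fits `ps_unidentifiable` with a
warning. The 5% threshold is a documented engineering choice: at net
response fraction $x$, the fractional curvature signal is $\approx x/2$, so
$x < 0.05$ puts it below ~2.5%, comparable to two noise standard
deviations on a single point.

**Two-step batch fit.** Because $P_s$ is a batch property, `fit_batch_two_step()`
first fits every film freely, averages $P_s$ over the batch, then refits
each film's slope at the shared optimum. Multi-field reference films are
excluded from the average: scatter cross-talk between their subfields bends
their apparent curve toward earlier saturation and biases their fitted
$P_s$ low (the synthetic generator reproduces this mechanism — see below).

## Calibration transfer by parameter ratios

Ratios of same-day parameters cancel the processing factor $m_{FP}$, so the
slope ratio between a target geometry and the reference geometry is a
stable, geometry-only quantity. `derive_curve()` builds a curve for any
tabulated geometry from one reference curve:

$$P_0' = P_0, \qquad P_s' = P_s \cdot r_{P_s}, \qquad m' = m \cdot
r_m(\text{FS}, d).$$

The slope-ratio table is user-supplied measured data; empirically the ratios
fall in ≈0.99–1.05, decreasing with depth above ~0.5 cm
and increasing below it, and the package warns (but does not refuse) when a
table strays far outside that band. Lookup is by exact key; interpolation
(linear in depth at fixed field size) must be explicitly enabled, because no
principled interpolation rule across scatter conditions comes with the data.

The figure of merit for any substitute curve is the **local dose error**:
invert the truth curve's pixel value at dose $D$ through the test curve and
report the relative dose difference. `local_dose_error()` evaluates it on a
1-cGy grid over 10–150 cGy by default. Below 10 cGy relative errors are
dominated by the background and blow up while the *absolute* error stays
within ~0.1 cGy, so that region is reported separately rather than mixed
into the maximum.

Useful limiting behaviour (both are tested properties): a pure slope error
$\delta = \Delta m/m$ produces the dose-independent local error
$-\delta/(1+\delta)$, and a pure saturation error produces a local error
that grows monotonically with dose. Background errors matter only at very
low dose. This is why processing variation (slope) dominates the useful
range, and why a "universal" saturation value is safe only when the batch
truly matches it: the bundled reference sets include a batch whose
saturation sits 9% below the universal value, for which the
universal-saturation methods exceed 5% local dose error while Method III
(saturation from the data) stays within 1%.

## Uncertainty model

Propagating the four error sources through the dose inverse at net response
fraction $f = (P-P_0)/P_s$ gives

$$\left(\frac{\sigma_D}{D}\right)^2 =
\underbrace{c_{P_s}\left(\frac{\sigma_{P_s}}{P_s}\right)^2 +
c_m\left(\frac{\sigma_m}{m}\right)^2}_{\text{systematic}} +
\underbrace{c_P\left(\frac{\sigma_P}{P}\right)^2 +
c_{P_0}\left(\frac{\sigma_{P_0}}{P_0}\right)^2}_{\text{random}}$$

with $c_m = 1$ exactly (since $\partial D/\partial m = -D/m$) and the other
weights given by the squared logarithmic sensitivities
(`propagation_coefficients()`). At midrange ($f = 0.5$) with typical
parameter magnitudes the exact weights are ≈(0.20, 1, 2.8, 0.047); the
conventional rounded quadruple (0.25, 1, 3, 0.05) is available as
`rounded_coefficients()` and is the default of `propagate_analytic()`. Note
the weights for the pixel and background terms are expressed against the
*total* pixel value and the background respectively, which is what makes
$c_P \approx 3$ at midrange.

Two conventions in this formula deserve a note. First, the saturation term
is *squared* like the others; the budget is a quadrature sum throughout
(the split into brackets is systematic-vs-random bookkeeping, and the
identity $\sigma_D^2 = \text{sys}^2 + \text{rand}^2$ is asserted in tests).
Second, with the typical component budget (0.5%, 1%, 1%, 0.5%) for
(saturation, slope, pixel, background), the total is ≈2.0% (1σ), i.e. ≈4%
at 95% confidence — the accuracy with which one to three dose points can
replace a full curve.

`propagate_monte_carlo()` cross-checks the analytic budget by perturbing
$(P_s, m, P_0)$ and the observed pixel with independent Gaussian relative
errors and inverting each draw. Independence is a modelling choice: no
parameter covariance information accompanies the fitted values, and the fit
correlations between $P_s$ and $m$ are deliberately not propagated (they
belong to a single film's fit, whereas the budget describes batch-level
dispersions). The Monte-Carlo check is compared against the *exact*
coefficients, where agreement at $10^5$ draws is within 3 bootstrap
standard errors; against the rounded quadruple only ~3% agreement can be
expected, which is the rounding error of the quadruple itself.

`parameter_influence_curves()` renders the same physics as curves: each
parameter perturbed alone by $\pm z\sigma$ at a chosen confidence level,
local dose error plotted against dose.

## The synthetic generator

`generator_config()` encodes the study conditions the package is tested
under, taken from a multi-year QA record of Kodak XV film read on a Lumisys
scanner:

* mean curve $(P_0, P_s, m) = (245, 3271, 31.7)$;
* inter-day relative SDs $(1.8\%, 5.7\%, 7.7\%)$ for $(P_0, P_s, m)$ —
  batch and processor drift over years;
* intra-day relative SDs $(1.8\%, 0.8\%)$ for $(P_s, m)$ — different films,
  same processing day;
* 1% Gaussian relative readout noise (multiplicative, because scanner
  counts are post-processed averages rather than raw quanta — Poisson
  statistics do not apply);
* an eight-dose schedule $\{16, 24, 32, 48, 64, 80, 96, 128\}$ cGy. Only
  the 16–128 cGy range is prescribed by the protocol; the interior points
  are this package's choice of a roughly geometric ladder and are
  configurable.

Parameter draws are independent Gaussians across parameters and days; no
covariance structure is imposed because none is known. Draws violating
positivity are rejected and redrawn (with an error if a configuration
rejects more than 10% — such SDs are physically implausible).

`render_eightfield_image()` synthesises the scan of a single film exposed
with eight 3×3 cm² subfields on a 2×4 grid with 1-cm unexposed gaps (the
grid spacing is this package's choice; only the subfield size and dose range
are prescribed), at 0.123 mm pixel pitch. Image coordinates are row-major
with origin top-left, half-open pixel footprints, position = index × pitch;
a 3-cm subfield is `floor(30/0.123)` = 243 px on a side. ROI extraction
averages pixels whose centres fall in a half-open square; at the default
pitch a 1.23 mm ROI is exactly 10×10 pixels and a 12.3 mm ROI 100×100,
regardless of alignment. The optional cross-talk term adds a fraction of the
edge-adjacent subfields' dose to each subfield; because low-dose fields gain
relatively more, the apparent curve saturates earlier and a subsequent fit
under-estimates $P_s$ — reproducing the reason multi-field reference films
are excluded from batch saturation averages.

What the generator does *not* emulate — and hence what green tests do not
certify about real film: scanner PSF and glare, spatial nonuniformity of
scanner response, film-grain spatial correlation, processor temporal drift
within a day, dose-rate (reciprocity) effects, and any phantom-material or
orientation dependence. Synthetic validation shows the algorithms are
correct under the stated noise model, not that the noise model exhausts
reality.

## Numerical choices and degenerate inputs

* Saturation guard: inversion refuses $P \ge P_0 + P_s(1 - 10^{-9})$.
* Closed-form/bracketed solvers for exactly-determined fits; bracket
  $mD/P_s \in (10^{-6}, 50)$.
* Half-open ROI windows carry a $10^{-9}$·size epsilon so exact-boundary
  pixel centres survive floating-point rounding.
* Duplicate doses, non-monotone pixels, backgrounds above exposed pixels,
  sub-linear two-point data: all are distinct, typed errors
  (`filmcal_unidentifiable_error`, `filmcal_infeasible_error`, …), never
  silent repairs.
* Ensemble statistics use the sample (n−1) standard deviation — ensembles
  of 7–12 films are the norm, where the distinction matters.
* Pairwise dose spread uses each curve of a pair alternately as truth and
  reports the worse direction, since an ensemble has no privileged member.

## Problem sizes used in validation

The shipped test-suite and acceptance computations use: 100 random-truth
noiseless refit draws per strategy; $10^5$ Monte-Carlo draws (200 bootstrap
resamples) for the uncertainty cross-check; 200 seeded ensembles of n = 12
for the variation-recovery check, asserted as coverage of the central 95%
χ²(11) interval (a per-seed assertion would fail by construction ~5% of the
time); 300 replicates for the noisy-fit scatter check; and one full-size
(729×1377 px) synthetic 8-field image for the pipeline closure. These sizes
were chosen so sampling error is comfortably below the asserted tolerances.

## Known limitations

* The model is specific to films with single-target single-hit response
  (e.g. Kodak XV); radiochromic films need a different response model.
* The saturation ratio between standard and multi-field methods partly
  reflects scanner nonuniformity, so it is scanner-specific and should be
  re-measured when hardware changes.
* Slope-ratio tables are measured inputs; the package validates their
  plausibility but cannot derive them from physics.
* No robust/outlier-resistant fitting and no per-point weighting from ROI
  statistics: datasets are assumed pre-screened.
* Dose unit is cGy throughout; no unit-conversion layer.
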