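---
title: "Densitometric DNA ploidy: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densitometric DNA ploidy: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feulgen)
```

## The measurement model

The Feulgen reaction stains DNA stoichiometrically, so under the
Beer–Lambert law the absorbance of a nucleus in a brightfield image is
proportional to its DNA content. The pipeline works on that single
physical assumption plus three procedural ones:

* **Flat illumination.** A single scalar blank reference (`white_level`)
  per image is the only photometric correction; no shading-field model is
  fitted. The default reference is the bit-depth maximum
  (`2^bit_depth - 1`); for slides whose background is visibly below
  saturation, the `"background"` policy instead uses the modal image
  intensity, which on a sparse slide is the background. The choice
  matters: with the `"max"` policy an unsaturated background contributes
  a constant per-pixel OD offset to every nucleus, which cancels in DI
  only approximately (it scales with area, not with DNA content).
* **Operator-delineated, nonoverlapping nuclei.** Segmentation is out of
  scope by design; ROIs come from an operator. Overlap is checked and is
  an error by default (`overlap = "warn"` downgrades it, since real ROI
  exports occasionally contain slips).
* **Internal diploid controls.** Each sample carries its own lymphocyte
  reference population (protocol: 30 controls, 150–200 epithelial cells;
  deviations warn), so DI is self-calibrating and invariant under global
  intensity rescaling — verified as a property test.

Per pixel, `OD = -10 * log10(max(I, eps * I0) / I0)` — ten times the
decadic absorbance, the conventional scale in densitometry. The clamp
`eps = 1e-4` (configurable in (0, 1)) keeps OD finite on dead-black
pixels, capping per-pixel OD at 40. Pixels brighter than the reference are
assigned OD 0 rather than negative stain. IOD is the plain sum of OD over
the ROI's rasterized pixel set; `min_area = 10` px rejects degenerate
delineations.

## Geometry conventions

Pixel coordinates are 0-based `(row, col)`; polygon vertices are
`(x = col, y = row)` and the center of pixel `(r, c)` is
`(c + 0.5, r + 0.5)`. A pixel belongs to a polygon iff its center lies
inside under the even–odd rule, implemented as a scanline interval fill;
an axis-aligned square of side `s` therefore covers exactly `s^2` pixels,
and a polygon and its own rasterized label mask always measure
identically. The test suite checks the scanline against an independent
per-pixel ray-casting implementation on random polygons.

## Binning: modal IOD and peak DI

Neither "modal IOD" nor the histogram bin width is standardized, so the
package fixes one convention and uses it for both the control mode and
the DI histogram:

* **Center-anchored uniform bins.** Bin `k` covers
  `[(k - 1/2) w, (k + 1/2) w)`, so bin *centers* sit at integer multiples
  of the width `w` and a value exactly on an edge joins the upper bin.
  Centering the grid on multiples of `w` makes the reported mode land on
  round DI values (a pure-2N sample peaks at exactly 1.00, a 4N
  population at 2.00) and makes the control mode scale-equivariant:
  rescaling every IOD by `c` rescales the mode by `c` when the width
  scales along, which it does by default.
* **DI histogram width 0.05** DI units, range `[0, max(3, max DI))`:
  resolves 2N from 4N while keeping several cells per bin at the
  protocol's 150–200 cells. This is the "high-fidelity" resolution knob;
  halving it halves counts per bin.
* **Modal-IOD width `0.05 * median(control IODs)`**: five percent of the
  typical control IOD, the same relative resolution as the DI histogram.
* **Ties break toward the lower bin** in both the control mode and the
  peak DI — conservative toward diploid calls.

## Ploidy thresholds

A sample is aneuploid when its peak DI exceeds **1.1, strictly** — 1.10
itself is still diploid. The mild/moderate boundary is not standardized;
the default **1.40** lies between the DI regimes conventionally labelled
mild (~1.2) and moderate (~1.5) and is configurable
(`ploidy_thresholds()`). Classification is monotone in peak DI by
construction.

## Group statistics

Group summaries (mean, SD, range, aneuploid fraction) are computed over
**per-sample peak DIs**, and the t-tests use the number of samples as
`n`. The per-cell reading of `n` was rejected: group DI ranges on the
order of 0.2–0.8 are ranges of per-sample values, not of 150–200 cells
per sample, and aneuploid fractions have sample-count denominators. Note
the printed SD of such tables is sometimes described as a cell-population
SD; this package computes and reports per-sample SDs throughout.

The default test is the **pooled-variance one-tailed unpaired t-test** —
"unpaired t-test" classically denotes the equal-variance form — with
Welch available via `variant = "welch"`. The default alternative for each
pair is that the condition *later* in the stated progression order has
the greater mean DI; a fixed direction can be forced. p-values are
carried at full precision and only rounded (to 2 decimals) in the
rendered matrix. No multiple-testing correction is applied (alpha = 0.05
per test); with ten pairwise tests, users wanting family-wise control
should apply `p.adjust` to the `p` column themselves.

Implementation note: the summary-statistics route is the primitive
(closed-form `t`, `df`, `pt` tail), because published group tables are a
supported input; the raw-sample route delegates to it and is
cross-checked against `stats::t.test` in the tests.

## The synthetic slide simulator

`render_scene()` builds the validation substrate: dark elliptical nuclei
on a light background whose *total* absorbance is exact ground truth.

* **Absorbance profile.** Each nucleus is a 64-gon ellipse; within it a
  radial dome (`1 - rho^2`, floored at 0.02 so edge pixels stay stained)
  is scaled so the discrete per-pixel absorbance field sums *exactly* to
  `A = absorbance_per_2N * DNA multiple`. Absorbance is expressed
  directly in the pipeline's OD units (transmittance `10^(-A/10)`), so
  the measured IOD of a noiseless nucleus equals its true A with
  proportionality constant 1 — the Beer–Lambert inversion test then has
  an exact target (relative error under 1% at 16 bits, dominated by
  quantization).
* **Defaults as study conditions.** 512×512 16-bit images; 30 controls
  (semi-axes 4–6 px, CV 3%) and 150–200 epithelial nuclei (semi-axes
  6–10 px) per sample; `absorbance_per_2N = 400` OD·px, which keeps even
  4N dome peaks far above the clamp/quantization floor at 16 bits; noise
  is additive Gaussian on transmitted intensity with SD 1% of white,
  then clipping and quantization. The capture bit depth of real scanners
  varies and is configurable; 16 bits is the validation default, and
  8-bit rendering is supported but quantizes dark 4N dome centers
  visibly.
* **Placement.** Dart throwing with a bounded retry budget; a candidate
  center must clear every accepted nucleus by the sum of bounding radii
  plus one pixel, which *guarantees* the nonoverlap property the
  measurement protocol assumes. Infeasible requests fail with an
  explicit error rather than degrading.
* **Cohorts.** `generate_cohort()` mirrors a five-arm colonic study in
  progression order NCT, L-HP, L-SA, TA, AC with arm sizes
  (10, 9, 12, 8, 10); per-sample target peak DIs are drawn from each
  arm's Normal(mean, SD) truncated to its observed DI range
  (means 0.95/1.08/1.11/1.22/1.46, SDs 0.08/0.14/0.15/0.17/0.27), and
  within-sample per-cell CV widens along the progression (5% to 13%),
  reflecting the nuclear pleomorphism of advanced lesions. All
  randomness flows from one master seed through deterministically drawn
  per-sample sub-seeds; identical seeds give bit-identical images.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real slides: tissue architecture (glands,
serration, touching nuclei), chromatin texture, staining batch effects,
uneven illumination and vignetting, focus variation, section-thickness
differences, and cut nuclei at section boundaries. The simulator
validates the *densitometric* chain (OD integration, normalization,
binning, classification, statistics) end to end; photometric artifacts
of real scanners must still be controlled at acquisition time.

## Validation problem sizes

The suite validates the full five-arm cohort at protocol scale — 49
samples of ~190–230 nuclei each on 512×512 16-bit images — through
generation, measurement, analysis and group statistics, plus reduced
192×192 scenes for the per-operation tests. Parameter recovery on the
full cohort asserts each arm's mean recovered peak DI within three
standard errors of its intended targets and the carcinoma arm's
aneuploid fraction at exactly 1 (every AC target exceeds 1.1 by
construction of its truncation range).

## Known limitations

* No stoichiometric calibration to picograms of DNA: all quantities are
  relative, with DI carrying the normalization.
* No S-phase modeling or cell-cycle deconvolution of the DI histogram,
  and no 5c-exceeding-events metrics.
* Peak DI is quantized to the histogram bin width (0.05 by default);
  samples whose true mode straddles a bin edge can report either
  neighboring center.
* The modal-IOD estimate inherits the same granularity (5% of the
  control IOD), which propagates multiplicatively into every DI of that
  sample.
* A single scalar white level cannot correct spatially varying
  illumination; the `"background"` policy needs the background to be the
  modal intensity, which fails on densely cellular images.
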