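---
title: "Quantifying iron fortificants from paper-spot photographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying iron fortificants from paper-spot photographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferropaper)
```

## The measurement model

The assay deposits a small aliquot (5 µL by default) of an acid food extract
onto paper pre-loaded with Ferrozine reagents. Fe(II) forms a magenta
complex; more iron gives a darker spot. A photograph of the spot is reduced
to a single number — the mean pixel intensity $I$ of the detection zone on
the *inverted* 8-bit grayscale image — and calibrated against standards by
the log-linear model

$$ I = m \,\log_{10} c + b + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2), $$

where $c$ is the iron concentration of the deposited liquid in µg Fe/mL,
$m$ is the slope (intensity units per decade of concentration) and $b$ the
intensity at 1 µg/mL. Log-transforming the analyte concentration is the
standard linearisation for colorimetric paper assays, whose raw response
saturates at both ends. A sample is quantified by inverse prediction,
$\hat c = 10^{(I - b)/m}$, and converted to the food concentration by the
preparation factors:

$$ \text{food (µg Fe/g)} = \hat c \times
   \frac{\text{extraction volume (mL)}}{\text{sample mass (g)}}
   \times \text{extra dilution}. $$

The default preparation (2.5 g of food in 10 mL of extractant, no extra
dilution) multiplies the extract concentration by 4, so a 10 µg/mL extract
is a 40 µg/g food.

Assumptions worth keeping in mind:

* intensity noise is approximately Gaussian and homoscedastic on the
  intensity scale — which makes it *multiplicative* on the concentration
  scale: a fixed intensity error $\delta$ maps to a relative concentration
  error of $\ln(10)\,\delta/m \approx 4.9\%$ per intensity unit at
  $m = 47$. This is why high-concentration samples scatter more in
  concentration units and why re-assaying at a higher dilution helps;
* lighting is controlled (the physical assay uses a light-tight photo box);
  no illumination-field or colour-reference correction is applied;
* one spot, one measurement: replicates are separate spots.

## Imaging conventions

These are fixed so that results are bit-exact and testable:

* **Grayscale.** Default is the unweighted channel mean
  $\mathrm{round}((R+G+B)/3)$; the BT.601 luma
  $\mathrm{round}(0.299R + 0.587G + 0.114B)$ is available because imaging
  programs differ in their conversion and the two are *not* interchangeable
  on coloured spots (calibrate and measure with the same method — the curve
  object records which one was used). Rounding is half-away-from-zero, not
  banker's rounding.
* **Order.** Grayscale first, then inversion ($v \mapsto 255 - v$).
  Inversion makes the response increase with concentration; it is an
  involution, and measurement functions warn when handed a non-inverted
  image.
* **ROI membership.** A pixel belongs to a circular ROI when its 0-based
  (row, col) centre lies within Euclidean distance ≤ radius of the ROI
  centre, clipped to the image. The test suite checks this against an
  exhaustive per-pixel enumeration oracle on hundreds of random images.
* **Spot auto-detection.** Otsu's threshold on the inverted image, largest
  connected bright component, centroid + equal-area-circle radius (clamped
  to a plausible range). It is a convenience; manual ROIs remain the
  reference behaviour, and detection failure is an error the caller can
  catch to fall back to a manual ROI.
* **Bit depth.** 16-bit inputs are divided (integer division) by 257 to
  reach 8 bits; alpha channels are dropped.

## Calibration figures of merit

* **Fit.** Ordinary least squares of intensity on $\log_{10} c$ over all
  replicate rows. Zero-concentration standards never enter the fit (their
  log is undefined); they are the blanks for the LOD. Fewer than three
  distinct nonzero levels is an error; a non-positive slope yields a curve
  flagged unusable.
* **Working range.** The widest contiguous run of standard levels whose OLS
  fit has $R^2 > 0.95$ and positive slope; ties go to the run with more
  levels, then the lower start. The search is over printed levels only — no
  interior-point deletion. `cmd_calibrate` determines the range first and
  fits the reported curve on the in-range standards, since levels below the
  range are plateaued and would bias the slope.
* **LOD.** Intensity threshold $\bar I_0 + 3\,\mathrm{sd}(I_0)$ from blank
  replicates (reagents only; $n \ge 2$, 20 is typical), mapped through the
  curve. It is monotone in both the blank mean and the blank SD — a
  property the tests verify — and its closed form is checked analytically
  because real blank measurements are instrument-specific.
* **Sensitivity.** $(\bar I_{\text{high}} - \bar I_{\text{low}}) /
  (c_{\text{high}} - c_{\text{low}})$ from the *observed* level means at
  the range endpoints. On a log-linear assay this quantity depends almost
  entirely on the endpoints, and published values computed from raw versus
  fitted means can differ; this package makes no claim beyond the stated
  formula.
* **Averaging replicates.** Replicate spots are averaged in *concentration*
  space after inversion (the default), matching how the assay reports a
  final concentration; intensity-space averaging (a geometric-mean-like
  estimate through the log curve) is an option. The per-sample %CV is
  always computed over replicate concentrations.

## Validation statistics

* Sample standard deviations ($n-1$) everywhere, matching spreadsheet
  defaults.
* Apparent recovery $R_A = (x_{O+S} - x_O)/x_S$ is scale-invariant and
  errors on a zero spike.
* Interference bias is a difference of group means against the
  interferent-free baseline; report tables round to 2 decimals, machine
  output keeps raw values.
* Method comparison uses mean-difference bias (appropriate when the
  correlation with the reference method is below ~0.99), the SD of the
  differences, Bland–Altman limits of agreement $\text{bias} \pm k\,
  \mathrm{sd}$ with $k = 2$ by default ($k = 1.96$ via argument), and a
  two-sided paired t-test. With exactly constant differences the t-test is
  defined by continuity ($t = 0, p = 1$ at zero bias; $\pm\infty, p = 0$
  otherwise) rather than erroring.
* Regression-based bias models (Deming, Passing–Bablok) are out of scope.

## What the synthetic generator emulates — and what it does not

`spot_scene()`/`render_spot()` draw a magenta disc on a pale background so
that the inverted unweighted-mean grayscale of the disc has expectation
$m \log_{10} c + b$, plus iid Gaussian pixel noise (applied before clipping
to [0, 255]). Two rendering details matter:

* **Exact channel sums.** Each pixel's integer RGB triple is constructed to
  sum to exactly $3(255 - G)$ for the quantised target $G$ (green depressed
  by ≈1.1·G, red/blue by ≈0.95·G — magenta). A naive "pick three weights"
  colouring cannot make the unweighted mean exact *and* stay magenta, since
  the weights would have to average to one; constraining the sum instead
  makes the grayscale→inversion round trip exact up to the half-unit
  quantisation of the target itself, which is what lets the pipeline
  round-trip tests demand 5% concentration accuracy (one intensity unit is
  already ~4.9% at the default slope).
* **Heterogeneity.** `streaky` multiplies the disc target by a seeded
  low-frequency sinusoidal field (one cycle across the spot), emulating the
  uneven colour development of plain cellulose filter paper; `uniform`
  emulates hydrophobic silicone-treated paper where the sample sits on the
  surface and develops evenly.

Tabular generators produce calibration standards around the generating line
(optionally plateaued below a cutoff at the blank intensity, emulating
levels under the assay's useful range) and paired method-comparison data
(reference uniform over a concentration span, perturbed by the reference
method's own CV; candidate = reference + $N(\text{bias}, \text{sd}_\text{diff})$).

Generator defaults are the study conditions the package is characterised
under: transfer function 47.01/126.18, standards 0.5–100 µg/mL with $n=5$
replicates, method-comparison bias 8.65 µg/g with difference SD 18.00 µg/g
at $n = 35$ pairs and reference CV 4.24%, within-day CV 15.9% at $n = 9$.
The method-comparison concentration span defaults to 10–110 µg/g,
representing unfortified through highly fortified flours; with the default
error structure this yields a test–reference correlation in the high 0.8s.
The blank intensity defaults to 100 — below the 1 µg/mL intercept, as a
reagent-only spot must be — but real blank levels are instrument- and
batch-specific, so simulated LODs should be read as internally consistent,
not as predictions of a laboratory LOD.

What the generator does **not** model: camera optics and JPEG artifacts,
illumination gradients, the in-photo reference strip, matrix effects,
chemical kinetics, or inter-session drift. Passing tests therefore
demonstrate the correctness of the *computation* under the stated
statistical model, not the field performance of the physical assay.

## Numerical choices and degenerate inputs

* Log base 10 throughout (recorded in the serialized curve, so a different
  base remains reproducible).
* Noiseless fits recover generating parameters to machine precision;
  perfect-fit warnings from the underlying `summary.lm` are suppressed as
  uninformative in that setting.
* Out-of-range predictions warn and flag (`in_range = FALSE`) but never
  error: the remedy is a different dilution, not a failed run.
* Empty ROIs, fewer than 3 calibration levels, fewer than 2 blanks or
  replicates, zero spikes, mismatched pairs and zero-variance method
  vectors all raise classed errors (`fp_*`), which the CLI maps to exit
  status 2.
* All generators accept an integer seed and restore the caller's RNG state,
  so library use never perturbs a session's random stream.

## Problem sizes in the test suite

The suite exercises the ROI oracle on 500 random images up to 16×16,
slope-CI coverage and parameter recovery on 200-replicate Monte-Carlo runs
(n = 35 pairs; n = 9 within-day replicates), and the Bland–Altman coverage
property on 5,000 simulated pairs. These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands (e.g. ±0.7 µg/g for the
recovered bias, about 3 MC standard errors) while the whole suite runs in
seconds. The within-day CV band (±1.5 points) additionally absorbs the
~3% downward small-sample bias of the sample SD at $n = 9$.

## Known limitations

* No colour normalisation against an in-photo reference strip; photographs
  must come from a controlled light box.
* The grayscale conversions offered bracket, but are not guaranteed to
  match bit-for-bit, any particular imaging program's proprietary
  conversion.
* Mean-difference bias is the only systematic-error model; strongly
  proportional bias would call for a regression-based comparison.
* The working-range rule inherits the brittleness of $R^2$ thresholds: a
  gently curving response can qualify as "linear" over a wide run, as the
  plateau experiments in the tests illustrate.
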