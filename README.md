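# ferropaper

Iron fortification programs need field-usable quality control: the gold
standard for measuring iron in food — atomic emission spectroscopy (AES) —
is accurate but expensive and lab-bound. A low-cost alternative is a
paper-based Ferrozine assay read with a smartphone camera: a 5 µL aliquot of
an acid food extract is deposited on reagent-loaded hydrophobic paper, the
Fe(II)–Ferrozine complex develops a magenta spot, and the spot's pixel
intensity encodes the iron concentration.

`ferropaper` implements the complete computational side of that assay for
analysts and method developers:

* **imaging** — PNG/JPEG/TIFF photographs are converted to 8-bit grayscale
  (unweighted channel mean by default, BT.601 luma optional), colour-inverted
  so darker spots score higher, and summarised as the mean pixel intensity
  *I* inside a circular detection zone (manual ROI or automatic spot
  detection via Otsu thresholding).
* **calibration** — standards are fit by ordinary least squares on the
  log-linear model

  *I* = *m* · log₁₀ *c* + *b*,

  with *c* in µg Fe/mL. The toolbox determines the working range (widest
  contiguous run of levels with R² > 0.95 and positive slope), the limit of
  detection (blank mean + 3σ mapped through the curve,
  LOD = 10^((*Ī*₀ + 3σ₀ − *b*)/*m*)), the sensitivity
  (Δresponse/Δconcentration across the range endpoints), and inverse
  prediction *c* = 10^((*I* − *b*)/*m*) with dilution correction
  (food µg/g = extract µg/mL × extraction volume / sample mass × extra
  dilution).
* **validation** — apparent spike recovery R_A = (x₍O+S₎ − x₍O₎)/x₍S₎,
  interference bias (mean difference against an interferent-free baseline),
  within-day random error (%CV = SD/mean × 100), and method comparison
  against AES: Pearson r, mean-difference bias, Bland–Altman limits of
  agreement bias ± k·SD (k = 2 by default), and a paired t-test.
* **synth** — a seeded generator of synthetic spot photographs and tabular
  datasets whose statistics follow the model above, so the entire pipeline
  is testable without laboratory images.
* **cli** — a `colorassay` command-line front end
  (`calibrate | quantify | validate | simulate`).

## Worked example

Calibrate from a standards CSV (here generated synthetically: blanks, a flat
response below 5 µg/mL, and a log-linear response from 5–100 µg/mL with
intensity noise), then quantify a spot photograph of a 10 µg/mL extract from
2.5 g of food extracted into 10 mL of dilute HCl:

```r
library(ferropaper)

st <- generate_calibration_dataset(c(0, 0.5, 1, 2.5, 5, 10, 25, 50, 100), 5,
                                   noise_sd = 3, flat_below = 5, seed = 42)
write.csv(data.frame(concentration_ug_per_ml = st$concentration,
                     intensity = st$intensity), "standards.csv",
          row.names = FALSE)
curve <- cmd_calibrate("standards.csv", "curve.json")
#> calibrated: slope 45.6708, intercept 127.1708, R2 0.9806,
#> range [5, 100] ug/mL, LOD 0.3720557 ug/mL

img <- render_spot(spot_scene(10, noise_sd = 2, seed = 7))  # or read_assay_image()
g   <- invert_gray(to_grayscale(img))
m   <- mean_roi_intensity(g, detect_spot(g))
m
#> <intensity 173.23 +/- 2.06 over 5013 px>

quantify_sample(curve, m$mean_intensity, sample_prep(2.5, 10))
#> extract 10.2 ug Fe/mL -> food 40.8 ug Fe/g (CV 0.0%, n = 1)
```

The calibration recovered the generating line (slope 47.01, intercept
126.18) within its noise, flagged 5–100 µg/mL as the usable range, and the
10 µg/mL spot quantified to 40.8 µg Fe/g — the true value is 40 µg/g
(10 µg/mL × 10 mL / 2.5 g).

The same flow from a shell:

```sh
Rscript inst/cli/colorassay.R calibrate --standards standards.csv --out curve.json
Rscript inst/cli/colorassay.R quantify --curve curve.json --prep prep.yaml \
    --images spot1.png,spot2.png,spot3.png --roi auto --out results.csv
Rscript inst/cli/colorassay.R validate --mode comparison --input paired.csv
```

Exit codes: 0 on success, 2 on input/schema errors. Logs go to stderr,
results to files/stdout.

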