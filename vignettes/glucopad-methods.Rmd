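---
title: "Colorimetric glucose readout: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric glucose readout: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucopad)
```

## The measurement model

A paper-based glucose chip wicks a drop of whole blood through a salt- and
heparin-functionalized strip. Red cells are retained near the sample zone;
plasma reaches the analysis zone, where glucose oxidase produces hydrogen
peroxide and horseradish peroxidase oxidizes TMB to its blue (then green)
charge-transfer products. Color development is therefore a monotone proxy
for glucose, and a smartphone photograph carries the signal.

`glucopad` quantifies that signal in four steps.

**Color space.** Photographs are converted from sRGB to HSV in the common
8-bit convention: hue in half-degrees (an integer 0–179, so pure blue at
240° is H = 120), saturation and value in 0–255. HSV is used because the
TMB transition moves mostly in hue and saturation, while illumination
changes move mostly in value: a multiplicative brightness change leaves H
and S unchanged up to quantization and scales V (this is asserted as a
property test on vivid pixels, V ≥ 200 and S ≥ 120 under factors 0.6–1,
with a ±1 quantization allowance; darker or grayer pixels quantize too
coarsely for a ±1 guarantee, which is one reason the segmentation ranges
require S ≥ 50 and V ≥ 50). Hue is halved from degrees and rounded
half-up; R's default banker's rounding is deliberately not used anywhere a
printed decimal is reproduced.

**Segmentation.** A pixel is "reacted" when its HSV triple lies inside a
closed box. Defaults: blue `[90,50,50]–[130,255,255]`, green
`[35,50,50]–[85,255,255]`, combined by union (`mask_mode = "union"`),
because oxidized TMB spans blue into green and scoring only one hue band
would undercount the transition; single-band scoring remains available by
configuration for chemistry that stays in one band. Blood is a
hue-wraparound red, represented as two boxes (`[0,10]` and `[170,179]` in
hue, S, V ≥ 50) and unioned — ranges are never encoded with lower > upper.

**Chip geometry and the score.** The strip is located by Otsu's threshold
on V followed by largest connected component (8-connectivity, so 1-pixel
diagonal noise breaks do not split a region; interior holes such as the
dark blood zone are filled). A frame whose brightness range is under 8
units has no background/paper split to threshold: it is treated as
all-chip when mean V ≥ 128 and as chip-not-found otherwise. The reaction
ROI is the largest connected reacted component — the "region of greatest
intensity"; ties are broken by higher mean saturation, then leftmost. An
empty reaction mask raises a distinct no-reaction condition rather than
returning a zero score: a zero score is a valid measurement (no color), an
empty mask usually means an unusable photo.

The intensity score is
`score = 255 × white_count / roi_area`, with `white_count` the pixel count
of the extracted reacted component. A raw white-pixel count would double
with image resolution; dividing by the reaction-zone area makes the score
a resolution-free in-range *fraction* on a 0–255 scale (verified by
rendering the same chip at 20 and 40 px/mm). The denominator is the
*nominal* analysis-zone area in pixels: the zone's known geometry (4 mm
disc plus tangent-cone tip) rasterized at the scale estimated from the
detected strip's bounding-box length. The reacted blob itself cannot serve
as the denominator (the score would always be 255), and the full zone
cannot be segmented by color since its unreacted part is paper-white; using
the designed geometry is how a fixed-geometry assay turns a pixel count
into a fraction. A fixed `roi_area` override is available when the scale is
known externally.

**Calibration.** Ordinary least squares with glucose (mg/dL) as response
and intensity as predictor — the direction the calibration equations are
written in; no errors-in-variables correction is attempted. Two reference
lines are built in: whole blood `1.4686·I − 157.16` and plasma
`1.5278·I − 194.35`. The lines are parallel to within |Δslope| < 0.06 with
a near-constant vertical offset: at matched glucose the plasma model
requires the higher intensity, consistent with residual red cells and
faint hemolysis intensifying the whole-blood color. Predictions are
reported to one decimal (the precision of the published readings) and
flagged — never clamped — when outside the 50–140 mg/dL detection range,
which is itself approximate and configurable per model.

`compare_models()` reports the slope difference and the vertical offset at
the midpoint of the shared detection range; since that midpoint is a
glucose value, the offset is evaluated at the mean of the two models'
inverse-mapped intensities at that midpoint. Comparing a model with itself
gives (0, 0); shifting an intercept by +10 gives (0, 10).

**Classification.** Low < 70 ≤ Normal ≤ 110 < High, both boundaries
inclusive on the Normal side. Inclusivity is a package decision (the
clinical window is conventionally quoted as "70–110"); the boundaries are
plain configuration, and classification is property-tested under random
valid band configs.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| HSV blue range | [90,50,50]–[130,255,255] | H half-deg; S,V 8-bit | intense and soft blues, S/V floors exclude paper and shadow |
| HSV green range | [35,50,50]–[85,255,255] | " | late TMB transition |
| `mask_mode` | union | — | blue ∪ green spans the transition |
| Bands | 70 / 110 | mg/dL | normal fasting window |
| Detection range | 50–140 | mg/dL | usable strip response |
| Chip geometry | 5 mm sample, 10×2 mm channel, 4 mm zone + 2 mm tip | mm | refined chip design |
| `pixels_per_mm` | 20 | px/mm | ≈ 10 cm smartphone shot |

## The synthetic generator

The generator is explicitly model-based, not photochemical: a target
glucose is mapped to an intended intensity by inverting a calibration
model (default: the whole-blood reference line), and exactly
`round(N · intensity/255)` of the N analysis-zone pixels receive an
in-range TMB blue (H 105, S 200, V 210). Reacted pixels fill in from the
pointed tip, ranked by axial distance plus 0.7× the perpendicular offset,
producing the V-shaped color front that the real chips show at the tip.
On top of the clean render: a white paper strip (250 ± 1.5 texture) on a
gray background (70), a red sample zone (RGB 200, 40, 50), an optional
left-to-right multiplicative illumination ramp, and additive Gaussian
channel noise, clipped to [0, 255]. Every random draw comes from the render
specification's seed, so a fixed specification renders bit-identical images; ladder rungs derive
their seeds from the template seed plus the rung index.

The analysis zone is a disc of radius r with a tangent-cone tip toward an
apex at distance d = r + tip length; its closed-form area
`πr² + r√(d²−r²) − r²·acos(r/d)` agrees with the rasterized pixel count to
well under 2 % at 20 px/mm, and the pipeline's nominal-area denominator
uses the same rasterization, so the score reproduces the intended
intensity almost exactly.

What the generator emulates: geometry, color-fraction development, the
V-front, illumination gradients, sensor noise, a dark background.
What it does not: real TMB chemistry (hue and saturation co-varying with
concentration — no quantitative color-vs-concentration law is available to
emulate), paper fiber texture at reagent scale, perspective or motion
blur, specular highlights, white-balance shifts (the measurement protocol
uses no color reference, so neither does the package). Passing round-trip
tests therefore demonstrates that the *software* pipeline is faithful and
stable under noise and illumination changes; it does not validate the
chemistry or transfer of the calibration to new devices.

## Study conditions used in tests

The round-trip suite renders a 10-rung ladder, 50→140 mg/dL in steps of
10, at noise SD 5 and a 10 % illumination gradient, and requires
leave-one-out prediction error ≤ 5 mg/dL at every rung and refit
R² ≥ 0.99; a zero-noise ladder must recover the generative slope and
intercept within 1 %. Property tests use 100 random 16×16 images against a
per-pixel brute-force mask oracle, fuzzed min/max envelope containment for
semi-automatic range derivation, and a closed-form normal-equations oracle
for the OLS fit (1e-9 relative). These sizes keep the full suite under a
minute on one CPU while exercising every pipeline stage end to end.

## Known limitations

- The published intensity values are on a 0–255 scale that cannot be a raw
  pixel count of a photographed 4 mm zone; the normalized in-range
  fraction reproduces their magnitude and is flagged prominently here, but
  it is a reconstruction. The raw count is always carried alongside.
- The published fit diagnostics (R² = 0.83, RMSE ≈ 10.83) refer to a
  kit-vs-chip pairing whose exact dataset is not recoverable from the
  published table; they are documented but deliberately not asserted
  anywhere. The packaged chip-glucose columns were themselves generated by
  the reference lines, which is why refitting them recovers those lines to
  printed-rounding precision.
- Scale estimation assumes a roughly frontal photo of a strip of known
  length; perspective correction and fiducials are out of scope.
- Semi-automatic range derivation uses a min/max envelope with additive
  margins — a deliberate, easily-audited rule rather than a statistical
  color model.
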