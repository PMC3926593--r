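---
title: "Measuring crop height from a striped reference marker: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crop height from a striped reference marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropheight)
```

## The measurement model

A fixed camera photographs a field once a day. A rigid bar of known
length, painted in alternating 10 cm red and white stripes, stands in the
field; the default geometry is a 250 cm bar driven 20 cm into the soil,
leaving 230 cm (23 stripes) above ground. The canopy in front of the bar
hides its lower part, so the visible bar length is a proxy for canopy
height. With a calibration frame on which the visible bar measures $I$
pixels and $L$ centimetres while the crop stands at $R$ centimetres, a
later frame with a detected visible bar of $M$ pixels gives

$$H = \frac{I - M}{I}\,L + R .$$

This is exact under two assumptions: the camera and bar do not move
between frames, and centimetres per pixel is constant along the bar
(orthographic viewing). Close-range perspective distortion and camera
nonlinearity are out of scope; in practice the bar should stand neither
very close to nor very far from the camera, so that its image width is a
few pixels.

`computeHeight()` implements the conversion and refuses $M > I$ (a run
longer than the calibrated bar implies a mis-detection). Its boundary
identities $H(M{=}I) = R$ and $H(M{=}0) = L + R$ are property-tested.

## Band selection

Detection runs on a single scalar plane. Two choices are supported:

* **Excess green**, $2G - R - B$: red stripes are strongly negative,
  white stripes near zero, vegetation strongly positive, sky near zero.
  Both stripe colours thus sit uniformly *low* against the canopy, and —
  because the index is a zero-sum combination of the channels — a common
  additive shift of all three channels cancels exactly, which is what
  makes the index robust to day-to-day illumination changes.
* **Red band**: both stripe colours are uniformly *bright*, but the band
  inherits every illumination change directly, and a golden (mature)
  canopy approaches the stripes' red intensity.

Indices are computed in signed arithmetic without clipping or rescaling,
because the downstream threshold operates on the filtered plane and needs
the full intermediate range. The three excess indices sum to zero at
every pixel; this identity, the $[-510, 510]$ bound, and agreement with a
per-pixel loop are tested on random images.

## The marker-matched kernel

A Laplacian finds the bar's edges but leaves gaps; an x-directional
derivative finds its long vertical edges but also every other vertical
edge. The pipeline's kernel combines both ideas and matches the bar's
width $w$ (pixels): a square kernel of side $2w + 1$ whose central $w$
columns carry one negative constant and whose $(w{+}1)/2$ leftmost and
rightmost columns carry one positive constant, all entries within a
column equal. For the deployed width $w = 5$ this is the 11 × 11 kernel;
down-sampled and up-sampled frames with $w = 3$ and $w = 7$ take 7 × 7
and 15 × 15 kernels.

Only the sign pattern and the column-constant structure are fixed by the
design; the coefficient magnitudes are an open choice. The package uses
$+w$ on the flank columns and $-(w{+}1)$ on the central columns, the
smallest integer pair that makes **every row sum to zero for every
$w$**. Zero row sums buy two properties the tests rely on: a constant
offset added to every pixel leaves the response unchanged, and any
laterally uniform region (sky, closed canopy, and — less obviously — any
*horizontal* boundary between two uniform regions, such as the canopy/sky
line) responds exactly zero. On an excess-green plane centred on the bar,
negative stripe values meet negative coefficients and positive canopy
values meet positive coefficients, so the response peaks at the bar's
centre column; this localisation is property-tested on synthetic stripes
of widths 3 and 5.

Responses are computed by direct spatial correlation (no kernel flip; the
kernel is mirror-symmetric, so the distinction is unobservable) with
replicate-padding at the borders, keeping output and input the same size
so run lengths are comparable across frames. A nested-loop correlation
oracle checks the vectorised implementation.

In red-band mode the bar is bright on a dark surround — the polarity the
kernel was *not* designed for — so the pipeline negates the response
before thresholding, which is equivalent to running the sign-flipped
kernel. This keeps one kernel definition while serving both features.

## Thresholding

The response plane becomes a mask by a single strictly-greater clip
level: `value > threshold` → 1, `value == threshold` → 0. The shipped
default of 2000 is the level calibrated for the excess-green pipeline on
720 × 480 field frames; any deployment with a different camera geometry
should relearn it. `selectThreshold()` formalises the calibration as the
midpoint of the gap between the largest of ~200 background response
samples and the smallest of ~200 marker response samples, failing loudly
when the two groups overlap. The midpoint rule is deterministic,
classifies every training sample correctly whenever a gap exists, and
places the level half-way so that a response contraction of up to ~2×
(weather, dimming) still clears it. Whether samples are single pixels or
patch means is left to the caller; the sampler for synthetic scenes uses
single pixels.

No morphological cleanup is applied: isolated noise pixels yield only
short vertical runs, and the run-length selection below ignores them.

## Marker detection and degenerate inputs

The visible bar is taken as the longest maximal vertical run of mask
pixels, each run confined to a single column with no gap bridging (the
matched filter is designed to make the bar's mask solid; a configurable
gap tolerance was considered and rejected as masking real truncation
failures). Ties are broken toward the smaller column index, then the
smaller top row — an arbitrary but fixed rule that makes outputs
reproducible; the bar's multi-column blob produces near-equal runs in
adjacent columns and the tie-break settles the choice. Requesting $n > 1$
runs supports fields with several bars. An empty mask (or empty region of
interest) raises a detection error rather than returning a zero-length
run, so series processing can distinguish "bar hidden" from "bar
absent". An exhaustive per-column walking oracle checks the detector on
random masks.

When the topmost white stripes cannot be separated from a bright sky, the
calibration region is shortened by whole stripes
(`adjustReferenceForSky()`): $L$ drops by the cut stripes' length and $I$
shrinks proportionally, rounded to the nearest pixel half away from zero
(symmetric, unlike banker's rounding, and off by at most half a pixel
from the exact ratio).

Pixel coordinates are 1-based with rows running downward, matching R's
native matrix indexing; all modules share the convention.

## Series flags, correction and statistics

Per-day reliability comes from the station's sensors: any rain at capture
time flags the frame (rain blurs the image and truncates the segmented
bar) for every feature; in red-band mode low light — pyranometer below
400 W/m², or a darkness label when no reading exists — also flags it.
The light classes put the boundaries 400 and 1000 W/m² in "normal"
because the outer classes are defined by strict inequalities.

Flagged estimates are replaced from reliable neighbours. The default is
date-weighted linear interpolation between the nearest unflagged
neighbours (single nearest value at the series ends); a "previous"
strategy carries the last reliable value forward, and is provided because
carrying forward is the natural choice when the following day is not yet
available in an operational daily feed. Corrections land in a separate
`corrected_cm` column with their strategy recorded, unflagged records are
never altered, and the operation is idempotent — all property-tested.

Accuracy is summarised as the relative error
$|\mathrm{est} - \mathrm{ref}| / \mathrm{ref} \times 100$, with the
arithmetic mean and the sample ($n - 1$) standard deviation; two feature
pipelines are compared by Welch's unequal-variance $t$ with
Welch–Satterthwaite degrees of freedom. The $n - 1$ convention and the
Welch variant were confirmed against the bundled 48-day deployment
tables: the excess-green column gives mean 3.34 % and sd 5.23 %, the
red-band column mean 24.85 %, and the Welch statistic between them is
5.529 — the package's acceptance checks. (The pooled-variance $t$ does
not reproduce that statistic; the red-band column's own sd computes to
26.45 %, not the 43.45 % that circulates with these data, so the latter
is not asserted anywhere.)

## The synthetic scene generator

`renderScene()` builds frames with exact ground truth: a sky band over a
per-pixel-jittered canopy (green or gold phase), the striped bar drawn at
its calibrated position, and the bar's bottom occluded up to the true
crop height; `truth$visible_marker_px = round(visible cm / cm per px)`
by construction. The defaults — 240 × 320 canvas, 1 cm per pixel, bar
width 5 px, 230 cm above ground, canopy jitter sd 12 — keep the geometry
of the deployed setup while staying quick to render; end-to-end tests
run twenty-plus scenes in seconds. All randomness derives from the spec's
seed; identical specs render bit-identical frames.

Weather conditions are modelled as:

* **darkness** — a dimmer, *bluer* illuminant (channel scales 0.45, 0.65,
  0.85) plus extra sensor noise. The scales satisfy $r + b = 2g$, so
  white surfaces stay excess-green-neutral and the canopy's excess-green
  contrast shrinks only mildly (the learned midpoint threshold tolerates
  it), while the red band's marker-vs-canopy contrast falls below half
  and its segmentation fragments at the red stripes. This reproduces,
  with an explicit mechanism, the field observation that low light breaks
  the red band but not excess green.
* **brightness** — uniform gain 1.35, clipped at 255; both features
  survive (clipping at white is excess-green-neutral).
* **drizzle** — mild 3 × 3 box blur with slight extra noise.
* **rainfall** — strong 7 × 7 box blur plus heavy noise, sized so that
  segmentation visibly truncates the bar and the height estimate
  overshoots grossly, the failure mode rain produces in the field. The
  series machinery then relies on the rain-gauge flag, not the image.

The generator emulates occlusion geometry and colour statistics only: no
perspective, no wind-induced sway, no raindrop optics, no real canopy
texture. Passing tests therefore demonstrate the pipeline's logic —
calibration, filtering, segmentation, run selection, correction — not
photometric performance on real imagery, which is what the bundled
deployment tables document.

## Problem sizes and numerical notes

Tests and examples use 240 × 320 scenes (the recovery suite runs 20
normal-condition scenes across crop heights 0–210 cm and asserts
recovery within ±10 cm, one stripe; the darkness comparison runs six
scenes per feature). Convolution is exact arithmetic (vectorised
shift-and-add), so results are reproducible to the last bit under a fixed
seed; the only tolerances in the tests cover floating-point summation
order (≤ 1e-9) and print-precision of the bundled tables. Detected run
lengths can exceed the calibrated $I$ by a few pixels of kernel smear on
a crop-free frame; `estimateFrame()` clamps the detection at $I$ (height
floor at $R$) rather than failing the frame.

## Known limitations

* Heights within about half a stripe of the bar's top (crop nearly
  covering the bar) leave too few visible pixels to segment; the
  detection error is the intended signal.
* The threshold default of 2000 is meaningful only for the geometry it
  was calibrated on; new deployments must relearn it.
* The red-band pipeline is included for comparison, not recommended use.
* Condition labels read from files are trusted as-is; sensor readings
  override light-related labels when both are present.
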