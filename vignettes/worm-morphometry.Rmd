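---
title: "Measuring nematode length, volume and surface area from silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nematode length, volume and surface area from silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormetrics)
```

## The problem

Adult *Caenorhabditis elegans* are about 1 mm long and 50 µm wide, and they
are rarely straight: a live worm on agar lies in a sinusoidal crawling
posture.  Length must therefore be measured *along the body*, and volume or
surface area cannot be read off a bounding box.  Treating the worm as a
cylinder of its maximum width substantially overestimates volume, because
the body tapers toward both ends.

`wormetrics` measures a single worm from a calibrated micrograph in five
stages:

1. **Binarize** (`preprocess_image`): pick the highest-contrast colour
   channel, stretch contrast, threshold globally, fill holes, clean up
   morphologically, keep the largest component, and rotate the worm so its
   long axis is horizontal on an expanded canvas.
2. **Skeletonize** (`skeletonize`): thin the silhouette to a one-pixel
   "spine line" and keep the longest geodesic path between skeleton
   endpoints.
3. **Trace** (`trace_full`): find a seed point where a vertical line
   through the image centre crosses the spine, then walk along the spine in
   steps of a few pixels, re-centring at each step on a short profile line
   drawn perpendicular to the local tangent.
4. **Extend and measure** (`extend_ends`, `measure_widths`): thinning
   erodes the spine short of the true tips, so each end is extended along
   its terminal slope until it crosses the one-pixel outline of the worm;
   then the diameter is measured at every spine point as the distance
   between the first outline crossings on either side of a normal probe.
5. **Integrate** (`total_morphometrics`): treat the body between
   consecutive width samples as a truncated cone (frustum) with radii
   $r_1 = w_i/2$, $r_2 = w_{i+1}/2$ and height $h = s_{i+1} - s_i$, and sum

$$V = \tfrac{1}{3}\pi\,(r_1^2 + r_1 r_2 + r_2^2)\,h, \qquad
  S = \pi\,(r_1 + r_2)\sqrt{(r_1-r_2)^2 + h^2}.$$

With $r_1 = r_2 = r$ these reduce to the cylinder formulas $\pi r^2 h$ and
$2\pi r h$, which is how the radical in $S$ (easily lost in typesetting) is
confirmed.  Because the frustum chain follows the true taper, its summed
volume is always below the cylinder estimate $\pi r_\max^2 L$ — the
direction of the bias that motivates shape-aware measurement.  Midline
curvature $k = d\phi/ds$ (change of unwrapped tangent angle per arc length)
and a straightened silhouette rebuilt from the $(s, w)$ pairs are also
available.

## Assumptions and failure modes

* **One worm per image**, circular cross-section, not overlapping itself.
  Crop multi-worm images first.
* **Calibration is the user's responsibility**: every command takes a
  mandatory scale (physical length per pixel).  Length scales linearly with
  it, area quadratically, volume cubically — exactly, which the tests
  assert.
* **Self-proximity**: when two parts of the midline approach within about
  20 px, the perpendicular profiles become ambiguous (they cross the spine
  in two clusters).  Tracing then *stops with an error*
  (`"spine self-proximity"`) instead of returning a silently wrong path.
  A tightly folded hairpin posture is the canonical trigger, and the
  synthetic module can build exactly that fixture.
* **Degenerate shapes**: a blob without elongation (e.g. a disk) collapses
  to a near-point skeleton and is rejected (`"degenerate skeleton"`).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `scale` | none (required) | length/px | spatial calibration |
| `step` | 4 | px | trace advance ("a few pixels"); small enough to follow curvature at ~50 px body width |
| `profile_half` | 20 | px | tracing profile reach (a ~40 px line); must stay below the self-proximity spacing |
| `probe_half` | 30 | px | width probe reach; must exceed the maximum body radius |
| `threshold_method` | `"otsu"` | — | global threshold (`"isodata"` selectable) |
| `close_iters`, `open_iters` | 1, 0 | — | edge smoothing / artefact (egg) removal |
| `pad_px` | 60 | px | canvas margin so 40 px profiles never leave the image |
| `min_area_px` | 200 | px | reject specks masquerading as worms |
| `edge_offset` | 0.5 | px | sub-pixel boundary correction (below) |
| `smooth_sd` | 0 (off) | samples | optional Gaussian smoothing of the tangent angle before curvature differencing |

## Numerical choices

* **Channel selection**: "greatest contrast" is operationalized as the
  largest intensity standard deviation; deterministic and parameter-free.
* **Contrast stretch**: 0.35 % of pixels saturated per tail, the
  conventional default of enhance-contrast tools.
* **Polarity**: the threshold side covering the minority of the image area
  is the worm, so dark-on-bright and bright-on-dark images give identical
  masks; writers emit the conventional black worm on white.
* **Orientation**: rather than trial rotations, the mask is rotated by the
  principal-axis angle of its second central moments on a canvas sized by
  the bounding-box diagonal (which no rotation can clip), re-thresholded at
  0.5, then trimmed and re-padded.
* **Skeleton branches**: thinning ragged masks leaves short spurs, and
  8-connected skeletons contain staircase pixels that look like junctions
  to naive degree counts.  Both problems disappear by keeping the longest
  geodesic path between endpoints (double breadth-first search), which
  drops every side branch regardless of length; walk-based spur pruning
  was tried and abandoned because staircase pixels made it cut the main
  line.
* **Sub-pixel positions**: profile and probe lines sample rasters by
  bilinear interpolation; crossings are weighted centroids of the first
  above-threshold run.  Tangent angles are unwrapped so consecutive
  differences stay below π/2.
* **The half-pixel edge offset**: the one-pixel outline consists of
  foreground pixels whose centres lie on average half a pixel inside the
  continuous boundary.  Crossing positions are therefore pushed 0.5 px
  outward; without this every diameter is ~1 px low, which biased volume
  by about −8 % on a 24 px-wide test tube.
* **Tips**: the two appended end points get width 0 by construction,
  closing the solid; no hemispherical caps are added (frustum-only model).
* **Missing widths**: a probe that misses the outline on one side is
  recorded and linearly interpolated in arc length; more than 5 % missing
  aborts the worm (`"radii failure"`), never silently.
* **Curvature**: central differences of the unwrapped tangent angle.  The
  raw per-point series carries skeleton-quantization noise of roughly the
  same magnitude as 1/250 px⁻¹; for per-point curvature work the
  `smooth_sd` flag (e.g. 2–4 samples, i.e. ~8–16 px, far below a crawling
  wavelength of several hundred px) suppresses it without visibly
  attenuating the signal.  Constant-curvature summaries (an arc's 1/R) are
  unbiased even unsmoothed when averaged over interior points.
* **Straightening** is silhouette reconstruction from the width profile on
  a straight axis — symmetric by construction — not grey-level image
  resampling.
* **Reporting precision**: length 3 decimals, volume 5, surface area 4,
  matching conventional morphometry tables; batch output is
  tab-separated with a header that states the units (the header can be
  disabled for drop-in compatibility with headerless consumers).

## The synthetic generator: what a green test establishes

`worm_spec()` + `render_worm()` build binary worms from parametric
centerlines (straight, circular arc, sine, hairpin) swept by a radius
profile that tapers quadratically to zero over the final 5 % of arc length
at each tip.  Length, volume ($\int \pi r(s)^2\,ds$), lateral area
($\int 2\pi r(s)\sqrt{1+r'(s)^2}\,ds$) and curvature are computed at
construction by high-resolution quadrature (20 001 nodes; refining tenfold
changes volume by under 0.1 %), independently of any raster — they are the
oracle the pipeline is judged against.  The default worm matches adult
proportions: 1000 px (1 mm) long, 50 px (50 µm) wide, 20:1.

Rendering adds per-vertex Gaussian jitter along the boundary normal
(default σ = 0.5 px), emulating the focus/threshold variability that
drives repeat-measurement scatter, then rotation and padding.
`replicate_experiment()` re-renders one worm under seeded uniform random
rotations — a synthetic stand-in for photographing the same worm 18 times.

What the generator does **not** emulate: grey-level optics (defocus halos,
uneven illumination), debris touching the worm, elliptical cross-sections,
or self-overlap.  A green repeatability test therefore establishes the
*pipeline's* geometric stability under pose and boundary noise, not
robustness to poor imaging; the preprocessing stages are tested separately
on two-level images.

The repeatability experiment (18 poses of the full-size default worm
through the whole pipeline) yields relative standard deviations of a few
tenths of a percent for length, surface area and volume — comfortably
inside the few-percent scatter reported for real repeated micrographs,
as expected for noise-free synthetic silhouettes.  Mean absolute accuracy
against the analytic truth is ~0.3 % (length) and ~1 % (volume, area) at
this resolution.

## Design choices that were genuinely open

* **Rotation mechanism**: a trial-rotation loop ("rotate until widest")
  and the moment-based rotation have the same goal; the latter is a single
  deterministic step and was chosen.
* **Seeding semantics**: on a binary spine the "maximum of the profile" is
  a run of identical values; the *topmost* crossing is used for the first
  vertical line, and the crossing nearest in row for the second (+5 px)
  line.
* **Ambiguity tolerance**: a second skeleton cluster within 20 px of the
  chosen one aborts tracing; 20 px is the documented failure distance and
  stays below the 40 px profile length (the collision horizon).
* **Tie-breaks**: equal-area components keep the topmost-then-leftmost
  centroid.
* **Table units**: position/width tables are labelled with their physical
  units explicitly in the header, since bare numbers are ambiguous between
  px and µm.

## Known limitations

* Point-wise spacing along the traced spine is bounded by 1.5× the step
  in the body, but the two appended tip points can be further from their
  neighbours (the thinning retreat, up to about one body radius).
* Widths carry ~0.3 px sub-pixel noise from the quantized outline, so two
  mirror-image masks agree on average to better than 0.5 px but
  individual interpolated samples can differ by up to ~1 px.
* The 4-neighbour boundary of a rasterized disk contains ~11 % more
  pixels than 2πr (diagonal stretches need extra pixels); outline pixel
  *counts* are not perimeter estimates, and the package never uses them
  as such.
* Worms that overlap themselves cannot be measured (by design, reported
  as an error), and no head/tail identity is assigned.

## A worked example

```{r example, eval = FALSE}
library(wormetrics)

spec <- worm_spec("sine", length_px = 1000, radius_px = 25,
                  amplitude_px = 60, periods = 1.5, scale = 0.001)  # mm/px
worm <- render_worm(spec)
mask <- preprocess_mask(worm$mask)
m <- measure_worm(mask)
m$morphometrics
spec$truth[c("length", "volume", "surface_area")]
```
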