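# wormetrics

Length, volume and surface area of nematodes from single-worm micrographs.

Studies of *Caenorhabditis elegans* and other nematodes routinely need the
size of individual worms, but live worms are rarely straight, so length must
be measured along the curved body, and treating the worm as a cylinder of
its maximum width overestimates volume because the body tapers toward both
ends.  `wormetrics` measures a calibrated photograph of a single worm by:

1. binarizing and cleaning the image (channel selection, contrast stretch,
   global threshold, hole filling, morphological cleanup, rotation to
   horizontal);
2. thinning the silhouette to a one-pixel **spine line** and tracing it end
   to end with moving perpendicular profile lines;
3. extending the spine to the worm's true tips using the one-pixel outline
   (thinning erodes the skeleton short of the tips);
4. measuring the diameter *w(s)* normal to the midline at every arc
   position *s*;
5. modelling the body as a chain of truncated cones between consecutive
   width samples, with radii r₁ = wᵢ/2, r₂ = wᵢ₊₁/2 and height
   h = sᵢ₊₁ − sᵢ, and summing

   V = (1/3) π (r₁² + r₁r₂ + r₂²) h    S = π (r₁ + r₂) √((r₁ − r₂)² + h²)

Curvature k = dφ/ds along the midline and a straightened silhouette
rebuilt from the (s, w) pairs are also available.  Because the frustum
chain follows the taper, the summed volume is always below the cylinder
estimate π r²ₘₐₓ L: a 1.24 mm worm of maximum width 0.1 mm gives 0.0097 mm³
as a cylinder but substantially less when its real shape is integrated.

A synthetic-worm generator renders binary tubes around parametric
centerlines (straight, arc, sine, hairpin) with *analytic* length, volume,
surface area and curvature, providing exact ground truth for every stage;
the hairpin doubles as the fixture for the documented failure mode (tracing
aborts when two parts of the midline come within ~20 px instead of
returning a silently wrong answer).

## Worked example

```r
library(wormetrics)

# a synthetic adult-like worm: 1 mm x 50 um at 1 um/px, sinusoidal posture
spec <- worm_spec("sine", length_px = 1000, radius_px = 25,
                  amplitude_px = 60, periods = 1.5, scale = 0.001)  # mm/px
worm <- render_worm(spec)

mask <- preprocess_mask(worm$mask)   # orient horizontal, validate
m <- measure_worm(mask)
m$morphometrics
#> <morphometrics>
#>   length 1.001, volume 0.00189, surface area 0.1544
unlist(spec$truth[c("length", "volume", "surface_area")])
#>       length       volume surface_area
#> 1.000000e+00 1.872476e-03 1.529782e-01
```

The measured 1.001 mm / 0.00189 mm³ / 0.1544 mm² agree with the generator's
analytic 1.000 mm / 0.00187 mm³ / 0.1530 mm² to ~0.1 %, ~1 % and ~1 %.

For a real micrograph:

```r
img  <- read_worm_image("photos/worm1.png", scale = 0.0012)  # mm per pixel
mask <- preprocess_image(img)       # channel, threshold, clean, orient
m    <- measure_worm(mask, worm_id = "worm1.png")
```

## Batch workflow and CLI

The two-stage batch layout mirrors the classic macro workflow: raw images
in `photos/`, masks in a sibling `binary/`, then per-worm width tables
`output<name>.txt` (Position/Width columns) and one summary `output.txt`
(File, Length (mm), Volume (mm^3), Surface area (mm^2)) per folder.

```sh
wormetrics binarize <root> --scale 0.0012 [--threshold otsu|isodata] [--open N] [--close N]
wormetrics measure <root>/binary --scale 0.0012 [--step 4] [--profile-half 20] \
           [--probe-half 30] [--straighten] [--debug-overlays]
wormetrics synth sine --out fixtures --n 18 --seed 1 --scale 0.001
```

(`wormetrics` is `inst/exec/wormetrics`; equivalently call
`wormetrics::cmd_binarize()`, `cmd_measure()`, `cmd_synth()` from R.)
Per-worm failures (self-proximity, radii failure) are logged and recorded
in `output_failures.txt`; the batch continues.  Re-running on unchanged
inputs reproduces the output files byte for byte.

## Package layout

- `R/preprocess.R` — binarization chain; `R/skeleton.R`, `R/spine.R` —
  thinning, tracing, end extension; `R/radii.R` — width profile;
  `R/morphometry.R` — frustum integration, curvature, straightening;
  `R/synthetic.R` — ground-truth generator; `R/cli.R` — batch commands.
- `vignettes/worm-morphometry.Rmd` — the model, parameters, numerical
  choices and limitations in detail.
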