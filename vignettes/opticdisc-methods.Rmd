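---
title: "Multispectral optic-disc localisation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral optic-disc localisation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticdisc)
```

This vignette is the package's own account of the method: the model behind
each stage, the tunable parameters with their defaults and units, what the
synthetic phantom does and does not emulate, the numerical choices, and the
places where the design was genuinely open and we had to commit.

## The problem and the method

A colour fundus photograph shows the illuminated circular field of view
(FOV) of the retina on a dark surround.  The optic disc (OD) is a bright,
roughly circular region of diameter about 1.75 mm where the optic nerve and
central vessels enter; its centre anchors all downstream vasculature
measurements.  The only a-priori parameter is the *nominal radius* `R_a`:
the expected OD radius in pixels for the camera/dataset at hand.

The detector is multispectral because no single channel is reliable.  The
OD is best contrasted in red, where the retina is translucent and nearly
featureless — but red is also the channel that most often saturates under
overexposure, destroying exactly that contrast.  Green carries the sharpest
vessel and lesion contrast; blue is dim and noisy but rarely saturated.

**Coarse phase.**  Working at quarter scale for images with a side over
1,000 px, each channel is masked to the FOV (two-class Otsu on the red
channel plus a circle completion via the component's major axis), range
normalised over in-FOV pixels, and smoothed with a truncated Gaussian whose
support spans one nominal radius (`sigma = R_a/4`): structures much smaller
than the disc — vessels, exudates, haemorrhages — are blurred away while
disc-sized blobs survive.  Multilevel Otsu with `k = 5` thresholds splits
each smoothed channel into six classes; the maximum-intensity class of each
channel becomes a binary mask, and the masks combine as
`bw_out = bw_R & (bw_G | bw_B)`.  The logic of that formula: after
normalisation the brightest pattern in green and blue is almost always the
OD, so their union contains it; intersecting with red keeps only patterns
bright in all channels, which removes FOV-rim glare and exudate clusters,
and still works under red saturation because the saturated red mask is then
a large blob that contains the disc.  The surviving objects are screened by
roundness (`4*pi*Area/Perimeter^2 >= 0.6`) and the one whose equivalent
radius `sqrt(Area/pi)` is closest to `R_a` provides the ROI centroid.

**Fine phase.**  On the unsmoothed normalised channels, vessels are removed
by grayscale closing with a disc structuring element of radius `0.15 R_a` —
the anatomical ratio of main-vessel width to disc diameter is about 0.15,
so an element of that radius (diameter `0.3 R_a`) just covers the widest
vessels — followed by a 3 x 3 mean filter.  Each channel is cropped to a
`2R_a x 2R_a` square at the coarse centroid and the crop with the largest
Shannon entropy (256-level histogram over crop-and-FOV pixels) selects the
search channel; ties break red > green > blue.  A circular Hough transform
over integer radii in `[0.95, 1.3] R_a` finds the centre and radius, which
are finally mapped back through the crop offset and the scale factor.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `nominal_radius` | — (mandatory) | px (original scale) | expected OD radius for the dataset |
| `k` | 5 | — | Otsu thresholds; 6 intensity classes |
| `roundness_min` | 0.6 | — | disc-likeness gate on coarse objects |
| `sigma_factor` | 0.25 | × `R_a` | Gaussian scale of the coarse blur |
| `se_factor` | 0.15 | × `R_a` | closing element radius (vessel suppression) |
| `r_min_factor`, `r_max_factor` | 0.95, 1.3 | × `R_a` | Hough radius band |
| `downscale_trigger` | 1000 | px | side length above which quarter-scaling applies |
| `downscale_factor` | 0.25 | — | linear reduction factor |
| `mean_filter_size` | 3 | px | post-closing mean filter |
| `fov_channel` | `"R"` | — | channel used for the FOV mask |
| `gradient_quantile` | 0.9 | — | Sobel-magnitude quantile above which pixels vote |
| `accumulator_sigma` | 2 | px | smoothing of each radius's accumulator |
| `ring_width` | 2 | px | half-width of the radial-contrast bands |

The first eight are the method's fixed factors; the last four belong to the
Hough stage, whose internals (gradient operator, vote threshold, smoothing,
ring width) are not pinned down by the two-stage description the method
follows, so they are our documented defaults and all configurable.

## The circular Hough transform, in detail

Edge pixels (Sobel magnitude above the 90th in-FOV percentile) vote along
full circles, with votes weighted by gradient magnitude, into a *separate*
accumulator per integer radius.  We keep the accumulator radius-resolved
because a single radius-summed accumulator lets arcs at different distances
— a rim arc here, a vessel edge there — conspire at a spurious point; with
per-radius accumulators a peak needs coherent support at one radius.  Each
radius contributes its top three smoothed peaks (5-px non-maximum
suppression) as centre candidates.

Candidates are then verified on the radial intensity histogram: ring means
on 1-px rings around the candidate.  The winning candidate maximises *disc
evidence* — mean intensity inside the circle minus the surrounding annulus
— because the OD is a bright region, and a rim-local score alone is fooled
by half-visible pseudo-circles at the crop border.  The radius at the
winning centre maximises the inward-outward ring-mean contrast over the
band, weighted by ring support (the observed fraction of the circumference;
gated below 20%), ties to the smallest radius.  An alternative rule
(`radius_rule = "ring_mean"`), the first local maximum of the raw radial
profile, is selectable.

One consequence of the fixed `2R_a` crop deserves emphasis: a disc at the
top of the radius band (`1.3 R_a`) barely fits the crop, so its outside
annulus has almost no pixels *inside the crop*.  Verification therefore
reads the full vessel-suppressed channel at absolute coordinates (the
`context` argument of `hough_circle()`); only the vote accumulation is
restricted to the crop.

If no pixel passes the vote threshold the stage signals failure and
`detect_od()` returns the coarse centroid with the nominal radius, flagged
`cht_failed`.  The tool's role is screening: a flagged best guess that a
grader can inspect beats an error.

## Candidate selection when the disc is fragmented

A vessel crossing the disc can split the blurred disc into sectors, and the
surviving fragments are ragged: their chain-code roundness often lands just
*below* the 0.6 gate while a small, compact distractor (a blurred exudate)
sails through it.  Selecting purely within the roundness-passing pool then
picks the distractor — the radius criterion never sees the true disc
object.  We therefore add a radius-consistency override: if the best object
*overall* has an equivalent-radius error less than half that of the gated
winner, it is selected instead and the detection is flagged `radius_only`.
The roundness gate keeps doing its real job (rejecting elongated FOV-rim
artefacts); the override restores the radius criterion's authority over
compact distractors.  When no object passes the gate at all, the radius
criterion applies to every object, likewise flagged.

## Exact multilevel Otsu

The between-class variance objective is maximised exactly by dynamic
programming over histogram prefix sums (`O(k L^2)` for `L = 256` levels),
rather than by a derivative-free search, which is initialisation-dependent
and can return local optima.  Classes are the level intervals
`(th_{j-1}, th_j]` with `th_0 = -1`; the "maximum class" is everything
strictly above `th_k`; the objective sums over all `k + 1` classes.  Among
tied optima the lexicographically smallest threshold vector is returned
(front-to-back reconstruction against a suffix table).  The implementation
is verified in the tests against exhaustive enumeration of every threshold
combination at `L = 32`.

## Numerical choices and conventions

* Coordinates are 0-based `(row, col)`; a pixel is inside a circle iff its
  centre is within the radius.  All rasterisations (ground-truth masks,
  predicted circles, the FOV circle) share this rule, so metric identities
  hold exactly.
* Normalisation min/max are computed over in-FOV pixels only.  The masked
  surround is zero; including it would pin the minimum at 0 and make the
  normalisation a no-op for the lower tail.
* Normalised channels are re-quantised to 256 levels by `floor(v*255 + 0.5)`
  before any histogram (thresholding and entropy), since both statistics
  are defined over discrete levels.
* The quarter-scale reduction is a separable Catmull-Rom (a = −0.5) bicubic
  with the kernel widened by the inverse scale — plain bicubic aliases when
  shrinking 4:1.  Results are clipped back to [0, 255] because cubic
  kernels overshoot.  The working-scale radius is `round(R_a/4)`, floored
  at 8 px so every derived kernel stays non-degenerate.
* The Gaussian kernel support is `[-R_a/2, R_a/2]` (side `R_a + 1` for even
  `R_a`), renormalised to unit sum; borders are mirror-reflected.
* Perimeter is the 8-connected contour chain length with `sqrt(2)` diagonal
  steps; a single-pixel object has roundness 1 by convention.  Connected
  components are 8-connected.
* The closing element radius is `0.15 R_a` (`se` interpreted as a radius):
  a disc of that radius has diameter `0.3 R_a + 1`, just above the widest
  anatomical vessel (`0.15` of the disc diameter, i.e. `0.3 R_a`), which is
  exactly what closing needs to fill a dark line.
* Degenerate inputs error with typed conditions (`od_fov_error`,
  `od_roi_error`, `od_histogram_error`, ...) or return flagged results
  (`degenerate` channels, `empty_class` masks, `cht_failed`), never silent
  zeros.

## The phantom: what it emulates, and what it does not

The generator renders the image properties the algorithm exploits, with
exact ground truth: a circular FOV on a dark surround; a bright disc with
per-channel contrast strongest in red (defaults 215/150/100 over a
150/90/50 background) and a paler optic cup; smooth low-frequency
"choroidal" texture, strongest in red (12/4/2 levels) because choroidal
mottle is essentially invisible at green wavelengths; dark vessels leaving
the cup margin as quadratic Bezier strokes, the widest at the anatomical
0.15 ratio of the disc diameter and faint in red but strongly contrasted in
green; optional yellow exudate distractors (bright in red/green, dark in
blue); optional red saturation as a wide illumination blob clipped at 255,
covering most of the FOV; an illumination ramp; and Gaussian pixel noise
(sigma 3 levels).

Batches span four regimes — unsaturated, red-saturated, with exudates, and
disc near the FOV rim — with per-phantom variation in disc radius
(`U[0.96, 1.24] * R_a`), position (100–130 px from the FOV centre), vessel
count (4–7) and illumination direction.  The default batch geometry
(512 x 512, FOV radius 230, `R_a = 50`) keeps run times at a few seconds per
image; the test suite uses 50-phantom batches and the quarter-scale checks
render one 2,048 x 2,048 phantom.

What the phantom does *not* emulate: physiological vessel branching and
tapering, pathology beyond bright blobs, camera vignetting beyond a linear
ramp, chromatic aberration, and the joint statistics of real sensor noise.
Passing the phantom suite therefore demonstrates that every stage behaves
as designed under the image *properties the method reasons about* —
spectral contrast ordering, saturation, disc-scale structure, vessel
occlusion, distractors — not that real-camera performance figures are
reproduced.  Evaluating on real datasets needs only a directory of images
plus centres or masks (`od_detect_dir()`, `od_evaluate_files()`).

## Evaluation metrics

Centre accuracy is `delta_C = |C_m - C_a| / R_m`, the Euclidean error
normalised by the ground-truth equivalent radius; `delta_C >= 1` places the
found centre outside the marked disc and counts as a misdetection.
Delineation uses the pixel contingency table of the rasterised detected
circle against the marked disc: TPR, FPR, accuracy, percentage overlap
(Jaccard × 100) and Dice.  Two detectors are compared per image with the
mid-p McNemar test on discordant pixels (`b`, `c`):
`midp = min(1, 2[P(X <= min(b,c)) - P(X = min(b,c))/2])` for
`X ~ Binomial(b + c, 1/2)`, rejecting equal accuracy at the 5% level, with
each model's misclassification rate reported alongside.  The mid-p closed
form is verified against exhaustive binomial enumeration in the tests.
Summaries report misdetection counts, per-channel usage (`N_R`, `N_G`,
`N_B`), medians with quartiles for `delta_C`, and means of the mask metrics
over non-misdetected images.

## Known limitations

* The detected boundary is necessarily a circle; free-form boundary
  refinement (active contours, level sets) and cup/disc measures are out of
  scope.
* A lesion that is large, bright in all three channels, and disc-sized can
  still capture the ROI — the coarse combination has no vascular-context
  cue.  Such failures surface as `delta_C >= 1` and are exactly what the
  screening flags are for.
* `R_a` must be roughly right: the crop, the closing element and the Hough
  band all scale with it.  Discs beyond about 1.3 `R_a` leave the search
  band.
* Working-scale kernels assume `R_a/4 >= 8` px after reduction; tiny images
  with large trigger settings should be processed at full scale.
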