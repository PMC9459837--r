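---
title: "orchardtrack: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orchardtrack: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(orchardtrack)
```

## The problem

A fixed camera photographs an apple canopy daily over a growing season.
Three things stand between those photographs and a per-fruit growth
curve: (i) a segmentation model must find each fruit's *full* region even
where leaves, shadows or other fruits hide it, which requires training
masks that include hidden pixels — masks nobody wants to annotate by
hand; (ii) detections from different days must be linked to the same
physical fruit; (iii) the resulting radius series must be extrapolated to
a harvest-size prediction while the season is still running. The package
implements one tested component for each step, plus the standard
evaluation metrics, and chains them into a reproducible demo pipeline.

## Synthetic canopy images (the compositor)

A scene is painted in four layers: background plate, background leaves,
fruits, then (shadow, foreground leaf) pairs. Because leaves are painted
*after* fruits, fruit regions end up partially hidden exactly as in a
real canopy, while the compositor knows each fruit's complete footprint.
Two masks are recorded per fruit:

* the **amodal mask** — the full transformed footprint before any
  foreground occlusion (this is the training target for hidden-region
  detection), and
* the **visible mask** — amodal pixels not covered by any later-painted
  opaque layer. Shadows darken multiplicatively and are not opaque, so a
  shadowed fruit pixel stays visible (darker), which matches how a
  human annotator would treat it.

Default generation parameters (units px, %, degrees):

| parameter | default | meaning |
|---|---|---|
| canvas | 1088 × 1088 | model input size |
| fruit height, width | U(140, 190) each | drawn independently |
| leaf height, width | U(60, 90) each | drawn independently |
| brightness | U(60, 120) % | multiplicative, clamped |
| angle | U(−90, 90)° | rotation about sprite center |
| fruits per image | U{3..8} | |
| foreground leaves | 80 | fixed count per image |
| background leaves | one of {0, 100, 200, 400} | drawn per scene |
| P(red apple) | 0.553 | else green |
| shadow factor | 0.55 | multiplicative darkening |

Height and width are sampled independently within one range; this *is*
the aspect-ratio variation, so no separate aspect parameter exists. The
foreground-leaf count is read as a fixed 80 leaves per image, and the
background-leaf counts {0, 100, 200, 400} as per-scene variants drawn
uniformly unless fixed in the configuration; both readings are
documented choices, since count semantics at this level (per image vs.
dataset variants) are interchangeable for training-data purposes.
Brightness is implemented as a multiplicative luminance factor (the
natural reading for sprite compositing; an additive shift would push
dark pixels out of gamut much sooner).

Further conventions:

* **Coordinates** are 0-based, origin top-left, x rightward, y downward;
  boxes are half-open. Pixel (x, y) has center (x + 0.5, y + 0.5).
* **Anchoring**: a placement's position is the top-left of the
  transformed sprite's bounding box; the sprite *center* is what is
  drawn uniformly over the canvas, so sprites may overhang edges.
  Fruits whose on-canvas amodal footprint falls below 25% of the
  unclipped footprint are redrawn elsewhere — near-empty slivers make
  useless training instances. The threshold is configurable.
* **Paint order among fruits** is draw order: a later fruit occludes an
  earlier one, so fruit-on-fruit occlusion appears in the data.
* **Shadows** take the leaf's footprint under an independently drawn
  scale/aspect/angle transform, displaced from the leaf by a random
  10–30 px offset, painted immediately before their leaf so a shadow can
  fall onto a fruit. No shadow darkening factor is standard anywhere;
  0.55 was fixed once as a visually plausible default and exposed in the
  configuration.
* **Randomness**: one master seed; sample *i* uses a seed derived by a
  fixed mixing rule (`split_seed`), so a dataset is reproducible,
  order-independent and resumable.

The procedural fixture assets (shaded near-elliptical fruit blobs,
harmonic-wobble leaves, low-frequency textured background) stand in for
manually cropped photographs. They reproduce the *geometry* of the
problem — occlusion, scale and color statistics, mask bookkeeping — but
not photorealistic texture, lighting, specularity or real leaf shapes. A
green test on synthetic scenes therefore establishes the correctness of
the compositing, masking and bookkeeping machinery, not that a model
trained on these particular sprites transfers to orchard photographs;
for that, users supply their own cropped sprite assets.

## Annotations and tiling

VIA (VGG Image Annotator) 2.x polygon projects are read and written
losslessly; polygons rasterize by an even-odd pixel-center rule chosen
for exact countability (an axis-aligned n × n square covers exactly n²
pixels), and masks vectorize by a crack-following boundary trace whose
polygon → mask → polygon → mask composition is idempotent. Both
directions are verified against brute-force per-pixel oracles.

Full-resolution 5184 × 3456 frames are tiled into 1088 × 1088 model
inputs. The published workflow cuts such a frame into 11 sections, but
no geometry for that count is derivable from the frame and tile sizes
alone; the default `"paper11"` layout therefore fixes 4 × 3 clamped
origins minus the bottom-right tile — honoring the *count*, which is the
only recoverable contract — and any other layout can be supplied
explicitly.

## Detections and the oracle detector

A detection is a contour polygon with bounding box, center, radius,
capture date and score. The fruit radius is the **equivalent-circle
radius** `sqrt(area/π)`: it is rotation-invariant and robust to partial
contour jitter, unlike box-derived measures (half the mean box side is
available as an alternative). The center is the mask centroid rather
than the rectangle center, again for robustness; both sources are
computed from the same contour/box data.

The oracle detector converts ground-truth instance masks into detections
(amodal mode emulates a perfect hidden-region detector; modal mode a
visible-region one) and corrupts them per a specification: instance
drops, vertex jitter, multiplicative radius bias, spurious elliptical
detections — all seed-deterministic and independent across frames. Any
callable with the same signature can replace it, which is the package's
adapter contract for a trained segmentation model.

## The tracker

Gate semantics follow the forms given in the README exactly: the
distance gate is strict (`<`), the size and contour gates inclusive
(`≤`), and all three compare the candidate detection against the
track's **most recent observation**, not a track average — the
identification logic is day-to-previous-observation comparison. `T`
starts at 0, increases by the number of elapsed calendar days whenever a
frame passes without a match (daily frames make this +1 per day) and
resets to 0 on a match; it never caps by default, matching unbounded
relaxation, though `max_gap_days` can terminate stale tracks.

Where the matching rule is underdetermined — several detections passing
all gates for one track, or several tracks competing for one detection —
the package resolves it deterministically: candidate pairs are assigned
one-to-one, greedily by ascending center distance, ties broken by lower
shape dissimilarity and then lower track id. The test suite proves this
greedy pass equals exhaustive enumeration whenever the gate-feasibility
matrix admits a unique maximal assignment. Unmatched detections spawn
new tracks by default (a general tool must bootstrap); a targets mode
restricts tracking to user-selected initial detections instead.

Hu invariants are computed **analytically** from the contour polygon via
Green's-theorem closed forms, so the dissimilarity is exactly
translation/rotation/scale invariant and independent of any raster
resolution. Invariant pairs with magnitude below 1e-5 are skipped, the
conventional floor for this distance.

## The growth model

`Y(X) = a / (1 + b·e^{cX})` with a > 0, b > 0, c < 0; X counts days from
April 1 of the detection year (April 1 = 0 internally; reports that want
a 1-based "days 1..227" axis apply a +1 display offset — the printed
convention cannot be pinned down more precisely than that, and the
offset never affects the asymptote). Day 227 of a non-leap year is
November 14, the assumed optimum harvest time. The harvest-radius
prediction is the convergence value `a`; a fit with c ≥ 0 has none and
is an error to extrapolate.

Fitting is bounded nonlinear least squares (`nls` "port", with an
`optim` L-BFGS-B fallback for degenerate series):

* initialization `a₀ = 1.05·max(Y)`; `log b₀` and `c₀` from the linear
  regression of `log(a₀/Y − 1)` on X (the logit-linearization of the
  model);
* bounds a ∈ (max Y, 50·max Y), b ∈ (1e-6, 1e6), c ∈ (−1, −1e-6) — a
  must exceed every observation for the model to pass through the data,
  and the c bound keeps the rate physically plausible (well under
  doubling per day);
* convergence at relative RSS change < 1e-10 or 500 iterations;
  non-convergence and flat series yield *flagged* fits, not exceptions,
  so real-time scans continue past bad days.

Real-time prediction refits on each day's observation prefix and records
the asymptote; days with fewer than 5 points or spanning under 14 days
are reported missing, suppressing the wild early-prefix estimates that
short logistic prefixes produce (predictions genuinely stabilize only
once the series approaches its inflection — a model property the test
suite demonstrates with noisy replicates, and the reason early-season
harvest prediction is out of scope). All radii are relative (pixels);
`calibrate_to_physical` rescales a prediction series through one
physical measurement at a chosen day.

## Evaluation

Precision, recall and IoU follow their standard pixel/count forms. One
rule is a package decision, stated prominently: *what counts as a true
positive* is one-to-one greedy matching by descending IoU at threshold
0.5 (configurable) — no universal criterion exists, and published
aggregate tables depending on a particular unstated rule are not
reproduction targets here. MAPE is reported as a fraction (0.079 =
7.9%). "Filtered" IoU is the per-day IoU of the detection the tracker
assigned to a fruit; "averaged" IoU is the mean over all detections
overlapping that fruit's truth mask — their gap measures how much the
identification filters help under fruit-on-fruit overlap.

## The demo pipeline

`run_demo` synthesizes a 30-frame daily sequence in which each of 4
fruits keeps a fixed sprite and position (with a 0.5 px/day downward
drift emulating the sag of heavier fruit) while its sprite scale follows
a logistic schedule; it then runs oracle detection, tracking, fitting
and evaluation from one seed, and writes a byte-reproducible report.

The demo's schedule rate deserves a note. A full season's logistic rate
(|c| ≈ 0.02–0.03/day over ~227 days) compressed into a 30-day demo
window would leave the asymptote ill-identified, while too fast a rate
would violate the 10% size gate between consecutive days. The default
`c = −0.08/day` with frames starting at the inflection point gives a
~4% day-over-day radius change (comfortably inside the gate) and brings
the series to ~92% of its asymptote within the window, so the fit is
well-conditioned. This was chosen once, from the gate arithmetic, as the
demo's stated world. The scheduled asymptote in *measured* units is
known analytically (sprite equivalent radius scales linearly with target
size), so asymptote-recovery error is measured without circularity.

## Known limitations

* The compositor targets mask bookkeeping fidelity, not photorealism; no
  blur, boundary anti-aliasing, or lighting model beyond brightness and
  shadows. Boundary hardness in particular differs from photographs.
* The tracker assumes an essentially static camera; it has no motion
  model and no appearance embedding, so large inter-day displacements
  (beyond `40 + 2T` px) break identity, and very dense fruit clusters
  can defeat the distance gate.
* The growth model is single-season logistic; multi-year models and
  early-season (pre-inflection) prediction are out of scope.
* Nearest-neighbor resampling keeps masks crisp and countable but
  introduces ~1-pixel contour noise; radius estimates inherit a relative
  error of order 0.5/r.
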