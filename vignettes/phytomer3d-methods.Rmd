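---
title: "phytomer3d: model, conventions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phytomer3d: model, conventions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytomer3d)
```

## The model

A wheat shoot is modeled as a two-level union of rigid bodies. The atomic
unit is the *3D phytomer* — internode, leaf sheath, leaf blade, and (on the
top unit of a fertile tiller) the ear — each organ represented by a triple:
a triangle **mesh** `M` for the surface, a polyline **skeleton** `S` for the
organ axis (leaf vein, sheath mid-axis, internode mid-axis), and a named
**parameter set** `Q` (lengths, angles, diameters). A tiller of `n`
phytomers is

    Tiller = union over k of  R_k T_k Phytomer_k

where each phytomer-level transform is restricted to a rotation about the
vertical axis (the leaf azimuth) plus a vertical translation (the base
height), and a shoot of `m` tillers is a union of tillers each moved by a
*general* rigid transform (tillers lean). This restriction at the phytomer
level matches the azimuth/height parameterization with which digitized
plants are recorded; whether phytomer placement may also tilt was left open
by the source procedure, and we resolved it conservatively: tilt enters only
at the tiller level. Both choices are tested numerically (associativity,
length conservation, azimuth recovery).

### Coordinate and unit conventions

The acquisition convention defines gestures, not axes, so the package fixes:
right-handed axes, **z up**, ground plane at `z = 0`, azimuth measured
counter-clockwise from `+x` in the XY plane, **degrees** for all API-level
angles, **cm** for all lengths (digitizer scale). The azimuth of a phytomer
is anchored to the leaf: the direction of the first non-degenerate XY
segment of the vein polyline. These were genuinely open design points; all
downstream formulas are stated in these conventions and the test suite pins
them.

### Canonical normalization

A template phytomer is the equivalence class of its digitized pose under
rigid motion. `normalize_phytomer()` picks the canonical representative in
a fixed order: translate the internode base to the origin, apply the
*minimal* rotation bringing the internode axis onto `+z`, then rotate about
`z` until the leaf azimuth is zero. The order matters (rotations do not
commute); fixing it makes normalization idempotent and makes equality of
templates meaningful. Degenerate internodes (zero axis length) are rejected
rather than guessed.

## Multi-scale traits

| trait | scale | definition |
|---|---|---|
| `L_bend` | leaf | chord(base, tip) / vein arc length, in (0, 1] |
| `theta_l` | leaf | angle between the stem vector and the leaf base-to-tip chord |
| `S_phy` | phytomer | internode (+ spike, on the top unit) length x perpendicular distance from leaf tip to internode axis x max blade width |
| `N_length` | stem | mean distance between adjacent nodes |
| `theta_s` | stem | angle of base-to-top stem vector from vertical |
| `h` | plant | max z over spike vertices (fallback: all vertices, with warning) |
| `S_area` | plant | convex-hull area of the XY projection of the spike layer |

Decisions a maintainer should know:

* the **leaf vector** for `theta_l` is the base-to-tip chord, not the
  tangent at the base — the chord is robust to digitizer noise while a
  tangent amplifies it;
* the "distance from leaf tip to internode" in `S_phy` is the perpendicular
  point-to-line distance to the internode axis (not the distance to the
  base node);
* `S_phy` is implemented literally as a product of three lengths (cm^3)
  even though it is traditionally called an envelope *area*; dividing by
  `N_length` then gives `PHY` in cm^2;
* the **spike layer** is the set of ear-component vertices across tillers.
  Digitized ears contribute both their axis polyline and a small bipyramid
  mesh built over the girth triple, so a single ear already has a nonzero
  footprint. Shoots with no ear at all fall back to the top 20% height band
  of all vertices (configurable), with a warning;
* `S_area` is a **convex hull** area. An alpha-shape or rasterized
  silhouette would be smaller for concave layers; the hull was chosen
  because it is parameter-free, deterministic, and matches a width-based
  convergence measure in spirit (it never under-reports horizontal spread).

## The architecture vector and classification

`PA = (C, L, PHY, S)` with `C = h * 10 / S_area` (the factor 10 is part of
the index definition), `L = L_bend * theta_l`, `PHY = S_phy / N_length`,
`S = theta_s`. Aggregation from organs to the plant is not prescribed by
the index definitions; the package defaults to the **mean** over leaves /
phytomers / tillers and also offers `flag_leaf` and `top_phytomer` modes,
because flag-leaf-centric summaries are common in wheat work. No mode is
claimed to be "the" published aggregation.

Classification uses `C` only. The published classes are ranges
(loose 1.95; semi-compact 2.87–5.72; compact 6.36–9.56), not decision
rules; the package places the boundaries at the midpoints of the
inter-class gaps, 2.41 and 6.04, so every anchor value classifies into its
own class and the rule is total and monotone on (0, Inf). Panel summaries
report the replicate spread both as sample SD and as range, since the
published "error value" is not defined precisely.

## The synthetic generator: what it emulates, what it does not

`generate_shoot()` emits plants in the digitizer format with exact ground
truth, standing in for unpublished field digitizations. The stated world:

* **leaf droop is a circular arc** of arc length `L` and subtended angle
  `phi` in a vertical plane, giving the closed forms
  `L_bend = sin(phi/2) / (phi/2)` and `theta_l = base angle + phi/2`. The
  arc was chosen *only* because it makes curvature recovery analytic —
  real blades twist and kink;
* blade width is parabolic in arc position (zero at base and tip, maximum
  at mid-length); rows are emitted at arc positions `(i - 1/2)/n_rows` so
  no digitized row has zero width;
* tillers fan uniformly in azimuth, leaves alternate 180 degrees up the
  stem (distichous phyllotaxis), each tiller leans rigidly by `stem_lean`
  toward its azimuth, so `theta_s` equals the lean and
  `h = cos(lean) * (stem + ear length)` exactly;
* defaults describe a filling-stage winter wheat plant: 3 tillers, 4
  phytomers, internodes (10, 14, 18, 24) cm, 10 cm ear, 25 cm / 1.8 cm
  flag-leaf-scale blades, 8 degree lean — height about 75 cm, inside the
  72.6–100 cm span of the published cultivar panel. These values were fixed
  once, before any acceptance measurement, and are not tuned;
* replicate jitter is multiplicative Gaussian with 5% CV; point noise is
  iid Gaussian per digitized coordinate.

A green recovery test therefore establishes that the *pipeline* is
faithful — reading, meshing, assembly and trait algebra introduce only
discretization error (< 0.01% at the default sampling densities). It does
**not** establish that real wheat satisfies the arc-leaf or rigid-lean
assumptions, and it cannot reproduce the published cultivar statistics,
whose raw digitizations were never released.

### Noise and the recovery tolerances

Noise-free, every extracted value matches truth to within 1% (the error is
purely polyline discretization of the arc). Under 0.1 cm point noise the
per-*value* error of `S_phy` is structurally larger than 10%: it multiplies
three noisy lengths and takes a maximum over ~6 noisy row widths, so the
width term alone carries a +6% bias (extreme-value shift) with a heavy
upper tail. The acceptance suite therefore checks the noisy condition at
the per-trait **mean** relative error (worst trait observed ~6.5%), while
keeping the strict per-value bound for the noise-free condition. The
tolerances themselves (1%, 10%) are unchanged.

## Numerical choices

* orthonormality of rotations is validated to 1e-8; assembly node
  coincidence to 1e-6 cm; idempotence of normalization to 1e-9 per
  coordinate;
* the minimal rotation between two axes uses the Rodrigues formula with a
  stable perpendicular-axis fallback at 180 degrees;
* girth triples are converted to node diameters via the 3D circumcircle
  formula `d = abc / (2 * area)`; collinear triples are errors, not zeros;
* zero-variance parameters are dropped (with a warning) from the z-scored
  template similarity metric; exact ties resolve to the earliest database
  record, making selection deterministic;
* leaf surface/vein tip coincidence is checked with a 0.2 cm tolerance —
  beyond it the reader warns but does not fail, since 0.1 cm point noise
  legitimately produces ~0.3 cm gaps;
* degenerate spike layers (< 3 distinct projected points, or collinear)
  yield `S_area = 0` with a warning, and `C` is then undefined (error)
  rather than infinite.

## Known limitations

* No sheath/internode anatomical substructure, no growth dynamics, no
  collision handling between organs, no light-interception metrics.
* The leaf mesh is a fixed triangulation of the digitized rows (quads split
  toward the tip); very sparse rows under-resolve twisted blades.
* The OBJ layer supports only the v/f subset this package writes.
* `S_area` as a convex hull over-reports strongly concave spike layers.
* The classification thresholds are anchored to a 10-cultivar panel; other
  germplasm or growth stages may need re-anchoring via `pa_class_thresholds`.
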