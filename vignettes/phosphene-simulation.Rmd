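---
title: "Simulating cortical prosthetic vision from retinotopic phosphene maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cortical prosthetic vision from retinotopic phosphene maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmap)
```

## The problem

A cortical visual prosthesis stimulates the visual cortex through small
electrode arrays; each electrode elicits a phosphene, a punctate light
percept at the visual-field location encoded by the stimulated patch of
cortex. Simulation studies of prosthetic vision have mostly assumed
phosphenes laid out on regular grids. Real implants sit on a folded,
individually variable cortical surface under hard surgical constraints, so
the phosphenes an implant recipient actually receives cluster unevenly and
cover an idiosyncratic region of the visual field. `phosmap` implements a
simulation pipeline that derives phosphene maps from retinotopically mapped
cortical surfaces and posed implants, renders stimuli through those maps,
relocates stimuli onto dense phosphene clusters, and scores maps with
predictive spatial metrics.

## The world model: retinotopically mapped surfaces

The pipeline operates on a cloud of *grayordinates* (cortical surface
vertices), each carrying a 3D position and population receptive-field (pRF)
estimates: polar angle (0° at the upper vertical meridian, clockwise
positive so the right visual field has positive x), eccentricity (deg),
pRF size (radius, deg), a V1/V2/other label, the hemisphere, and a
gyral/sulcal flag. Real data in this shape (for example high-field pRF
retinotopy releases, with grayordinates spaced about 2 mm apart) can be
supplied as a delimited table via `read_retinotopy_table()`.

`generate_synthetic_surface()` builds surfaces with the same structure so
that every downstream stage is testable without any download. Design
choices, each made once:

* **Retinotopy template.** A complex-log (log-polar) map: cortical distance
  along the eccentricity axis is `u = k·log(1 + ecc/a0)` with a foveal
  offset `a0 = 0.75°`, the standard minimal model of cortical
  magnification. V1 occupies the central band of the sheet, bounded by the
  vertical meridian; V2 is the mirror-reversed annulus adjacent to it,
  ending at the horizontal meridian — the topology of real V1/V2 borders.
* **Folding.** A single sinusoid (default amplitude 2 mm, wavelength
  20 mm) displaces the sheet along its normal; `is_gyrus` is true where
  the displacement is outward. This is the simplest geometry that makes
  the gyri-only placement constraint non-trivial. With amplitude 0 the
  sheet is flat and has no gyri.
* **Scale.** Grayordinate density is fixed at the emulated ~2 mm spacing,
  so the sheet area grows with the requested count rather than matching
  anatomical V1 area; the retinotopy always spans the requested
  eccentricity range. This trades anatomical surface area for the two
  properties downstream stages rely on (sampling density and
  magnification).
* **pRF size.** Linear in eccentricity (`0.05·ecc + 0.5` deg by default,
  a typical V1/V2 regime) plus optional Gaussian noise; the noise-free
  generator recovers its parameters exactly under OLS, which the tests
  exploit.
* **Coordinates.** x = left–right (coronal plane = x–z plane),
  y = posterior–anterior, z = inferior–superior, so "rotation relative to
  the coronal plane" is well defined. Hemisphere sheets sit at x = ±8 mm;
  the left hemisphere maps the right hemifield and vice versa. The
  polar-angle zero/sign convention above is declared, not inferred from
  any dataset.

What the generator does *not* emulate: real gyral/sulcal geometry beyond
one sinusoid, inter-subject variability in map topology, pRF measurement
noise structure, or subcortical grayordinates. Tests passing on synthetic
surfaces therefore validate the pipeline's mechanics and analytics, not
claims about any individual brain.

## Implant placement and constraints

The default array (`gennaris_layout()`) has 43 electrodes at 1 mm pitch: a
7×7 grid minus the four corners and the two horizontal mid-edge pads. The
published hardware does not print its pad geometry, so the layout is fully
configurable; only the count (43) and pitch (1 mm) are treated as fixed.

`place_implant()` embeds the layout in the tangent plane at a chosen
centre vertex, estimated by least squares over the K = 20 nearest
grayordinates. The in-plane frame is chosen so that at rotation 0 the long
axis lies in the coronal plane, making the rotation parameter directly the
constrained angle. `validate_placement()` checks, with inclusive
boundaries:

* rotation within ±45°,
* implant centres within 20 mm of the inductive-coil centroid (default:
  the centroid of the implant centres),
* electrode-to-electrode separation of at least 3.6 mm between arrays
  (downgraded to a warning in dense 12-implant configurations, where
  pairwise footprint overlaps are quantified instead),
* most electrodes over V1∪V2 (default threshold 0.9 of electrodes whose
  nearest grayordinate is V1/V2 — "most" is qualitative in the source
  constraint, so the threshold is configurable),
* implant centres on gyri.

`overlap_distance()` measures how far two array bodies interpenetrate:
both footprint rectangles are projected into the mid-plane between the
implants and the overlap is the mutual extent along the arrays' short axes
(given positive long-axis overlap). Identical poses give the footprint
short side; disjoint footprints give 0; the measure is symmetric and
rigid-motion invariant.

`suggest_implant_sites()` exists so that scripted, seeded runs on
synthetic surfaces are reproducible: it greedily accepts gyral V1/V2
vertices in centre-out order subject to a minimum centre spacing (default
13 mm, which guarantees the 3.6 mm electrode separation for 6 mm grids at
any relative orientation). It replaces the manual, surgeon-guided site
selection used with real anatomy and optimises no visual objective.

## From electrodes to phosphenes

**Position.** Each electrode is projected into the visual field by finding
its 50 nearest grayordinates (3D Euclidean distance — a documented
approximation to geodesic distance, which a point cloud does not support)
and averaging their visual-field positions and pRF sizes with inverse
distance weights `1/d` (exponent 1; an electrode within 1e-9 mm of a
grayordinate inherits its values exactly).

**Size.** Phosphene radius comes from a two-factor scaling of pRF size.
The activated cortical diameter under stimulation current `I` follows a
sigmoid

\[ AC(I) = \frac{MD}{1 + e^{-slope\,(I - I_{50})}} \]

with `MD = 5.3 mm`, `I50 = 0.89 mA`, `slope = 5.85 mm/mA`, and inverse
cortical magnification is linear in eccentricity,
`1/M = (ecc + e2)/A` with `e2 = 3.67°`, `A = 29.8`. At half-saturation
current the activated radius is `MD/4 = 1.325 mm`, giving the subdural
phosphene-radius relation

\[ PS(ecc) = \frac{MD/4}{A}\,ecc + \frac{(MD/4)\,e_2}{A}
          \approx 0.044\,ecc + 0.163 . \]

A subject whose own pRF-size fit is `PS = a·ecc + b` is rescaled onto this
relation by `0.044/a`, and subdural is shrunk to intracortical stimulation
by the ratio of activated radii, `0.34/1.325 ≈ 0.257` (the 0.34 mm
intracortical radius at 80 µA is taken as a given constant: evaluating the
sigmoid at 0.08 mA does not yield it, so it presumably derives from an
unstated current-spread relation). The combined factor applied to every
interpolated pRF size is therefore `≈ 0.011/a`
(`prf_to_phosphene_scale()`). One published variant of this chain prints
an intercept term `b/a × 0.007` that is inconsistent with scaling the
whole relation by a single factor; this package scales the entire pRF size
by `0.011/a`, the reading that reproduces every other printed constant.

The subject fit itself (`fit_ecc_size()`) is OLS of pRF size on
eccentricity over V1∪V2 with outlier clamping: observations outside their
95% *prediction* intervals (the interval type implied by per-observation
response bounds) are replaced by their predicted value and the model refit
once. The number of clamped points is reported; a single refit leaves a
residual contamination of order (outlier magnitude)/n, which the tests
quantify.

**Control maps.** `generate_control_map()` draws the same number of
phosphenes uniformly over a disc (radius defaulting to the 95th-percentile
eccentricity of the paired retinotopic map — the field extent of control
maps is not pinned down by the source description, so it is configurable)
and assigns radii from an average eccentricity-size fit, preserving
cortical magnification while removing spatial clustering.

## Rendering and acuity testing

Stimuli are physical-scale grayscale matrices at 40 px/deg (anchored to
the clustering scale of 200 px ≈ 5°). Tumbling-E optotypes use the
standard 5×5 construction (height 5·MAR, stroke MAR, with
MAR = 10^LogMAR arc-minutes); gratings are square waves with bar width
MAR at 50% duty inside a circular patch (patch size and duty cycle are
declared choices; the source battery does not print them). Five
parameterised object silhouettes (top, trousers, dress, sneaker, bag) are
generated in code as synthetic stand-ins for grayscale object photographs.

Two presentation rules select active phosphenes: *skeleton sampling* for
thin optotypes (Zhang–Suen thinning to a 1 px medial axis, then each
skeleton pixel activates its nearest phosphene, ties to the lowest index —
the phosphene lights at its own location) and *direct masking* for area
stimuli (a phosphene is active iff the image at its centre exceeds 0.5;
off-canvas phosphenes are tallied, not errors). Rendering draws each
active phosphene as an isotropic Gaussian with σ = radius/3 and peak 1,
summed and capped at 1.

`brvt_score()` applies the rudimentary-acuity ladder rules: a tumbling-E
level passes at ≥ 4/8 correct, a grating level at ≥ 7/8; the assigned VA
is the best passed level, with 3.0 LogMAR assigned when nothing passes.
`validation_block()` brackets a measured VA with 12 trials at VA ± 0.2 and
VA. The simulated observer that would *answer* trials is out of scope;
scoring consumes trial outcomes from any source.

## Cluster-based relocation

Retinotopic maps concentrate phosphenes in patches, so a stimulus centred
at fixation may fall on empty field. `relocate_stimulus()` runs DBSCAN
(eps = 200 px ≈ 5°, minimum 100 points; closed neighbourhood, the point
counting itself — conventions differ between implementations, so these are
declared) on phosphene pixel positions and translates the stimulus by the
integer pixel shift bringing its centre closest to the arithmetic-mean
centroid of the target cluster: the largest one, ties resolved toward the
canvas centre. If no cluster forms the stimulus is returned unchanged with
a warning flag, and shifts are clamped so the stimulus stays on canvas.

## Map metrics

Three per-map metrics, computed by `map_complexity()`,
`mutual_information()` and `map_area()`:

* **Complexity** adapts a contour shape-complexity method to unordered
  point sets: Shannon entropy (base 2; the base is a declared choice) of
  the histogram of distances to the centroid (16 bins over [0, max]),
  entropy of the histogram of each point's two-nearest-neighbour angle
  (16 bins over [0, π]), and perceptual smoothness, the mean of
  `1 − θ/π` (0 where neighbours are diametrically opposite, 1 at a
  degenerate spike). The combined score is the unweighted mean of the two
  normalised entropies and the smoothness — weights are unpublished, so
  equal weighting is used, and only qualitative orderings (circle <
  noisy polygon < uniform random) are asserted. Note one consequence of
  the two-nearest-neighbour angle on open chains: the endpoints see both
  neighbours on one side (angle 0, the spike case), so a collinear chain
  of n points has smoothness exactly 2/n rather than 0.
* **Mutual information** between a stimulus and its rendered frame (both
  accepted in either order; images are centre zero-padded to a common
  size): intensities are binned (64 bins on [0,1]), the joint PMF is
  estimated from co-located pixels, cells below 1e-12 are dropped (the
  excluded mass is reported), and marginals are taken from the retained
  joint so MI ≥ 0, MI(X,X) = H(X) and symmetry hold exactly.
* **Area** is the area under a compact concave boundary of the phosphene
  centres: the tightest single-component alpha shape containing all
  points, computed from an in-package Bowyer–Watson Delaunay
  triangulation by binary search over circumradius thresholds
  (circumradii are quantised at 1e-6 of the point-cloud span so
  cocircular ties — ubiquitous on grid-like maps — are kept or dropped
  together; a deterministic sub-nanometre jitter regularises the
  triangulation only, with areas always computed from the original
  coordinates). Collinear maps yield area 0 with a degenerate flag. This
  is the declared analogue of a maximally shrunk concave boundary; tests
  validate it against exact hand-triangulated fixtures and a raster
  oracle rather than against any particular proprietary routine.

The regressions of these metrics against human visual acuity or
recognition accuracy require psychophysics data this package does not
ship; `metric_correlation()` is provided as a generic utility and asserts
nothing about published correlation values.

## The pipeline and reproducibility

`run_pipeline()` chains all stages from a `run_config()` (JSON
serialisable; defaults reproduce the study parameters: 43 electrodes at
1 mm pitch, ±45°, 20 mm coil distance, 3.6 mm separation, k = 50
projection, σ = r/3, 40 px/deg, eps = 200 px, minPts = 100). All
randomness flows from the single config seed through scoped RNG (the
caller's RNG state is never disturbed), so two runs with the same seed
produce byte-identical artifacts. A thin command-line wrapper
(`inst/cli/phosmap`) exposes `synth`, `place`, `derive`, `render`,
`relocate`, `metrics` and `run` subcommands over these functions.

```{r example, eval = FALSE}
cfg <- run_config(seed = 1L, n_implants = 12L, out_dir = "run1")
bundle <- run_pipeline(cfg)
nrow(bundle$map$phosphenes)        # 516 = 12 implants x 43 electrodes
bundle$metrics$retinotopic$area_deg2
```

Problem sizes used in the test suite are deliberately modest (surfaces of
400–2000 grayordinates per hemisphere, maps of 86–516 phosphenes,
canvases of 540–1080 px), chosen so the full suite exercises every stage
— including the O(n²) Delaunay and DBSCAN oracles — in under a minute
while remaining well inside the regimes the algorithms are used in.

## Known limitations

* One phosphene per electrode, no interactions, no brightness or temporal
  dynamics (appearance/fading, drift) — these are explicitly deferred.
* Geodesic cortical distance is approximated by 3D Euclidean distance in
  the KNN projection.
* The synthetic folding is a single sinusoid; anatomical realism of the
  surface is limited to density, magnification and V1/V2 topology.
* No automatic implant-placement optimisation: site suggestion is a
  spacing-constrained convenience, and real surgical planning remains a
  manual decision.
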