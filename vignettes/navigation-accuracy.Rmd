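---
title: "Modeling navigation accuracy of template-guided transperineal biopsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling navigation accuracy of template-guided transperineal biopsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(biopsynav)
```

## The measurement problem

In MR-guided transperineal prostate biopsy, a rigid grid template of
parallel guide holes is fixed against the perineum. The template carries
fiducial markers at known positions; a physician clicks those markers on the
planning scan and a rigid *calibration* transform maps the template into the
image frame. Targets are then planned by clicking in the image: the system
snaps each click to the nearest guide-hole trajectory and reports the hole
coordinate and a cannula insertion *depth* such that the fired needle's
tissue core is centered on the target. How far the sampled core actually
lands from the planned target is the navigation error, and the clinical
stakes set the bar: a clinically significant lesion of 0.5 cm³ has an
equivalent-sphere radius of about 5 mm
(`sphere_radius_from_volume(0.5)` = `r round(sphere_radius_from_volume(0.5), 2)` mm),
so mean errors must stay below 5 mm for targeting to be meaningful.

Measuring that error requires an independent record of where each needle
went. The package models the standard phantom protocol: needles are
inserted into prostate phantoms under navigation, the phantoms are rescanned
on a high-field reference scanner where needles are clearly visible, two
observers mark each needle's entry point and tip on the reference scan, and
the sampled core is extrapolated from those picks. Corners of the phantom
box, visible in both scans, provide landmarks for a rigid registration
between the two frames so planned and actual cores can be compared.

## Geometry and the two error metrics

All computation happens on continuous coordinates in mm in three named
right-handed frames — `TEMPLATE` (the physical grid), `LOWFIELD` (the
planning scan) and `REFERENCE` (the ground-truth scan) — connected by proper
rigid transforms. Frame identity is carried on every point and enforced at
every operation, because silently mixing frames is the classic failure mode
of registration code.

Both calibration and frame registration reduce to least-squares rigid
point-set fitting, solved in closed form by the SVD-based orthogonal
Procrustes method with reflection correction (`fit_rigid()`). The RMS
residual of a fit is the fiducial registration error (FRE). No scaling or
affine terms are ever admitted: both mappings are between rigid bodies.

Per needle and calibrating observer, three errors are reported:

* **center to center** — Euclidean distance between the planned target
  (equivalently, the planned core center: the depth formula guarantees they
  coincide on the trajectory) and the ground-truth core center;
* **point to line** — perpendicular distance
  $|\overline{M_0 M_1} \times s| / |s|$ from the planned target to the
  infinite line through the ground-truth core;
* **point to segment** — the same distance clamped to the finite core.

The line and segment variants are both provided deliberately. The
perpendicular-to-the-trajectory reading is the conventional headline
metric, but a core has finite extent, so the clamped variant is the more
physical one; they differ only when the target's axial projection falls
beyond a core end. Reporting both costs nothing and removes an ambiguity
rather than baking in a guess. Every record satisfies the geometric
ordering `point_to_line <= point_to_segment` and
`point_to_line <= center_to_center`, which the test suite checks on random
records.

## Planning model

The template grid defaults to 13 × 13 holes at exactly 5 mm pitch (lettered
rows A–M, numbered columns 1–13) — the standard clinical grid spacing, at a
size typical of commercial brachytherapy-style templates. Snapping assigns
a click to the hole whose full 3-D needle line comes closest
(`snap_target()`), not merely the nearest hole in the grid plane; ties
break to the lowest row label, then the lowest column label, so snapping is
deterministic. Depth is measured from the patient-side face of the template
along the hole axis — a datum had to be fixed, and the distal face is the
natural zero for a cannula scale.

The biopsy kit defaults to a 20 mm throw, an 18 mm core, and a
tip-to-core-center offset of half the throw (10 mm). Needle gauges say
nothing about these lengths, so they are configurable
(`biopsy_kit()`), and the ground-truth extrapolation
(`extrapolate_core()`) reuses the same offsets so that the planning and
measurement sides describe the same physical kit.

`compute_depth()` and `projected_core()` are exact inverses by
construction: projecting a core at the computed depth puts its center on
the target's on-axis projection to within 1e-9 mm over thousands of random
configurations (tested). This round-trip identity is what licenses treating
"planned target" and "planned core center" as the same point in the error
metrics.

## Ground truth and exclusions

Each observer's entry/tip pick pair defines a needle direction
$u = (tip - entry)/|tip - entry|$; the sampled core center is extrapolated
as $tip + d_{tc} u$ with $d_{tc}$ the kit's tip-to-core-center offset. The
consensus core across observers takes the componentwise mean of centers and
the renormalized mean of unit directions. A needle whose entry point could
not be visualized is flagged, not dropped: the flag excludes the needle
from the error analysis across *all* calibrating observers, the reason is
carried in the exclusion log and in the retained records, and tip picks of
flagged needles still contribute to the interobserver variability table
(tip visibility is unaffected).

Interobserver pick variability is summarized from tip coordinates only —
mean, SD, min, max of the per-needle distance between the two observers'
tip picks. Interobserver variance of the *error* is the sample variance of
per-observer mean errors; pooling per-observer means (rather than
per-needle means) was an open choice, made because the question it answers
is "how much does the result depend on which physician calibrated".

Confidence intervals use the standard t-based formula
$\bar{x} \pm t_{0.975,\,n-1}\, s/\sqrt{n}$ on the pooled per-record errors.
A single-observation summary reports SD 0 with an explicit degeneracy flag
rather than `NA`, so downstream tables never silently propagate missing
values.

## What the synthetic generator emulates

`generate_experiment()` produces a complete, seeded study:

* **Phantoms.** Five prostate volumes (25, 40, 60, 90, 120 cc by default)
  as ellipsoids with fixed 0.7 : 1.0 : 0.85 relative semi-axes, each in a
  120 mm box whose corners are the registration landmarks. An ellipsoid is
  enough: navigation geometry cares about volume and extent, not surface
  detail.
* **Poses.** Per phantom, a true `TEMPLATE→LOWFIELD` calibration (rotations
  up to ±10° per axis, translations up to ±20 mm) and a true
  `LOWFIELD→REFERENCE` pose (±15°, ±30 mm), the scale of repositioning a
  phantom between scanners.
* **Targets.** Uniform in each prostate ellipsoid, snapped to the grid; a
  trajectory that misses the gland triggers a logged resample. The needle
  allocation defaults to {3, 3, 3, 4, 4} across the five phantoms — "three
  or more per phantom" pinned down to a 17-needle total.
* **Execution.** The realized needle leaves the planned hole with a single
  angular kink (angle ~ N(0, σ²), σ default 1°, about a uniform random
  azimuth) and a depth error ~ N(0, 0.5² mm²). A straight-but-deflected
  trajectory is the simplest model consistent with deflection being a
  recognized error source without a published mechanism.
* **Picks.** Every human pick (fiducials, entry/tip, box corners) gets
  isotropic in-plane Gaussian noise (default σ = 1 mm) while its
  through-plane coordinate is *quantized* to the nearest slice center —
  3.0 mm slices for the planning scan, 3.48 mm for the reference scan.
  Observers select points on discrete slices; modeling that as
  quantization rather than extra Gaussian noise reproduces the
  characteristic floor it puts under achievable accuracy.
* **Exclusion.** One needle (the last, `N17`) is flagged
  entry-not-visualizable by default, so the default study yields
  16 usable needles × 4 calibrating observers = 64 error records.

The in-plane σ defaults (1 mm for fiducial and observer picks) were chosen
once as realistic pick precision for the pixel sizes involved, and they
land the simulated mean errors in the low-millimeter regime that phantom
accuracy studies of this kind report; they are generator tuning, not
measured quantities.

Randomness is split into per-component streams (poses, targets, execution,
fiducial picks, ground-truth picks, landmarks) derived from one root seed,
and noise draws are standard normals scaled by σ. Consequently switching
one noise source on, off or up leaves every other component's draws
bit-identical — which is what makes paired-seed monotonicity comparisons
clean.

What the generator does **not** emulate: image formation (contrast, SNR,
distortion), anisotropic in-plane pixelation, observer bias or learning
effects, gland deformation, curved needle paths, and any coupling between
noise sources. Passing tests therefore demonstrate that the *pipeline*
(calibration, planning arithmetic, extrapolation, registration, metrics,
accounting) is correct and that its error budget behaves sensibly under a
plausible noise model — not that a particular hardware system achieves a
particular accuracy on real tissue.

## Numerical choices and degenerate inputs

* Collinearity of a fiducial or landmark set is detected from the singular
  values of the centered point matrix (second singular value below 1e-9 of
  the first) and refused with a named error; three non-collinear points
  plus the proper-rotation constraint make the fit unique.
* Rotations are validated orthonormal and det +1 to 1e-9 at construction;
  direction vectors are normalized at construction and zero-norm inputs
  refused.
* Snapping ties (a click equidistant from two hole lines) resolve by label
  order with a 1e-9 comparison slack, so results are stable to roundoff.
* Negative computed depth (target proximal to the template) is an error,
  not a silent clamp.
* Slice quantization uses round-to-nearest (`round()`), so the maximum
  through-plane displacement is exactly half the slice spacing.

## Reproducibility scale of the shipped checks

The test suite and the acceptance script run the full 17-needle study —
generation plus evaluation takes about 0.2 s — at sizes chosen to keep the
whole suite fast while leaving the estimates stable: 20 seeded replicates
for the headline below-5-mm check, 200 paired replicates per level for the
noise-monotonicity property (three levels per noise parameter, shared
baseline), 500 replicates for the FRE-versus-theory check
(RMS FRE $= \sigma\sqrt{3(1 - 2/N)}$ for N fiducials with isotropic noise),
10 seeds for the zero-noise identity, and 100–1000 random instances per
geometry oracle.

## A complete run

```{r}
cfg <- default_study_config(seed = 1)
exp <- generate_experiment(cfg)
ev <- evaluate_experiment(exp)
ev
```

The same pipeline is available against disk artifacts:
`run_simulate()` writes the dataset directory (YAML config + CSV tables +
manifest), `run_evaluate()` reads one back and writes `errors.csv`,
`summary.json` and the rendered tables, and `run_end_to_end()` chains the
two. A thin command-line wrapper with the same stages ships in
`inst/scripts/biopsynav`.

## Known limitations

* The generator's noise magnitudes are plausible, not fitted to any
  measured pick distribution; absolute simulated errors should be read as
  regime checks, not predictions for specific hardware.
* Ground-truth extrapolation assumes the kit offsets are exact; a biased
  tip-to-core-center value would shift both planning and truth equally and
  thus hide itself — a real study would calibrate it independently.
* The interobserver variance convention (variance of per-observer means)
  and the t-based CI are stated conventions; other published tables may
  use different, sometimes unstated, formulas, so compare definitions
  before comparing numbers.
* Registration landmarks are box corners with the same pick noise as other
  picks; systematic registration bias (e.g. box flex between scans) is not
  modeled.
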