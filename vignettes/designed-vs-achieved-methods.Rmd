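---
title: "Measuring designed versus achieved 3D tooth movement: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring designed versus achieved 3D tooth movement: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomotion)
```

## The problem

Clear-aligner treatment is planned on a virtual setup: a *designed* final
position is prescribed for every tooth, and the *achieved* position after a
series of aligners rarely matches it exactly. In premolar-extraction cases
the discrepancy is clinically important — space closure tends to tip
anterior teeth distally and posterior teeth mesially (the "roller-coaster"
pattern), and buccolingual root torque is chronically under-expressed.
`orthomotion` quantifies these discrepancies on 3D whole-tooth (crown plus
root) models of the maxilla across three stages per patient:
pretreatment, designed, and achieved, for the twelve study teeth
U1–U3 and U5–U7 bilaterally (first premolars extracted).

The pipeline has four stages, each exposed as ordinary functions:

1. **Superimposition** — the achieved-stage scan is expressed in the
   pretreatment coordinate space by rigid best-fit registration on the
   maxillary bone surface (`superimpose_case()`), verified with a signed
   deviation map. Pretreatment and designed models already share one
   space (the virtual setup is built on the pretreatment scan), so the
   designed stage passes through unchanged.
2. **Reference frames** — a *world* coordinate system is built once from
   pretreatment landmarks (`build_world_frame()`) and transferred to the
   other stages; a per-tooth measurement frame (`build_tooth_frame()`)
   supplies the mesiodistal and buccolingual planes, the vertical line
   and the anatomical sign directions.
3. **Metrics** — five numbers per tooth and stage
   (`case_movement_records()`): mesiodistal angulation (MD°),
   buccolingual inclination (BL°), and mesiodistal, buccolingual and
   vertical displacements (MD, BL, IE, in mm). The reported discrepancy
   is always designed − achieved.
4. **Cohort statistics** — paired t-tests per tooth × metric
   (`summarize_movements()`), repeated-measurement reliability as
   ICC(A,1) (`icc_agreement()`), and a linear mixed model of
   influencing factors (`fit_lmm()`).

## Coordinate systems

**World frame.** The occlusal (transverse) plane is the best-fit plane of
three landmarks: the mesiobuccal cusps of the bilateral first molars and
the mesioincisal point of the central incisor; with exactly three points
the best-fit plane is the exact three-point plane, and `fit_plane()`
accepts more points only for sensitivity checks. The coronal plane
contains the bilateral first-molar cusp line and is perpendicular to the
occlusal plane; the midsagittal plane is perpendicular to both and passes
through the mesioincisal point. Because the incisal midpoint is digitized
on each central incisor, the package takes the midpoint of the two U1
incisal-edge midpoints as "the" mesioincisal point; on a symmetric arch
the two coincide at the midline.

Plane normals are canonically oriented — occlusal normal occlusally (away
from the root apices, resolved by apex landmarks when present, otherwise
by an `up_hint`), coronal normal anteriorly, midsagittal normal toward
the patient's left. The frame triad is right-handed with Z the occlusal
normal and Y the coronal normal. Axis *labels* are an internal
convention only: every reported metric is projected onto per-tooth
anatomical directions, so no result depends on which world axis is
called X or Y. The frame origin (the incisal point projected onto the
occlusal plane) likewise cancels out of every difference.

**Tooth frames.** For each tooth the mesiodistal plane passes through the
tooth's reference point — its named crown landmark: incisal-edge midpoint
(U1, U2), cusp tip (U3), buccal cusp (U5), mesiobuccal cusp (U6, U7) —
is perpendicular to the occlusal plane, and is parallel to the coronal
plane for anterior teeth or to the midsagittal plane for posterior teeth;
the buccolingual plane is the perpendicular counterpart, and the vertical
line is their intersection. Anatomical unit vectors fix the signs:
mesial points toward the midsagittal plane for anterior teeth and
anteriorly for posterior teeth, buccal points away from the arch center,
extrusion points occlusally. Left and right quadrants therefore mirror:
a mesial tip is positive on both sides, and a perfectly symmetric arch
yields identical metrics bilaterally. Tooth frames are rebuilt on each
stage's own reference point, so angular metrics use stage-local frames
under the shared world frame.

**Long axes.** The tooth long axis joins the crown landmark and the root
apex (for molars, the mesiobuccal cusp and the mesiobuccal root apex),
oriented apex → crown; a 5 mm floor on the crown–apex distance guards
against corrupt landmarks.

## The five metrics and their signs

Angular metrics are *absolute orientations per stage*: the signed angle
between the long axis and the vertical line after projection into the
mesiodistal (MD°) or buccolingual (BL°) plane, positive for mesial tip
and for buccal tip (lingual root torque) respectively. Linear metrics
are displacements of the reference point from its pretreatment position,
decomposed along the anatomical directions, positive mesially, buccally
and occlusally (extrusion). This mixed convention — absolute angles,
relative displacements — matches how such cohorts report their tables,
and the difference Δ = designed − achieved is fixed by reproducing the
published arithmetic (e.g. U1 BL°: 39.34 − 28.46 = 10.88).

Two conventions are the package's own, since the source material states
magnitudes and anatomical directions but no algebra: the angle range is
(−180°, 180°] with the sign taken about a per-tooth axis chosen so the
anatomical conventions hold; and projections shorter than 10⁻⁶ of the
vector norm raise a degenerate-geometry error rather than returning
noise. Tolerances are uniform: 10⁻⁹ for algebraic identities, 10⁻⁶
mm/deg for fitted quantities.

A note on the published linear columns: per-stage linear "designed" and
"achieved" SDs of tens of mm are not reconcilable with per-tooth
displacements of a few mm and most plausibly reflect pooled signed
coordinates across quadrants; the package reports mirrored anatomical
displacements, reproduces the Δ structure, and does not attempt to
reproduce those per-stage SD columns.

## Superimposition

Registration is trimmed point-to-plane ICP (`icp_register()`): a seeded
uniform subsample of source vertices (default 5,000) is matched to
nearest target vertices, residuals are taken along target vertex
normals, the worst 20% of correspondences are trimmed, and the
linearized 6-dof update is accepted only if the trimmed RMS decreases —
so the RMS trace is non-increasing by construction. Convergence is a
relative RMS change below 10⁻⁶ or 100 iterations; registrations whose
initial RMS exceeds 20 mm are rejected as non-overlapping. Only the
bone drives the registration; tooth meshes and landmarks are passengers
moved by the same global motion, which avoids bias from teeth that
genuinely moved. These parameters are the package's own defaults
(commercial "best-fit" tools do not publish theirs) and are all
surfaced in `icp_config()`. The closed-form Kabsch landmark fit
(`fit_rigid_landmarks()`) serves as an independent cross-check: on
landmark-decorated meshes the two solutions agree to well under 0.1 mm.

## Statistics

* **Paired t** (`paired_t()`, `paired_t_from_summary()`): classic paired
  t on designed − achieved with two-sided p on n − 1 df; zero-variance
  differences are flagged degenerate rather than silently dropped.
* **Normality** (`shapiro_screen()`): Shapiro–Wilk as a screen only; the
  test family is never switched silently.
* **Reliability** (`icc_agreement()`): two-way random-effects,
  absolute-agreement, single-measurement ICC(A,1) from the two-way ANOVA
  mean squares, with the F-based confidence interval. The source
  material is ambiguous between intra- and inter-rater phrasing; the
  package implements the repeated-measurement (sessions-as-raters) model
  and labels it explicitly in every output.
* **Influencing factors** (`fit_lmm()`): REML linear mixed model with
  fixed effects age, gender, overbite, overjet, TADs, crowding, G6,
  attachment type and power ridge, and a random intercept per patient —
  teeth are nested in patients and the intercept absorbs that
  clustering; the random-effects structure is the package's choice since
  none is stated in the source. Reference levels: female, TADs present,
  G6 present, V3 attachment, power ridge absent. Wald (normal) p-values
  are reported and labelled as such. Bilateral rows are pooled by
  default with the patient random effect handling the within-patient
  correlation; per-patient averaging is available
  (`pool_bilateral = FALSE` in the pipeline). Singular fits are
  reported with a flag, never hidden; rank-deficient designs error,
  naming the aliased columns. No multiple-testing correction is applied
  by default (α = 0.05 throughout); a Benjamini–Hochberg option exists.

The minimum sample size reported for such cohorts cannot be reproduced
without the underlying effect-size convention, so the package notes the
figure and does not implement a power computation.

## The synthetic generator

No real scan data accompany this package, so every stage is exercised on
a synthetic maxilla (`synth_case()`): a parabolic arch (intermolar
mesiobuccal-cusp width 50 mm, arch depth 30 mm), a swept bone band with
scalloped top edge (the scallops give ICP tangential texture), and
twelve capped-frustum teeth whose crown and apex landmarks are analytic.
U4 sites are left as extraction gaps. Realism is deliberately minimal:
the meshes carry the required landmarks and surface structure, nothing
more.

Movements are prescribed per tooth as target absolute angles and
anatomical displacements (`apply_prescription()`). A sequential
"rotate-about-one-axis-then-the-other" realization cannot make *both*
projected angles equal their prescriptions simultaneously, so the
generator instead constructs the long-axis direction whose mesiodistal
and buccolingual projections equal the prescribed angles exactly —
d ∝ tan(MD°)·mesial + tan(BL°)·buccal + vertical — and rotates the
pretreatment axis onto it about the reference point (prescribed angles
must therefore lie within ±89°). Because rotations are centered on the
reference point, angular prescriptions leave linear metrics untouched,
and the full pipeline recovers every prescribed value to machine
precision in the noiseless case; the acceptance suite asserts 0.01°/0.01
mm. The default prescription reproduces the reference cohort's
designed/achieved means, i.e. the anterior-distal/posterior-mesial
tipping pattern with under-expressed torque.

Cohort simulation (`simulate_cohort()`) draws patient covariates from
the reference baseline distributions (age 24.7 ± 6.1 years truncated to
18–35, 1/3 male, overbite 2.27 ± 1.57 mm, overjet 4.42 ± 2.24 mm,
crowding 3.21 ± 3.34 mm floored at zero) and generates deviations as

Δ = baseline(tooth, metric) + Σ β·covariate + patient intercept + residual,

with defaults σ_patient = 0.5 and σ_residual = 1.0 in each metric's
units and baselines equal to the reference difference means. TADs, G6
and power-ridge prevalences (0.6, 0.5, 0.3) and the attachment mix
(V3/O1/H3/none = 0.40/0.25/0.20/0.15) are the package's one-time
choices of clinically plausible values; none is stated in the source.
Fast mode emits the metric table directly; full mode realizes every
patient geometrically and re-measures through the pipeline — the two
agree to 10⁻⁹ by construction, which is itself a tested invariant. A
JSON truth manifest (`write_truth_manifest()`) records seeds, true
transforms and true coefficients so that every expected output is
recomputable.

What passing these tests shows — and does not show. The generator
produces rigid tooth movements, exact landmarks, and Gaussian
deviations. Real data add landmark digitization error, segmentation
artifacts, non-rigid gingival change near the bone, and non-Gaussian
deviation tails; recovery to machine precision on synthetic cases
validates the *measurement algebra and registration*, not robustness to
those real-data effects.

## Problem sizes and runtime choices

The shipped analyses use a 33-patient cohort (396 tooth rows) for the
descriptive and per-tooth mixed-model tables, 200 patients per replicate
for coverage of a simulated TADs effect (−1.79 mm on U1 mesiodistal
deviation; 200 replicates), and 400 replicates for the null
rejection-rate check, sizes at which the Monte-Carlo error of a coverage
estimate is about 1.5 percentage points. The bone band uses 80 stations
(324 vertices) — small enough that brute-force nearest-neighbour ICP is
instantaneous, large enough that the trimmed solver is exercised
non-trivially.

## Known limitations

* Crown rotation (rotation about the long axis) is not measured; the
  whole-tooth analysis is angulation/inclination/translation only.
* Only maxillary arches with the U1–U3/U5–U7 bilateral dentition are
  modelled; no lower-arch frames.
* ICP is rigid; scaled or non-rigid registration is out of scope, as is
  any automatic segmentation or landmarking of real scans.
* The mixed model assumes a single random intercept per patient; more
  elaborate covariance structures (per-side, per-tooth random effects)
  are not fitted.
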