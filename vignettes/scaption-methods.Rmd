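---
title: "Dynamic subacromial impingement from bone morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic subacromial impingement from bone morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaption)
```

## The problem

Subacromial impingement — compression of the rotator cuff between the humerus
and the acromial roof of the scapula — is associated with two static
radiographic markers: the **critical shoulder angle** (CSA), capturing how far
the acromion reaches laterally over the joint, and the **greater tuberosity
angle** (GTA), capturing how far the tuberosity protrudes superolaterally from
the humeral head. Both are measured on a single corrected coronal image and
say nothing about what happens while the arm moves. This package implements a
dynamic complement: the humerus of a patient-specific 3D bone model rotates
through scaption (elevation in the scapular plane) against a fixed scapula,
the minimum **acromio-humeral distance** (AHD) is measured at every degree,
and the **impingement-free range of motion** (IF-ROM) is read off as the first
elevation angle at which the AHD drops below 6 mm — a conventional allowance
for the soft tissues that occupy the subacromial space. The scientific claim
the pipeline is built to interrogate is a *joint* morphology effect: CSA and
GTA individually correlate only weakly with IF-ROM, while their sum correlates
strongly and negatively.

## Mesh distances

The AHD is a mesh-to-mesh minimum distance. Two routes are provided with an
identical contract:

* `min_distance_brute()` — the exhaustive scan over all triangle pairs, with
  the closed-form triangle–triangle distance (minimum of 6 vertex–triangle
  and 9 edge–edge subproblems, plus an edge-piercing test so interpenetrating
  surfaces report exactly 0);
* `min_distance_fast()` — a dual bounding-volume-hierarchy traversal with
  branch-and-bound pruning on axis-aligned box distances, using the *same*
  closed-form primitive at the leaves. It is an accelerator, not an
  approximation: the test suite asserts equality with the brute-force route
  to 10⁻⁹ mm on randomized meshes.

Distances are unsigned: touching or interpenetrating surfaces give 0, which
under the 6 mm rule simply means "impinged". No penetration depth is
computed — that would require watertight meshes, which the threshold test does
not need. This clamp is recorded in each simulation result
(`interpenetration_policy`).

Units are millimetres throughout and are never rescaled on load; files written
in metres can be declared as such (`read_mesh(..., unit = "m")`).

## Anatomical frames and the measurement plane

The glenohumeral joint centre and radius come from a sphere fit of the humeral
head: a linear algebraic fit followed by Levenberg–Marquardt refinement of the
orthogonal residuals. Head points are selected by a deliberately
parameter-light rule — the proximal third of the bone's principal-axis extent
(the end with the larger radial spread), then one residual-trimming pass at
twice the median residual to shed tuberosity and shaft contamination. The rule
is this package's own choice; the upstream convention it stands in for is
simply "fit a sphere to the humeral head".

Bone coordinate systems follow the International Society of Biomechanics
conventions. For the scapula: origin at the acromial angle (AA), z along the
scapular spine (TS → AA), x normal to the scapular plane (AA, TS, AI), y
completing the right-handed frame. The sign of the plane normal is fixed
deterministically by requiring the inferior-to-superior glenoid direction
(IG → SG) to have a positive y component in the resulting frame. Shoulder CT
rarely includes the elbow, so the humeral frame has a documented fallback
(y along the reversed diaphyseal axis, x from the scapular anterior axis)
next to the epicondyle-based construction; the choice is recorded in the
frame's `option` field and cannot affect AHD, which depends only on the
joint centre and the scapular plane.

All angle measurements are made in the **corrected coronal plane**: the
scapular plane through the inferior glenoid rim, with points projected
orthogonally onto it before any angle is taken. CSA is the angle at IG
between the glenoid line and the ray to the most lateral projected acromion
vertex (ties broken by the most inferior candidate); GTA is the angle at the
joint centre between the proximal shaft direction and the ray to the
projected humeral vertex of greatest planar radius among candidates within
1.4 fitted head radii whose polar angle lies in (10°, 90°). These
vertex-selection rules are deterministic, resolution-stable surrogates for a
radiologist's point picks; the radial cutoff excludes the articular surface
and the polar window excludes the shaft.

## The scaption simulator

Scaption is modelled as a pure rotation of the humerus about the scapular
plane normal through the joint centre, 1° per step from 0° to 120°, scapula
fixed, no translation and no scapulohumeral rhythm. The axis sign is chosen so
that positive rotation carries the lateral direction toward the superior
direction (the arm goes up). The humerus starts at its as-given pose; a
`pre_rotation_deg` option is exposed for data whose acquisition pose is not
the arm-at-side reference. At each step the AHD is the minimum distance
between the `"acromion"`-labelled scapular subregion and the humerus.
Restricting to the acromion is deliberate: the glenoid articular gap is a few
millimetres at all times and would flag every shoulder at every angle; the
colour-map distance field, by contrast, *is* computed over the entire scapula
surface (red = minimum) and can be exported to PLY per angle.

IF-ROM is the smallest grid angle with AHD < threshold, or the sweep maximum
(120°) when the curve never crosses. An AHD curve may re-open after the first
crossing; only the first crossing is given semantics.

## The synthetic shoulder family

Patient CT reconstructions are not distributable, so the package carries a
parametric stand-in built from solid primitives that admit closed-form
distances: a head sphere (radius 25 mm), a tuberosity sphere (radius 8 mm)
whose apex sits at exactly the target GTA polar angle, a shaft cylinder
(radius 12 mm), an acromion box whose undersurface is 34 mm above the joint
centre and whose lateral extent is solved in closed form from the target CSA,
a glenoid disc across a 4 mm articular gap, and a coarse medial strut. Mesh
vertices lie exactly on the primitives, so the mesh AHD can only exceed the
solid AHD, and only by the chord sagitta (≈ 0.005 mm at the default 1.0 mm
edge length). `closed_form_ahd()` / `closed_form_ifrom()` evaluate the solid
distances directly — including the shaft term, which matters at high
elevation for very lateral acromions — and serve as the independent oracle
for the mesh simulator.

The one genuinely free modelling choice is how GTA couples to geometry. The
apex *angle* alone cannot reproduce the observed physics: with a fixed
prominence, a larger GTA only means the apex starts further from the acromion
and the impingement angle would *grow* with GTA. What makes a high-GTA
shoulder impinge early is that its tuberosity protrudes further. The default
prominence is therefore coupled to the angle,

\[ h(\mathrm{GTA}) = \mathrm{clamp}\big(4.8 + 0.22\,(\mathrm{GTA}-70) +
   0.033\,\max(\mathrm{GTA}-70,0)^2,\; 0.5,\; 9.0\big) \text{ mm}, \]

chosen once, by closed-form exploration of the family before any mesh test
existed, so that (i) IF-ROM is non-increasing in each angle across the tested
grid, (ii) both angles contribute comparably in a sampled two-group cohort,
and (iii) the combined angle is the dominant rank correlate — the qualitative
pattern the real cohort shows. The mild convexity counteracts a flattening of
the crossing angle in the lateral-corner contact regime at low CSA; a single
residual +1° step remains there (within the 1° monotonicity tolerance), an
honest artefact of the box-plus-sphere geometry. `bump_height` stays an
explicit, overridable field; `bump_height = 0` gives a purely spherical head
whose AHD is constant over the sweep (the rotation-invariance control, with
analytic clearance 34 − 25 = 9 mm).

The cohort sampler reproduces the study conditions of the source population:
44 rotator-cuff-tear shoulders (CSA 41.3 ± 5.4°, GTA 73.9 ± 4.4°) and 17
controls (CSA 36.8 ± 4.1°, GTA 68.3 ± 3.5°), CSA and GTA drawn independently,
clipped to the generator validity window (CSA 25–57°, GTA 59–85°; clipping is
rare and logged). One printed group-mean table lists the tear-group GTA as
79.3°, which is inconsistent with its own printed range, with the combined
CSA+GTA mean and with the abstract; the sampler uses 73.9°.

What the family emulates: independent, normally distributed angle morphology
with the published group separations; an impingement mechanism driven jointly
by lateral acromial reach and tuberosity prominence. What it does not:
cortical detail, cartilage and soft tissue, scapular dyskinesis, humeral-head
translation, anatomic covariance between prominence height and angle (the
coupling is an assumption, flagged here and in the generated manifests).
Passing tests on this family therefore validate the *pipeline* — geometry,
frames, measurement, sweep, statistics — not any clinical magnitude; absolute
IF-ROM values are not comparable to patient values.

## Statistics

The statistical layer mirrors the published analysis: pooled-variance Student
t tests for group comparisons (the source table's "paired" footnote is
presumed a typo — the groups are unpaired and of unequal size; a Welch option
is exposed), Shapiro–Wilk normality checks, Pearson correlation between the
two angles, Spearman rank correlations (average ranks on ties; exact p for
n ≤ 10 without ties, t approximation otherwise) against IF-ROM, and a 2×2
chi-square of proportions with the Yates correction exposed as a flag —
the two published proportion p-values are each reproducible only under a
different variant, so both variants are first-class and the one used is
recorded in the output. Reproducibility of repeated measurements uses
ICC(2,1) — two-way random effects, absolute agreement, single measure —
computed from the ANOVA mean squares; the variant is named in all reports
because consistency-type ICCs ignore exactly the systematic offsets that
absolute agreement penalises.

## Numerical choices

* Degenerate faces are rejected at area ≤ 10⁻⁹ mm²; sphere fits require ≥ 4
  non-coplanar points (smallest singular value test).
* Orthonormality and right-handedness of frames are enforced to 10⁻⁹.
* CSA lateral-point ties (10⁻⁹ mm) break to the most inferior candidate; GTA
  radial near-ties within 0.05 mm spanning more than 10° of polar angle are
  reported as degenerate (spherical head) with a warning, returning the
  smallest-angle candidate.
* The closed-form shaft–box distance is minimised by `optimize()` on the
  segment parameter — the point-to-box distance is convex along a segment, so
  the 1-D minimisation is exact to tolerance (10⁻⁹).
* Continuous IF-ROM crossings are refined by `uniroot()` to 0.01°.
* Rotation matrices from axis–angle are re-orthonormalised through an SVD to
  keep long compositions within the 10⁻⁹ orthonormality gate.

## Problem sizes

Default study resolution is a 1.0 mm target edge length (≈ 40k humeral
faces); the acceptance-level checks run the full 5 × 5 angle grid and a
61-subject cohort at that resolution. Unit tests exercise the same code paths
at 2–3 mm, where a sweep takes about a second. These sizes are the package's
own choices for routine verification; the generator accepts any edge length
down to sub-millimetre if finer convergence studies are wanted.

## Limitations

IF-ROM here is a purely bony, purely rotational quantity: no cuff tissue, no
capsule, no humeral translation, no scapular motion. The synthetic family is
a test harness with analytic oracles, not a statistical shape model; its
correlation magnitudes depend on the assumed GTA–prominence coupling even
though their signs and ordering are structural. Measurements are
vertex-selection rules on meshes and will differ from a radiologist's manual
picks at the sub-degree level; the repeatability ICC utility quantifies
agreement between repeated measurement columns but no observer simulation is
included.
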