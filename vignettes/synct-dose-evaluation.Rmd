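---
title: "Evaluating MR-derived synthetic CT for lung dose calculation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating MR-derived synthetic CT for lung dose calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MR-only radiotherapy planning replaces the planning CT with a *synthetic CT*
(synCT) derived from MR images, removing the MR-to-CT registration
uncertainty and the extra CT dose. In the lung this is demanding: dose
calculation is heterogeneity-corrected, so errors in the electron densities
assigned to lung, soft tissue and bone propagate directly into the dose.
`synctdose` implements the complete evaluation loop for a Dixon-MR-based
synCT workflow — tissue classification, atlas bone insertion, HU
conversion, planning, dose recomputation on the reference CT, and agreement
quantification with DVH metrics and 3D gamma analysis — exercised on
digital thorax phantoms, because real paired PET/MR + CT patient data are
not publicly available.

Everything below is the package's own account of its models and choices;
the quantitative statements are exactly the ones its test-suite and
`scripts/acceptance.R` recompute.

## The synthetic-CT model

1. **Tissue classification.** Dixon water/fat pairs are classified into
   air, fat, lung and soft tissue by a rule-based classifier: outside the
   body mask is air; inside, a voxel with fat fraction `F/(W+F) >= 0.5` is
   fat (ties deliberately classify as fat, for determinism); large
   low-signal components enclosed by the body are lung; the rest is soft
   tissue. The fat-fraction rule is invariant to common rescaling of both
   channels; the body and lung thresholds are absolute signal thresholds
   and are exposed in `classification_config()`. The published method this
   emulates uses a proprietary classifier; the rule-based stand-in
   reproduces its four-class output contract, which is all the downstream
   pipeline consumes.
2. **Attenuation coefficients.** The four classes receive 511 keV linear
   attenuation coefficients 0.0, 0.0854, 0.0224 and 0.1 cm^-1 (air, fat,
   lung, soft tissue) — a pure lookup.
3. **Bone insertion.** Bone cannot be separated from air in conventional
   Dixon MR, so it comes from an atlas: a reference MR plus bone masks
   carrying per-voxel bone LACs in [0.1, 0.2485] cm^-1, registered to the
   patient by a landmark least-squares affine followed by a demons-style
   deformable refinement. Warped bone voxels overwrite fat and soft tissue
   only; air and lung are never overwritten, which also makes insertion
   idempotent. The desk-scale atlas contains the spine only — ribs,
   skull and femora are out of scope, as in the workflow being emulated.
4. **HU conversion.** The class LACs map exactly to -1000, -110, -767 and
   70 HU; bone LACs map linearly with anchors (0.1, 70) and
   (0.2485, 2661). The printed class (LAC, HU) pairs do not lie on a single
   two-segment line, so the package uses a per-class lookup plus the linear
   bone branch — this honours every printed value exactly, is monotone over
   its defined inputs, and rejects any other LAC loudly.

## The dose engine

The clinical reference engine (a convolution/superposition algorithm) is
proprietary; `synctdose` declares its own simplified engine and treats it
identically for synCT and planCT, which is what the comparison requires:

* relative electron density from HU via a piecewise-linear calibration
  curve (water (0 HU, 1.00), air (-1000 HU, ~0); the shipped control points
  are the package default, not a published clinic curve);
* primary attenuation `exp(-mu_eff * WED)` along the water-equivalent depth
  (WED), with `mu_eff = 0.005/mm` (roughly 6 MV-like);
* inverse-square divergence from a point source at 1000 mm SAD (a parallel
  mode exists for closed-form verification);
* an error-function aperture penumbra whose Gaussian width
  `sigma_lat / max(density, 0.5)` broadens in lung — a first-order model of
  lateral electron transport (`sigma_lat = 3` mm in water). The clamp keeps
  near-vacuum voxels finite.

The exported `radiological_depth()` is exact Siddon voxel-intersection ray
tracing. The per-voxel depth field inside `beam_dose()` instead uses an
incremental plane sweep: one grid plane per step along the beam's major
axis, trapezoidal density and a trilinear look-back into the already-computed
depth planes. This is O(n voxels) per beam instead of O(n voxels x path
length) and is cross-checked against per-voxel Siddon in the tests (median
relative deviation within 2% on smooth density fields, exact in homogeneous
media). IMRT fluence modulation is approximated by per-beam scalar weights:
a non-negative least-squares optimiser (projected quasi-Newton on a smooth
objective: squared PTV deviation plus one-sided squared OAR overshoots)
sets the weights, and `normalize_plan()` rescales globally so the
prescription covers exactly 95% of the PTV. "Same monitor units" on the
reference CT means bit-identical beam geometry and weights; only the
density grid changes.

## Agreement metrics

* **DVH.** `Vx` counts voxels with dose *strictly greater* than x Gy (the
  printed definition read literally; on the 1..100 Gy ladder V20 is 80%,
  not 81%). `Dx` is the largest dose still covering at least x% of the
  structure, computed exactly by sorting (D95 of 1..100 Gy is 6 Gy);
  curve-based queries interpolate linearly between 0.01 Gy bins and return
  the larger dose on plateaus. Lung metrics exclude the PTV by mask
  subtraction before counting. PTV Dx values are reported relative to the
  prescription (the alternative, relative to maximum dose, is not used;
  this is a documented choice).
* **Gamma.** Global 3D gamma with the reference dose = planCT dose and
  evaluated dose = synCT dose (the synthetic plan is the one on trial; the
  asymmetry is intentional and fixed). Normalisation defaults to the global
  maximum of the reference dose — the common convention for "global" gamma —
  with a prescription mode available. The low-dose threshold (default 10%)
  is applied on the reference, and sub-threshold voxels are excluded from
  both the gamma map statistics and the pass-rate denominator. The search
  scans a displacement lattice (step `dta/3` by default, capped at 4 x dta)
  ordered by distance, stopping exactly when the distance term alone
  exceeds the running minimum. `brute_force_gamma()` is an independently
  implemented dense scan at `dta/10` used as the oracle; the equivalence
  suite runs both on the same `dta/10` lattice so that it tests the search
  logic rather than lattice coarseness. A note on the shifted-ramp
  benchmark: for a 1%/mm ramp shifted 1 mm at 2%/2mm the exhaustive-search
  gamma is `1/sqrt(8) ~ 0.354` (minimising `sqrt(d^2/4 + (d-1)^2/4)`), not
  the 0.5 obtained when displacement compensation is ignored; the tests
  assert the exhaustive value.
* **Statistics.** Differences are always synCT minus planCT. Across plans a
  one-sample paired t-test is used; between PTV groups (size, location) the
  rank-sum (Mann-Whitney) test, exact for group sizes <= 12 without ties —
  chosen over the signed-rank test because the groups are independent sets
  of plans. Confidence intervals use t quantiles (the alternative normal
  quantiles differ negligibly at n = 43 but the choice is documented). No
  multiple-testing correction is applied, and the report footer says so.

## The phantom: what it emulates, and what it does not

`build_phantom()` rasterises a desk-scale thorax: body ellipsoid
(105 x 82 x 115 mm semi-axes) with a 7 mm subcutaneous fat shell, two lung
ellipsoids (44 x 58 x 90 mm), a spherical heart, and a vertebral column
(14 mm bone cylinder) carrying the 5 mm spinal cord. Ground-truth HU means
are the synCT class values themselves (air -1000, fat -110, lung -767,
soft 70) plus spine bone at 336 HU — so a perfect pipeline reproduces the
truth exactly, which turns end-to-end agreement into a testable identity.
Per-tissue Gaussian noise emulates CT texture; no published noise model
exists for this data, so the defaults (30 HU in lung, 20 HU in soft
tissue/fat, 40 HU in bone) are the package's calibration of "realistic
diagnostic CT" and are stated once here. Dixon signals follow a declared
per-class (water, fat) table — fat voxels fat-dominant, soft tissue
water-dominant, lung faint, air zero, bone marrow-like (so the 4-class
classifier maps bone to soft tissue, exactly where the atlas later
re-inserts it). MR intensity values are arbitrary units; round-trip
recoverability, not MR physics, is the design requirement.

PTVs are spheres in three size classes (11.9 +/- 5.5, 83.5 +/- 14.5,
222.3 +/- 39.8 cm^3; draws truncated at 1.5 SD so every draw is placeable
and within 2 SD) and four location classes (apex, near mediastinum, near
ribs, near spine), rasterised as the exact number of nearest lung voxels so
the volume is correct to within one voxel. The breath-hold-MR versus
free-breathing-CT mismatch is a smooth random displacement field with a
controlled maximum norm (2 mm in the standard fixture) applied to the
reference CT; the true field is kept for registration-recovery tests.

Not emulated: MR bias fields and chemical shift, respiratory 4D motion,
ribs, anatomical variability beyond a mild per-patient habitus scaling,
bowel gas, and CT artefacts. Passing tests therefore demonstrate the
internal consistency and sensitivity of the evaluation pipeline under
known, controlled errors — not clinical performance on real patients.

## Numerical choices and degenerate inputs

* Voxel-centre convention everywhere: `world = origin + (index + 0.5) *
  spacing` (0-based); resampling is trilinear for continuous volumes and
  nearest-neighbour for labels/masks, which provably never invents label
  values.
* Registration: rigid (6-DOF Nelder-Mead on mean squared difference, run
  at 3x downsampling) then diffeomorphic-style demons with Gaussian field
  regularisation (sigma 2 voxels), coarse-to-fine (30 + 10 iterations).
  Iterations are accepted only while the metric improves; if no level ever
  improves the registration errors with its iteration log. Near-zero rigid
  solutions snap to the exact identity so aligned inputs round-trip without
  resampling — this is what makes the zero-noise pipeline an exact
  identity. Metric traces are attached to the returned transform.
* The brute-force gamma oracle prunes its shell scan only by the exact
  distance-dominance bound (a shell whose radius alone exceeds the current
  minimum cannot improve it), so its result equals the complete dense scan.
* Degenerate inputs error early and loudly: empty body mask, empty
  structure masks, zero D95 at normalisation, all-below-threshold gamma,
  non-monotone calibration curves, LACs outside their defined set,
  fewer than 3 non-collinear landmarks.

## Problem sizes and the standard study fixture

The standard fixture (`run_config()`) evaluates 43 PTVs — 18 small, 13
medium, 12 large, crossed with 9 apex / 16 mediastinum / 9 ribs / 9 spine —
across 11 phantom patients, with 7 equispaced beams per plan and the IMRT
prescription 59.40 Gy in 33 x 1.8 Gy fractions (SBRT 60 Gy in 3 x 20 Gy is
available). The planning grid is 96^3 at 2.5 mm isotropic: a 240 mm cube
that holds the whole desk-scale thorax. The clinical 1.25 x 1.25 x 2.5 mm^3
grid and the coarser 2.60 x 2.60 x 3.12 mm MR grid are both supported by the
resampling layer and exercised in unit tests; the fixture keeps MR and CT
on a common grid so that the noise-free configuration is an exact identity
rather than an interpolation-limited approximation. The fixture's atlas
uses the uniform bone-LAC model matched to the phantom spine (336 HU) for
the same reason; the cortical-rim-to-marrow gradient model is the default
for standalone atlas construction. The atlas registration in the fixture
stops after the landmark stage, because the fixture's spine geometry is
shared between atlas and patients and the affine already places it exactly;
the deformable refinement is exercised separately in the registration tests.

```{r, eval = FALSE}
library(synctdose)
ev <- run_pipeline(run_config(), out_dir = "report")
print(ev)
summary(ev)
```

## Known limitations

* The dose engine is a primary-attenuation + penumbra model: no scatter
  kernels, no collimator/MLC, no absolute dosimetry. It is shared by both
  arms of every comparison, so conclusions are about synCT-vs-CT density
  differences, which is the question under study.
* The phantom's anatomy is geometric and its per-patient variability mild;
  atlas registration is correspondingly easy compared with real anatomy.
* Fluence modulation is reduced to scalar beam weights; "IMRT" here means
  a multi-beam weighted plan, not a modulated fluence map.
* The gamma pass rate excludes sub-threshold voxels from its denominator
  (the usual but not universal convention); including them would only
  raise pass rates.
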