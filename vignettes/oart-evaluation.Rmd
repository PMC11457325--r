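---
title: "Evaluating automated online adaptive radiotherapy workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating automated online adaptive radiotherapy workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtadapt)
```

## The problem

In CBCT-guided online adaptive radiotherapy (oART) for bladder cancer, a
new plan is optimized at every fraction on the anatomy of the day. The
vendor workflow segments the bladder and rectum automatically (the
"influencers"), uses them to guide the deformable propagation of the
target structures, and re-optimizes the plan. In clinical practice the
proposed contours are usually corrected manually before optimization; a
*fully* automated workflow would skip those corrections and save several
minutes of on-couch time, at the risk of treating on inaccurate contours.

`rtadapt` implements the evaluation that quantifies this trade-off. Two
arms are compared per treatment session:

* **clin** — the clinically corrected structure set `Contour_clin` and the
  dose `D_clin` optimized on it (the ground truth);
* **auto** — the automatically proposed structure set `Contour_auto` and
  the dose `D_auto` optimized on it.

The evaluation has four stages.

1. **Geometric contour agreement** between `Contour_auto` and
   `Contour_clin` for the bladder, rectum and boost CTV: Dice similarity
   coefficient `DSC = 2|A∩B| / (|A|+|B|)`, relative volume
   `100·V_auto/V_clin`, the 95th-percentile Hausdorff distance (95%HD) and
   the mean distance to agreement (MDA) over pooled symmetric surface
   distances.
2. **Dosimetric evaluation** of the *clinical* contours (always the ground
   truth) under both doses: `V95%`, the structure volume receiving at
   least 95% of its prescribed dose (boost level for GTV/CTV_boost/
   PTV_boost, elective level for CTV_elective/PTV_elective), checked
   against the clinical requirement `V95% ≥ 98%` (inclusive), and the
   spill `V95,out = V95,body − V95,target` in cm³.
3. **Cohort statistics**: median [min–max] summaries and paired Wilcoxon
   signed-rank tests between dose arms, at a Bonferroni-corrected level
   (0.05 / 10 = 0.5% by default).
4. **Stratification**: sessions are binned by the influencer volume change
   between the reference CT and the online anatomy (bladder bins of
   50 cm³, rectum bins of 25 cm³, last bin open) and the per-bin share of
   sessions failing the CTV coverage requirement under `D_auto` is
   tabulated.

Because clinical DICOM exports of such a study are not publicly
deposited, the package ships a synthetic phantom cohort generator with the
same statistical structure (17 patients × 20 fractions by default), so
that every stage of the pipeline can be exercised and validated
end-to-end.

## Data model and conventions

All spatial data live on regular axis-aligned voxel grids
(`volume_grid`): binary masks for structures, Gy for dose. Voxel centers
follow the voxel-center convention, world position = origin +
index·spacing, with anisotropic spacing supported everywhere. All masks
of one session share one frame; dose grids may differ and are resampled
to the structure frame by trilinear interpolation (queries outside the
dose grid get 0 Gy and are counted, never extrapolated).

Structure sets enforce the radiotherapy containment invariants at load
time: `GTV ⊆ CTV_boost ⊆ PTV_boost`, and the body contains every target.
Empty required structures are validation errors rather than silent NaNs,
since every reported metric is undefined on an empty structure.

Sessions are read and written as self-contained bundles: one NIfTI file
per structure/arm and per dose arm plus a JSON manifest (grid frames,
correction flags, reference influencer volumes). Planar contour input
(the polygon-per-slice form that RTSTRUCT files carry) is rasterized by
an even-odd voxel-center rule with a deterministic half-open edge
convention; holes are supported by XOR combination.

## Surface distances

Surfaces are the centers of face-connected boundary voxels. The 95%HD
and MDA are computed from the *pooled symmetric* distance multiset (both
directed nearest-neighbour sets concatenated), with the 95th percentile
interpolated linearly between order statistics. The directed convention
and the mesh-vs-voxel surface question are genuinely open in the field;
pooled-symmetric voxel surfaces were chosen because one multiset serves
both metrics and the result is exactly checkable against a brute-force
all-pairs oracle, which the test suite does on random anisotropic masks.

Nearest distances are found with an exact anisotropic Euclidean distance
transform (separable lower-envelope algorithm, compiled code), which on a
common lattice is identical to the all-pairs search at a fraction of the
cost.

## The synthetic cohort

`phantom_config()` describes a parametric pelvic phantom on a 2 mm
isotropic grid (68×68×60 voxels). Per patient, a reference anatomy is
sampled: an ellipsoidal bladder (reference volume uniform in
100–180 cm³), a curved rectal tube (30–60 cm³), and a spherical tumor
bed (GTV, 12 mm radius) seated on the posterior-inferior bladder wall.
The margin chain mirrors clinical practice: CTV_boost = GTV ⊕ 5 mm,
PTV_boost = CTV_boost ⊕ 5 mm, CTV_elective = bladder ∪ CTV_boost
(lymph-node volumes are deliberately simplified away — the analysis is
agnostic to how a mask arose), PTV_elective = (bladder ⊕ 7 mm) ∪
PTV_boost, everything cropped to the body as planning systems crop PTVs
to the patient surface.

Per fraction, the online (clin) anatomy varies: the bladder starts at
0.7–1.5× its reference volume and fills at 1–4 ml/min over a 15–25 min
on-couch time (the clinically reported filling range); the rectum varies
between 0.5–2× its reference volume; the GTV rides on the moving bladder
wall. The auto arm is derived by a level-set perturbation: the signed
distance of each mask (referenced to the surface midway between the
inner and outer voxel layers, so sub-voxel offsets act) is offset by a
smooth, unit-bounded, seeded noise field times the session amplitude and
re-thresholded. The influencers are perturbed directly; the GTV is
perturbed with a larger amplitude (factor 1.5) plus a systematic 1 mm
inward bias — automatic boost delineations tend to be too small — and
its margins are re-applied, which mimics influencer-guided propagation
error. The session amplitude grows with the bladder volume change
(`amp · (1 + ΔV/100 cm³)`, capped at 10 mm), emulating the degradation
of deformable propagation under large anatomical change; the cap is
chosen so that the GTV can never be eroded away entirely
(10 mm + 1 mm bias = GTV radius − half voxel).

The dose model is geometric, not physics-based: each prescription level
contributes `Rx · 2^(−s/d_half)` with `s` the Euclidean distance outside
that level's PTV and `d_half = 5 mm`; the voxel dose is the maximum over
the two levels (40 Gy elective / 55 Gy boost in 20 fractions, per
fraction by default). This guarantees exact prescription inside each PTV
and a realistic lateral falloff — enough structure for DVH evaluation,
while making no claim about beam transport. `D_clin` is shaped around the
clin PTVs and `D_auto` around the auto PTVs, so contouring errors
propagate into coverage of the ground-truth contours exactly as in the
real workflow.

Manual-correction flags are sampled at the clinically observed
frequencies (bladder 91%, rectum 13%, GTV 68%). Seeding is hierarchical:
the master seed spawns per-patient and per-session child seeds, so any
single session is reproducible in isolation and a full cohort is
bit-reproducible.

What the phantom does *not* emulate: CBCT image content, the actual
segmentation network, deformable registration, optimizer behaviour,
lymph-node anatomy, and inter-patient shape variability beyond volume
parameters. Passing tests on the phantom therefore validate the
*pipeline* (metrics, statistics, bookkeeping, directional mechanisms),
not the clinical performance of any segmentation software.

## Numerical choices

* Dose comparisons are inclusive (`≥` threshold), matching the "minimum
  of" phrasing of both the V95 definition and the 98% requirement.
* The DVH and V95 are voxel-count based; no sub-voxel partial-volume
  weighting (the bundle format retains no contour geometry).
* The spill's body threshold defaults to the *elective* prescription
  level — the lower of the two levels, so spill is never negative for
  elective targets; per-target thresholds are available via
  `body_threshold = "target"`. Which convention the clinical analysis
  used is not determinable from the study text.
* Percentiles use linear interpolation of order statistics (type 7), the
  most common numeric default, pinned for reproducibility.
* Volume differences for stratification are absolute by default
  (configurable to signed).
* Zero paired differences are discarded before ranking (the classical
  signed-rank convention); the exact null distribution is computed by
  generating-function convolution on doubled ranks, which handles ties
  exactly and equals full sign enumeration; above 20 effective pairs a
  tie-corrected normal approximation with continuity correction is used.
* Margin expansion uses the voxel-center metric (a voxel is added iff its
  center is within the margin of a set voxel center). On coarse grids
  this under-reaches the continuum operator by up to half a voxel
  diagonal at the surface; analytic-convergence checks are therefore run
  at 0.5 mm spacing, where the bias is within 2%.
* The phantom grid is 2 mm isotropic, which keeps the voxelization error
  of organ volumes ≥ 100 cm³ under 2% and a full 340-session cohort
  evaluation at desk scale (a few minutes on one CPU).

## A small worked example

```{r example, eval = FALSE}
cfg <- phantom_config(seed = 1, patients = 2, fractions = 3)
res <- run_evaluation(cfg)
res
res$summary$geometric$CTV_boost$dsc$formatted
res$tests
write_report(res, "report")
```

The acceptance script `scripts/acceptance.R` (repository root) runs the
full default cohort and writes the main summary quantities as JSON; see
the README for how to reproduce.

## Known limitations

The rasterizer expects axial planar polygons matched to grid slices; no
DICOM parsing is bundled (sessions enter via the NIfTI + JSON bundle
format). Surface metrics use voxel-center surfaces, which differ from
mesh-based implementations by up to about half a voxel. The paired
Wilcoxon treats sessions as independent units, as the underlying study
design does; within-patient correlation is not modelled.
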