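---
title: "Segmenting the axial skeleton and detecting bone PET lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the axial skeleton and detecting bone PET lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axskel)
```

This vignette documents the models, conventions and design choices behind
`axskel`, at the level of detail a maintainer or a methodologically
curious user needs. The package's claims are covered by the test suite and
by `scripts/acceptance.R`; nothing stated here goes beyond what those
compute.

## Scope and data model

The pipeline starts *after* whole-body CT labelling: its input is a CT
volume plus a multi-label skeletal map in the TotalSegmentator dialect
(per-vertebra C1–L5, per-rib, sacrum, ilia, spinal cord, femora, liver,
aorta), pinned to the integer taxonomy in `default_taxonomy()` and shipped
as `inst/extdata/taxonomy.json`. The label dialect is the contract: any
segmentation source that emits these structures can feed the pipeline.

All volumes live on a common working grid of 4 × 4 × 4 mm, matched to the
PET resolution; `resample_to_grid()` brings finer inputs down on load
(trilinear for intensities, nearest-neighbour for labels, so label sets
can never grow). Axes are ordered left–right, posterior–anterior,
inferior–superior, which turns "anterior of" and "superior of" into plain
index comparisons. Voxel indices are 1-based — the native R convention,
used consistently in every exported function and output table — and the mm
coordinate of voxel `(i,j,k)` is `origin + (c(i,j,k) - 1) * spacing`.

## Morphological route

**Vertebra decomposition.** The spinal cord is the landmark. Per axial
slice, the reference anteroposterior position is the cord's most anterior
voxel for C1–T3 (their transverse processes reach relatively far
anterior, so the cord centre would swallow process voxels into the body)
and the cord-slice centre for T4–L5. Voxels strictly anterior of the
reference become vertebral body (VB); ties — voxels exactly at the
reference column — go to the posterior part, a deliberate convention that
keeps "strictly anterior" unambiguous on an integer grid. The posterior
remainder is split left/right by the sagittal plane through the
*whole-cord* centre of mass rather than per-slice cord centres: per-slice
centres wobble with cord segmentation noise, while the whole-cord plane is
stable and anatomically equivalent for the symmetric structures involved.
Slices that hold vertebra but no cord voxels (cord segmentations
occasionally terminate a slice early) borrow the nearest cord-bearing
slice's reference and raise a warning.

**Disks, SIJs, joint centres.** All three reuse one primitive: dilate two
disjoint structures until their dilations overlap, then take the overlap.
Disks use a single vertical-line dilation per partner with a one-sided
extent of 12 / 8 / 4 mm (lumbar / thoracic / cervical) — interpreted as
`round(extent / spacing)` voxels, i.e. ±3 / ±2 / ±1 at 4 mm, the reading
that keeps the cervical element non-degenerate — and subtract the original
bone so only true inter-body space remains. SIJs and all joint centres use
the 4 mm-radius sphere (the 6-neighbourhood plus centre at this spacing),
iterated at most 5 times; the cap bounds runtime on pathological inputs
and flags non-converging pairs in the QC report instead of spinning.
A joint centre is the centre of mass of the first non-empty overlap,
rounded half-away-from-zero to a voxel.

**Joint pairings.** Facet joints pair the left (resp. right) posterior
parts of *adjacent* levels — facet joints lie between vertebrae — for the
24 pairs C1-C2 … L5-sacrum, with the sacrum standing in as the inferior
partner of the lowest pair; this yields the canonical 48 FJs.
Costovertebral joints pair each rib with its same-level VB (the rib head
articulates with the body), costotransverse joints pair the rib with the
same-level ipsilateral posterior part (the tubercle articulates with the
transverse process), restricted to T1–T10 because the two lowest ribs
have no costotransverse articulation — giving 24 CVJs and 20 CTJs.

## Multi-atlas route

Atlas scans are chosen at the {10, 30, 50, 70, 90}th percentiles of the
spinal length (Euclidean distance between the C1 and sacrum centres of
mass), which buys anatomical diversity with only five registrations per
unit. The percentile convention is nearest-rank ceiling
(`rank = ceiling(p·n/100)`) on the stable ascending sort, with duplicate
ranks stepping to the next unused rank; for n = 45 this selects ranks
{5, 14, 23, 32, 41}. No single standard convention reproduces a published
rank of 39 for the 90th percentile at n = 45, so the package fixes the
ceiling convention and documents it rather than reverse-engineering one.

Each atlas is cut into 26 partial atlases — the joint bounding boxes
(2-voxel margin) of the 24 adjacent-vertebra pairs and of sacrum + each
ilium — holding the CT crop, a unit-local reference label crop (1 = upper
structure, 2 = lower structure, 3 = disk/SIJ), and the unit's joint
centres (the pair's facet joints plus the upper member's CVJ/CTJ) in mm.

**Registration contract.** `register_similarity()` estimates the
similarity transform (3 rotations, 3 translations, isotropic scale about
the fixed-image centre, in the pull/resampling convention) minimising the
mean squared intensity difference over a random subsample of fixed voxels
(2000 by default, one seeded draw per resolution level). The optimiser is
BFGS on numerically differenced gradients in a scaled parameter space
(rotations and log-scale weighted by the image half-extent so all seven
parameters move in mm-equivalent units), run over two resolution levels —
a twice-mean-filtered level for capture range, then full resolution — with
a fixed total budget of 100 iterations. The fixed crop is zero-padded by
10 voxels beforehand so the moving image cannot drift or scale outside the
field of view unpunished. The backend is deliberately pluggable behind
this contract; only the metric family, the iteration budget and
determinism-given-seed are contractual. On phantom units the reference
implementation recovers random similarity transforms (|rot| ≤ 10°, scale
0.9–1.1, |t| ≤ 12 mm) with sub-voxel median centre error (asserted in the
acceptance suite).

**Fusion.** Propagated label crops vote per voxel and per label: a label
wins with at least 3 of 5 votes, a strict majority that cannot produce
conflicting winners. Joint centres fuse by component-wise mean of the five
propagated mm coordinates, then snap to the voxel grid. Fused unit crops
re-integrate into the target frame craniocaudally, then the two SIJ units;
later units never overwrite earlier non-background voxels, making the
output independent of harmless box overlaps.

## DVU composition and the VOI inventory

Each VB is split into 8 quadrants: the centre of mass fixes a mid-sagittal
slice, the VB bounding box within that slice contributes its four corners
(antero/postero × superior/inferior), every VB voxel is assigned to the
nearest corner in 2-D (anteroposterior, craniocaudal) mm distance, and the
centre-of-mass sagittal plane doubles the four groups left/right. The
corner definition via the in-slice bounding box is the only parameter-free
reading of "corners of the VB" we found; distance ties take the first
corner in a fixed order, and plane ties go right, so the split is a true
partition. A DVU is then inferior quadrants (upper VB) ∪ disk ∪ superior
quadrants (lower VB). For the L5–sacrum unit the sacral contribution
applies the same quadrant rule to the sacrum mask; the C1–C2 unit may
legitimately carry an empty disk (QC-flagged, not an error — ankylosed
disks produce the same signature in real data). Posterior-joint centres
become closed-ball spherical VOIs of radius 10 mm (81 voxels at 4 mm; a
radius below the voxel size degenerates to the single centre voxel, and
boundary centres are clipped). A complete scan yields exactly
24 + 48 + 24 + 20 + 2 = 118 VOI records; every missing structure removes
only its own records and leaves a QC flag.

## Validation metrics

Dice is `2|A∩B|/(|A|+|B|)` (1 when both masks are empty). The average
Hausdorff distance is fixed to the symmetric mean-of-directed-means
variant — the mean nearest-neighbour distance from A to B averaged with
the reverse direction, in mm between voxel centres — because the
directed/percentile variants differ between toolkits and the symmetric
mean is the common default; it is zero iff the masks are equal and scales
linearly with spacing. Joint centres are compared by Euclidean mm distance
between voxel centres, so one-voxel axial and in-plane diagonal
disagreements on the 4 mm grid produce the characteristic 4.00 and
5.66 mm values. Test–retest reproducibility rigidly aligns the second
scan's spine bone mask onto the first (centre-of-mass translation +
principal-axes rotation, scale locked to 1), warps the second scan's
output through that transform, and re-scores; aligned joint centres are
snapped back to the grid before measuring, since both inputs are voxel
centres. Method comparison reports per-structure paired differences
(median and IQR) with a Wilcoxon signed-rank p-value delegated to
`stats::wilcox.test()`.

## Detection layer

SUVmax and SUVmean are plain mask statistics. SUVpeak is not universally
defined; the package adopts the ~1 mL spherical-neighbourhood convention —
the maximum over VOI voxels of the mean inside a 6 mm-radius ball
(19 voxels at 4 mm), neighbourhoods drawing from the whole volume and
clipped at the grid edge. Background correction divides by the median SUV
of the spine segment matched to the VOI's own level; the median is the
right location statistic here because focal lesions inside the reference
region must not shift it. SIJ VOIs use the lumbar segment, the
anatomically adjacent choice (the mapping is not otherwise dictated).
Femur and aorta reference regions are eroded by one voxel
(6-connectivity) before the median, removing the hot cortical rim and the
vascular wall and absorbing small PET/CT misalignment; no further
alignment correction is applied. Thresholds are closed (`score >= cutoff`
is positive) so printed cut-offs act as minimal positive values; the
defaults are TBR(SUVmax) 1.8 for joints/SIJs and 2.25 for DVUs, or 10.4 /
13.0 on raw SUVmax.

AUC uses the rank (Mann–Whitney) formulation, which ties out exactly with
trapezoidal ROC integration and handles tied scores without arbitrary
choices. The Kolmogorov–Smirnov optimal threshold is the argmax of
TPR − FPR over observed scores with ties broken toward the lower
threshold; cut-offs are optimised per VOI family (joints vs DVUs), which
is why two defaults exist. The DeLong test is implemented directly via
midrank placement values (the fast formulation), because the variance of
the AUC difference is itself a reported quantity; the test suite
cross-checks the p-value against `pROC::roc.test` and the variance against
a 2000-replicate paired bootstrap.

## The phantom: what it does and does not emulate

`generate_phantom_ldct()` builds a 46 × 44 × 158-voxel (4 mm) spine: 24
vertebrae as cuboid bodies with posterior arches (pedicles, lateral
blocks, spinous block), a continuous cord column, 24 L-shaped ribs
articulating with both the body and the lateral block, a sacrum with
oblique single-voxel sacro-iliac gaps to both ilia, femora, liver and
aorta. Vertebra heights default to 24 / 16 / 12 mm (lumbar / thoracic /
cervical) — the coarse-grid caricature of real vertebral proportions —
with one-voxel disk gaps. Intensities are piecewise constant (bone
≈ 400 HU, soft tissue ≈ −80 HU) plus Gaussian noise of 15 HU, a plausible
low-dose noise floor. A global pose jitter (z-rotation, isotropic scale
0.8–1.2, translation) makes atlas libraries anatomically diverse and
registration non-trivial. All randomness flows through the spec seed; equal
seeds give bit-identical volumes.

The PET phantom lays region-constant backgrounds (defaults 4 / 5 / 6 SUV
for cervical/thoracic/lumbar bone — reproducing the craniocaudal uptake
gradient of real Na[18F]F scans — 3 femur, 5 liver, 1.5 blood pool, 0.5
soft tissue) and adds Gaussian lesion blobs. Lesion truth is geometric —
a VOI is positive iff a lesion centre voxel lies inside it — precisely so
that detection operating points can be swept against a truth that does not
itself depend on any uptake threshold.

What passing on the phantom demonstrates: the set algebra, bookkeeping,
geometry, registration recovery and statistics are correct, and the
end-to-end pipeline is deterministic. What it does not demonstrate:
robustness to real anatomical variability (curved spines, transitional
vertebrae, ankylosis), to segmentation errors of the upstream network, to
PET reconstruction effects (partial volume, scatter), or to genuine
PET/CT misalignment. Clinical performance claims require patient data and
reader labels, which are outside the package's scope.

## Numerical conventions, in one place

* Rounding of continuous voxel coordinates: half away from zero
  (`round_half_away`), not banker's rounding.
* "Strictly anterior" ties → posterior part; quadrant corner ties → first
  corner in ant-sup, ant-inf, post-sup, post-inf order; sagittal-plane
  ties → right.
* Vertical element voxel extent: `round(length / spacing)`, one-sided.
* Sphere membership: closed ball on voxel-centre distances.
* Majority voting: `>= 3` of exactly 5; other library sizes are rejected.
* Classification thresholds: closed (`>=`).
* Iterative dilation cap: 5 rounds, then QC flag.
* Erosion/neighbour connectivity: 6 (faces).
* Registration determinism: one RNG draw per resolution level from the
  caller's seed; the global RNG state is restored afterwards.

## Problem sizes used by the tests and the acceptance script

The test suite builds one shared phantom (≈ 320k voxels) and exercises
registration on single partial-atlas units; the acceptance script
additionally generates a 7-scan phantom cohort, builds the 5-scan atlas
library, runs the full 26-unit multi-atlas segmentation once, and recovers
10 random similarity transforms. These sizes keep a complete run in the
low minutes on one CPU while leaving every code path — including the full
atlas route — executed, not mocked.

## Known limitations

* The morphological VB split assumes the cord segmentation spans the
  vertebral column; long cord gaps degrade the split to
  nearest-slice references.
* The atlas route registers rigid-plus-scale only; strongly non-rigid
  anatomy (scoliosis, fractures) is out of reach by design — non-rigid
  registration is explicitly not attempted.
* SIJ segmentation inherits the thin-structure sensitivity of
  overlap metrics; small errors move Dice a lot.
* The phantom's geometric realism is intentionally minimal (see above).
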