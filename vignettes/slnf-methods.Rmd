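---
title: "Multi-pinhole fingerprinting: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pinhole fingerprinting: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnf)
```

## The physical problem

In sentinel lymph node biopsy a ⁹⁹ᵐTc-labelled tracer accumulates in the
first lymph nodes draining a tumor. Locating those few point-like depots in
3D from a *single* stationary γ-image — rather than by sweeping a hand-held
probe and listening to count-rate audio — requires a collimator that encodes
position: a plate with several small pinholes, each projecting an inverted
image spot of every source onto the detector. The set of spots a source
produces is its *fingerprint*, and the fingerprint changes with all three
coordinates of the source, which is what makes single-image 3D localization
possible.

## Forward model

All geometry lives in one frame: origin at the center of the collimator
plate, z pointing into the scene, detector plane parallel to the plate at
`z = -plane_offset`. The source volume in front of the plate is sampled on a
regular grid (x-fastest linearization, 1-based indices; z planes start one
spacing in front of the plate). Photons travel in straight lines through
pinhole centers, so with `u ≥ 0` the expected-illumination image is `A u`,
where `A ∈ {0,1}^(N×M)` has a 1 wherever a voxel-to-pixel ray exists through
some pinhole and the ray's angle to the plate normal is within the pinhole's
field of view. Two modelling simplifications keep `A` binary:

* **ideal point aperture** — rays pass through the pinhole center; the
  physical 1 mm bore appears only as optional Gaussian blur in the
  simulator;
* **no solid-angle weighting** — an open ray contributes 1 regardless of
  obliquity; a voxel seen through two pinholes on the same pixel still
  yields entry 1.

`trace_ray()` is the single-ray primitive (similar triangles: a source at
depth z hits `pinhole + (offset/z) * (pinhole - source)` in the detector
plane, hence the point inversion), and `build_system_matrix()` assembles the
sparse column-compressed operator so that per-voxel fingerprint extraction —
the inner loop of everything else — is a contiguous gather.

## The greedy reconstruction

`slnf_reconstruct()` assumes the number of sources is known (the clinical
protocol fixes how many depots are being chased) and repeats, per source:

1. score every voxel: `C(d_proj, d_obs) = Σ_i d_proj[i] d_obs[i]`, i.e. for
   binary fingerprints the observed counts collected on the footprint;
2. select the argmax voxel;
3. zero the observed image on that voxel's footprint, so the next-strongest
   source dominates the following round.

Scores are raw inner products: no footprint-size normalization. The residual
after the final mask is returned for inspection; `correlation()` of an
extracted fingerprint with the residual is exactly 0, which is the masking
completeness property the tests assert.

Numerical/degeneracy choices, fixed for reproducibility:

* **tie-break** — the argmax takes the lowest linear voxel index; the tie
  count is reported per round (`n_ties`), never hidden.
* **all-zero images** — every voxel ties at score 0; the result is flagged
  `degenerate` instead of silently returning voxel 1.
* **identifiability** — with unnormalized scores, a voxel whose fingerprint
  is a *subset* of another voxel's ties exactly with it on its own noiseless
  projection, so exact recovery is guaranteed only for voxels with
  non-dominated, non-empty fingerprints. `duplicate_footprints()` reports
  identical fingerprints, `dominated_footprints()` the full containment
  relation; both are diagnostics the user can run on any geometry. On the
  reduced test geometry >75 % of the volume is strictly identifiable and the
  phantom positions all are (one has a two-voxel duplicate along z,
  contributing a deterministic one-spacing error).
* **stopping heuristic** — an optional rule (stop when a round's best score
  drops below a fraction of the first round's) exists but is off by default,
  matching the known-source-count assumption.

A full-scale scan is one sparse matrix–vector product per round
(`t(A) %*% d`, ~10⁷ nonzeros at M = 1.2·10⁶), well within an interactive
budget of seconds per round on one CPU.

## Assessability of candidate positions

For a candidate position with fingerprint `d` (a column of `A`), the
A-optimal-design statistic

$$\tilde V(d) = \mathrm{trace}\!\left(d\,(d^{T}d)^{-2}\,d^{T}\right)
             = \frac{1}{d^{T}d} = \frac{1}{\mathrm{nnz}(d)}$$

measures expected localization difficulty: the fewer pixels a position
illuminates, the less information each acquisition carries about it, and the
higher the score. The closed form is exact (the trace of the rank-1 matrix
`d v dᵀ`-type product collapses to `1/(dᵀd)`), so the implementation never
forms the N×N matrix; the explicit-trace path survives only as the
independent reference `oracle_assessability()` used by the tests, which
verify agreement to 1e-12 relative error on 10,000 random binary vectors.
`rank_positions()` applies the score to a source table, flags positions with
empty fingerprints as `invisible` (no score rather than an infinite one) and
ranks hardest-first.

## What the simulator emulates — and what it does not

`simulate_acquisition()` reproduces the statistical structure of the bench
acquisitions:

* expected image `λ = Σ_s activity_s · exposure · counts_per_mbq_s ·
  column(voxel_s)`, plus a **septal-penetration smear** — a uniform additive
  background carrying `penetration_fraction` of the source mass (default
  0.075, the midpoint of the plate's 5–10 % leakage) — plus, optionally, the
  forward projection of a **hot background**: a box volume whose activity
  (120 MBq in the bench protocol, tracer soaked into the phantom's
  cellulose/lignin block) is split uniformly over the voxels it covers;
* each repeat is an independent Poisson draw from `λ` (default protocol: 10
  repeats of 8 s); fixed seeds give bit-identical stacks;
* off-grid sources snap to the nearest voxel with the snap distance recorded
  as the quantization floor of the ground truth;
* 2×2 binning by block summation conserves counts exactly; images serialize
  as 16-bit grayscale TIFF with clipping at 65535 warned about;
* optional extras: Gaussian aperture blur (binned pixels) and a saturated
  sensor-artifact column, both off by default.

`counts_per_mbq_s` is the calibration constant standing in for the
detector's full efficiency chain (10 % quantum efficiency at 140.5 keV,
solid angle, branching). Its default of 10 counts/(MBq·s·ray) makes a
15 MBq vial at 8 s deposit ≈10⁴ counts over a 9-pinhole fingerprint — the
regime of the physical acquisitions. Only relative signal-to-background
matters to the reconstruction, so absolute dose realism is explicitly out of
scope.

Not modelled: tissue scatter and attenuation, detector dead time and energy
response, keV thresholding, septal-wall attenuation by material thickness.
Passing tests therefore demonstrate the *algorithmic* properties of the
pipeline under Poisson counting statistics with the stated backgrounds — not
detector-physics fidelity.

## Geometry presets and the phantom

The pinhole pattern is a required configuration input; the shipped default
is nine pinholes on a jittered 3×3 grid (seeded Gaussian jitter, rounded to
machining precision) spanning the central plate. The jitter is what makes
fingerprints of distinct voxels differ — a regular grid would produce many
identical fingerprints by symmetry. The collimator-to-detector distance is
never more than a magnification factor for the algorithms, so it is a plain
config value (default 30 mm).

Three presets (`fixture_geometry()`):

| profile | detector | grid | M | role |
|---|---|---|---|---|
| `tiny` | 64×128, 0.6 mm | 9×17×28 @ 4 mm | 4,284 | exhaustive reference scans in < 1 s |
| `default` | 64×128, 0.6 mm | 15×31×56 @ 2 mm | 26,040 | seeded noisy localization studies |
| `full_scale` | 257×515, 0.15 mm | 60×100×200 @ 2 mm | 1,200,000 | the physical problem size |

The full-scale grid keeps the literal 60×100×200 sampling points at 2 mm
even though 200 z-samples × 2 mm exceeds the 200 mm working depth range the
bench setup quotes; both counts and spacing are plain config values, and the
literal counts preserve M = 1.2·10⁶.

`fixture_phantom()` is the 3×3 vial grid in the y–z plane with 20 mm
spacing: adjacent positions 20 mm apart, same-row end pairs 40 mm, diagonal
neighbors 28.28 mm. Its standoff is 60 mm for the reduced profiles (100 mm
at full scale): far enough that all nine positions sit inside every
pinhole's 45° half-angle field of view and carry multi-pixel fingerprints,
as in the bench arrangement where the phantom stands well in front of the
plate. Test-fixture bundles (`make_fixture()`) are text-only, regenerate
bit-identically from (profile, seed), and their expected outputs come from
the independent reference implementations (`oracle_*()`: scalar ray tracing,
nested-loop enumeration, exhaustive scans, explicit traces) — never from the
code paths they validate.

## Evaluation conventions

* **error metric** — ℓ² distance in mm between the reconstructed voxel
  center and the ground truth snapped to the grid.
* **pairing** — with several sources, estimates pair to truths by
  minimum-total-error assignment (exact permutation enumeration, guarded at
  n ≤ 8; the use case is n ≤ 2).
* **summaries** — per position, the median and third quartile of the
  per-repeat errors, both by linear interpolation of order statistics at
  rank `p(n−1)+1` (R's default quantile type 7).
* **per-repeat reconstruction** — each of the 10 acquisitions is
  reconstructed independently and the errors summarized; images are never
  averaged first.

## Study conditions chosen for the simulation studies

Where a study condition is not pinned down by the protocol, it was fixed
once, on the following grounds, and not revisited:

* **nominal counts** — `counts_per_mbq_s = 10`, i.e. ≈10⁴ expected counts
  per 15 MBq source per 8 s acquisition (see above). Single-source medians
  on the reduced geometry are then at the grid-quantization floor at every
  phantom position, and increasing counts tenfold never worsens them.
* **the low-count regime** for the difficulty correlation —
  `counts_per_mbq_s = 0.003` (≈3–9 expected counts per source) with 100
  repeats. This is the transition regime in which localization is genuinely
  count-limited: above ≈5 counts per ray the matched filter saturates and
  every position's median collapses to the quantization floor, making a rank
  correlation against the assessability score degenerate; far below, the
  argmax is essentially uniform guessing. In the transition, positions with
  fewer fingerprint pixels receive proportionally fewer counts and err
  more — which is exactly the information argument behind the score.
* **overlapping two-source pairs** — the jittered pattern decorrelates
  fingerprints so strongly that the phantom's own pairs share at most one
  pixel. Overlapping pairs are therefore constructed programmatically: each
  phantom position is paired with the grid position ≥ 15 mm away sharing the
  most fingerprint pixels. The overlap-vs-disjoint comparison runs at
  moderate counts (`counts_per_mbq_s = 0.01`, 25 repeats), where median
  estimation is stable; at bench-level counts both pair types reconstruct
  exactly and the comparison holds with equality.

## Known limitations

* Fingerprint degeneracy is geometry-dependent: voxels far off-axis may be
  seen through one pinhole only (or none), and duplicate or dominated
  fingerprints concentrate there. The diagnostics make this visible; a
  denser or wider pinhole pattern reduces it.
* Depth resolution is intrinsically weaker than lateral resolution: a
  voxel's fingerprint changes with z only through slow magnification
  changes, so low-count errors concentrate along z.
* The simulator's penetration model is a uniform smear; the physical
  leakage is structured around the pinholes, which is harsher on the
  reconstruction than the uniform assumption.
* The assessability score depends only on footprint size, not on which
  pixels overlap with other candidates' fingerprints; it ranks single-source
  difficulty and says nothing about two-source confusability.
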