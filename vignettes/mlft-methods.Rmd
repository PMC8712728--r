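---
title: "Multi-level fiber tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level fiber tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deterministic tractography reconstructs white-matter bundles by marching
streamlines through a voxel-wise model of local fiber orientation. For
bundles that fan — the corticospinal tract (CST) being the canonical
example, with lateral projections leaving the main trunk at angles well
above 45° near the motor cortex — single-pass deterministic trackers
systematically miss the high-angulation branches: every step is bounded by
an angular threshold, and at a branch point the peak that continues the
current direction always wins over the peak that turns.

Multi-level fiber tracking (MLFT) addresses this without abandoning
determinism. Tracking runs between a seed region (here, a single transverse
slice through the brainstem trunk) and a target region (motor cortex).
Pathways that reach the target form level 1 of the reconstruction — exactly
the output of a conventional deterministic CSD tracker. Pathways that fail
are not discarded: every point along a failed pathway is revisited, the
fiber-orientation-distribution (FOD) peaks at that point that were *not*
followed become new unidirectional seeds (a point with several unused peaks
is duplicated, one seed per peak), and branches that reach the target are
concatenated with the parent segment up to the branch point, forming level
2. The junction between parent and branch may turn by more than the per-step
angular threshold — that is the point: the per-step smoothness constraint is
preserved inside every propagated segment, while the assembled pathway can
have one sharp, anatomically motivated turn.

Two consequences follow by construction and are verified in the test suite:

* with one level, MLFT *is* the CSD baseline (bit-identical streamlines);
* the MLFT reconstruction always covers the CSD reconstruction, so
  visitation-based metrics can only improve with levels.

## Local models

**Diffusion tensor.** Per voxel, ordinary least squares on
`ln(S/S0) = -b g' D g`, with `S0` the mean of the b0 volumes and signals
clipped to a small positive floor before the log. FA uses the standard
eigenvalue formula (negative eigenvalues from noisy fits are admitted); the
principal direction is the eigenvector of the algebraically largest
eigenvalue. OLS was chosen as the deterministic baseline; no robust or
weighted variants are offered.

**Constrained spherical deconvolution.** The normalized signal is
deconvolved by a single-fiber response in the real, symmetric, even-order
spherical-harmonic (SH) basis (degree-major ordering, `m < 0` sine terms
first; the basis is orthonormal and verified against an independent
construction). The response is calibrated recursively: starting from a
deliberately fat (FA 0.1) tensor profile, candidate voxels are deconvolved,
voxels whose FOD has a single dominant peak (second-to-first accepted-peak
amplitude ratio below 0.1) are kept, and the response is re-fitted as the
zonal profile of the kept voxels' signals aligned peak-to-z; iteration stops
when the selected set stabilizes.

Two numerical choices deserve emphasis, both driven by the emulated
clinical acquisition (one b0 plus 32 directions at b = 1000 s/mm², 2 mm
voxels):

1. *Super-resolved solve, truncated report.* A 32-direction shell cannot
   separate SH degree 8+ signal content from degrees ≤ 6 by least squares
   alone; solving directly at the reported order `L_max = 6` aliases that
   content into spurious FOD lobes measured at 20–45% of the main peak —
   the same order of magnitude as genuine secondary fibers. The
   non-negativity constraint, however, makes higher orders well posed (the
   original constrained-deconvolution literature used exactly this to
   exceed the direction-count limit), so the solve runs at order 10 and the
   result is truncated to the reported `L_max = 6`. After truncation the
   spurious content drops to ~6% of peak, below the tracking threshold.
2. *Amplitude scale.* FOD amplitudes are normalized so that a canonical
   single-fiber FOD (an order-6 delta) has unit peak amplitude. On this
   scale the peak threshold 0.08 sits above truncation ringing and below
   genuine fiber-population peaks, which is precisely the role the
   threshold plays in the tracking setup emulated here.

The non-negativity constraint itself is the classic soft scheme: amplitudes
on a 300-direction constraint sphere falling below `tau` (0.1 of the mean
initial amplitude) are quadratically penalized — toward `tau` rather than
zero, which keeps the converged floor slightly positive instead of slightly
negative — with the penalty matrix rescaled by the ratio of design-matrix
norms, for at most 50 constraint-set iterations. A soft penalty of this
class leaves small negative residuals (one to a few percent of peak; exact
non-negativity would require an active-set quadratic program, a different
algorithm). Voxels whose most negative constraint-direction amplitude
exceeds 5% of their peak after the cap are treated as non-converged and
excluded from tracking; the 5% bound was calibrated on noisy-phantom
behavior, where well-behaved crossing voxels reach ~4%.

**Peak extraction.** Candidate maxima are peeled from a 642-vertex
icosphere tessellation with a 25° exclusion zone, refined by projected
gradient ascent on the SH expansion (batched finite-difference tangent
steps with a shrinking step size), antipodally collapsed, deduplicated at
25° separation, thresholded at 0.08 amplitude, and capped at 3 peaks. The
refinement is verified against exhaustive search on a 10242-vertex sphere.
During tracking, three refinement iterations suffice (the search grid
localizes peaks to ~4°, far below the 45° deviation rule); the standalone
extractor defaults to eight.

## Tracking

Fixed-step Euler integration at half the smallest voxel dimension, with
trilinear interpolation of SH coefficients (CSD) or tensor components
(DTI) and model quantities recomputed at the interpolated point —
eigenvectors and peaks are antipodal, so interpolation happens on the
underlying fields, never on directions. Baseline tracking is bidirectional
from each seed with the two half-tracks joined; MLFT branch seeds propagate
unidirectionally along their assigned peak. Termination: tracking-mask
exit, FA below 0.1 (DTI), no peak at or above 0.08 (CSD/MLFT), per-step
deviation above 45°, or a 250 mm half-track guard against pathological
loops. Five seed points per voxel are drawn uniformly within each
seed-mask voxel's in-plane extent, all on the voxel-centre plane of the
single-slice seed mask. Streamlines are stored in world millimetres; voxel
space is entered only for interpolation and visitation masks
(centre-of-voxel convention, nearest voxel by `floor(index + 0.5)`).

MLFT specifics: the "used" peak at a failed-pathway point is the one within
1° of the locally traversed segment direction (the harvest re-extracts
peaks with the same settings as propagation, so the match is exact up to
numerical noise); peaks within 10° of the incoming axis are discarded as
backtracking. Level-1 pathways are bidirectional, so the traversal
orientation at a point is ambiguous; both orientations are considered and
branch seeds landing in the same voxel with directions within 5° are
merged. Levels beyond 2 are supported (failed branches of level k seed
level k+1 from their new tail segments); the default of 2 levels matches
the emulated clinical setup. Interhemispheric filtering removes pathways
that visit both hemisphere masks at points superior to the seed plane —
the shared brainstem seed region below the plane is exempt by
construction.

## Quantitative metrics

**Visitation masks** mark voxels containing at least one streamline point;
with half-voxel steps no voxel is skipped along straight segments (a
documented limitation for extremely curved steps, which the 45° rule
precludes in practice).

**Coverage** of a reference reconstruction by a candidate is
`100 · |reference ∧ candidate| / |reference|` on visitation masks.

**Radial extent** maps the coronal projection of the motor mask to a 90°
arc and measures the covered portion. The anterior–posterior axis
(identified from the affine) is collapsed; every projected motor pixel
receives a polar angle about the arc centre; the projection's angular span
is rescaled to [0°, 90°] and divided into 1° bins. Bins containing at
least one motor pixel constitute the arc; the extent is 90° times the
covered fraction of those bins, which makes "full coverage = 90°" exact
for any discrete mask (a raw covered-bin count would undercount whenever
fewer than 90 bins are occupied). The arc centre is a least-squares (Kasa)
circle fit of the projected motor pixels: for a circular-arc mask this
maps arc length uniformly to angle, so covering half the arc scores
45° ± 1° by geometry; the midpoint of the projection's inferior
bounding-box edge is the fallback when the pixels are too collinear to
define a circle. The left hemisphere's lateral direction is mirrored so the
sweep runs medial-to-lateral in both hemispheres.

**Outliers** in a vector of extent differences are values deviating from
the mean by strictly more than twice the sample standard deviation.

## The synthetic phantom

No patient data ships with the package; every algorithm and metric is
exercised on a generated phantom with full ground truth. Each hemisphere is
a bundle of parallel 2-voxel-wide columns rising from a shared single-slice
seed region: a central column runs to an apical target patch, and each
additional column feeds one straight branch that leaves the trunk at its
prescribed angle (positive = lateral, negative = medial) toward its own
target patch. This multi-column construction is deliberate: deterministic
pathways from a single column share one fate, so a phantom in which *all*
level-1 pathways succeed would never exercise branch harvesting, and one in
which all fail would leave the CSD baseline empty. With per-branch columns,
central-column pathways give the baselines a non-empty reconstruction while
branch-column pathways terminate at their junction whenever the branch
angle exceeds the 45° threshold — exactly the failure population MLFT
re-seeds. Junction voxels carry both fiber populations with
occupancy-proportional volume fractions from quarter-voxel rasterization.

The default acquisition emulates the clinical protocol: 2 mm isotropic
voxels, one b0 and 32 electrostatically optimized directions (Jones-style
antipodal Coulomb minimization — a Fibonacci lattice measurably doubles
the degree-8 aliasing) at b = 1000 s/mm². Diffusivities default to typical
white matter (λ∥ = 1.7 × 10⁻³, λ⊥ = 0.2 × 10⁻³ mm²/s); the background is
isotropic at 1.0 × 10⁻³ mm²/s. Noise is Rician with σ = S0/SNR and SNR 30
by default; the noise-free signal is bit-reproducible. The per-hemisphere
motor mask is a quarter-circle shell in the coronal plane whose radius
matches the trunk geometry, so apex and lateral branch endpoints land on
the arc and the radial-extent metric has a meaningful ground truth. The
default geometry (30³ voxels, branches at −40° medial and +70° lateral,
branch level at 0.6 of trunk height) keeps a full three-way comparison
under a minute on one CPU; these sizes are stated here as the package's
reference configuration.

What the phantom does *not* emulate — curving fibers, kissing bundles,
partial-volume gray matter, susceptibility distortion, tumor mass effect —
bounds what passing tests show: they validate the algorithmic contracts
(level containment, branch recovery, threshold behavior, metric
calibration), not clinical reconstruction fidelity on real acquisitions.

## Degenerate inputs and tie-breaking

Empty seed or target masks, overlapping hemisphere masks, empty coverage
references and empty motor masks are errors; an empty tractogram is a valid
value (a warning at tracking time, not an error). Peak ties on the search
grid resolve to the first vertex; the antipodal representative of a peak is
the hemisphere with positive z (then y, then x). Voxels with zero b0 signal
are excluded from model fitting. ROI filtering and target-reaching both use
any-point traversal, and bidirectional propagation is used for the
baselines; both conventions are fixed here because the emulated setup does
not state them.

## Known limitations

* The soft non-negativity scheme's residual negativity (documented above)
  means the FOD field's non-negativity is approximate, at the few-percent
  level typical of this algorithm class.
* Sub-45° branches are not separable from their trunk at `L_max = 6` (a
  40° crossing blurs into one lobe); the tracker then follows the blended
  lobe smoothly onto the branch, which is the behavior that makes such
  branches reachable by the plain CSD baseline in the first place.
* Harvesting every failed-pathway point before deduplication makes level-2
  seed counts grow with step density; the 5°-per-voxel merge bounds this.
* Single-shell only; multi-tissue deconvolution is out of scope.
* All inputs must share one grid; no resampling or registration is
  performed anywhere.
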