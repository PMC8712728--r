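# mlftrack

Deterministic diffusion-MRI tractography with **multi-level fiber tracking
(MLFT)** — an iterative branch re-seeding scheme that recovers
high-angulation bundle branches which single-pass deterministic trackers
miss — together with the two standard baselines (DTI-based and CSD-based
deterministic tracking) and the quantitative metrics used to compare them.
The toolkit is aimed at researchers studying bundles that fan, such as the
corticospinal tract (CST), where lateral projections leave the trunk at
angles beyond any per-step angular threshold.

## The algorithm in brief

Deterministic CSD tracking marches streamlines along fiber orientation
distribution (FOD) peaks, at each step choosing the peak that minimizes
angular deviation from the previous direction and stopping when that
deviation exceeds a threshold θ (45° here). At a branch point the
straight-ahead peak always wins, so branches leaving at > θ are never
reconstructed.

MLFT runs tracking between a seed region and a target region for a
user-chosen number of levels:

* **Level 1** — deterministic CSD tracking from the sampled seeds;
  pathways reaching the target are kept (level 1 *is* the CSD baseline).
* **Level k+1** — every point of every failed pathway is revisited; FOD
  peaks not followed during the parent's traversal become unidirectional
  branch seeds (a point with *m* unused peaks yields *m* seeds). Branches
  that reach the target are concatenated with the parent segment up to the
  branch point and form the new level.

Within every propagated segment the per-step constraint `angle ≤ θ` holds;
only the parent–branch junction may exceed it. By construction the MLFT
reconstruction always contains the CSD reconstruction.

Local models: log-linear least-squares diffusion tensor (FA threshold 0.1
for DTI tracking) and constrained spherical deconvolution at `L_max = 6`
with a recursively calibrated single-fiber response and FOD peak threshold
0.08. Comparison metrics: binary visitation masks, coverage
(`100·|ref ∧ cand|/|ref|`), radial extent of the bundle on a 90° motor-mask
arc, and 2σ outlier detection on extent differences. A synthetic
branching-phantom generator (trunk plus angled branches, mirrored
hemispheres, Rician noise, full ground truth) makes everything testable
without patient data — no clinical images are included or required.

## Worked example

Generate the default branching phantom (30³ voxels at 2 mm, one b0 + 32
directions at b = 1000 s/mm², SNR 30; per hemisphere a trunk with a 40°
medial and a 70° lateral branch), run all three algorithms on it and
compute the metrics:

```r
library(mlftrack)

res <- run_comparison(rng_seed = 3)
print(res)
#> three-way comparison (DTI / CSD / MLFT)
#>  streamlines: dti_left 24, csd_left 18, mlft_left 22, dti_right 15, csd_right 15, mlft_right 19
#>  radial extents (deg):
#>    dti_left    14.40
#>    csd_left     7.20
#>    mlft_left   14.40
#>    dti_right   14.40
#>    csd_right    7.20
#>    mlft_right  14.40
#>  coverages (%):
#>    dti_by_csd_left   62.50
#>    dti_by_mlft_left  96.43
#>    csd_by_mlft_left 100.00
#>    dti_by_csd_right  73.33
#>    dti_by_mlft_right  97.78
#>    csd_by_mlft_right 100.00
```

Reading the numbers: the CSD baseline cannot turn into the 70° lateral
branch, so its bundle hugs the trunk and covers only 7.2° of the motor
arc. MLFT re-seeds the failed branch-column pathways from their unused FOD
peaks and reaches the lateral target, doubling the radial extent — while
its coverage of the CSD bundle is exactly 100%, the containment that holds
on every input. Writing `out_dir = "comparison"` additionally saves the
tractograms (`.tck`), per-level MLFT files, visitation masks (`.nii.gz`)
and a `summary.json`.

The pieces are available individually — `make_branching_phantom()`,
`fit_tensor()`, `calibrate_response_recursive()`, `csd_deconvolve()`,
`extract_peaks()`, `track_bundle()`, `mlft_track()`, `visitation_mask()`,
`coverage()`, `radial_extent()` — and read/write NIfTI, FSL bval/bvec,
MRtrix `.tck` and TrackVis `.trk`. A thin command-line wrapper lives at
`inst/cli/mlft.R` (`phantom`, `track`, `metrics-*`, `compare`
subcommands).

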