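# laminarfmri

Layer-specific (laminar) analysis of high-resolution block-design BOLD
fMRI, with a synthetic cortical phantom providing ground truth for every
stage.

At 7 T, T2-weighted fMRI at 0.7 mm isotropic resolution can resolve how the
BOLD response is distributed across cortical depth — and thereby across the
cortical layers that house different circuit elements (thalamic input in
middle layers, feed-back and horizontal connections in superficial and deep
layers). Turning a voxel grid into a laminar claim requires: assigning each
gray-matter voxel a **relative cortical depth** (0 at the white-matter
boundary, 1 at the pial surface) from paired WM/pial surface meshes;
estimating a **depth-binned response profile** by averaging equally
populated depth bins before regression on an HRF-convolved block regressor;
assessing significance by **block-label permutation**; and interpreting
profile shape under the **point-spread function** with which cubic voxels
sample a folded sheet. This package implements that pipeline, plus
differential profiles between stimulus conditions, depth ANOVAs, corrected
per-depth paired t-tests, and Fourier-phase onset latency by depth.

The core quantities, in the field's notation:

- relative depth of a voxel: `d = (distance from WM surface) / (local
  cortical thickness)`, both measured along lines connecting matched WM/GM
  mesh vertices (alternatives: WM-surface normals, shortest WM-to-pial
  lines; all three agree on `d` to within 0.05 RMS on curved geometry);
- per-bin amplitude: OLS of the bin-averaged, drift-filtered series on the
  boxcar ⊗ double-gamma HRF, reported as percent signal change
  `100 · β / baseline`;
- permutation p: `p = (1 + #{|β*| ≥ |β|}) / (N + 1)` over `N` whole-block
  relabelings;
- laminar PSF: the orientation-averaged 1-D projection of a unit cube,
  FWHM ≈ 0.87 of the voxel edge;
- latency: phase of the Fourier component at the block-alternation
  frequency, scaled so one 32 s cycle spans 0–32 s.

Because no public dataset accompanies this design, the package ships a
first-class synthetic world: a sinusoidally folded ribbon phantom with
matched WM/pial meshes and exact depth truth (`make_ribbon_phantom()`,
`voxelize()`), a laminar BOLD simulator with depth-dependent amplitude,
latency and vascular baseline bias, Gaussian PSF blur and AR(1) noise
(`simulate_session()`), and a generator for occluded, rotation-scrambled
object stimuli with their low-level image statistics
(`make_aperture_grid()`, `scramble_image()`, `rms_contrast()`,
`orientation_power()`).

## Worked example

```r
library(laminarfmri)

cfg <- default_pipeline_config(seed = 1)   # folded ribbon, 2 conditions,
run <- run_pipeline(cfg, out_dir = "demo") # 0.5% mid-depth "scrambled" excess
read.csv(file.path("demo", "differential_profile.csv"))
```

```
  bin mean_depth         diff          se
1   1 0.09839889  0.002239236 0.007367397
2   2 0.29069111 -0.011369668 0.007238428
3   3 0.48548758 -0.403334201 0.006903138
4   4 0.68908451 -0.023226411 0.006294961
5   5 0.90044327  0.000365866 0.007027206
```

Each row is one of five equally populated depth bins (bin 1 deepest);
`diff` is the intact − scrambled amplitude difference in percent signal
change with its standard error. The simulated world gives the "scrambled"
condition a 0.5% excess confined to mid-depth, and the pipeline recovers
exactly that: a differential profile flat everywhere except bin 3, where it
reaches −0.40% (the injected 0.5% attenuated by the 0.87-voxel PSF blur).
The run directory also holds the laminar profile per condition, the depth
map and QC report, NIfTI/OBJ artifacts, and a manifest (seeds, digests,
timings) that makes re-runs byte-identical.

A thin CLI over the same functions is installed at
`inst/cli/laminar.R` (subcommands `run`, `simulate`, `depth`, `analyze`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes from scratch, using only package functions: the mean absolute
rotation angle of the aperture-scrambling distribution (100,000 seeded
draws from the equal mixture of uniform [60°, 120°] and [−120°, −60°]),
and the FWHM of the laminar voxel point-spread function (100,000
orientations uniform on the sphere, averaged cube-projection profile,
width at half maximum as a percentage of the voxel edge), and writes both
to the JSON file named by `--out`.

## Documentation

The methods vignette (`vignettes/laminar-pipeline.Rmd`) describes the
model and its assumptions, the tunable parameters with their defaults and
units, what the synthetic world does and does not establish, and the
numerical decisions (regressor conventions, drift filtering of data and
regressors alike, permutation statistic, PSF estimator).
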