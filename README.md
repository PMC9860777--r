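# kinrepro

Reproducibility analysis for repeated depth-camera body-tracking runs.

Markerless body tracking (e.g. the Azure Kinect family of RGB-D cameras with
a skeleton-tracking SDK) is widely used in movement and posture research.
Re-processing the *same* recording, however, does not always give the same
joint positions: some compute backends ("processing modes") are
deterministic on a given machine, others scatter from run to run by
clinically relevant amounts; different machines can disagree even for
deterministic modes; and every run starts with an initialization transient.
`kinrepro` is for researchers and QA engineers who need to quantify these
effects before trusting a tracking pipeline.

## What it computes

For a set of repeated runs of one recording (per-frame 3-D joint positions
in mm, 18 main joints), grouped by processing-mode and machine labels:

* **Initialization transient** — per run/joint/axis fit of
  `f(t) = a·exp(−b·t) + c`; half-life `T½ = ln 2 / b`; cutoff at `4·T½`
  (93.75% completion); per-cell mean cutoffs, their 85%-quantile, and a
  frame-discard recommendation rounded up to a full second of video.
* **Dispersion ellipsoids** — per run/joint 2-SD Gaussian ellipsoid of the
  windowed positions; volume of the convex hull of its 20×20 surface mesh
  plus the closed form `(4/3)·π·sd³·√det Σ`.
* **Run-pairwise Euclidean distances** — `d_t(p, q) = ‖p_t⁽ⁱ⁾ − q_t⁽ʲ⁾‖₂`
  per frame, joint and unordered run pair, with
  min/max/mean/median/SD summaries per joint.
* **Bone lengths** — `‖s_t − e_t‖₂` per frame/run for a configurable
  11-bone table; near-constant lengths indicate a stable skeleton scale.
* **Steady ranges and switches** — least-squares binary segmentation of
  each series into steady value ranges, and per-(joint, axis)
  classification of two run sets (e.g. two machines) into
  equivalent / one switches / both switch at different times /
  close / distinct steady ranges.
* **Synthetic runs** — a seeded generator with transient, steady-range
  switches, frame noise, per-run offsets and a global per-frame skeleton
  scale wobble; `preset_study_like()` emulates 100 runs × 900 frames of a
  static subject. Deterministic-mode emulation yields bit-identical runs.

Input formats: the JSON dialect of the offline body-tracking processor
(field names configurable via `tracking_schema()`) or a long CSV
(`run_id, frame, joint, x_mm, y_mm, z_mm`). See the vignette in
`vignettes/body-tracking-reproducibility.Rmd` for the methods.

## Worked example

```r
library(kinrepro)

det <- generate_runset(preset_study_like(seed = 1, stochastic = FALSE, n_runs = 20))
sto <- generate_runset(preset_study_like(seed = 2, stochastic = TRUE,  n_runs = 20))
wd <- apply_window(det, 60)   # discard the 2-s initialization window
ws <- apply_window(sto, 60)

pairwise_distances(wd, joints = c("PELVIS", "FOOT_LEFT"))$summary
#>       joint min max mean median sd
#> 1    PELVIS   0   0    0      0  0
#> 2 FOOT_LEFT   0   0    0      0  0

pairwise_distances(ws, joints = c("PELVIS", "FOOT_LEFT"))$summary
#>       joint    min   max mean median    sd
#> 1    PELVIS 0.0226  4.04  1.3   1.25 0.568
#> 2 FOOT_LEFT 0.1853 38.22 11.3  10.88 4.806
```

The deterministic emulation reproduces exactly (all distances 0.0 mm); the
stochastic one moves the left foot by up to 38 mm between runs while the
pelvis stays within ~4 mm — outer extremities scatter most.

```r
fit_exponential(sto$runs[[1]]$xyz[, "z", "FOOT_RIGHT"], frames = sto$frames)
#> <convergence_fit> status=fitted: a=-49.423 mm, b=0.00743 /frame,
#>   c=1799.036 mm, T1/2=93.34, cutoff=373.34 frames (rmse=2.908 mm)
```

This foot's z-coordinate approaches its steady state from ~49 mm below with
a 93-frame half-life; its transient is 93.75% complete at frame 373.

```r
ellipsoid_volumes(ws, joints = c("PELVIS", "FOOT_LEFT"))$summary[, c("joint", "mean", "sd")]
#>       joint      mean        sd
#> 1 FOOT_LEFT 1.153e+04 520.67811
#> 2    PELVIS 8.856e-01   0.03877
```

The foot's 2-SD dispersion ellipsoid (inflated by its mid-recording 60 mm
steady-range switch) is four orders of magnitude larger than the pelvis's.

The numbered scripts in `analysis/` walk the full pipeline (simulate →
convergence → dispersion → distances/bones → cross-machine comparison) and
write their tables under `results/`.

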