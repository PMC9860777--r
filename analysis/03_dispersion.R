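#!/usr/bin/env Rscript
# Step 3: spatiotemporal dispersion ellipsoids.
#
# Per run and joint, the 2-SD Gaussian ellipsoid of the windowed positions
# (frames 61..900) and the volume of the convex hull of its 20x20 surface
# mesh. Deterministic emulation: volumes identical across runs (SD 0.0 mm^3).
# Stochastic emulation: outer extremities disperse far more than the trunk.

suppressPackageStartupMessages(library(kinrepro))
dir.create("results", showWarnings = FALSE)

for (mode in c("deterministic", "stochastic")) {
  rs <- generate_runset(preset_study_like(
    seed = if (mode == "deterministic") 2301L else 2302L,
    stochastic = mode == "stochastic", n_runs = 30L))
  w <- apply_window(rs, 60)
  ev <- ellipsoid_volumes(w, sd_multiplier = 2, npts = 20)
  write.csv(ev$volumes, sprintf("results/03_volumes_%s.csv", mode),
            row.names = FALSE)
  write.csv(ev$summary, sprintf("results/03_volume_summary_%s.csv", mode),
            row.names = FALSE)
  cat(sprintf("\n[%s] per-joint hull-volume summary (mm^3):\n", mode))
  print(ev$summary[order(-ev$summary$mean),
                   c("joint", "min", "max", "mean", "median", "sd")],
        digits = 4)
  cat(sprintf("[%s] SD of volumes across runs is zero for all joints: %s\n",
              mode, all(ev$summary$sd == 0)))
}
cat("\nFinding: identical runs give volume SD 0.0 mm^3 for every joint;",
    "stochastic runs disperse most at feet/wrists, least at pelvis/spine.\n")
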