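#!/usr/bin/env Rscript
# Step 4: run-pairwise Euclidean distances and bone-length stability.
#
# Distances: for every frame in 61..900, joint, and unordered run pair.
# Bone lengths: per frame and run for the 11 default bones. The deterministic
# emulation must give exactly 0.0 mm distances; bone lengths vary only
# through noise and the global frame-to-frame scale wobble.

suppressPackageStartupMessages(library(kinrepro))
dir.create("results", showWarnings = FALSE)

for (mode in c("deterministic", "stochastic")) {
  rs <- generate_runset(preset_study_like(
    seed = if (mode == "deterministic") 2301L else 2302L,
    stochastic = mode == "stochastic", n_runs = 30L))
  w <- apply_window(rs, 60)

  pd <- pairwise_distances(w)
  write.csv(pd$summary, sprintf("results/04_distance_summary_%s.csv", mode),
            row.names = FALSE)
  cat(sprintf("\n[%s] max pairwise distance: %.3f mm over %d pairs x %d frames\n",
              mode, pd$max_distance, pd$n_pairs, pd$n_frames))
  top <- pd$summary[order(-pd$summary$mean), ]
  print(head(top[, c("joint", "min", "max", "mean", "median", "sd")], 5),
        digits = 3)

  bl <- bone_lengths(w, keep_records = TRUE)
  write.csv(bl$summary, sprintf("results/04_bone_summary_%s.csv", mode),
            row.names = FALSE)
  cat(sprintf(
    "[%s] bone-length spread pooled over frames+runs (max SD): %.2f mm (%s)\n",
    mode, max(bl$summary$sd), bl$summary$bone[which.max(bl$summary$sd)]))
  # cross-run spread at a fixed frame isolates run-to-run variation from the
  # within-run drift (residual transient + scale wobble)
  per_frame_sd <- aggregate(length ~ bone + frame, data = bl$records, FUN = sd)
  cat(sprintf(
    "[%s] bone-length SD across runs at a fixed frame: max %.2f mm, mean %.3f mm\n",
    mode, max(per_frame_sd$length), mean(per_frame_sd$length)))
}
cat("\nFinding: stochastic runs move joint positions by tens of mm between",
    "runs while bone lengths vary noticeably less. In this emulation the",
    "cross-run bone spread comes from per-run offsets drawn independently",
    "per joint; a real tracker's internal skeleton model couples the",
    "endpoints more strongly, so its bone lengths are steadier still.",
    "Pooled over the window, bone lengths also drift with the slow residual",
    "transients of the outer joints.\n")
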