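# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths.

# Triangulated surface volume of an ellipsoid mesh as returned by
# fit_ellipsoid: rebuild the latitude-longitude grid indexing (south pole,
# npts-2 rings of npts points, north pole), fan-triangulate every band quad
# and both polar caps, and sum signed tetrahedra about the centroid.
# For a convex surface this equals the convex-hull volume of the vertices.
oracle_mesh_volume <- function(mesh, npts) {
  ctr <- colMeans(mesh)
  ring <- function(i) {                     # i in 1..npts-2
    1L + (i - 1L) * npts + seq_len(npts)
  }
  south <- 1L
  north <- nrow(mesh)
  tet <- function(i1, i2, i3) {
    abs(det(rbind(mesh[i1, ] - ctr, mesh[i2, ] - ctr, mesh[i3, ] - ctr))) / 6
  }
  v <- 0
  r1 <- ring(1L)
  for (k in seq_len(npts))
    v <- v + tet(south, r1[k], r1[k %% npts + 1L])
  if (npts > 3L) {
    for (i in seq_len(npts - 3L)) {
      a <- ring(i); b <- ring(i + 1L)
      for (k in seq_len(npts)) {
        k2 <- k %% npts + 1L
        v <- v + tet(a[k], a[k2], b[k2]) + tet(a[k], b[k2], b[k])
      }
    }
  }
  rl <- ring(npts - 2L)
  for (k in seq_len(npts))
    v <- v + tet(north, rl[k], rl[k %% npts + 1L])
  v
}

# check that a plane through three mesh points supports the whole point set
# (all points on one side within tol) -- evidence the triangulated surface is
# the convex hull
plane_supports <- function(mesh, i1, i2, i3, tol = 1e-9) {
  nrm <- pracma_cross(mesh[i2, ] - mesh[i1, ], mesh[i3, ] - mesh[i1, ])
  if (sqrt(sum(nrm^2)) < 1e-12) return(NA)
  d <- as.numeric((mesh - matrix(mesh[i1, ], nrow(mesh), 3, byrow = TRUE)) %*% nrm)
  scale <- max(abs(d))
  all(d <= tol * max(scale, 1)) || all(d >= -tol * max(scale, 1))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# exhaustive least-squares single change-point: returns the first frame of
# the second segment, or NA when no admissible split improves on no split
oracle_single_changepoint <- function(x, min_segment = 30) {
  n <- length(x)
  if (n < 2 * min_segment) return(NA_integer_)
  sse <- function(v) sum((v - mean(v))^2)
  cand <- min_segment:(n - min_segment)
  cost <- vapply(cand, function(s) sse(x[1:s]) + sse(x[(s + 1):n]), numeric(1))
  cand[which.min(cost)] + 1L
}

# small run set with explicit per-run, per-joint constant positions
const_runset <- function(positions_by_run, n_frames = 40, fps = 30,
                         mode_label = "T", machine_label = "A") {
  runs <- lapply(seq_along(positions_by_run), function(r) {
    jp <- positions_by_run[[r]]        # named list joint -> length-3
    xyz <- array(NA_real_, c(n_frames, 3, length(jp)),
                 dimnames = list(NULL, c("x", "y", "z"), names(jp)))
    for (j in names(jp)) xyz[, , j] <- matrix(jp[[j]], n_frames, 3, byrow = TRUE)
    bt_run(r, xyz)
  })
  runset(runs, mode_label = mode_label, machine_label = machine_label, fps = fps)
}

# tiny generator config: one or more joints, no transient by default
tiny_config <- function(joints = c("PELVIS", "FOOT_LEFT"),
                        n_runs = 2, n_frames = 60, seed = 1,
                        noise_sd = 0.5, jitter = 0, shared_noise = FALSE,
                        skeleton_scale_sd = 0, ...) {
  centers <- preset_skeleton_centers_test()
  jcs <- lapply(joints, function(j)
    joint_gen_config(j, centers[[j]], noise_sd = rep(noise_sd, 3),
                     per_run_jitter_sd = jitter, ...))
  runset_gen_config(n_runs = n_runs, n_frames = n_frames, seed = seed,
                    joint_configs = jcs, shared_noise = shared_noise,
                    skeleton_scale_sd = skeleton_scale_sd)
}

preset_skeleton_centers_test <- function() {
  list(PELVIS = c(0, 100, 1900), NECK = c(0, -380, 1885),
       FOOT_LEFT = c(-105, 935, 1800), WRIST_LEFT = c(-245, 140, 1885),
       SPINE_NAVEL = c(0, -50, 1895))
}

# run set whose FOOT_LEFT z-series follows `levels` with switches at `at`
# (frame labels start at `first_frame`, emulating a windowed series)
switching_set <- function(levels, at, n_runs = 3, n_frames = 840,
                          first_frame = 61, seed = 1, noise = 0.3) {
  centers <- preset_skeleton_centers_test()
  sw <- if (length(at))
    lapply(seq_along(at), function(k) list(
      frame = at[k] - first_frame + 1L,
      step = c(0, 0, levels[k + 1] - levels[k])))
  else list()
  jcs <- list(
    joint_gen_config("PELVIS", centers$PELVIS, noise_sd = rep(noise, 3)),
    joint_gen_config("FOOT_LEFT",
                     centers$FOOT_LEFT + c(0, 0, levels[1]),
                     noise_sd = rep(noise, 3), switch_schedule = sw)
  )
  rs <- generate_runset(runset_gen_config(n_runs = n_runs, n_frames = n_frames,
                                          seed = seed, joint_configs = jcs))
  rs$frames <- seq(first_frame, length.out = n_frames)
  rs
}

# apply one rigid transform (rotation + translation) to every run of a set
transform_runset <- function(rs, R, tr) {
  runs <- lapply(rs$runs, function(r) {
    xyz <- r$xyz
    for (j in dimnames(xyz)[[3]])
      xyz[, , j] <- sweep(xyz[, , j, drop = TRUE] %*% t(R), 2, tr, "+")
    bt_run(r$run_id, xyz, r$gaps)
  })
  runset(runs, rs$mode_label, rs$machine_label, rs$fps, rs$frames)
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
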