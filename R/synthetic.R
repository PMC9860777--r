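#' Per-joint generator configuration
#'
#' Describes the generative model for one joint: a steady-state centre, an
#' exponential initialization transient `a * exp(-b * t)` per axis, optional
#' step switches between steady value ranges, Gaussian frame noise, and a
#' run-level constant offset emulating run-to-run variation of stochastic
#' processing modes.
#'
#' @param joint Joint name (must exist in [joint_table()]).
#' @param steady_center Length-3 numeric, steady-state position (mm).
#' @param transient_amplitude Length-3 numeric `a` (mm); 0 disables the
#'   transient on that axis.
#' @param transient_rate Length-3 numeric `b` (per frame, > 0 wherever the
#'   amplitude is non-zero). The transient half-life is `ln(2)/b` frames.
#' @param noise_sd Length-3 non-negative numeric, per-frame Gaussian noise SD (mm).
#' @param switch_schedule List of `list(frame =, step =)` entries; from
#'   `frame` on, `step` (length-3 mm) is added cumulatively. May be empty.
#' @param per_run_jitter_sd Scalar >= 0 (mm); SD of the per-run constant
#'   offset. 0 emulates a deterministic processing mode (no run-level shift).
#' @return Object of class `joint_gen_config`.
#' @export
joint_gen_config <- function(joint, steady_center,
                             transient_amplitude = c(0, 0, 0),
                             transient_rate = c(0.1, 0.1, 0.1),
                             noise_sd = c(0, 0, 0),
                             switch_schedule = list(),
                             per_run_jitter_sd = 0) {
  stopifnot(joint %in% joint_table()$name,
            length(steady_center) == 3L, all(is.finite(steady_center)),
            length(transient_amplitude) == 3L, length(transient_rate) == 3L,
            length(noise_sd) == 3L, all(noise_sd >= 0),
            per_run_jitter_sd >= 0)
  if (any(transient_amplitude != 0 & transient_rate <= 0))
    stop("transient_rate must be > 0 wherever transient_amplitude is non-zero")
  for (sw in switch_schedule)
    stopifnot(is.list(sw), !is.null(sw$frame), length(sw$step) == 3L)
  structure(
    list(joint = joint, steady_center = as.numeric(steady_center),
         transient_amplitude = as.numeric(transient_amplitude),
         transient_rate = as.numeric(transient_rate),
         noise_sd = as.numeric(noise_sd),
         switch_schedule = switch_schedule,
         per_run_jitter_sd = per_run_jitter_sd),
    class = "joint_gen_config"
  )
}

#' Run-set generator configuration
#'
#' @param n_runs Number of runs (>= 1).
#' @param n_frames Frames per run (>= 2).
#' @param fps Frames per second (default 30).
#' @param seed Base seed; a fixed seed makes the output bit-identical across
#'   calls. Sub-streams are derived per (run, joint, axis), so adding runs
#'   never perturbs earlier runs.
#' @param joint_configs List of [joint_gen_config()] (one per joint).
#' @param skeleton_scale_sd Log-scale SD of a global per-frame similarity
#'   rescaling applied about the PELVIS (dimensionless; 0 disables). Emulates
#'   frame-to-frame rescaling of the whole skeleton with preserved bone-length
#'   ratios.
#' @param shared_noise When TRUE, the frame-noise and scale-wobble streams are
#'   shared across runs; together with `per_run_jitter_sd = 0` this makes all
#'   runs identical, emulating a deterministic processing mode.
#' @param mode_label,machine_label Labels stamped on the generated run set.
#' @return Object of class `runset_gen_config`.
#' @export
runset_gen_config <- function(n_runs, n_frames, fps = 30, seed = 1L,
                              joint_configs, skeleton_scale_sd = 0,
                              shared_noise = FALSE,
                              mode_label = "SYNTH", machine_label = "A") {
  stopifnot(n_runs >= 1, n_frames >= 2, fps > 0, skeleton_scale_sd >= 0,
            length(joint_configs) >= 1)
  if (!all(vapply(joint_configs, inherits, logical(1), "joint_gen_config")))
    stop("joint_configs must be a list of joint_gen_config objects")
  joints <- vapply(joint_configs, `[[`, character(1), "joint")
  if (anyDuplicated(joints)) stop("duplicate joints in joint_configs")
  for (jc in joint_configs)
    for (sw in jc$switch_schedule)
      if (sw$frame < 1 || sw$frame > n_frames)
        stop("switch frame outside the series for joint ", jc$joint)
  if (skeleton_scale_sd > 0 && !"PELVIS" %in% joints)
    stop("skeleton_scale_sd > 0 requires a PELVIS joint config (scaling pivot)")
  names(joint_configs) <- joints
  structure(
    list(n_runs = as.integer(n_runs), n_frames = as.integer(n_frames),
         fps = fps, seed = as.integer(seed), joint_configs = joint_configs,
         skeleton_scale_sd = skeleton_scale_sd, shared_noise = shared_noise,
         mode_label = mode_label, machine_label = machine_label),
    class = "runset_gen_config"
  )
}

# deterministic sub-stream seed below 2^31, exact in double arithmetic
substream_seed <- function(base, run, joint_idx, axis) {
  m <- 2147483647
  s <- (as.double(base) %% m)
  s <- (s * 69069 + run * 100003 + joint_idx * 1009 + axis * 97 + 17) %% m
  as.integer(s)
}

rnorm_stream <- function(seed, n, sd) {
  if (sd == 0) return(numeric(n))
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}

#' Generate a synthetic run set
#'
#' Per run, joint and axis the position series is
#' `steady_center + a * exp(-b * t) + cumulative switch steps +
#' N(0, noise_sd) + run offset`, followed by a global per-frame similarity
#' rescaling about the PELVIS with log-normal scale factors
#' (`skeleton_scale_sd`). With `shared_noise = TRUE` and zero per-run jitter
#' all runs are byte-identical.
#'
#' @param config A [runset_gen_config()].
#' @return A [runset()].
#' @export
generate_runset <- function(config) {
  stopifnot(inherits(config, "runset_gen_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  nf <- config$n_frames
  t <- seq_len(nf)
  joints <- names(config$joint_configs)
  runs <- lapply(seq_len(config$n_runs), function(r) {
    noise_run_tag <- if (config$shared_noise) 0L else r
    xyz <- array(NA_real_, dim = c(nf, 3L, length(joints)),
                 dimnames = list(NULL, c("x", "y", "z"), joints))
    for (ji in seq_along(joints)) {
      jc <- config$joint_configs[[ji]]
      offset <- if (jc$per_run_jitter_sd > 0)
        rnorm_stream(substream_seed(config$seed, r, ji, 0L), 3L,
                     jc$per_run_jitter_sd)
      else numeric(3)
      for (ax in 1:3) {
        base <- jc$steady_center[ax] +
          jc$transient_amplitude[ax] * exp(-jc$transient_rate[ax] * t)
        for (sw in jc$switch_schedule)
          base[t >= sw$frame] <- base[t >= sw$frame] + sw$step[ax]
        noise <- rnorm_stream(
          substream_seed(config$seed, noise_run_tag, ji, ax),
          nf, jc$noise_sd[ax]
        )
        xyz[, ax, ji] <- base + noise + offset[ax]
      }
    }
    if (config$skeleton_scale_sd > 0) {
      s <- exp(rnorm_stream(
        substream_seed(config$seed, noise_run_tag, 0L, 4L),
        nf, config$skeleton_scale_sd
      ))
      pelvis <- xyz[, , "PELVIS", drop = TRUE]
      for (ji in seq_along(joints)) {
        if (joints[ji] == "PELVIS") next
        xyz[, , ji] <- pelvis + s * (xyz[, , ji, drop = TRUE] - pelvis)
      }
    }
    bt_run(r, xyz)
  })
  runset(runs, mode_label = config$mode_label,
         machine_label = config$machine_label, fps = config$fps)
}

# nominal mannequin skeleton, mm, camera coordinates (x right, y down,
# z forward), subject ~1.9 m from the camera, camera ~1 m above the floor
preset_skeleton_centers <- function() {
  list(
    PELVIS         = c(0, 100, 1900),
    SPINE_NAVEL    = c(0, -50, 1895),
    SPINE_CHEST    = c(0, -200, 1890),
    NECK           = c(0, -380, 1885),
    SHOULDER_LEFT  = c(-180, -350, 1890),
    ELBOW_LEFT     = c(-225, -90, 1895),
    WRIST_LEFT     = c(-245, 140, 1885),
    SHOULDER_RIGHT = c(180, -350, 1890),
    ELBOW_RIGHT    = c(225, -90, 1895),
    WRIST_RIGHT    = c(245, 140, 1885),
    HIP_LEFT       = c(-90, 110, 1900),
    KNEE_LEFT      = c(-100, 490, 1910),
    ANKLE_LEFT     = c(-105, 870, 1925),
    FOOT_LEFT      = c(-105, 935, 1800),
    HIP_RIGHT      = c(90, 110, 1900),
    KNEE_RIGHT     = c(100, 490, 1910),
    ANKLE_RIGHT    = c(105, 870, 1925),
    FOOT_RIGHT     = c(105, 935, 1800)
  )
}

#' Study-like generator preset
#'
#' A documented preset emulating the reference study's conditions: 100 runs of
#' a 30-s, 30-FPS recording (900 frames) of a static subject, all 18 included
#' joints. Trunk joints carry small frame noise (0.3 mm SD), elbows/knees
#' intermediate (1 mm), wrists/ankles/feet large (3 mm); initialization
#' transients span half-life-based durations from about 2 to 360 frames across
#' joints and axes; optionally FOOT_LEFT switches its z steady range by
#' +60 mm mid-recording. `stochastic = FALSE` emulates a deterministic
#' processing mode (shared noise stream, no per-run jitter: all runs
#' identical); `stochastic = TRUE` adds run-level offsets (0.5 / 1.5 / 4 mm SD
#' for trunk / intermediate / outer joints) and independent noise per run.
#' A global per-frame scale wobble (log-SD 0.002) emulates whole-skeleton
#' rescaling with preserved bone-length ratios.
#'
#' @param seed Base seed.
#' @param stochastic Emulate a stochastic (TRUE) or deterministic (FALSE) mode.
#' @param n_runs,n_frames,fps Override the study-scale defaults.
#' @param foot_switch Include the FOOT_LEFT z-switch (default TRUE).
#' @return A [runset_gen_config()].
#' @export
preset_study_like <- function(seed = 1L, stochastic = TRUE,
                              n_runs = 100L, n_frames = 900L, fps = 30,
                              foot_switch = TRUE) {
  joints <- included_joints()
  trunk <- c("PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK",
             "SHOULDER_LEFT", "SHOULDER_RIGHT", "HIP_LEFT", "HIP_RIGHT")
  mid <- c("ELBOW_LEFT", "ELBOW_RIGHT", "KNEE_LEFT", "KNEE_RIGHT")
  centers <- preset_skeleton_centers()
  # transient durations (4 half-lives) log-spaced over 2..360 frames across
  # the 18 x 3 joint/axis combinations
  dur <- exp(seq(log(2), log(360), length.out = 3L * length(joints)))
  amp_sign <- rep_len(c(1, -1), 3L * length(joints))
  jcs <- vector("list", length(joints))
  for (ji in seq_along(joints)) {
    j <- joints[ji]
    grp <- if (j %in% trunk) "trunk" else if (j %in% mid) "mid" else "outer"
    noise <- switch(grp, trunk = 0.3, mid = 1.0, outer = 3.0)
    jitter <- if (!stochastic) 0 else switch(grp, trunk = 0.5, mid = 1.5, outer = 4.0)
    amp <- switch(grp, trunk = 10, mid = 25, outer = 50)
    k <- (ji - 1L) * 3L + 1:3
    b <- 4 * log(2) / dur[k]
    sw <- list()
    if (foot_switch && j == "FOOT_LEFT")
      sw <- list(list(frame = as.integer(ceiling(n_frames / 2)),
                      step = c(0, 0, 60)))
    jcs[[ji]] <- joint_gen_config(
      joint = j, steady_center = centers[[j]],
      transient_amplitude = amp_sign[k] * amp,
      transient_rate = b, noise_sd = rep(noise, 3),
      switch_schedule = sw, per_run_jitter_sd = jitter
    )
  }
  runset_gen_config(
    n_runs = n_runs, n_frames = n_frames, fps = fps, seed = seed,
    joint_configs = jcs, skeleton_scale_sd = 0.002,
    shared_noise = !stochastic,
    mode_label = if (stochastic) "SYNTH_STOCHASTIC" else "SYNTH_DETERMINISTIC"
  )
}

#' Read a generator configuration from JSON
#'
#' Mirrors [runset_gen_config()]: top-level fields `n_runs`, `n_frames`,
#' `fps`, `seed`, `skeleton_scale_sd`, `shared_noise`, labels, and a
#' `joint_configs` array of [joint_gen_config()] fields.
#'
#' @param path JSON file path.
#' @return A [runset_gen_config()].
#' @export
read_gen_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  jcs <- lapply(doc$joint_configs, function(d) {
    joint_gen_config(
      joint = d$joint, steady_center = unlist(d$steady_center),
      transient_amplitude = if (!is.null(d$transient_amplitude))
        unlist(d$transient_amplitude) else c(0, 0, 0),
      transient_rate = if (!is.null(d$transient_rate))
        unlist(d$transient_rate) else c(0.1, 0.1, 0.1),
      noise_sd = if (!is.null(d$noise_sd)) unlist(d$noise_sd) else c(0, 0, 0),
      switch_schedule = if (!is.null(d$switch_schedule))
        lapply(d$switch_schedule, function(s)
          list(frame = s$frame, step = unlist(s$step))) else list(),
      per_run_jitter_sd = if (!is.null(d$per_run_jitter_sd))
        d$per_run_jitter_sd else 0
    )
  })
  runset_gen_config(
    n_runs = doc$n_runs, n_frames = doc$n_frames,
    fps = if (!is.null(doc$fps)) doc$fps else 30,
    seed = if (!is.null(doc$seed)) doc$seed else 1L,
    joint_configs = jcs,
    skeleton_scale_sd = if (!is.null(doc$skeleton_scale_sd))
      doc$skeleton_scale_sd else 0,
    shared_noise = isTRUE(doc$shared_noise),
    mode_label = if (!is.null(doc$mode_label)) doc$mode_label else "SYNTH",
    machine_label = if (!is.null(doc$machine_label)) doc$machine_label else "A"
  )
}
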