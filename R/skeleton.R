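#' Joint taxonomy of the 32-joint body-tracking skeleton
#'
#' The body-tracking SDK estimates 32 joints per body. Analyses are restricted
#' by default to the 18 main joints that are reliably recognized (trunk,
#' shoulders, arms to the wrist, legs to the foot); hands, face and clavicles
#' are parsed from input files but dropped before analysis.
#'
#' @return A data.frame with columns `name` (joint label), `index` (0-based
#'   position in the SDK joint array) and `included` (logical, whether the
#'   joint takes part in analyses by default). Exactly 18 joints are included.
#' @export
#' @examples
#' jt <- joint_table()
#' sum(jt$included)  # 18
joint_table <- function() {
  names32 <- c(
    "PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK",
    "CLAVICLE_LEFT", "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
    "HAND_LEFT", "HANDTIP_LEFT", "THUMB_LEFT",
    "CLAVICLE_RIGHT", "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
    "HAND_RIGHT", "HANDTIP_RIGHT", "THUMB_RIGHT",
    "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
    "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT",
    "HEAD", "NOSE", "EYE_LEFT", "EAR_LEFT", "EYE_RIGHT", "EAR_RIGHT"
  )
  included <- c(
    "PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK",
    "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
    "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
    "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
    "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT"
  )
  data.frame(
    name = names32,
    index = seq_along(names32) - 1L,
    included = names32 %in% included,
    stringsAsFactors = FALSE
  )
}

#' Names of the joints included in analyses
#'
#' @return Character vector of the 18 included joint names, in SDK order.
#' @export
included_joints <- function() {
  jt <- joint_table()
  jt$name[jt$included]
}

#' Default bone table
#'
#' Extremity bones plus a trunk segment, each defined by a start and an end
#' joint whose per-frame Euclidean distance is the bone length. The default
#' covers upper arms, forearms, thighs, shanks and feet on both sides, and a
#' Torso segment from PELVIS to NECK. Callers may supply their own table with
#' the same columns anywhere a `bone_table` argument is accepted.
#'
#' @return data.frame with columns `bone`, `start_joint`, `end_joint`
#'   (11 rows); every endpoint is an included joint.
#' @export
default_bone_table <- function() {
  tab <- data.frame(
    bone = c(
      "UpperArm_L", "UpperArm_R", "Forearm_L", "Forearm_R",
      "Thigh_L", "Thigh_R", "Shank_L", "Shank_R",
      "Foot_L", "Foot_R", "Torso"
    ),
    start_joint = c(
      "SHOULDER_LEFT", "SHOULDER_RIGHT", "ELBOW_LEFT", "ELBOW_RIGHT",
      "HIP_LEFT", "HIP_RIGHT", "KNEE_LEFT", "KNEE_RIGHT",
      "ANKLE_LEFT", "ANKLE_RIGHT", "PELVIS"
    ),
    end_joint = c(
      "ELBOW_LEFT", "ELBOW_RIGHT", "WRIST_LEFT", "WRIST_RIGHT",
      "KNEE_LEFT", "KNEE_RIGHT", "ANKLE_LEFT", "ANKLE_RIGHT",
      "FOOT_LEFT", "FOOT_RIGHT", "NECK"
    ),
    stringsAsFactors = FALSE
  )
  validate_bone_table(tab)
  tab
}

validate_bone_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("bone", "start_joint", "end_joint") %in% names(tab)))
  if (any(tab$start_joint == tab$end_joint))
    stop("bone table has a bone whose start and end joint coincide")
  known <- joint_table()$name
  bad <- setdiff(c(tab$start_joint, tab$end_joint), known)
  if (length(bad))
    stop("bone table references unknown joints: ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$bone))
    stop("duplicate bone names in bone table")
  invisible(tab)
}

#' Construct a single body-tracking run
#'
#' @param run_id Integer identifier (1-based).
#' @param xyz Numeric array `n_frames x 3 x n_joints`, millimetres, in the
#'   depth camera's coordinate system (x right, y down, z forward). The third
#'   dimension must carry joint names as dimnames.
#' @param gaps Integer vector of file-order frame positions in which no body
#'   was tracked (informational; such frames carry no positions).
#' @return Object of class `bt_run`.
#' @export
bt_run <- function(run_id, xyz, gaps = integer()) {
  stopifnot(is.numeric(run_id), length(run_id) == 1L)
  if (!is.array(xyz) || length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stop("xyz must be an n_frames x 3 x n_joints array")
  if (is.null(dimnames(xyz)[[3]]))
    stop("xyz must carry joint names on its third dimension")
  if (!all(is.finite(xyz)))
    stop("non-finite joint positions in run ", run_id)
  structure(
    list(run_id = as.integer(run_id), xyz = xyz, gaps = as.integer(gaps)),
    class = "bt_run"
  )
}

#' Construct a run set
#'
#' A run set holds every run of one condition: the same recording processed
#' repeatedly under one processing-mode label on one machine. All runs must
#' share frame count and joint set.
#'
#' @param runs List of [bt_run()] objects.
#' @param mode_label Processing-mode label (e.g. "CPU", "CUDA").
#' @param machine_label Machine label (e.g. "A").
#' @param fps Frames per second of the underlying recording (default 30).
#' @param frames Optional integer vector of 1-based frame indices; defaults to
#'   `1:n_frames`. Kept explicit so windowed subsets retain original indices.
#' @return Object of class `runset`.
#' @export
runset <- function(runs, mode_label = "", machine_label = "", fps = 30,
                   frames = NULL) {
  if (!length(runs)) stop("a run set needs at least one run")
  if (!all(vapply(runs, inherits, logical(1), "bt_run")))
    stop("runs must be a list of bt_run objects")
  if (fps <= 0) stop("fps must be positive")
  dims <- vapply(runs, function(r) dim(r$xyz)[1], integer(1))
  if (length(unique(dims)) != 1L)
    stop("runs have differing frame counts: ", paste(unique(dims), collapse = ", "))
  jsets <- lapply(runs, function(r) dimnames(r$xyz)[[3]])
  if (length(unique(vapply(jsets, paste, character(1), collapse = "|"))) != 1L)
    stop("runs have differing joint sets")
  n_frames <- dims[1]
  if (is.null(frames)) frames <- seq_len(n_frames)
  frames <- as.integer(frames)
  if (length(frames) != n_frames || is.unsorted(frames, strictly = TRUE))
    stop("frames must be strictly increasing and match the frame count")
  structure(
    list(
      mode_label = mode_label, machine_label = machine_label,
      fps = fps, frames = frames, joints = jsets[[1]], runs = runs
    ),
    class = "runset"
  )
}

#' @export
print.runset <- function(x, ...) {
  cat(sprintf(
    "<runset> mode=%s machine=%s: %d runs, %d frames (%d..%d @ %g FPS), %d joints\n",
    if (nzchar(x$mode_label)) x$mode_label else "?",
    if (nzchar(x$machine_label)) x$machine_label else "?",
    length(x$runs), length(x$frames),
    min(x$frames), max(x$frames), x$fps, length(x$joints)
  ))
  invisible(x)
}

#' @rdname runset
#' @param x A `runset`.
#' @export
n_runs <- function(x) length(x$runs)

#' @rdname runset
#' @export
n_frames <- function(x) length(x$frames)

#' Extract one joint's trajectory from a run
#'
#' @param run A `bt_run`.
#' @param joint Joint name.
#' @param frames Optional frame labels (used for the `frame` column).
#' @return data.frame with columns frame, x, y, z (millimetres).
#' @export
joint_trajectory <- function(run, joint, frames = NULL) {
  joints <- dimnames(run$xyz)[[3]]
  if (!joint %in% joints) stop("joint not present in run: ", joint)
  m <- run$xyz[, , joint, drop = TRUE]
  if (is.null(frames)) frames <- seq_len(nrow(m))
  data.frame(frame = frames, x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Per-joint, per-axis series across all runs of a set
#'
#' @param rs A `runset`.
#' @param joint Joint name.
#' @param axis One of "x", "y", "z".
#' @return Numeric matrix `n_frames x n_runs`; rownames are frame indices.
#' @export
joint_axis_matrix <- function(rs, joint, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  if (!joint %in% rs$joints) stop("joint not present in run set: ", joint)
  m <- vapply(rs$runs, function(r) r$xyz[, ai, joint],
              numeric(length(rs$frames)))
  m <- matrix(m, nrow = length(rs$frames))
  rownames(m) <- rs$frames
  m
}

# stack one joint across runs: n_frames x 3 x n_runs
joint_run_array <- function(rs, joint) {
  a <- vapply(rs$runs, function(r) r$xyz[, , joint, drop = TRUE],
              matrix(0, length(rs$frames), 3))
  array(a, dim = c(length(rs$frames), 3L, length(rs$runs)))
}
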