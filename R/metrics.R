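#' Five-number summary of a metric
#'
#' Minimum, maximum, mean, median and standard deviation, as reported per
#' joint or bone. The SD uses the sample (n-1) convention by default; a single
#' value yields SD 0 with `sd_defined = FALSE`.
#'
#' @param values Numeric vector (>= 1 finite value).
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return One-row data.frame: `n, min, max, mean, median, sd, sd_defined`.
#' @export
metric_summary <- function(values, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!length(values)) stop("metric_summary requires at least one value")
  if (!all(is.finite(values))) stop("non-finite values in metric_summary input")
  n <- length(values)
  s <- if (n == 1L) 0 else stats::sd(values)
  if (sd_denominator == "n" && n > 1L) s <- s * sqrt((n - 1) / n)
  data.frame(
    n = n, min = min(values), max = max(values), mean = mean(values),
    median = stats::median(values), sd = s, sd_defined = n > 1L
  )
}

#' Run-pairwise Euclidean distances per joint
#'
#' For every frame of the (already windowed) run set, every included joint and
#' every unordered run pair (i < j), the 3-D Euclidean distance between the
#' two runs' positions of that joint. Distances are summarized per joint over
#' all frames and pairs. Identical runs give exactly 0 everywhere. Only
#' unordered pairs are stored; the symmetric double-count changes no summary
#' statistic except trivially the count.
#'
#' @param rs A windowed [runset()] with at least 2 runs.
#' @param joints Optional subset of joints (default: all in the set).
#' @param keep_records Return the full per-(joint, frame, pair) record table
#'   (can be large: frames x pairs x joints rows).
#' @return List with `summary` (per-joint [metric_summary()] plus `joint`),
#'   `max_distance` (overall, mm), `n_pairs`, `n_frames`, and `records`
#'   (data.frame joint, frame, run_i, run_j, distance) when requested.
#' @export
pairwise_distances <- function(rs, joints = NULL, keep_records = FALSE) {
  stopifnot(inherits(rs, "runset"))
  if (length(rs$runs) < 2L)
    stop("pairwise distances require at least 2 runs in the set")
  if (is.null(joints)) joints <- rs$joints
  miss <- setdiff(joints, rs$joints)
  if (length(miss)) stop("joints not in run set: ", paste(miss, collapse = ", "))
  nr <- length(rs$runs)
  pr <- utils::combn(nr, 2L)
  ii <- pr[1, ]; jj <- pr[2, ]
  run_ids <- vapply(rs$runs, `[[`, integer(1), "run_id")
  summ <- vector("list", length(joints))
  recs <- if (keep_records) vector("list", length(joints)) else NULL
  overall_max <- 0
  for (k in seq_along(joints)) {
    a <- joint_run_array(rs, joints[k])          # frames x 3 x runs
    d2 <- (a[, 1, ii] - a[, 1, jj])^2 +
          (a[, 2, ii] - a[, 2, jj])^2 +
          (a[, 3, ii] - a[, 3, jj])^2
    d <- sqrt(d2)                                # frames x pairs
    overall_max <- max(overall_max, d)
    summ[[k]] <- cbind(
      data.frame(joint = joints[k], stringsAsFactors = FALSE),
      metric_summary(as.numeric(d))
    )
    if (keep_records)
      recs[[k]] <- data.frame(
        joint = joints[k],
        frame = rep(rs$frames, times = ncol(pr)),
        run_i = rep(run_ids[ii], each = length(rs$frames)),
        run_j = rep(run_ids[jj], each = length(rs$frames)),
        distance = as.numeric(d), stringsAsFactors = FALSE
      )
  }
  res <- list(
    summary = do.call(rbind, summ), max_distance = overall_max,
    n_pairs = ncol(pr), n_frames = length(rs$frames)
  )
  if (keep_records) res$records <- do.call(rbind, recs)
  res
}

#' Per-frame bone lengths and their stability
#'
#' The length of each bone is the Euclidean distance between its start and end
#' joints, per frame and run; a stable skeleton shows near-constant lengths.
#' Summaries pool frames and runs per bone.
#'
#' @param rs A windowed [runset()].
#' @param bone_table Bone definitions (default [default_bone_table()]).
#' @param keep_records Return the full per-(bone, run, frame) record table.
#' @return List with `summary` (per-bone [metric_summary()] plus `bone`) and
#'   `records` (data.frame bone, run_id, frame, length) when requested.
#' @export
bone_lengths <- function(rs, bone_table = default_bone_table(),
                         keep_records = FALSE) {
  stopifnot(inherits(rs, "runset"))
  validate_bone_table(bone_table)
  miss <- bone_table$bone[!(bone_table$start_joint %in% rs$joints &
                            bone_table$end_joint %in% rs$joints)]
  if (length(miss))
    stop("bone(s) reference joints missing from the run set: ",
         paste(miss, collapse = ", "))
  summ <- vector("list", nrow(bone_table))
  recs <- if (keep_records) vector("list", nrow(bone_table)) else NULL
  for (k in seq_len(nrow(bone_table))) {
    sj <- bone_table$start_joint[k]; ej <- bone_table$end_joint[k]
    lens <- lapply(rs$runs, function(r) {
      d <- r$xyz[, , sj, drop = TRUE] - r$xyz[, , ej, drop = TRUE]
      sqrt(rowSums(d^2))
    })
    all_len <- unlist(lens)
    summ[[k]] <- cbind(
      data.frame(bone = bone_table$bone[k], stringsAsFactors = FALSE),
      metric_summary(all_len)
    )
    if (keep_records)
      recs[[k]] <- data.frame(
        bone = bone_table$bone[k],
        run_id = rep(vapply(rs$runs, `[[`, integer(1), "run_id"),
                     each = length(rs$frames)),
        frame = rep(rs$frames, times = length(rs$runs)),
        length = all_len, stringsAsFactors = FALSE
      )
  }
  res <- list(summary = do.call(rbind, summ))
  if (keep_records) res$records <- do.call(rbind, recs)
  res
}
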