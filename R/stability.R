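# sum of squared deviations of x[i..j] about its mean, via cumulative sums
make_sse <- function(x) {
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  function(i, j) {
    n <- j - i + 1
    s <- c1[j + 1] - c1[i]
    (c2[j + 1] - c2[i]) - s^2 / n
  }
}

#' Robust per-frame noise SD of a series
#'
#' MAD of first differences divided by sqrt(2): insensitive to level shifts
#' and slow drifts, so it estimates the frame noise even when the series
#' switches between steady value ranges.
#'
#' @param x Numeric series.
#' @return Estimated noise SD (same unit as `x`).
#' @export
robust_noise_sd <- function(x) {
  if (length(x) < 3) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

#' Segment a series into steady value ranges
#'
#' Least-squares binary segmentation of the mean: the split minimizing the
#' total within-segment sum of squares is accepted only when the two sides'
#' means differ by more than `jump_threshold`, then both sides are searched
#' recursively (minimum segment length `min_segment`). Adjacent segments whose
#' levels (segment medians) ended up closer than the threshold are merged, so
#' consecutive levels always differ by at least `jump_threshold`.
#'
#' @param series Numeric positions (mm) of one joint/axis.
#' @param frames 1-based frame labels (default `seq_along(series)`).
#' @param min_segment Minimum segment length in frames (default 30, i.e. 1 s
#'   at 30 FPS).
#' @param jump_threshold Minimum level difference (mm) for a switch; default
#'   5 x [robust_noise_sd()] of the series.
#' @return Object of class `segmentation`: `segments` (data.frame
#'   start_frame, end_frame, level), `n_switches`, `switch_frames` (first
#'   frame of each new range), `jump_threshold`, `noise_sd`, `short_series`.
#' @export
segment_steady_ranges <- function(series, frames = seq_along(series),
                                  min_segment = 30, jump_threshold = NULL) {
  stopifnot(length(series) == length(frames), all(is.finite(series)))
  n <- length(series)
  nsd <- robust_noise_sd(series)
  if (is.null(jump_threshold)) jump_threshold <- 5 * nsd
  short <- n < 2 * min_segment
  bounds <- integer(0)
  if (!short) {
    sse <- make_sse(series)
    split_rec <- function(lo, hi) {
      len <- hi - lo + 1
      if (len < 2 * min_segment) return(invisible(NULL))
      cand <- (lo + min_segment - 1):(hi - min_segment)
      cost <- vapply(cand, function(s) sse(lo, s) + sse(s + 1, hi), numeric(1))
      s <- cand[which.min(cost)]
      gap <- abs(mean(series[lo:s]) - mean(series[(s + 1):hi]))
      if (gap <= jump_threshold) return(invisible(NULL))
      bounds <<- c(bounds, s)
      split_rec(lo, s)
      split_rec(s + 1, hi)
    }
    split_rec(1L, n)
  }
  bounds <- sort(bounds)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  levels <- vapply(seq_along(starts), function(k)
    stats::median(series[starts[k]:ends[k]]), numeric(1))
  # merge adjacent segments whose levels are within the threshold
  repeat {
    if (length(starts) < 2L) break
    gaps <- abs(diff(levels))
    if (all(gaps > jump_threshold)) break
    k <- which.min(gaps)
    starts <- starts[-(k + 1L)]
    ends <- ends[-k]
    levels_new <- vapply(seq_along(starts), function(i)
      stats::median(series[starts[i]:ends[i]]), numeric(1))
    levels <- levels_new
  }
  structure(
    list(
      segments = data.frame(
        start_frame = frames[starts], end_frame = frames[ends], level = levels
      ),
      n_switches = length(starts) - 1L,
      switch_frames = if (length(starts) > 1L) frames[starts[-1L]] else integer(0),
      jump_threshold = jump_threshold, noise_sd = nsd, short_series = short
    ),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d segment(s), %d switch(es)%s\n",
              nrow(x$segments), x$n_switches,
              if (x$short_series) " [series shorter than 2 x min_segment]" else ""))
  print(x$segments)
  invisible(x)
}

# majority switching behavior and representative level / switch frame of one
# (joint, axis) series across the runs of a set
set_behavior <- function(rs, joint, axis, min_segment, jump_threshold) {
  m <- joint_axis_matrix(rs, joint, axis)
  segs <- lapply(seq_len(ncol(m)), function(r)
    segment_steady_ranges(m[, r], frames = rs$frames,
                          min_segment = min_segment,
                          jump_threshold = jump_threshold))
  n_sw <- vapply(segs, `[[`, integer(1), "n_switches")
  switching <- sum(n_sw >= 1L) * 2L >= length(segs)  # ties -> switching
  first_switch <- if (any(n_sw >= 1L))
    stats::median(vapply(segs[n_sw >= 1L], function(s)
      as.numeric(s$switch_frames[1L]), numeric(1)))
  else NA_real_
  list(switching = switching, level = stats::median(m),
       first_switch = first_switch)
}

#' Compare two run sets per joint and axis
#'
#' Classifies the cross-set (typically cross-machine) behavior of every
#' (joint, axis) series into one of five categories: `equivalent` (levels and
#' switch timing agree within tolerances), `one_switches` (exactly one set
#' switches steady ranges), `both_switch_different_times` (both switch, median
#' first-switch frames more than `frame_gap` apart), `close_steady_ranges`
#' (neither switches, levels within `level`), `distinct_steady_ranges`
#' (levels further apart). Per-run segmentations are reduced to a set verdict
#' by majority, ties counting as switching (the conservative reading).
#'
#' @param set_a,set_b Windowed [runset()]s sharing joints, fps and window.
#' @param thresholds Named list: `level` (mm, neither-switches levels counting
#'   as "close", default 2), `equiv_level` (mm, levels counting as equal,
#'   default 0.5), `frame_gap` (frames, switch-time agreement, default 60),
#'   `min_segment` (default 30), `jump` (segmentation threshold, mm; NULL =
#'   per-series robust default).
#' @return data.frame with one row per (joint, axis): `joint`, `axis`,
#'   `category`, `level_gap` (mm), `switch_frame_gap` (frames, NA unless both
#'   sets switch).
#' @export
compare_runsets <- function(set_a, set_b,
                            thresholds = list()) {
  stopifnot(inherits(set_a, "runset"), inherits(set_b, "runset"))
  if (!identical(sort(set_a$joints), sort(set_b$joints)))
    stop("run sets have different joint sets")
  if (set_a$fps != set_b$fps) stop("run sets have different fps")
  if (!identical(set_a$frames, set_b$frames))
    stop("run sets have different analysis windows")
  th <- utils::modifyList(
    list(level = 2, equiv_level = 0.5, frame_gap = 60,
         min_segment = 30, jump = NULL),
    thresholds
  )
  axes <- c("x", "y", "z")
  rows <- list()
  for (j in set_a$joints) {
    for (ax in axes) {
      a <- set_behavior(set_a, j, ax, th$min_segment, th$jump)
      b <- set_behavior(set_b, j, ax, th$min_segment, th$jump)
      level_gap <- abs(a$level - b$level)
      frame_gap <- NA_real_
      if (a$switching && b$switching) {
        frame_gap <- abs(a$first_switch - b$first_switch)
        category <- if (frame_gap > th$frame_gap) "both_switch_different_times"
        else if (level_gap <= th$level) "equivalent"
        else "distinct_steady_ranges"
      } else if (xor(a$switching, b$switching)) {
        category <- "one_switches"
      } else {
        category <- if (level_gap <= th$equiv_level) "equivalent"
        else if (level_gap <= th$level) "close_steady_ranges"
        else "distinct_steady_ranges"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, axis = ax, category = category,
        level_gap = level_gap, switch_frame_gap = frame_gap,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
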