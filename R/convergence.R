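#' Half-life of an exponential transient
#'
#' For a transient decaying as `exp(-b * t)` the half-life is `ln(2) / b`
#' frames: the time over which the remaining transient amplitude halves.
#'
#' @param b Decay rate per frame (> 0).
#' @return Half-life in frames.
#' @export
half_life <- function(b) {
  if (!is.numeric(b) || any(b <= 0)) stop("half_life requires b > 0")
  log(2) / b
}

#' Fit an exponential initialization transient
#'
#' Fits `f(t) = a * exp(-b * t) + c` to one joint/axis position series by
#' Levenberg-Marquardt nonlinear least squares with `b` constrained positive,
#' using a documented multi-start schedule (`c0` = median of the last 20% of
#' frames, `a0` = first value minus `c0`, `b0` in 0.1, 0.01, 0.05, 0.5).
#' A series is classified `no_transient` when the fitted amplitude is smaller
#' than `amp_k` times the residual SD of a constant fit, or when the fit does
#' not beat the constant fit's RMSE by the relative margin `rmse_margin`.
#' `fit_failed` is returned when no start converges.
#'
#' @param series Numeric vector of positions (mm).
#' @param frames 1-based frame indices (default `seq_along(series)`).
#' @param amp_k Amplitude threshold multiplier (default 2).
#' @param rmse_margin Required relative RMSE improvement over the constant fit
#'   (default 0.05).
#' @return Object of class `convergence_fit`: list with `a`, `b`, `c`,
#'   `half_life`, `cutoff` (4 half-lives; 0 for `no_transient`), `status`
#'   (`fitted`, `no_transient` or `fit_failed`) and `rmse` (mm).
#' @export
fit_exponential <- function(series, frames = seq_along(series),
                            amp_k = 2, rmse_margin = 0.05) {
  if (length(series) < 8) stop("need at least 8 frames to fit a transient")
  if (!all(is.finite(series))) stop("non-finite values in series")
  if (length(frames) != length(series)) stop("frames/series length mismatch")
  n <- length(series)
  c_const <- mean(series)
  rmse_const <- sqrt(mean((series - c_const)^2))

  out <- function(a, b, c, status, rmse) {
    hl <- if (identical(status, "fitted")) log(2) / b else NA_real_
    structure(
      list(a = a, b = b, c = c, half_life = hl,
           cutoff = if (identical(status, "fitted")) 4 * hl else 0,
           status = status, rmse = rmse),
      class = "convergence_fit"
    )
  }

  # numerically flat series: nothing to fit
  scale <- max(abs(series), 1)
  if (rmse_const <= 1e-10 * scale)
    return(out(0, NA_real_, c_const, "no_transient", rmse_const))

  tail_n <- max(1L, ceiling(0.2 * n))
  c0 <- stats::median(series[(n - tail_n + 1L):n])
  a0 <- series[1] - c0
  if (a0 == 0) a0 <- rmse_const
  dat <- data.frame(y = series, t = frames)
  best <- NULL
  for (b0 in c(0.1, 0.01, 0.05, 0.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-b * t) + c, data = dat,
        start = list(a = a0, b = b0, c = c0),
        lower = c(a = -Inf, b = 1e-6, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best))
    return(out(NA_real_, NA_real_, NA_real_, "fit_failed", NA_real_))
  cf <- best$coef
  rmse_fit <- sqrt(best$rss / n)
  if (abs(cf[["a"]]) < amp_k * rmse_const ||
      rmse_fit > (1 - rmse_margin) * rmse_const)
    return(out(cf[["a"]], cf[["b"]], cf[["c"]], "no_transient", rmse_fit))
  out(cf[["a"]], cf[["b"]], cf[["c"]], "fitted", rmse_fit)
}

#' @export
print.convergence_fit <- function(x, ...) {
  cat(sprintf("<convergence_fit> status=%s", x$status))
  if (identical(x$status, "fitted"))
    cat(sprintf(": a=%.3f mm, b=%.5f /frame, c=%.3f mm, T1/2=%.2f, cutoff=%.2f frames",
                x$a, x$b, x$c, x$half_life, x$cutoff))
  cat(sprintf(" (rmse=%.4g mm)\n", x$rmse))
  invisible(x)
}

#' Convergence cutoff of a fitted transient
#'
#' Four half-lives after the start the remaining transient amplitude is
#' 2^-4 = 6.25% of `a`, i.e. the transient is 93.75% complete; that frame is
#' taken as the boundary between convergence and noise.
#'
#' @param fit A `convergence_fit` with status `fitted`.
#' @return Cutoff in frames (4 half-lives).
#' @export
convergence_cutoff <- function(fit) {
  stopifnot(inherits(fit, "convergence_fit"))
  if (!identical(fit$status, "fitted"))
    stop("convergence_cutoff requires a fit with status 'fitted'")
  4 * fit$half_life
}

#' Fit transients for every run, joint and axis of a run set
#'
#' @param rs A [runset()].
#' @param ... Passed to [fit_exponential()].
#' @return data.frame with one row per (run, joint, axis): columns `mode`,
#'   `machine`, `run_id`, `joint`, `axis`, `a`, `b`, `c`, `half_life`,
#'   `cutoff`, `status`, `rmse`.
#' @export
fit_runset_transients <- function(rs, ...) {
  stopifnot(inherits(rs, "runset"))
  axes <- c("x", "y", "z")
  rows <- list()
  for (r in rs$runs) {
    for (j in rs$joints) {
      for (ai in 1:3) {
        f <- fit_exponential(r$xyz[, ai, j], frames = rs$frames, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          mode = rs$mode_label, machine = rs$machine_label,
          run_id = r$run_id, joint = j, axis = axes[ai],
          a = f$a, b = f$b, c = f$c, half_life = f$half_life,
          cutoff = f$cutoff, status = f$status, rmse = f$rmse,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate per-fit cutoffs into an overall cutoff frame
#'
#' Within each (joint, axis, mode) cell the mean cutoff over runs is taken
#' (`no_transient` fits contribute cutoff 0; `fit_failed` fits are excluded
#' and counted). The overall cutoff frame is the chosen quantile over the cell
#' means (linear interpolation between order statistics, `stats::quantile`
#' type 7), rounded up to an integer frame.
#'
#' @param fits data.frame as returned by [fit_runset_transients()] (columns
#'   `joint`, `axis`, `cutoff`, `status`; optional `mode`).
#' @param quantile_level Quantile over cell means (default 0.85).
#' @param fps When given, a frame-discard recommendation
#'   ([recommend_discard()]) is included.
#' @return Object of class `cutoff_summary`: `cell_means` (data.frame),
#'   `overall_quantile_frame`, `quantile_level`, `n_fit_failed`, and
#'   `discard_frames` when `fps` was supplied.
#' @export
aggregate_cutoffs <- function(fits, quantile_level = 0.85, fps = NULL) {
  stopifnot(is.data.frame(fits),
            all(c("joint", "axis", "cutoff", "status") %in% names(fits)),
            quantile_level > 0, quantile_level <= 1)
  if (!"mode" %in% names(fits)) fits$mode <- ""
  n_failed <- sum(fits$status == "fit_failed")
  ok <- fits[fits$status != "fit_failed", , drop = FALSE]
  if (!nrow(ok)) stop("all fits failed; nothing to aggregate")
  cell_means <- stats::aggregate(
    cutoff ~ joint + axis + mode, data = ok, FUN = mean
  )
  names(cell_means)[names(cell_means) == "cutoff"] <- "mean_cutoff"
  q <- stats::quantile(cell_means$mean_cutoff, probs = quantile_level,
                       type = 7, names = FALSE)
  overall <- as.integer(ceiling(q))
  res <- list(
    cell_means = cell_means,
    overall_quantile_frame = overall,
    quantile_level = quantile_level,
    n_fit_failed = n_failed
  )
  if (!is.null(fps)) res$discard_frames <- recommend_discard(overall, fps)
  structure(res, class = "cutoff_summary")
}

#' @export
print.cutoff_summary <- function(x, ...) {
  cat(sprintf(
    "<cutoff_summary> %d (joint, axis, mode) cells; %g%%-quantile frame = %d%s%s\n",
    nrow(x$cell_means), 100 * x$quantile_level, x$overall_quantile_frame,
    if (!is.null(x$discard_frames))
      sprintf("; recommended discard = %d frames", x$discard_frames) else "",
    if (x$n_fit_failed > 0)
      sprintf(" (%d fits failed and were excluded)", x$n_fit_failed) else ""
  ))
  invisible(x)
}

#' Round a cutoff frame up to the next full second
#'
#' @param overall_frame Overall cutoff frame (>= 0).
#' @param fps Frames per second (> 0).
#' @return Smallest multiple of `fps` that is >= `overall_frame`; e.g. frame
#'   55 at 30 FPS rounds up to frame 60 (2 s).
#' @export
recommend_discard <- function(overall_frame, fps) {
  stopifnot(overall_frame >= 0, fps > 0)
  as.integer(fps * ceiling(overall_frame / fps))
}

#' Restrict a run set to its post-transient analysis window
#'
#' @param rs A [runset()].
#' @param discard_frames Number of leading frames to drop (the analysis window
#'   is `discard_frames + 1` to the last frame, 1-based inclusive).
#' @return Windowed [runset()]; frame indices keep their original labels.
#' @export
apply_window <- function(rs, discard_frames) {
  stopifnot(inherits(rs, "runset"), discard_frames >= 0)
  if (discard_frames == 0) return(rs)
  keep <- rs$frames > (min(rs$frames) - 1L + discard_frames)
  if (!any(keep)) stop("discarding ", discard_frames, " frames empties the series")
  runs <- lapply(rs$runs, function(r)
    bt_run(r$run_id, r$xyz[keep, , , drop = FALSE], gaps = r$gaps))
  runset(runs, mode_label = rs$mode_label, machine_label = rs$machine_label,
         fps = rs$fps, frames = rs$frames[keep])
}
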