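#' Assemble an analysis report bundle
#'
#' Collects the per-mode results of a full analysis (convergence summary,
#' ellipsoid volumes, pairwise distances, bone lengths) plus optional
#' cross-set verdicts into one machine-readable structure with a plain-text
#' narrative. A mode is flagged `reproducible` when all its run-pairwise
#' Euclidean distances are exactly 0 mm.
#'
#' @param mode_results Named list (one entry per processing-mode label), each
#'   a list that may contain `convergence` (a `cutoff_summary`), `volumes`
#'   (from [ellipsoid_volumes()]), `distances` (from [pairwise_distances()]),
#'   `bones` (from [bone_lengths()]).
#' @param verdicts Optional data.frame from [compare_runsets()].
#' @param discard_frames Optional recommended discard (frames).
#' @return Object of class `kinrepro_report`.
#' @export
build_report <- function(mode_results, verdicts = NULL, discard_frames = NULL) {
  if (!length(mode_results)) stop("build_report needs at least one result")
  if (is.null(names(mode_results)) || any(!nzchar(names(mode_results))))
    stop("mode_results must be a named list (one entry per mode label)")
  modes <- lapply(names(mode_results), function(lab) {
    mr <- mode_results[[lab]]
    reproducible <- if (!is.null(mr$distances))
      mr$distances$max_distance == 0 else NA
    list(
      mode = lab,
      reproducible = reproducible,
      max_pairwise_distance_mm = if (!is.null(mr$distances))
        mr$distances$max_distance else NULL,
      distance_summary = if (!is.null(mr$distances)) mr$distances$summary else NULL,
      volume_summary = if (!is.null(mr$volumes)) mr$volumes$summary else NULL,
      bone_summary = if (!is.null(mr$bones)) mr$bones$summary else NULL,
      convergence = if (!is.null(mr$convergence)) list(
        overall_quantile_frame = mr$convergence$overall_quantile_frame,
        quantile_level = mr$convergence$quantile_level,
        discard_frames = mr$convergence$discard_frames,
        n_fit_failed = mr$convergence$n_fit_failed
      ) else NULL
    )
  })
  names(modes) <- names(mode_results)

  lines <- c("Body-tracking reproducibility report", "")
  if (!is.null(discard_frames))
    lines <- c(lines, sprintf(
      "Recommended discard: first %d frames (analysis window starts at frame %d).",
      discard_frames, discard_frames + 1L))
  for (m in modes) {
    flag <- if (isTRUE(m$reproducible)) "reproducible"
    else if (isFALSE(m$reproducible)) "non-reproducible" else "not assessed"
    extra <- if (isFALSE(m$reproducible))
      sprintf(" (max pairwise distance %.1f mm)", m$max_pairwise_distance_mm)
    else ""
    lines <- c(lines, sprintf("Mode %s: %s%s", m$mode, flag, extra))
  }
  if (!is.null(verdicts)) {
    cnt <- table(verdicts$category)
    lines <- c(lines, "",
               sprintf("Cross-set comparison over %d (joint, axis) series:",
                       nrow(verdicts)),
               sprintf("  %s: %d", names(cnt), as.integer(cnt)))
  }
  structure(
    list(modes = modes, verdicts = verdicts,
         discard_frames = discard_frames, narrative = lines),
    class = "kinrepro_report"
  )
}

#' @export
print.kinrepro_report <- function(x, ...) {
  cat(paste(x$narrative, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (full structure), one CSV per summary table, and
#' `narrative.txt`.
#'
#' @param report A `kinrepro_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "kinrepro_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  paths <- c(paths, p)
  for (lab in names(report$modes)) {
    m <- report$modes[[lab]]
    for (tab in c("distance_summary", "volume_summary", "bone_summary")) {
      if (is.null(m[[tab]])) next
      f <- file.path(dir, sprintf("%s_%s.csv", lab, sub("_summary", "s", tab)))
      data.table::fwrite(m[[tab]], f)
      paths <- c(paths, f)
    }
  }
  if (!is.null(report$verdicts)) {
    f <- file.path(dir, "verdicts.csv")
    data.table::fwrite(report$verdicts, f)
    paths <- c(paths, f)
  }
  f <- file.path(dir, "narrative.txt")
  writeLines(report$narrative, f)
  paths <- c(paths, f)
  invisible(paths)
}

#' Validate the structure of a report (in memory or re-read from JSON)
#'
#' Structural schema check: required fields, types and per-mode table columns.
#' Accepts either a `kinrepro_report` or the list obtained by re-reading
#' `report.json`.
#'
#' @param report Report object or parsed JSON list.
#' @return TRUE invisibly; otherwise an error describing the first violation.
#' @export
validate_report <- function(report) {
  r <- unclass(report)
  for (f in c("modes", "narrative"))
    if (is.null(r[[f]])) stop("report is missing field '", f, "'")
  if (!length(r$modes)) stop("report has no modes")
  for (lab in names(r$modes)) {
    m <- r$modes[[lab]]
    if (is.null(m$mode)) stop("mode entry '", lab, "' is missing its label")
    if (!is.null(m$distance_summary)) {
      ds <- as.data.frame(do.call(rbind, lapply(
        if (is.data.frame(m$distance_summary)) list(m$distance_summary)
        else m$distance_summary, as.data.frame)))
      need <- c("joint", "min", "max", "mean", "median", "sd")
      miss <- setdiff(need, names(ds))
      if (length(miss))
        stop("mode '", lab, "' distance_summary missing columns: ",
             paste(miss, collapse = ", "))
    }
  }
  if (!is.character(unlist(r$narrative)))
    stop("narrative must be text")
  invisible(TRUE)
}
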