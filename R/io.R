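#' Default schema configuration for the tracking JSON dialect
#'
#' The offline body-tracking processor stores one JSON object per recording:
#' a list of frame records, each carrying the number of tracked bodies and a
#' body list whose entries hold a 32 x 3 joint-position array (millimetres).
#' Field names vary across processor versions, so they are configurable; the
#' default matches the public sample output.
#'
#' @param frames Name of the frame-list field.
#' @param bodies Name of the per-frame body-list field.
#' @param num_bodies Name of the per-frame body-count field.
#' @param positions Name of the per-body joint-position array field.
#' @param joint_names Name of the optional top-level joint-name list; when the
#'   field is absent from a file, the canonical 32-joint SDK order is assumed.
#' @return Named list used by [read_tracking_json()] / [write_tracking_json()].
#' @export
tracking_schema <- function(frames = "frames", bodies = "bodies",
                            num_bodies = "num_bodies",
                            positions = "joint_positions",
                            joint_names = "joint_names") {
  list(frames = frames, bodies = bodies, num_bodies = num_bodies,
       positions = positions, joint_names = joint_names)
}

#' Read one body-tracking run from a processor JSON file
#'
#' Frames are renumbered 1-based in file order. Frames with zero tracked
#' bodies are recorded as gaps (reported in the run's `gaps` field) and carry
#' no positions. Only the included joints of [joint_table()] are retained.
#'
#' @param path Path to the JSON file.
#' @param schema_config Field-name mapping, see [tracking_schema()].
#' @param run_id Run identifier to stamp on the result.
#' @param body_select How to handle frames with more than one tracked body:
#'   `"error"` (default; the reference use case tracks a single static
#'   mannequin) or `"largest"` (keep the body with the largest joint
#'   bounding-box diagonal).
#' @return A [bt_run()] restricted to included joints.
#' @export
read_tracking_json <- function(path, schema_config = tracking_schema(),
                               run_id = 1L,
                               body_select = c("error", "largest")) {
  body_select <- match.arg(body_select)
  if (!file.exists(path)) stop("file does not exist: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sc <- schema_config
  frames <- doc[[sc$frames]]
  if (is.null(frames)) stop("malformed file: no '", sc$frames, "' field in ", path)
  jnames <- if (!is.null(sc$joint_names) && !is.null(doc[[sc$joint_names]]))
    unlist(doc[[sc$joint_names]]) else joint_table()$name
  keep <- included_joints()
  ki <- match(keep, jnames)
  if (anyNA(ki))
    stop("malformed file: joint names do not cover the included joint set")

  pos_list <- vector("list", length(frames))
  gaps <- integer()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    nb <- fr[[sc$num_bodies]]
    if (is.null(nb)) nb <- length(fr[[sc$bodies]])
    if (nb == 0) { gaps <- c(gaps, i); next }
    bodies <- fr[[sc$bodies]]
    if (nb > 1L || length(bodies) > 1L) {
      if (body_select == "error")
        stop("frame ", i, " has ", max(nb, length(bodies)),
             " tracked bodies; expected one (set body_select = 'largest' to override)")
      sizes <- vapply(bodies, function(b) {
        p <- do.call(rbind, lapply(b[[sc$positions]], unlist))
        sqrt(sum((apply(p, 2, max) - apply(p, 2, min))^2))
      }, numeric(1))
      bodies <- bodies[which.max(sizes)]
    }
    p <- bodies[[1]][[sc$positions]]
    if (is.null(p) || length(p) < max(ki))
      stop("malformed file: frame ", i, " is missing joint positions")
    m <- do.call(rbind, lapply(p, function(v) {
      v <- unlist(v)
      if (length(v) != 3L || !all(is.finite(v)))
        stop("malformed file: frame ", i, " has a non-[x,y,z] joint position")
      v
    }))
    pos_list[[i]] <- m[ki, , drop = FALSE]
  }
  pos_list <- pos_list[!vapply(pos_list, is.null, logical(1))]
  if (!length(pos_list)) stop("file contains no tracked frames: ", path)
  xyz <- aperm(
    array(unlist(lapply(pos_list, t)),
          dim = c(3L, length(keep), length(pos_list))),
    c(3L, 1L, 2L)
  )
  dimnames(xyz) <- list(NULL, c("x", "y", "z"), keep)
  bt_run(run_id, xyz, gaps = gaps)
}

#' Write one run in the processor JSON dialect
#'
#' Emits the same dialect [read_tracking_json()] consumes; positions survive a
#' write/read round trip at full double precision. Joints absent from the run
#' (e.g. the excluded face/hand joints) are written as zeros.
#'
#' @param run A [bt_run()].
#' @param path Output path.
#' @param schema_config Field-name mapping, see [tracking_schema()].
#' @export
write_tracking_json <- function(run, path, schema_config = tracking_schema()) {
  stopifnot(inherits(run, "bt_run"))
  sc <- schema_config
  joints <- dimnames(run$xyz)[[3]]
  if (!length(joints)) stop("run has an empty joint set")
  all32 <- joint_table()$name
  idx <- match(joints, all32)
  nfr <- dim(run$xyz)[1]
  frames <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    p <- matrix(0, length(all32), 3L)
    p[idx, ] <- t(run$xyz[i, , ])
    body <- list(body_id = 0L)
    body[[sc$positions]] <- lapply(seq_len(nrow(p)), function(k) p[k, ])
    fr <- list(frame_id = i - 1L)
    fr[[sc$num_bodies]] <- 1L
    fr[[sc$bodies]] <- list(body)
    frames[[i]] <- fr
  }
  doc <- list()
  doc[[sc$joint_names]] <- all32
  doc[[sc$frames]] <- frames
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a run set from a long-format CSV
#'
#' Fallback tabular input: one row per (run, frame, joint) with columns
#' `run_id, frame, joint, x_mm, y_mm, z_mm` (UTF-8, '.' decimal separator).
#'
#' @param path CSV path.
#' @param mode_label,machine_label,fps Run-set metadata.
#' @return A [runset()].
#' @export
read_runs_csv <- function(path, mode_label = "", machine_label = "", fps = 30) {
  dt <- data.table::fread(path)
  need <- c("run_id", "frame", "joint", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("CSV is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(dt, by = c("run_id", "frame", "joint")))
    stop("duplicate (run_id, frame, joint) rows in ", path)
  run_ids <- sort(unique(dt$run_id))
  joints <- unique(dt$joint)
  frames <- sort(unique(dt$frame))
  # every run must cover the full frame x joint grid
  cnt <- table(dt$run_id)
  bad <- names(cnt)[cnt != length(frames) * length(joints)]
  if (length(bad))
    stop("ragged frame/joint coverage for run(s): ", paste(bad, collapse = ", "))
  data.table::setorderv(dt, c("run_id", "joint", "frame"))
  dt <- as.data.frame(dt)
  runs <- lapply(run_ids, function(rid) {
    sub <- dt[dt$run_id == rid, , drop = FALSE]
    xyz <- array(NA_real_, dim = c(length(frames), 3L, length(joints)),
                 dimnames = list(NULL, c("x", "y", "z"), joints))
    for (j in joints) {
      sj <- sub[sub$joint == j, , drop = FALSE]
      if (nrow(sj) != length(frames) || !identical(sort(sj$frame), frames))
        stop("run ", rid, " is missing frames for joint ", j)
      xyz[, , j] <- as.matrix(sj[, c("x_mm", "y_mm", "z_mm")])
    }
    bt_run(rid, xyz)
  })
  runset(runs, mode_label = mode_label, machine_label = machine_label,
         fps = fps, frames = frames)
}

#' Write a run set to a long-format CSV
#'
#' @param rs A [runset()].
#' @param path Output CSV path.
#' @export
write_runs_csv <- function(rs, path) {
  stopifnot(inherits(rs, "runset"))
  tabs <- lapply(rs$runs, function(r) {
    do.call(rbind, lapply(rs$joints, function(j) {
      m <- r$xyz[, , j, drop = TRUE]
      data.table::data.table(
        run_id = r$run_id, frame = rs$frames, joint = j,
        x_mm = m[, 1], y_mm = m[, 2], z_mm = m[, 3]
      )
    }))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read a bone table from CSV
#'
#' Columns: `bone, start_joint, end_joint`. The table replaces
#' [default_bone_table()] verbatim after validation.
#'
#' @param path CSV path.
#' @return Validated bone table data.frame.
#' @export
read_bone_table <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  validate_bone_table(tab)
  tab
}
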