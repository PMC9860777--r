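# latitude-longitude grid on the unit sphere: npts latitudes pole to pole,
# npts longitudes; pole rings collapse to single points
unit_sphere_grid <- function(npts) {
  stopifnot(npts >= 3)
  theta <- seq(-pi / 2, pi / 2, length.out = npts)
  phi <- 2 * pi * (seq_len(npts) - 1L) / npts
  z <- sin(theta)
  r <- cos(theta)
  pts <- list(c(0, 0, -1))
  for (i in 2:(npts - 1L))
    pts[[i]] <- cbind(r[i] * cos(phi), r[i] * sin(phi), z[i])
  pts[[npts]] <- c(0, 0, 1)
  m <- do.call(rbind, pts)
  colnames(m) <- c("x", "y", "z")
  list(points = m, z = z, r = r, m = npts)
}

# Exact convex-hull volume of the unit-sphere grid points. The quad facets of
# the latitude-longitude grid are planar (each band is the convex hull of two
# parallel regular m-gons aligned in longitude), so the hull is a stack of
# prismatoids whose polygonal cross-section interpolates linearly in z:
#   V_band = (m/2) sin(2 pi / m) * (z2 - z1) * (r1^2 + r1 r2 + r2^2) / 3
# with r = 0 at the poles this reduces to the polar pyramid volume.
sphere_grid_hull_volume <- function(npts) {
  g <- unit_sphere_grid(npts)
  m <- g$m
  a <- (m / 2) * sin(2 * pi / m)
  v <- 0
  for (i in seq_len(npts - 1L)) {
    r1 <- g$r[i]; r2 <- g$r[i + 1L]
    v <- v + a * (g$z[i + 1L] - g$z[i]) * (r1^2 + r1 * r2 + r2^2) / 3
  }
  v
}

#' Fit a Gaussian dispersion ellipsoid to a 3-D point cloud
#'
#' The ellipsoid is centred on the componentwise mean with shape given by the
#' sample covariance (denominator n-1 by default): the surface at Mahalanobis
#' distance `sd_multiplier`. A latitude-longitude mesh of the surface is built
#' from an `npts x npts` angular grid (pole duplicates removed) and the volume
#' of the convex hull of the mesh points is reported alongside the closed-form
#' ellipsoid volume `(4/3) pi sd^3 sqrt(det(covariance))`. Because the mesh is
#' an affine image of the unit-sphere grid, the hull volume is computed
#' exactly as `sd^3 sqrt(det(covariance))` times the sphere-grid hull volume;
#' it is always below the closed form and converges to it as `npts` grows.
#'
#' A rank-deficient covariance (e.g. identical points, or fewer than 4
#' non-coplanar points) yields both volumes 0 and `degenerate = TRUE` rather
#' than an error: identical-run sets are a central use case.
#'
#' @param points Numeric `n x 3` matrix of positions (mm), `n >= 2`.
#' @param sd_multiplier Mahalanobis radius of the surface (default 2).
#' @param npts Angular grid resolution (default 20).
#' @param cov_denominator `"n-1"` (sample covariance, default) or `"n"`.
#' @return Object of class `dispersion_ellipsoid`: `center` (mm), `covariance`
#'   (mm^2), `sd_multiplier`, `mesh` (surface points, mm), `hull_volume` and
#'   `analytic_volume` (mm^3), `degenerate` flag.
#' @export
fit_ellipsoid <- function(points, sd_multiplier = 2, npts = 20,
                          cov_denominator = c("n-1", "n")) {
  cov_denominator <- match.arg(cov_denominator)
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points to fit an ellipsoid")
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  stopifnot(sd_multiplier > 0)
  ctr <- colMeans(points)
  S <- stats::cov(points)
  if (cov_denominator == "n")
    S <- S * (nrow(points) - 1) / nrow(points)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  degenerate <- lam[3] <= 1e-12 * max(lam[1], 1e-300)
  grid <- unit_sphere_grid(npts)
  M <- sd_multiplier * eg$vectors %*% diag(sqrt(lam))
  mesh <- sweep(grid$points %*% t(M), 2, ctr, "+")
  colnames(mesh) <- c("x", "y", "z")
  if (degenerate) {
    hull_v <- 0
    analytic_v <- 0
  } else {
    det_fac <- sd_multiplier^3 * sqrt(prod(lam))
    hull_v <- det_fac * sphere_grid_hull_volume(npts)
    analytic_v <- (4 / 3) * pi * det_fac
  }
  structure(
    list(center = ctr, covariance = S, sd_multiplier = sd_multiplier,
         npts = npts, mesh = mesh, hull_volume = hull_v,
         analytic_volume = analytic_v, degenerate = degenerate),
    class = "dispersion_ellipsoid"
  )
}

#' @export
print.dispersion_ellipsoid <- function(x, ...) {
  cat(sprintf(
    "<dispersion_ellipsoid> sd=%g, npts=%d: hull %.4g mm^3, analytic %.4g mm^3%s\n",
    x$sd_multiplier, x$npts, x$hull_volume, x$analytic_volume,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Dispersion-ellipsoid volumes per run and joint
#'
#' Fits one ellipsoid per run and included joint over the (already windowed)
#' frames, and summarizes hull volumes across the runs of the set per joint.
#'
#' @param rs A windowed [runset()].
#' @param sd_multiplier,npts,cov_denominator Passed to [fit_ellipsoid()].
#' @param joints Optional subset of joints (default: all in the set).
#' @return List with `volumes` (data.frame: mode, machine, run_id, joint,
#'   hull_volume_mm3, analytic_volume_mm3, degenerate) and `summary`
#'   (per-joint [metric_summary()] of hull volumes across runs).
#' @export
ellipsoid_volumes <- function(rs, sd_multiplier = 2, npts = 20,
                              cov_denominator = "n-1", joints = NULL) {
  stopifnot(inherits(rs, "runset"))
  if (!length(rs$frames)) stop("empty analysis window")
  if (is.null(joints)) joints <- rs$joints
  miss <- setdiff(joints, rs$joints)
  if (length(miss)) stop("joints not in run set: ", paste(miss, collapse = ", "))
  rows <- vector("list", length(rs$runs) * length(joints))
  k <- 0L
  for (r in rs$runs) {
    for (j in joints) {
      e <- fit_ellipsoid(r$xyz[, , j, drop = TRUE], sd_multiplier, npts,
                         cov_denominator)
      k <- k + 1L
      rows[[k]] <- data.frame(
        mode = rs$mode_label, machine = rs$machine_label,
        run_id = r$run_id, joint = j,
        hull_volume_mm3 = e$hull_volume,
        analytic_volume_mm3 = e$analytic_volume,
        degenerate = e$degenerate, stringsAsFactors = FALSE
      )
    }
  }
  volumes <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(volumes, volumes$joint), function(d) {
    s <- metric_summary(d$hull_volume_mm3)
    cbind(data.frame(joint = d$joint[1], stringsAsFactors = FALSE), s)
  }))
  rownames(summ) <- NULL
  list(volumes = volumes, summary = summ)
}

#' Gaussian mass inside an s-standard-deviation ellipsoid
#'
#' Probability that a standard Gaussian sample of the given dimension has
#' Mahalanobis distance at most `sd_multiplier` (a chi-distribution CDF).
#' At `sd_multiplier = 2` this is 95.45% in 1-D, 86.47% (`1 - e^-2`) in 2-D
#' and 73.85% in 3-D; the commonly quoted "approximately 86.5%" figure for a
#' 2-SD ellipsoid is the 2-D value.
#'
#' @param sd_multiplier Mahalanobis radius (> 0).
#' @param dim Dimension, 1, 2 or 3.
#' @return Probability in `[0, 1]`.
#' @export
coverage_fraction <- function(sd_multiplier, dim) {
  stopifnot(sd_multiplier > 0)
  if (!dim %in% c(1, 2, 3)) stop("dim must be 1, 2 or 3")
  stats::pchisq(sd_multiplier^2, df = dim)
}
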