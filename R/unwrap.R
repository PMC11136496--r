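## Aortic-wall unwrapping. Per-slice ring contours are fitted to the wall
## signal and the wall intensity is projected onto a 2D cartography whose
## X axis is the axial position and whose Y axis is arc length along the
## perimeter, measured from a reference angle (0 deg = ventral / floor line).
## The fit is a discrete closed snake: radial intensity attraction per angular
## node plus circular smoothing of the radius profile (curvature
## regularization), propagated slice to slice.

## Bilinear interpolation of a (ny, nz) matrix at physical points (y_um, z_um)
## with grid origin at voxel (1,1) = (0,0) and spacing (dy, dz).
interp2 <- function(mat, dy, dz, y, z) {
  ny <- nrow(mat); nz <- ncol(mat)
  fy <- y / dy + 1; fz <- z / dz + 1
  fy <- pmin(pmax(fy, 1), ny); fz <- pmin(pmax(fz, 1), nz)
  i0 <- pmin(floor(fy), ny - 1); j0 <- pmin(floor(fz), nz - 1)
  ty <- fy - i0; tz <- fz - j0
  v00 <- mat[cbind(i0, j0)];     v10 <- mat[cbind(i0 + 1, j0)]
  v01 <- mat[cbind(i0, j0 + 1)]; v11 <- mat[cbind(i0 + 1, j0 + 1)]
  v00 * (1 - ty) * (1 - tz) + v10 * ty * (1 - tz) +
    v01 * (1 - ty) * tz + v11 * ty * tz
}

## circular moving average of a periodic profile
smooth_circular <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  xx <- c(x[(n - k + 1):n], x, x[1:k])
  stats::filter(xx, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)[(k + 1):(k + n)]
}

#' Fit per-slice ring contours to a tube wall
#'
#' Starting from a user-supplied circle on the first slice, refines a closed
#' contour on every axial slice by radial search for the wall signal
#' (intensity-weighted centroid along each ray), with circular smoothing of
#' the radius profile and re-centering; each slice is seeded from the previous
#' fit.
#'
#' @param stack a [volume_stack()]; tube axis along x.
#' @param channel channel index carrying the wall signal.
#' @param init_circle list/vector with `y`, `z`, `r` in um: initial circle on
#'   the first slice.
#' @param band_um radial search half-width around the current radius, um.
#' @param n_angles number of angular nodes (default: one per arc step of
#'   `min(spacing)` at the initial radius).
#' @param iters refinement iterations per slice.
#' @param smooth_frac fraction of nodes used as half-width of the circular
#'   smoother.
#' @param slices axial indices to fit (default all).
#' @return A `ring_set`: per-slice centers, contours (closed, as n_angles
#'   points in um), arc-length parameterization and perimeters. If the wall
#'   becomes undetectable mid-stack, a warning is raised and the partial
#'   result returned; an undetectable first slice is an error
#'   (`eht_no_ring`).
#' @export
fit_rings <- function(stack, channel = 1L, init_circle,
                      band_um = 3, n_angles = NULL, iters = 3L,
                      smooth_frac = 0.04, slices = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  ic <- unlist(init_circle)
  if (!all(c("y", "z", "r") %in% names(ic))) {
    eht_stop("eht_config_error", "init_circle must name y, z, r (um)")
  }
  dy <- stack$spacing["y"]; dz <- stack$spacing["z"]
  d <- dim(stack$data)
  ext_y <- (d[1] - 1) * dy; ext_z <- (d[2] - 1) * dz
  if (ic["y"] < 0 || ic["y"] > ext_y || ic["z"] < 0 || ic["z"] > ext_z) {
    eht_stop("eht_config_error", "init_circle center outside the image")
  }
  slices <- slices %||% seq_len(d[3])
  step <- min(dy, dz)
  K <- n_angles %||% max(64L, ceiling(2 * pi * ic["r"] / step))
  theta <- (seq_len(K) - 1) / K * 2 * pi
  ct <- cos(theta); st <- sin(theta)
  rho_off <- seq(-band_um, band_um, by = step / 2)

  centers <- matrix(NA_real_, length(slices), 2)
  contours <- vector("list", length(slices))
  perims <- rep(NA_real_, length(slices))
  cen <- c(ic["y"], ic["z"])
  r_prof <- rep(ic["r"], K)
  fitted <- 0L
  for (si in seq_along(slices)) {
    sl <- vol_slice(stack, slices[si], channel)
    thr <- stats::median(sl) + 4 * stats::mad(sl)
    ok_slice <- TRUE
    cen_i <- cen; r_i <- r_prof
    for (it in seq_len(iters)) {
      ## radial sample grid: K x n_off
      R <- outer(r_i, rho_off, `+`)
      R[R < step] <- step
      Y <- cen_i[1] + R * ct
      Z <- cen_i[2] + R * st
      I <- matrix(interp2(sl, dy, dz, as.vector(Y), as.vector(Z)), K)
      pk <- apply(I, 1, max)
      valid <- pk > thr & pk > 0
      if (!any(valid)) { ok_slice <- FALSE; break }
      W <- I - 0.5 * pk
      W[W < 0] <- 0
      r_new <- rowSums(W * R) / pmax(rowSums(W), 1e-12)
      ## fill invalid nodes by periodic interpolation
      if (!all(valid)) {
        idx <- which(valid)
        allk <- seq_len(K)
        r_new[!valid] <- stats::approx(
          x = c(idx - K, idx, idx + K), y = rep(r_new[idx], 3),
          xout = allk[!valid])$y
      }
      r_i <- as.numeric(smooth_circular(r_new, max(1L, round(K * smooth_frac))))
      pts <- cbind(cen_i[1] + r_i * ct, cen_i[2] + r_i * st)
      cen_new <- colMeans(pts)
      ## re-express radii about the updated center
      r_i <- sqrt(rowSums(sweep(pts, 2, cen_new)^2))
      cen_i <- cen_new
    }
    if (!ok_slice) {
      if (fitted == 0L) {
        eht_stop("eht_no_ring", sprintf(
          "no detectable wall signal on slice %d", slices[si]))
      }
      eht_warn("eht_partial_rings", sprintf(
        "wall signal lost at slice %d; returning %d fitted ring(s)",
        slices[si], fitted))
      break
    }
    pts <- cbind(cen_i[1] + r_i * ct, cen_i[2] + r_i * st)
    centers[si, ] <- cen_i
    contours[[si]] <- pts
    perims[si] <- polygon_perimeter(pts)
    cen <- cen_i; r_prof <- r_i
    fitted <- fitted + 1L
  }
  keep <- seq_len(fitted)
  structure(list(
    slices = slices[keep],
    x_um = (slices[keep] - 1) * stack$spacing["x"],
    centers = centers[keep, , drop = FALSE],
    contours = contours[keep],
    theta = theta,
    perimeters = perims[keep],
    spacing = stack$spacing), class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("<ring_set> %d slice(s), median perimeter %.2f um\n",
              length(x$slices), stats::median(x$perimeters)))
  invisible(x)
}

#' Per-slice perimeter measurement
#'
#' Arc length of each fitted ring contour, in physical units.
#' @param rings a `ring_set` from [fit_rings()].
#' @return data.frame (slice, x_um, perimeter_um) with a `summary` attribute
#'   (mean, median, sd).
#' @export
measure_perimeter <- function(rings) {
  if (!inherits(rings, "ring_set") || length(rings$slices) == 0) {
    eht_stop("eht_config_error", "non-empty ring_set required")
  }
  for (ctr in rings$contours) {
    if (is.null(ctr) || nrow(ctr) < 3) {
      eht_stop("eht_geometry_error", "degenerate ring: fewer than 3 points")
    }
  }
  per <- vapply(rings$contours, polygon_perimeter, 0)
  out <- data.frame(slice = rings$slices, x_um = rings$x_um, perimeter_um = per)
  attr(out, "summary") <- c(mean = mean(per), median = stats::median(per),
                            sd = stats::sd(per))
  out
}

#' Unwrap a tube wall into a 2D cartography
#'
#' For every fitted ring, samples the wall intensity at fixed arc-length steps
#' starting from the reference angle and writes one cartography column per
#' slice. Intensity at each arc position is the maximum (default) or mean over
#' a radial band of +/- `band_halfwidth_um` around the contour.
#'
#' @param stack a [volume_stack()].
#' @param rings `ring_set` from [fit_rings()].
#' @param channel channel to project.
#' @param band_halfwidth_um radial half-width of the sampling band, um.
#' @param stat `"max"` (junction signal is a thin bright sheet) or `"mean"`.
#' @param reference_angle_deg angle (deg, from the ventral +y direction) of
#'   cartography row Y = 0.
#' @param arc_step_um arc sampling step; default `min(spacing)`.
#' @return A `cartography`: intensity matrix (rows = arc position, columns =
#'   axial slice; rows beyond a column's perimeter are NA), per-column
#'   perimeters and the 3D back-mapping tables.
#' @export
unwrap <- function(stack, rings, channel = 1L, band_halfwidth_um = 1.5,
                   stat = c("max", "mean"), reference_angle_deg = 0,
                   arc_step_um = NULL) {
  stopifnot(inherits(stack, "volume_stack"), inherits(rings, "ring_set"))
  stat <- match.arg(stat)
  dy <- stack$spacing["y"]; dz <- stack$spacing["z"]
  if (length(rings$slices) == 0) eht_stop("eht_config_error", "empty ring_set")
  if (max(rings$slices) > dim(stack$data)[3]) {
    eht_stop("eht_dimension_error", "ring slices outside the stack")
  }
  arc_step <- arc_step_um %||% min(dy, dz)
  n_rows <- ceiling(max(rings$perimeters) / arc_step)
  ncol_ <- length(rings$slices)
  val <- matrix(NA_real_, n_rows, ncol_)
  map_y <- matrix(NA_real_, n_rows, ncol_)
  map_z <- matrix(NA_real_, n_rows, ncol_)
  ref_rad <- reference_angle_deg * pi / 180
  band <- seq(-band_halfwidth_um, band_halfwidth_um, by = min(dy, dz) / 2)
  for (ci in seq_len(ncol_)) {
    ctr <- rings$contours[[ci]]
    cen <- rings$centers[ci, ]
    K <- nrow(ctr)
    ## rotate the contour start to the reference angle
    node_theta <- rings$theta
    shift <- which.min((node_theta - ref_rad) %% (2 * pi))
    ord <- c(shift:K, seq_len(shift - 1L))
    pts <- ctr[ord, , drop = FALSE]
    seg <- sqrt(rowSums((rbind(pts[-1, , drop = FALSE], pts[1, ]) - pts)^2))
    cum <- c(0, cumsum(seg))            # length K+1, cum[K+1] = perimeter
    perim <- cum[K + 1]
    n_i <- max(3L, floor(perim / arc_step))
    s_j <- (seq_len(n_i) - 1) * arc_step
    ## interpolate contour position at each arc position
    py <- stats::approx(cum, c(pts[, 1], pts[1, 1]), xout = s_j)$y
    pz <- stats::approx(cum, c(pts[, 2], pts[1, 2]), xout = s_j)$y
    ur <- cbind(py - cen[1], pz - cen[2])
    ur <- ur / pmax(sqrt(rowSums(ur^2)), 1e-12)
    sl <- vol_slice(stack, rings$slices[ci], channel)
    Iband <- matrix(0, n_i, length(band))
    for (bi in seq_along(band)) {
      Iband[, bi] <- interp2(sl, dy, dz,
                             py + band[bi] * ur[, 1], pz + band[bi] * ur[, 2])
    }
    val[seq_len(n_i), ci] <- if (stat == "max") {
      apply(Iband, 1, max)
    } else rowMeans(Iband)
    map_y[seq_len(n_i), ci] <- py
    map_z[seq_len(n_i), ci] <- pz
  }
  structure(list(
    intensity = val, arc_step_um = arc_step,
    axial_step_um = unname(stack$spacing["x"]),
    x_um = rings$x_um, perimeters = rings$perimeters,
    reference_angle_deg = reference_angle_deg,
    map_y = map_y, map_z = map_z,
    n_rows_valid = colSums(!is.na(val))), class = "cartography")
}

#' @export
print.cartography <- function(x, ...) {
  cat(sprintf("<cartography> %d arc rows x %d axial columns (arc step %.3g um)\n",
              nrow(x$intensity), ncol(x$intensity), x$arc_step_um))
  invisible(x)
}

#' Map cartography coordinates back to 3D
#'
#' Inverse of the projection: returns the 3D wall location (um) sampled into
#' each cartography pixel. Y wraps at the column perimeter (the cartography is
#' cyclic in Y).
#' @param carto a `cartography` from [unwrap()].
#' @param points matrix/data.frame with columns (X, Y) in um: X axial, Y arc
#'   position from the reference angle.
#' @return data.frame (x_um, y_um, z_um).
#' @export
back_map <- function(carto, points) {
  pts <- rbind(as.matrix(points))
  xr <- range(carto$x_um)
  if (any(pts[, 1] < xr[1] - carto$axial_step_um / 2) ||
      any(pts[, 1] > xr[2] + carto$axial_step_um / 2) ||
      any(pts[, 2] < 0)) {
    eht_stop("eht_range_error", "point outside cartography bounds")
  }
  ci <- vapply(pts[, 1], function(x) which.min(abs(carto$x_um - x)), 0L)
  out <- matrix(NA_real_, nrow(pts), 3)
  for (k in seq_len(nrow(pts))) {
    col <- ci[k]
    perim <- carto$perimeters[col]
    if (pts[k, 2] > perim) {
      if (pts[k, 2] > max(carto$perimeters) + carto$arc_step_um) {
        eht_stop("eht_range_error", "arc position outside cartography bounds")
      }
    }
    yv <- pts[k, 2] %% perim
    ri <- round(yv / carto$arc_step_um) + 1L
    if (ri > carto$n_rows_valid[col]) ri <- 1L
    out[k, ] <- c(carto$x_um[col], carto$map_y[ri, col], carto$map_z[ri, col])
  }
  data.frame(x_um = out[, 1], y_um = out[, 2], z_um = out[, 3])
}
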