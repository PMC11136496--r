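## Synthetic aorta phantom: a fluorescent tube whose wall carries a paving of
## junction-labelled polygonal cells, plus a nuclear channel. Geometry mirrors
## confocal acquisitions of the zebrafish dorsal aorta at 48-55 hpf: the
## vessel axis runs along x, cross-sections are (y, z) planes with anisotropic
## voxel spacing (xy pixel vs z step). All ground truth needed by downstream
## stages is returned in a ledger so images never have to be re-measured.

#' Configuration for the tube phantom
#'
#' @param radius_um tube radius in um; a length-2 vector (a, b) gives an
#'   elliptical cross-section with semi-axes a (y) and b (z). Cell pavings are
#'   only generated for circular sections.
#' @param segment_length_um axial extent of the imaged segment (um).
#' @param pixel_xy_um in-plane pixel size (y and x axes), um.
#' @param step_z_um z step, um.
#' @param n_cells number of wall cells (0 = bare wall).
#' @param cell_aspect axial elongation of the cell paving: the tessellation
#'   is built in (x / aspect, arc) space, so cells are on average `aspect`
#'   times longer along the vessel axis than around it (aortic cells are
#'   elongated antero-posteriorly).
#' @param floor_fraction_hemogenic fraction of floor-sector cells given a
#'   thick nucleus (hemogenic candidates); ledger types follow the
#'   morphometric rule cascade, so a candidate only becomes hemogenic if its
#'   true elongation passes the threshold.
#' @param junction_intensity,wall_intensity,nucleus_intensity intensities for
#'   cell borders, the wall sheet and nuclear blobs (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (0 = noise-free); clipped at 0.
#' @param noise_model `"gaussian"` or `"poisson"` (Poisson draws with mean =
#'   clean intensity; `noise_sd` ignored).
#' @param reference_angle_deg angular reference; 0 deg = ventral-most (floor)
#'   line.
#' @param stripe_angles_deg optional angles (deg from the reference) at which
#'   bright longitudinal stripes are painted, for unwrap verification.
#' @param stripe_intensity stripe intensity.
#' @param wall_thickness_um wall sheet thickness, um.
#' @param border_halfwidth_um half-width of painted cell borders, um.
#' @param margin_um empty margin around the tube, um.
#' @param fov_um optional fixed cross-section field of view (um); it is a
#'   configuration error if the tube does not fit.
#' @param seed integer RNG seed; identical configs and seeds give
#'   bit-identical output.
#' @return A list of class `tube_phantom_config`.
#' @export
tube_phantom_config <- function(radius_um = 25, segment_length_um = 330,
                                pixel_xy_um = 0.27, step_z_um = 0.3,
                                n_cells = 20, cell_aspect = 2.5,
                                floor_fraction_hemogenic = 0.5,
                                junction_intensity = 200, wall_intensity = 60,
                                nucleus_intensity = 150, noise_sd = 0,
                                noise_model = c("gaussian", "poisson"),
                                reference_angle_deg = 0,
                                stripe_angles_deg = NULL,
                                stripe_intensity = 255,
                                wall_thickness_um = 1.2,
                                border_halfwidth_um = 0.5,
                                margin_um = 8, fov_um = NULL, seed = 1L) {
  for (nm in c("segment_length_um", "pixel_xy_um", "step_z_um",
               "wall_thickness_um", "border_halfwidth_um"))
    stopifnot_scalar_pos(get(nm), nm)
  if (!is.numeric(radius_um) || !length(radius_um) %in% 1:2 || any(radius_um <= 0))
    eht_stop("eht_config_error", "`radius_um` must be 1 or 2 positive values")
  stopifnot_fraction(floor_fraction_hemogenic, "floor_fraction_hemogenic")
  stopifnot_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  noise_model <- match.arg(noise_model)
  if (!is.null(fov_um) &&
      fov_um < 2 * (max(radius_um) + wall_thickness_um)) {
    eht_stop("eht_config_error", "tube radius too large for the field of view")
  }
  cfg <- as.list(environment())
  class(cfg) <- "tube_phantom_config"
  cfg
}

#' Generate a tube phantom with ground truth
#'
#' Builds a dual-channel stack (channel 1 "junction": wall sheet with bright
#' cell borders and optional painted stripes; channel 2 "nuclei": one blob per
#' cell) plus a ground-truth ledger with the cell paving, per-cell
#' morphometrics computed in closed form from the true polygons, the paving
#' adjacency, stripe positions and the analytic perimeter.
#'
#' @param cfg a [tube_phantom_config()].
#' @return List with `stack` (a [volume_stack()]) and `truth` (ledger).
#' @export
make_tube_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "tube_phantom_config"))
  with_seed(cfg$seed, {
    a <- cfg$radius_um[1]
    b <- if (length(cfg$radius_um) == 2) cfg$radius_um[2] else a
    circular <- isTRUE(all.equal(a, b))
    dy <- cfg$pixel_xy_um; dz <- cfg$step_z_um; dx <- cfg$pixel_xy_um
    nx <- ceiling(cfg$segment_length_um / dx)
    fov <- cfg$fov_um %||% (2 * (max(a, b) + cfg$margin_um))
    ny <- ceiling(fov / dy); nz <- ceiling(fov / dz)
    cy <- (ny - 1) / 2 * dy; cz <- (nz - 1) / 2 * dz
    yy <- ((seq_len(ny) - 1) * dy - cy)
    zz <- ((seq_len(nz) - 1) * dz - cz)
    DY <- matrix(yy, ny, nz)
    DZ <- matrix(zz, ny, nz, byrow = TRUE)
    rho <- sqrt(DY^2 + DZ^2)
    q <- sqrt((DY / a)^2 + (DZ / b)^2)
    r_ray <- rho / pmax(q, 1e-12)            # distance to wall centreline along the ray
    wall <- abs(rho - r_ray) <= cfg$wall_thickness_um / 2 & q > 0
    ref_rad <- cfg$reference_angle_deg * pi / 180
    theta <- (atan2(DZ, DY) - ref_rad) %% (2 * pi)

    perim_true <- if (circular) 2 * pi * a else ellipse_perimeter(a, b)
    junction <- ifelse(wall, cfg$wall_intensity, 0)

    ## stripes: painted across all slices at fixed angles
    stripes <- NULL
    if (length(cfg$stripe_angles_deg)) {
      half_ang <- max(cfg$pixel_xy_um, 0.5) / max(a, b)  # ~1 px arc half-width
      for (ang in cfg$stripe_angles_deg) {
        th0 <- (ang * pi / 180) %% (2 * pi)
        dth <- pmin(abs(theta - th0), 2 * pi - abs(theta - th0))
        junction[wall & dth <= half_ang] <- cfg$stripe_intensity
      }
      stripes <- data.frame(angle_deg = cfg$stripe_angles_deg,
                            s_um = (cfg$stripe_angles_deg %% 360) / 360 * perim_true)
    }

    cells <- NULL; polys <- NULL; adjacency <- NULL
    nuclei_ctr <- NULL
    if (cfg$n_cells > 0 && circular) {
      P <- perim_true; L <- cfg$segment_length_um
      k_asp <- cfg$cell_aspect
      ## jittered seed grid in stretched (x / aspect, s) space; the Voronoi
      ## there maps back to an axially elongated paving
      Lk <- L / k_asp
      n_s <- max(2L, round(sqrt(cfg$n_cells * P / Lk)))
      n_x <- max(1L, ceiling(cfg$n_cells / n_s))
      pitch_u <- Lk / n_x; pitch_s <- P / n_s
      gu <- (rep(seq_len(n_x), each = n_s) - 0.5) * pitch_u
      gs <- (rep(seq_len(n_s), times = n_x) - 0.5) * pitch_s
      keep <- sample(length(gu), min(cfg$n_cells, length(gu)))
      su <- gu[keep] + stats::runif(length(keep), -0.3, 0.3) * pitch_u
      ss <- (gs[keep] + stats::runif(length(keep), -0.3, 0.3) * pitch_s) %% P
      su <- pmin(pmax(su, 0), Lk)
      sx <- su * k_asp
      n_actual <- length(sx)
      vor <- voronoi_paving(cbind(su, ss), bbox = c(0, Lk, -P, 2 * P), period_y = P)
      ## unstretch polygons back to (x, s)
      polys <- lapply(vor$polygons, function(p) cbind(p[, 1] * k_asp, p[, 2]))
      adjacency <- vor$adjacency
      ## per-cell truth from exact polygon moments
      mom <- lapply(polys, polygon_moments)
      cen_x <- vapply(mom, function(m) m$centroid[1], 0)
      cen_s <- vapply(mom, function(m) m$centroid[2], 0) %% P
      ang <- cen_s / P * 360
      region <- ifelse(ang < 60 | ang > 300, "floor",
                       ifelse(ang >= 120 & ang <= 240, "roof", "lateral"))
      ## nucleus-thickness flags for a fraction of floor cells (hemogenic
      ## candidates); the ledger type is the rule cascade applied to the
      ## true morphometrics, so labels are consistent with cell shape
      fl <- which(region == "floor")
      n_he <- round(cfg$floor_fraction_hemogenic * length(fl))
      thick <- rep(FALSE, n_actual)
      if (n_he > 0) thick[sample(fl, n_he)] <- TRUE
      elong <- vapply(mom, `[[`, 0, "elongation")
      type <- ifelse(region %in% c("floor", "lateral") & elong >= 2 & thick,
                     "hemogenic",
                     ifelse(region == "roof" | !thick, "endothelial",
                            "uncharacterized"))
      nb <- integer(n_actual)
      if (nrow(adjacency)) {
        t1 <- table(factor(adjacency$i, levels = seq_len(n_actual))) +
          table(factor(adjacency$j, levels = seq_len(n_actual)))
        nb <- as.integer(t1)
      }
      cells <- data.frame(
        id = seq_len(n_actual), type = type, region = region,
        nucleus_thick = thick,
        centroid_x_um = cen_x, centroid_s_um = cen_s,
        seed_x_um = sx, seed_s_um = ss,
        area_um2 = vapply(mom, `[[`, 0, "area"),
        elongation = vapply(mom, `[[`, 0, "elongation"),
        orientation_deg = vapply(mom, `[[`, 0, "orientation_deg"),
        major_length_um = vapply(seq_along(polys), function(i) {
          th <- mom[[i]]$orientation_deg * pi / 180
          pr <- polys[[i]][, 1] * cos(th) + polys[[i]][, 2] * sin(th)
          max(pr) - min(pr)
        }, 0),
        n_neighbors = nb)

      ## paint borders: wall voxels whose two nearest seeds are nearly
      ## equidistant (the Voronoi ridge), per axial slice
      wall_idx <- which(wall)
      s_wall <- (theta[wall_idx] * a)  # arc coordinate of each wall voxel
      xs_um <- (seq_len(nx) - 1) * dx
      ## periodic arc distance to each seed, precomputed parts
      border_tpl <- matrix(FALSE, length(wall_idx), nx)
      ds_mat <- outer(s_wall, ss, function(u, v) {
        d <- abs(u - v); pmin(d, P - d)
      })
      ds2 <- ds_mat^2
      for (ix in seq_len(nx)) {
        ## same stretched metric as the tessellation
        d2 <- sweep(ds2, 2, ((xs_um[ix] - sx) / k_asp)^2, `+`)
        if (ncol(d2) >= 2) {
          i1 <- max.col(-d2, ties.method = "first")
          d_first <- d2[cbind(seq_len(nrow(d2)), i1)]
          d2[cbind(seq_len(nrow(d2)), i1)] <- Inf
          d_second <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
          ridge <- sqrt(d_second) - sqrt(d_first) <= 2 * cfg$border_halfwidth_um
        } else ridge <- rep(FALSE, nrow(d2))
        border_tpl[, ix] <- ridge
      }
      nuclei_ctr <- cbind(x = sx, s = ss)
    }

    arr <- array(0, c(ny, nz, nx, 2))
    for (ix in seq_len(nx)) {
      sl <- junction
      if (!is.null(cells)) sl[wall_idx[border_tpl[, ix]]] <- cfg$junction_intensity
      arr[, , ix, 1] <- sl
    }

    ## nuclear channel: Gaussian blob per cell just inside the wall
    if (!is.null(nuclei_ctr)) {
      sig <- 1.5
      for (i in seq_len(nrow(nuclei_ctr))) {
        th <- nuclei_ctr[i, "s"] / a + ref_rad
        py <- (a - 1.5) * cos(th); pz <- (a - 1.5) * sin(th)
        px <- nuclei_ctr[i, "x"]
        iy <- which(abs(yy - py) <= 3 * sig)
        iz <- which(abs(zz - pz) <= 3 * sig)
        ixr <- which(abs((seq_len(nx) - 1) * dx - px) <= 3 * sig)
        if (!length(iy) || !length(iz) || !length(ixr)) next
        gy <- exp(-(yy[iy] - py)^2 / (2 * sig^2))
        gz <- exp(-(zz[iz] - pz)^2 / (2 * sig^2))
        gx <- exp(-(((ixr - 1) * dx) - px)^2 / (2 * sig^2))
        blob <- outer(gy, gz) # (iy, iz)
        for (k in seq_along(ixr)) {
          arr[iy, iz, ixr[k], 2] <- arr[iy, iz, ixr[k], 2] +
            cfg$nucleus_intensity * blob * gx[k]
        }
      }
    }

    if (cfg$noise_model == "poisson") {
      arr[] <- stats::rpois(length(arr), lambda = arr)
    } else if (cfg$noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, cfg$noise_sd)
      arr[arr < 0] <- 0
    }

    stack <- volume_stack(arr, spacing = c(y = dy, z = dz, x = dx),
                          channels = c("junction", "nuclei"))
    truth <- list(
      cells = cells, polygons = polys, adjacency = adjacency,
      stripes = stripes, perimeter_um = perim_true,
      radius_um = cfg$radius_um, center_um = c(y = cy, z = cz),
      reference_angle_deg = cfg$reference_angle_deg,
      wall_thickness_um = cfg$wall_thickness_um, config = cfg)
    class(truth) <- "ground_truth_cell_map"
    list(stack = stack, truth = truth)
  })
}

#' Ramanujan approximation of an ellipse perimeter
#' @param a,b semi-axes.
#' @return Perimeter (same units as the axes).
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
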