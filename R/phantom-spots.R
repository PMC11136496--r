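## Synthetic RNAscope scene: an aortic cylinder containing spherical roof
## endothelial and floor hemogenic/EHT cells plus sub-aortic cells below the
## vessel, and a point pattern of spots that is either uniform within the
## aorta or clustered around the hemogenic/EHT cells with an
## exponential-decay distance law. The ledger records, per spot, its true
## compartment and its analytic distance to the nearest hemogenic/EHT cell
## surface.

#' Configuration for the spot-scene simulator
#'
#' @param n_roof,n_hemogenic,n_sub_aortic cells per class.
#' @param n_spots number of spots.
#' @param clustering_scale_um exponential decay scale of spot distance from
#'   hemogenic/EHT cell surfaces; 0 = uniform placement in the aorta.
#' @param fraction_extra_aortic fraction of spots placed outside the aorta
#'   (sub-aortic space).
#' @param cell_radius_um cell sphere radius.
#' @param aorta_radius_um aortic cylinder radius.
#' @param box_um scene extent, named (x, y, z), um. z is the dorso-ventral
#'   axis; the aorta axis runs along x, with the sub-aortic space below.
#' @param spacing_um voxel size of the label volume (isotropic).
#' @param seed RNG seed.
#' @return List of class `spot_scene_config`.
#' @export
spot_scene_config <- function(n_roof = 6L, n_hemogenic = 5L, n_sub_aortic = 4L,
                              n_spots = 150L, clustering_scale_um = 3,
                              fraction_extra_aortic = 0.2,
                              cell_radius_um = 3, aorta_radius_um = 10,
                              box_um = c(x = 40, y = 30, z = 34),
                              spacing_um = 0.5, seed = 1L) {
  for (nm in c("n_roof", "n_hemogenic", "n_sub_aortic", "n_spots")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) eht_stop("eht_config_error",
                                          sprintf("`%s` must be >= 0", nm))
  }
  stopifnot_scalar_pos(clustering_scale_um, "clustering_scale_um", strict = FALSE)
  stopifnot_fraction(fraction_extra_aortic, "fraction_extra_aortic")
  if (clustering_scale_um > 0 && n_hemogenic == 0) {
    eht_stop("eht_config_error",
             "clustering requested but no hemogenic/EHT cells")
  }
  cfg <- as.list(environment())
  class(cfg) <- "spot_scene_config"
  cfg
}

#' Generate a spot scene with ground truth
#'
#' @param cfg a [spot_scene_config()].
#' @return List: `spots` (m x 3 coordinates), `cells` (a
#'   [cell_surface_set()]), `truth` data.frame per spot (compartment,
#'   parent_id, dist_hemogenic_um: analytic sphere-surface distance), and
#'   `cell_truth` (id, class, center, radius).
#' @export
make_spot_scene <- function(cfg) {
  stopifnot(inherits(cfg, "spot_scene_config"))
  with_seed(cfg$seed, {
    bx <- cfg$box_um[["x"]]; by <- cfg$box_um[["y"]]; bz <- cfg$box_um[["z"]]
    sp <- cfg$spacing_um
    d <- c(floor(bx / sp) + 1L, floor(by / sp) + 1L, floor(bz / sp) + 1L)
    R <- cfg$aorta_radius_um; rc <- cfg$cell_radius_um
    cy <- by / 2
    cz <- bz - R - 2                      # aorta center height; floor at cz - R
    ## voxel coordinate grids
    xs <- (seq_len(d[1]) - 1) * sp
    ys <- (seq_len(d[2]) - 1) * sp
    zs <- (seq_len(d[3]) - 1) * sp
    YZ2 <- outer((ys - cy)^2, (zs - cz)^2, `+`)     # (y, z)
    aorta2d <- YZ2 <= R^2
    aorta_mask <- array(rep(aorta2d, each = d[1]), d)  # constant along x

    ## cell centers: roof on the top interior wall, hemogenic on the floor,
    ## sub-aortic below the vessel; spread along x with jitter
    place_arc <- function(n, angle_deg_center, angle_jitter = 25) {
      if (n == 0) return(NULL)
      px <- (seq_len(n) - 0.5) / n * (bx - 2 * rc) + rc
      ang <- (angle_deg_center + stats::runif(n, -angle_jitter, angle_jitter)) * pi / 180
      rr <- R - rc
      cbind(px + stats::runif(n, -1, 1),
            cy + rr * sin(ang), cz + rr * cos(ang))
    }
    roof <- place_arc(cfg$n_roof, 0)          # top (z above center)
    floor_ <- place_arc(cfg$n_hemogenic, 180) # bottom
    sub <- if (cfg$n_sub_aortic > 0) {
      px <- (seq_len(cfg$n_sub_aortic) - 0.5) / cfg$n_sub_aortic * (bx - 2 * rc) + rc
      zl <- cz - R - rc - 0.5
      cbind(px + stats::runif(cfg$n_sub_aortic, -1, 1),
            cy + stats::runif(cfg$n_sub_aortic, -3, 3),
            pmax(zl + stats::runif(cfg$n_sub_aortic, -1, 0.5), rc))
    } else NULL
    centers <- rbind(roof, floor_, sub)
    classes <- data.frame(
      id = seq_len(nrow(centers)),
      class = rep(c("roof_endothelial", "hemogenic_EHT", "sub_aortic"),
                  c(cfg$n_roof, cfg$n_hemogenic, cfg$n_sub_aortic)))

    labels <- array(0L, d)
    for (i in seq_len(nrow(centers))) {
      ix <- which(abs(xs - centers[i, 1]) <= rc)
      iy <- which(abs(ys - centers[i, 2]) <= rc)
      iz <- which(abs(zs - centers[i, 3]) <= rc)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (xs[ix] - centers[i, 1])^2
      dy2 <- (ys[iy] - centers[i, 2])^2
      dz2 <- (zs[iz] - centers[i, 3])^2
      sph <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rc^2
      sub_lab <- labels[ix, iy, iz]
      sub_lab[sph & sub_lab == 0L] <- i
      labels[ix, iy, iz] <- sub_lab
    }
    cells <- cell_surface_set(labels, classes, aorta_mask, rep(sp, 3))

    he_centers <- centers[classes$class == "hemogenic_EHT", , drop = FALSE]
    dist_he <- function(p) {
      if (nrow(he_centers) == 0) return(Inf)
      max(0, sqrt(min(colSums((t(he_centers) - p)^2))) - rc)
    }
    ## membership uses the voxelized mask so the ledger agrees exactly with
    ## downstream voxel-based classification
    in_aorta <- function(p) {
      if (any(p < 0) || p[1] > bx || p[2] > by || p[3] > bz) return(FALSE)
      iy <- min(max(round(p[2] / sp) + 1L, 1L), d[2])
      iz <- min(max(round(p[3] / sp) + 1L, 1L), d[3])
      aorta2d[iy, iz]
    }

    n_extra <- round(cfg$fraction_extra_aortic * cfg$n_spots)
    n_in <- cfg$n_spots - n_extra
    spots <- matrix(NA_real_, 0, 3)
    ## intra-aortic spots
    k <- 0L
    while (k < n_in) {
      if (cfg$clustering_scale_um <= 0) {
        p <- c(stats::runif(1, 0, bx),
               cy + stats::runif(1, -R, R), cz + stats::runif(1, -R, R))
        if (!in_aorta(p)) next
      } else {
        ci <- sample(nrow(he_centers), 1)
        dd <- stats::rexp(1, 1 / cfg$clustering_scale_um)
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        p <- he_centers[ci, ] + u * (rc * stats::runif(1)^(1 / 3) + dd)
        if (!in_aorta(p)) next
      }
      spots <- rbind(spots, p); k <- k + 1L
    }
    ## extra-aortic spots: below the aorta
    k <- 0L
    while (k < n_extra) {
      p <- c(stats::runif(1, 0, bx), stats::runif(1, 0, by),
             stats::runif(1, 0, max(cz - R - 0.5, 1)))
      if (in_aorta(p)) next
      spots <- rbind(spots, p); k <- k + 1L
    }
    rownames(spots) <- NULL
    ## truth per spot
    vox <- spot_voxel(spots, cells)
    lab <- labels[vox]
    comp <- character(nrow(spots))
    for (i in seq_len(nrow(spots))) {
      inside_cell <- lab[i] > 0 &&
        classes$class[lab[i]] %in% c("roof_endothelial", "hemogenic_EHT")
      comp[i] <- if (inside_cell) "aortic_cell"
      else if (!in_aorta(spots[i, ])) "extra_aortic" else "unassigned"
    }
    truth <- data.frame(
      spot = seq_len(nrow(spots)),
      compartment = comp,
      parent_id = ifelse(lab > 0, lab, NA_integer_),
      dist_hemogenic_um = apply(spots, 1, dist_he))
    list(spots = unname(spots), cells = cells, truth = truth,
         cell_truth = data.frame(id = classes$id, class = classes$class,
                                 x = centers[, 1], y = centers[, 2],
                                 z = centers[, 3], radius_um = rc))
  })
}
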