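## Spatial statistics of single-molecule FISH (RNAscope) spots relative to
## labeled cell surfaces in the aortic volume: compartment classification,
## spots per cell, and the cumulative distance profile with its 50%/75%
## attraction distances (smallest distance from hemogenic/EHT cells within
## which 50%/75% of spots lie).

SPOT_COMPARTMENTS <- c("aortic_cell", "extra_aortic", "unassigned")
CELL_CLASSES <- c("roof_endothelial", "hemogenic_EHT", "sub_aortic")

#' Construct a labeled cell-surface set
#'
#' @param labels 3D integer array, dims (x, y, z) voxels; 0 = background,
#'   k > 0 = cell id k. Disjoint by construction.
#' @param classes data.frame (id, class) with class from
#'   roof_endothelial / hemogenic_EHT / sub_aortic.
#' @param aorta_mask logical array, same dims: the aortic lumen + wall.
#' @param spacing_um voxel spacing, length 3 (x, y, z).
#' @return Object of class `cell_surface_set`.
#' @export
cell_surface_set <- function(labels, classes, aorta_mask, spacing_um) {
  if (!identical(dim(labels), dim(aorta_mask))) {
    eht_stop("eht_input_error", "labels and aorta mask dims differ")
  }
  if (!all(c("id", "class") %in% names(classes)) ||
      !all(classes$class %in% CELL_CLASSES)) {
    eht_stop("eht_input_error", "classes must map id -> known class")
  }
  structure(list(labels = labels, classes = classes,
                 aorta_mask = aorta_mask,
                 spacing_um = rep_len(spacing_um, 3)),
            class = "cell_surface_set")
}

#' Combine per-cell masks, rejecting overlaps
#'
#' @param masks named list of logical arrays (names = ids).
#' @return Integer label array.
#' @export
combine_cell_masks <- function(masks) {
  lab <- array(0L, dim(masks[[1]]))
  cnt <- array(0L, dim(masks[[1]]))
  for (i in seq_along(masks)) {
    cnt <- cnt + masks[[i]]
    lab[masks[[i]]] <- i
  }
  if (any(cnt > 1)) {
    bad <- which(vapply(masks, function(m) any(m & cnt > 1), TRUE))
    eht_stop("eht_input_error",
             paste("overlapping cell masks:", paste(names(masks)[bad] %||% bad,
                                                    collapse = ", ")),
             ids = bad)
  }
  lab
}

spot_voxel <- function(coords, cells) {
  sp <- cells$spacing_um
  d <- dim(cells$labels)
  ix <- pmin(pmax(round(coords[, 1] / sp[1]) + 1L, 1L), d[1])
  iy <- pmin(pmax(round(coords[, 2] / sp[2]) + 1L, 1L), d[2])
  iz <- pmin(pmax(round(coords[, 3] / sp[3]) + 1L, 1L), d[3])
  cbind(ix, iy, iz)
}

#' Classify spots by tissue compartment
#'
#' A spot is `aortic_cell` when its center falls inside any aortic cell mask
#' (roof endothelial or hemogenic/EHT; boundary voxels count as inside),
#' `extra_aortic` when outside the aorta mask, and `unassigned` otherwise
#' (inside the aorta but in no cell).
#'
#' @param coords m x 3 matrix of spot centers (x, y, z), um.
#' @param cells a [cell_surface_set()].
#' @return data.frame of class `spot_set`: x, y, z, compartment, parent_id
#'   (cell id or NA).
#' @export
classify_spots <- function(coords, cells) {
  stopifnot(inherits(cells, "cell_surface_set"))
  coords <- rbind(as.matrix(coords))
  if (any(!is.finite(coords))) eht_stop("eht_input_error", "non-finite spot coordinates")
  vox <- spot_voxel(coords, cells)
  lab <- cells$labels[vox]
  in_aorta <- cells$aorta_mask[vox]
  aortic_ids <- cells$classes$id[cells$classes$class %in%
                                   c("roof_endothelial", "hemogenic_EHT")]
  comp <- ifelse(lab > 0 & lab %in% aortic_ids, "aortic_cell",
                 ifelse(!in_aorta, "extra_aortic", "unassigned"))
  out <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    compartment = comp,
                    parent_id = ifelse(lab > 0, lab, NA_integer_))
  class(out) <- c("spot_set", class(out))
  out
}

#' Spots per cell and count histogram
#'
#' @param spots a `spot_set` from [classify_spots()].
#' @param cells a [cell_surface_set()].
#' @param cell_class cell class counted (default hemogenic/EHT).
#' @return List: `per_cell` data.frame (id, n_spots), `histogram` named
#'   vector over bins 0, 1, 2, 3, 4+ (cells by spot count).
#' @export
count_spots_per_cell <- function(spots, cells, cell_class = "hemogenic_EHT") {
  ids <- cells$classes$id[cells$classes$class == cell_class]
  n <- vapply(ids, function(id) {
    sum(!is.na(spots$parent_id) & spots$parent_id == id)
  }, 0L)
  bins <- cut(n, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("0", "1", "2", "3", "4+"))
  list(per_cell = data.frame(id = ids, n_spots = n),
       histogram = table(bins))
}

## distance (um) from each point to the nearest surface of a voxel mask:
## 0 inside the mask, else minimum distance to mask surface voxel centers.
## Exact at voxel resolution and handles anisotropic spacing.
dist_to_mask_um <- function(coords, mask, spacing_um) {
  d <- dim(mask)
  sp <- rep_len(spacing_um, 3)
  ix <- pmin(pmax(round(coords[, 1] / sp[1]) + 1L, 1L), d[1])
  iy <- pmin(pmax(round(coords[, 2] / sp[2]) + 1L, 1L), d[2])
  iz <- pmin(pmax(round(coords[, 3] / sp[3]) + 1L, 1L), d[3])
  inside <- mask[cbind(ix, iy, iz)]
  ## surface voxels: mask minus its 6-neighborhood erosion
  er <- mask
  er[-1, , ] <- er[-1, , ] & mask[-d[1], , ]
  er[-d[1], , ] <- er[-d[1], , ] & mask[-1, , ]
  er[, -1, ] <- er[, -1, ] & mask[, -d[2], ]
  er[, -d[2], ] <- er[, -d[2], ] & mask[, -1, ]
  er[, , -1] <- er[, , -1] & mask[, , -d[3]]
  er[, , -d[3]] <- er[, , -d[3]] & mask[, , -1]
  surf <- which(mask & !er, arr.ind = TRUE)
  if (nrow(surf) == 0) surf <- which(mask, arr.ind = TRUE)
  sx <- (surf[, 1] - 1) * sp[1]
  sy <- (surf[, 2] - 1) * sp[2]
  sz <- (surf[, 3] - 1) * sp[3]
  out <- numeric(nrow(coords))
  for (k in which(!inside)) {
    out[k] <- sqrt(min((sx - coords[k, 1])^2 + (sy - coords[k, 2])^2 +
                         (sz - coords[k, 3])^2))
  }
  out
}

#' Cumulative spot-distance profile and attraction distances
#'
#' Euclidean distance from each spot center to the nearest surface point of
#' any target cell (0 inside a cell), the empirical cumulative curve, and the
#' 50%/75% attraction distances: the smallest observed distance d with
#' F(d) >= 0.5 / 0.75 (lower empirical quantile, no interpolation).
#'
#' @param spots `spot_set` (or m x 3 coordinate matrix).
#' @param cells a [cell_surface_set()].
#' @param target_class class of target cells.
#' @param grid_um distance grid for the averaged cumulative curve.
#' @return Object of class `distance_profile`: distances, d50, d75, grid,
#'   F (cumulative fraction on the grid).
#' @export
distance_profile <- function(spots, cells, target_class = "hemogenic_EHT",
                             grid_um = seq(0, 50, by = 0.5)) {
  stopifnot(inherits(cells, "cell_surface_set"))
  ids <- cells$classes$id[cells$classes$class == target_class]
  if (!length(ids)) eht_stop("eht_input_error", "no target cells")
  coords <- if (inherits(spots, "spot_set") || is.data.frame(spots)) {
    as.matrix(spots[, c("x", "y", "z")])
  } else rbind(as.matrix(spots))
  mask <- array(cells$labels %in% ids, dim(cells$labels))
  dists <- dist_to_mask_um(coords, mask, cells$spacing_um)
  structure(list(distances = dists,
                 d50 = attraction_distance(dists, 0.5),
                 d75 = attraction_distance(dists, 0.75),
                 grid = grid_um,
                 F = vapply(grid_um, function(g) mean(dists <= g), 0)),
            class = "distance_profile")
}

#' Lower empirical quantile of a distance set
#'
#' Smallest observed distance d with empirical F(d) >= q.
#' @param dists distances.
#' @param q fraction.
#' @return The attraction distance.
#' @export
attraction_distance <- function(dists, q) {
  if (!length(dists)) eht_stop("eht_input_error", "empty distance set")
  u <- sort(unique(dists))
  f <- vapply(u, function(v) mean(dists <= v), 0)
  u[which(f >= q)[1]]
}

#' Per-segment summary with spot-count / cell-count correlations
#'
#' @param segments data.frame with one row per aortic segment: `n_spots`,
#'   `n_he_cells`, `d50`, `d75` (as from [distance_profile()]).
#' @return List: `segments` (echoed), `correlations` data.frame with Pearson
#'   R, p and regression slope/intercept of each covariate against the
#'   hemogenic/EHT cell count; constant covariates are flagged
#'   not-applicable.
#' @export
summarize_scene <- function(segments) {
  if (nrow(segments) < 3) {
    eht_stop("eht_input_error", "need >= 3 segments for correlation")
  }
  covs <- intersect(c("n_spots", "d50", "d75"), names(segments))
  res <- do.call(rbind, lapply(covs, function(cv) {
    x <- segments$n_he_cells; y <- segments[[cv]]
    pc <- pearson_cor(x, y)
    if (!pc$applicable || stats::sd(x) == 0) {
      data.frame(covariate = cv, R = NA_real_, p = NA_real_,
                 slope = NA_real_, intercept = NA_real_, applicable = FALSE)
    } else {
      cf <- stats::coef(stats::lm(y ~ x))
      data.frame(covariate = cv, R = pc$R, p = pc$p,
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 applicable = TRUE)
    }
  }))
  list(segments = segments, correlations = res)
}
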