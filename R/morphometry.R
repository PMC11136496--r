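## Cell morphometry on 2D cartographies: ROI refinement into a joint paving,
## moment-ellipse descriptors, neighbor counts and the rule-based cell-type
## classification used for aortic wall cells (endothelial / hemogenic / EHT).

CELL_TYPES <- c("endothelial", "hemogenic", "EHT_pol_plus", "EHT_pol_minus",
                "uncharacterized")
CELL_REGIONS <- c("floor", "lateral", "roof")

#' Construct a cell ROI
#'
#' @param polygon n x 2 vertex matrix, cartography coordinates in um
#'   (column 1 = axial X, column 2 = arc Y).
#' @param id identifier.
#' @param type,region labels from the fixed vocabularies (or NA).
#' @param flags list of 3D shape flags read from the original stack (or a
#'   phantom ledger): `inward_bending`, `outward_round`, `nucleus_thick`;
#'   NA when unknown.
#' @return Object of class `cell_roi`.
#' @export
cell_roi <- function(polygon, id = NA_integer_, type = "uncharacterized",
                     region = NA_character_, flags = list()) {
  polygon <- as_polygon(polygon)
  if (!is.na(type) && !type %in% CELL_TYPES)
    eht_stop("eht_config_error", "unknown cell type")
  if (!is.na(region) && !region %in% CELL_REGIONS)
    eht_stop("eht_config_error", "unknown region")
  flags <- utils::modifyList(
    list(inward_bending = NA, outward_round = NA, nucleus_thick = NA), flags)
  structure(list(polygon = polygon, id = id, type = type, region = region,
                 flags = flags), class = "cell_roi")
}

roi_polygon <- function(x) if (inherits(x, "cell_roi")) x$polygon else as_polygon(x)

#' Morphometric descriptors of a cell ROI
#'
#' Area by the shoelace formula; best-fitting ellipse as the second-central-
#' moment equivalent ellipse of the rasterized filled polygon; elongation =
#' major/minor ellipse diameter ratio (>= 1); orientation = major-axis angle
#' to the axial (blood flow) X axis folded into [0, 180) degrees;
#' major length = extent of the polygon along the principal (major) axis,
#' i.e. the cell length in its longest axis.
#'
#' @param roi a [cell_roi()] or plain polygon matrix.
#' @param raster_res_um rasterization pixel size for the moment computation.
#' @return List of class `morphometrics`: area_um2, elongation,
#'   orientation_deg, major_length_um.
#' @export
compute_morphometrics <- function(roi, raster_res_um = 0.1) {
  poly <- roi_polygon(roi)
  area <- abs(polygon_area(poly))
  if (area <= raster_res_um^2) {
    eht_stop("eht_geometry_error", "degenerate polygon: zero area")
  }
  ras <- rasterize_polygon(poly, res = raster_res_um)
  idx <- which(ras$mask, arr.ind = TRUE)
  ## physical coordinates of mask pixels: rows index y, cols index x
  px <- ras$x0 + (idx[, 2] - 1) * ras$res
  py <- ras$y0 + (idx[, 1] - 1) * ras$res
  mx <- mean(px); my <- mean(py)
  mu20 <- mean((px - mx)^2); mu02 <- mean((py - my)^2)
  mu11 <- mean((px - mx) * (py - my))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- max((mu20 + mu02) / 2 - common, .Machine$double.eps)
  theta <- atan2(2 * mu11, mu20 - mu02) / 2
  proj <- poly[, 1] * cos(theta) + poly[, 2] * sin(theta)
  structure(list(
    area_um2 = area,
    elongation = sqrt(l1 / l2),
    orientation_deg = (theta * 180 / pi) %% 180,
    major_length_um = max(proj) - min(proj)), class = "morphometrics")
}

## ---- joint paving refinement ---------------------------------------------

#' Refine seed polygons into a joint paving
#'
#' Mirrors the semi-automated contour workflow used on real cartographies:
#' each manually drawn outline is first attracted to the junction signal
#' (closed-snake step: boundary points move along their normals towards the
#' local intensity ridge), then all outlines are jointly dilated until their
#' boundaries meet, producing a paving without overlap. The dilation is the
#' generalized Voronoi partition of the gap pixels between polygons; gaps
#' wider than `2 * max_dilate_um` are left unfilled, so an isolated polygon
#' comes back unchanged (up to raster snapping).
#'
#' @param seeds list of polygons or [cell_roi()] objects.
#' @param carto optional `cartography` (or plain intensity matrix) used for
#'   the snake step; NULL skips it.
#' @param raster_res_um pixel size of the paving raster.
#' @param max_dilate_um maximum one-sided dilation, um.
#' @param snake_search_um half-length of the normal intensity search, um.
#' @param snake_iters snake iterations.
#' @param overlap_tol_um2 maximum tolerated pairwise seed overlap area.
#' @return List of [cell_roi()] with refined polygons (ids and labels carried
#'   over from the seeds).
#' @export
refine_paving <- function(seeds, carto = NULL, raster_res_um = 0.25,
                          max_dilate_um = 3, snake_search_um = 1.2,
                          snake_iters = 2L, overlap_tol_um2 = 0.5) {
  rois <- lapply(seq_along(seeds), function(i) {
    s <- seeds[[i]]
    if (inherits(s, "cell_roi")) s else cell_roi(s, id = i)
  })
  polys <- lapply(rois, roi_polygon)
  n <- length(polys)
  if (n == 0) eht_stop("eht_config_error", "no seeds")

  img <- NULL; dy_img <- dx_img <- NULL
  if (!is.null(carto)) {
    if (inherits(carto, "cartography")) {
      img <- carto$intensity; img[is.na(img)] <- 0
      dy_img <- carto$arc_step_um; dx_img <- carto$axial_step_um
      xmax <- max(carto$x_um) + dx_img
      ymax <- nrow(img) * dy_img
      for (p in polys) {
        if (any(p[, 1] < -dx_img | p[, 1] > xmax | p[, 2] < -dy_img | p[, 2] > ymax))
          eht_stop("eht_range_error", "seed outside cartography")
      }
    } else {
      img <- carto; dy_img <- dx_img <- raster_res_um
    }
  }

  ## pairwise overlap check on a raster
  if (n > 1) {
    bad <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ov <- polygon_overlap_area(polys[[i]], polys[[j]], res = raster_res_um)
      if (ov > overlap_tol_um2) bad[[length(bad) + 1L]] <- c(rois[[i]]$id, rois[[j]]$id)
    }
    if (length(bad)) {
      eht_stop("eht_paving_error",
               paste0("seed polygons overlap beyond tolerance: ",
                      paste(vapply(bad, paste, "", collapse = "-"), collapse = ", ")),
               ids = bad)
    }
  }

  ## snake: attract boundaries to the junction intensity ridge
  if (!is.null(img)) {
    blur <- gaussian_blur_2d(img, sigma_px = 1)
    for (i in seq_len(n)) {
      p <- densify_polygon(polys[[i]], step = raster_res_um * 2)
      for (it in seq_len(snake_iters)) {
        m <- nrow(p)
        nxt <- p[c(2:m, 1), , drop = FALSE]
        prv <- p[c(m, 1:(m - 1)), , drop = FALSE]
        tg <- nxt - prv
        tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
        nrm <- cbind(tg[, 2], -tg[, 1])
        offs <- seq(-snake_search_um, snake_search_um, length.out = 9)
        best <- matrix(0, m, length(offs))
        for (k in seq_along(offs)) {
          q <- p + offs[k] * nrm
          best[, k] <- interp2(blur, dy_img, dx_img, q[, 2], q[, 1])
        }
        w <- best - 0.5 * apply(best, 1, max)
        w[w < 0] <- 0
        sw <- rowSums(w)
        shift <- ifelse(sw > 0, rowSums(w * rep(offs, each = m)) / pmax(sw, 1e-12), 0)
        p <- p + 0.5 * shift * nrm
        ## curvature regularization: light closed smoothing
        p[, 1] <- as.numeric(smooth_circular(p[, 1], 2))
        p[, 2] <- as.numeric(smooth_circular(p[, 2], 2))
      }
      polys[[i]] <- p
    }
  }

  ## joint dilation on a raster
  allv <- do.call(rbind, polys)
  x0 <- min(allv[, 1]) - max_dilate_um; x1 <- max(allv[, 1]) + max_dilate_um
  y0 <- min(allv[, 2]) - max_dilate_um; y1 <- max(allv[, 2]) + max_dilate_um
  res <- raster_res_um
  xs <- seq(x0, x1, by = res); ys <- seq(y0, y1, by = res)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  D <- matrix(Inf, nrow(pts), n)
  for (i in seq_len(n)) D[, i] <- dist_to_polygon(pts, polys[[i]])
  lab <- max.col(-D, ties.method = "first")
  d1 <- D[cbind(seq_len(nrow(D)), lab)]
  D[cbind(seq_len(nrow(D)), lab)] <- Inf
  d2 <- D[cbind(seq_len(nrow(D)), max.col(-D, ties.method = "first"))]
  keep <- d1 == 0 | (d1 <= max_dilate_um & (d1 + d2) <= 2 * max_dilate_um)
  lab[!keep] <- 0L

  out <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- matrix(lab == i, nrow = length(ys), ncol = length(xs))
    if (!any(mask)) next
    cc <- EBImage::bwlabel(mask)
    big <- which.max(tabulate(cc[cc > 0]))
    bnd <- trace_boundary(cc == big)
    poly <- cbind(x0 + (bnd[, 2] - 1) * res, y0 + (bnd[, 1] - 1) * res)
    if (nrow(poly) < 3) poly <- polys[[i]]
    out[[i]] <- cell_roi(poly, id = rois[[i]]$id, type = rois[[i]]$type,
                         region = rois[[i]]$region, flags = rois[[i]]$flags)
  }
  out[!vapply(out, is.null, TRUE)]
}

## overlap area of two polygons, raster estimate
polygon_overlap_area <- function(p1, p2, res = 0.25) {
  b1 <- apply(p1, 2, range); b2 <- apply(p2, 2, range)
  lo <- pmax(b1[1, ], b2[1, ]); hi <- pmin(b1[2, ], b2[2, ])
  if (any(lo >= hi)) return(0)
  xs <- seq(lo[1], hi[1], by = res); ys <- seq(lo[2], hi[2], by = res)
  if (!length(xs) || !length(ys)) return(0)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  sum(points_in_polygon(pts, p1) & points_in_polygon(pts, p2)) * res^2
}

## separable Gaussian blur of a matrix
gaussian_blur_2d <- function(mat, sigma_px = 1) {
  if (sigma_px <= 0) return(mat)
  r <- ceiling(3 * sigma_px)
  k <- stats::dnorm(-r:r, sd = sigma_px); k <- k / sum(k)
  pad <- function(m, r) rbind(m[rep(1, r), , drop = FALSE], m,
                              m[rep(nrow(m), r), , drop = FALSE])
  conv_cols <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(mat))))
}

## ---- neighbor counting ----------------------------------------------------

#' Count touching neighbors in a paving
#'
#' A neighbor pair shares a boundary stretch of positive length; vertex-only
#' contact does not count. For pavings with exactly coincident boundaries
#' (e.g. Voronoi polygons) shared lengths are computed exactly from collinear
#' edge overlaps. If no pair shares any boundary the input is not a paving: a
#' warning is raised and adjacency falls back to a distance criterion
#' (boundaries approaching within `contact_tol_um`).
#'
#' @param rois list of [cell_roi()] or polygons.
#' @param min_shared_um minimum shared boundary length to count as neighbors.
#' @param contact_tol_um distance tolerance of the fallback criterion (also
#'   used for rasterized pavings whose boundaries are one pixel apart).
#' @return List: `counts` named integer vector (by ROI id), `pairs`
#'   data.frame (i, j, shared_length).
#' @export
count_neighbors <- function(rois, min_shared_um = 1e-6, contact_tol_um = 0.6) {
  polys <- lapply(rois, roi_polygon)
  ids <- vapply(seq_along(rois), function(i) {
    id <- if (inherits(rois[[i]], "cell_roi")) rois[[i]]$id else NA_integer_
    if (is.na(id)) i else as.integer(id)
  }, 0L)
  n <- length(polys)
  pairs <- list()
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    sl <- shared_boundary_length(polys[[i]], polys[[j]])
    if (sl >= min_shared_um) {
      pairs[[length(pairs) + 1L]] <- data.frame(i = i, j = j, shared_length = sl)
    }
  }
  if (!length(pairs) && n > 1) {
    ## not a coincident-boundary paving: distance-based adjacency
    near <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      bi <- densify_polygon(polys[[i]], step = contact_tol_um / 3)
      d <- dist_to_boundary(bi, polys[[j]])
      len <- sum(d <= contact_tol_um) * contact_tol_um / 3
      if (len >= max(min_shared_um, 3 * contact_tol_um)) {
        near[[length(near) + 1L]] <- data.frame(i = i, j = j, shared_length = len)
      }
    }
    if (length(near)) {
      eht_warn("eht_not_a_paving",
               "no coincident boundaries; using distance-based adjacency")
      pairs <- near
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(i = integer(0), j = integer(0), shared_length = numeric(0))
  counts <- integer(n)
  if (nrow(pairs)) {
    t1 <- table(factor(pairs$i, levels = seq_len(n))) +
      table(factor(pairs$j, levels = seq_len(n)))
    counts <- as.integer(t1)
  }
  names(counts) <- ids
  pairs$i <- ids[pairs$i]; pairs$j <- ids[pairs$j]
  list(counts = counts, pairs = pairs)
}

## exact shared length of coincident (collinear, overlapping) edges
shared_boundary_length <- function(p1, p2, eps = 1e-6) {
  p1 <- as_polygon(p1); p2 <- as_polygon(p2)
  ## bbox prefilter
  if (max(p1[, 1]) < min(p2[, 1]) - eps || max(p2[, 1]) < min(p1[, 1]) - eps ||
      max(p1[, 2]) < min(p2[, 2]) - eps || max(p2[, 2]) < min(p1[, 2]) - eps)
    return(0)
  n1 <- nrow(p1); n2 <- nrow(p2)
  a1 <- p1; b1 <- p1[c(2:n1, 1), , drop = FALSE]
  a2 <- p2; b2 <- p2[c(2:n2, 1), , drop = FALSE]
  total <- 0
  for (i in seq_len(n1)) {
    u <- b1[i, ] - a1[i, ]
    L <- sqrt(sum(u^2))
    if (L < eps) next
    u <- u / L
    ## perpendicular distances of both endpoints of each edge of p2
    w1x <- a2[, 1] - a1[i, 1]; w1y <- a2[, 2] - a1[i, 2]
    w2x <- b2[, 1] - a1[i, 1]; w2y <- b2[, 2] - a1[i, 2]
    cr1 <- abs(u[1] * w1y - u[2] * w1x)
    cr2 <- abs(u[1] * w2y - u[2] * w2x)
    col <- cr1 < eps & cr2 < eps
    if (!any(col)) next
    t1a <- w1x[col] * u[1] + w1y[col] * u[2]
    t1b <- w2x[col] * u[1] + w2y[col] * u[2]
    lo <- pmax(pmin(t1a, t1b), 0)
    hi <- pmin(pmax(t1a, t1b), L)
    total <- total + sum(pmax(hi - lo, 0))
  }
  total
}

## ---- classification -------------------------------------------------------

#' Classify a cell by morphometric rules
#'
#' Region is assigned from the arc position of the polygon centroid (floor =
#' within `sectors[1]` degrees of the reference line, roof = within
#' `sectors[2]` degrees of the opposite line, lateral otherwise). The type
#' cascade then applies, in order: floor + luminal inward bending -> EHT
#' pol+; floor + rounded/ovoid outward shape + short axial length -> EHT
#' pol-; floor or lateral + elongation >= `e_min` + thick nucleus ->
#' hemogenic; roof position or flat nucleus -> endothelial; otherwise
#' uncharacterized. Shape flags come from 3D inspection (or a phantom
#' ledger); missing flags skip their rules and mark the call low-confidence.
#'
#' @param roi a [cell_roi()] (supplies flags and the centroid).
#' @param morph its [compute_morphometrics()] result.
#' @param perimeter_um cartography perimeter used to convert arc position to
#'   an angle.
#' @param sectors numeric(2): floor and roof half-widths, degrees.
#' @param e_min elongation threshold for "elongated".
#' @param short_axis_um axial-length threshold for the rounded EHT pol- rule.
#' @return List: type, region, low_confidence.
#' @export
classify_cell_type <- function(roi, morph, perimeter_um, sectors = c(60, 60),
                               e_min = 2.0, short_axis_um = 10) {
  ctr <- polygon_centroid(roi_polygon(roi))
  ang <- (ctr[2] %% perimeter_um) / perimeter_um * 360
  region <- if (ang <= sectors[1] || ang >= 360 - sectors[1]) "floor"
  else if (ang >= 180 - sectors[2] && ang <= 180 + sectors[2]) "roof"
  else "lateral"
  fl <- if (inherits(roi, "cell_roi")) roi$flags else
    list(inward_bending = NA, outward_round = NA, nucleus_thick = NA)
  low_conf <- any(vapply(fl, function(f) is.na(f), TRUE))
  type <- if (region == "floor" && isTRUE(fl$inward_bending)) {
    "EHT_pol_plus"
  } else if (region == "floor" && isTRUE(fl$outward_round) &&
             morph$major_length_um < short_axis_um) {
    "EHT_pol_minus"
  } else if (region %in% c("floor", "lateral") &&
             morph$elongation >= e_min && isTRUE(fl$nucleus_thick)) {
    "hemogenic"
  } else if (region == "roof" || isFALSE(fl$nucleus_thick)) {
    "endothelial"
  } else {
    "uncharacterized"
  }
  list(type = type, region = region, low_confidence = low_conf)
}

#' Summarize a segment's classified cells
#'
#' @param rois list of classified [cell_roi()] (types/regions filled in).
#' @param morphs optional list of matching [compute_morphometrics()] results.
#' @param count_uncharacterized_as_hemogenic count uncharacterized emerging
#'   cells with the hemogenic cells in the per-type totals (switchable, off
#'   by default).
#' @return List: `counts` (type x region table), `cells` per-cell descriptor
#'   data.frame.
#' @export
summarize_segment <- function(rois, morphs = NULL,
                              count_uncharacterized_as_hemogenic = FALSE) {
  if (!length(rois)) {
    tab <- table(factor(character(0), levels = CELL_TYPES),
                 factor(character(0), levels = CELL_REGIONS))
    return(list(counts = tab,
                cells = data.frame(id = integer(0), type = character(0),
                                   region = character(0))))
  }
  type <- vapply(rois, function(r) r$type %||% "uncharacterized", "")
  if (count_uncharacterized_as_hemogenic) type[type == "uncharacterized"] <- "hemogenic"
  region <- vapply(rois, function(r) {
    if (is.null(r$region) || is.na(r$region)) "lateral" else r$region
  }, "")
  cells <- data.frame(id = vapply(rois, function(r) as.integer(r$id), 0L),
                      type = type, region = region)
  if (!is.null(morphs)) {
    cells$area_um2 <- vapply(morphs, `[[`, 0, "area_um2")
    cells$elongation <- vapply(morphs, `[[`, 0, "elongation")
    cells$orientation_deg <- vapply(morphs, `[[`, 0, "orientation_deg")
    cells$major_length_um <- vapply(morphs, `[[`, 0, "major_length_um")
  }
  counts <- table(factor(type, levels = CELL_TYPES),
                  factor(region, levels = CELL_REGIONS))
  list(counts = counts, cells = cells)
}
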