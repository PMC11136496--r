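## Planar polygon primitives. No computational-geometry package ships with the
## environment, so the handful of operations the morphometric analysis needs
## (shoelace area, half-plane clipping, Voronoi cells, boundary tracing,
## point-to-polygon distance) are implemented here directly. Polygons are
## n x 2 matrices of vertices in order, without a repeated closing vertex.

#' Signed polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of vertices (x, y), not closed.
#' @return Signed area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon perimeter
#' @param poly n x 2 vertex matrix.
#' @return Total boundary length.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as_polygon(poly)
  d <- sqrt(rowSums((poly[c(2:nrow(poly), 1), , drop = FALSE] - poly)^2))
  sum(d)
}

#' Polygon centroid (area-weighted)
#' @param poly n x 2 vertex matrix.
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3) {
    eht_stop("eht_geometry_error", "polygon must be an n x 2 matrix with n >= 3")
  }
  ## drop a duplicated closing vertex if present
  n <- nrow(poly)
  if (all(abs(poly[1, ] - poly[n, ]) < 1e-12)) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3) eht_stop("eht_geometry_error", "degenerate polygon")
  unname(poly)
}

#' Test points for inclusion in a polygon
#'
#' Wrapper around [mgcv::in.out()]; points on the boundary may fall on either
#' side at floating-point resolution.
#' @param pts m x 2 matrix of points.
#' @param poly n x 2 vertex matrix.
#' @return Logical vector of length m.
#' @export
points_in_polygon <- function(pts, poly) {
  poly <- as_polygon(poly)
  pts <- rbind(as.matrix(pts))
  bnd <- rbind(poly, poly[1, ])
  mgcv::in.out(bnd, pts)
}

## Clip polygon with the half-plane {p : a . p <= b} (Sutherland-Hodgman).
## Returns a matrix with 0 rows when the polygon is fully clipped away.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- poly %*% a - b
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi <= 0) out <- rbind(out, poly[i, ])
    if ((vi <= 0) != (vj <= 0)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Voronoi paving of a rectangle
#'
#' Computes the Voronoi cell of every seed by successive half-plane clipping
#' of the bounding rectangle with perpendicular bisectors. Optionally periodic
#' in y (used for pavings of an unwrapped cylinder surface, where the arc
#' coordinate wraps at the perimeter).
#'
#' @param seeds n x 2 matrix of seed points.
#' @param bbox numeric(4): xmin, xmax, ymin, ymax.
#' @param period_y optional period for the y axis; seeds are virtually
#'   replicated at y +/- period so cells wrap correctly.
#' @return List with `polygons` (list of vertex matrices, one per seed) and
#'   `adjacency` (data.frame i, j, shared_length with i < j, from the clipping
#'   construction: pairs whose bisector contributes an edge of positive length).
#' @export
voronoi_paving <- function(seeds, bbox, period_y = NULL) {
  seeds <- rbind(as.matrix(seeds))
  n <- nrow(seeds)
  if (n < 1) eht_stop("eht_config_error", "need at least one seed")
  rect <- rbind(c(bbox[1], bbox[3]), c(bbox[2], bbox[3]),
                c(bbox[2], bbox[4]), c(bbox[1], bbox[4]))
  ## replicated generator set (index maps back to base seed)
  gen <- seeds; gmap <- seq_len(n)
  if (!is.null(period_y)) {
    gen <- rbind(gen,
                 cbind(seeds[, 1], seeds[, 2] + period_y),
                 cbind(seeds[, 1], seeds[, 2] - period_y))
    gmap <- rep(seq_len(n), 3)
  }
  polys <- vector("list", n)
  adj <- list()
  for (i in seq_len(n)) {
    poly <- rect
    cons <- list()  # constraints applied: list of (a, b, base index of j)
    d2 <- rowSums((gen - matrix(seeds[i, ], nrow(gen), 2, byrow = TRUE))^2)
    ord <- order(d2)
    for (k in ord) {
      if (!is.null(period_y)) { if (d2[k] == 0 && gmap[k] == i) next } else if (k == i) next
      if (nrow(poly) == 0) break
      a <- 2 * (gen[k, ] - seeds[i, ])
      b <- sum(gen[k, ]^2) - sum(seeds[i, ]^2)
      poly2 <- clip_halfplane(poly, a, b)
      if (nrow(poly2) < nrow(poly) || !isTRUE(all.equal(poly2, poly, tolerance = 1e-12))) {
        cons[[length(cons) + 1L]] <- list(a = a, b = b, j = gmap[k])
      }
      poly <- poly2
    }
    polys[[i]] <- poly
    ## measure edge length lying on each recorded bisector
    if (nrow(poly) >= 3 && length(cons)) {
      m <- nrow(poly)
      e1 <- poly; e2 <- poly[c(2:m, 1), , drop = FALSE]
      mid <- (e1 + e2) / 2
      len <- sqrt(rowSums((e2 - e1)^2))
      for (cn in cons) {
        scale <- sqrt(sum(cn$a^2))
        on_edge <- abs(mid %*% cn$a - cn$b) / scale < 1e-7
        sl <- sum(len[on_edge])
        if (sl > 0 && cn$j != i) {
          adj[[length(adj) + 1L]] <- data.frame(i = i, j = cn$j, shared_length = sl)
        }
      }
    }
  }
  adjacency <- if (length(adj)) {
    a <- do.call(rbind, adj)
    a[c("i", "j")] <- list(pmin(a$i, a$j), pmax(a$i, a$j))
    a <- stats::aggregate(shared_length ~ i + j, a, max)
    a[order(a$i, a$j), ]
  } else data.frame(i = integer(0), j = integer(0), shared_length = numeric(0))
  list(polygons = polys, adjacency = adjacency)
}

#' Shrink a polygon towards its centroid
#'
#' Moves every vertex a fixed distance towards the centroid (an approximate
#' inward offset, exact for star-shaped cells). Used to derive under-sized
#' seed outlines from ground-truth pavings.
#' @param poly n x 2 vertex matrix.
#' @param d shrink distance (same units as coordinates).
#' @return Shrunk polygon.
#' @export
shrink_polygon <- function(poly, d) {
  poly <- as_polygon(poly)
  ctr <- polygon_centroid(poly)
  v <- sweep(poly, 2, ctr)
  r <- sqrt(rowSums(v^2))
  f <- pmax(0.05, 1 - d / pmax(r, 1e-9))
  sweep(v * f, 2, ctr, `+`)
}

## Minimum distance from points (m x 2) to a polygon boundary.
dist_to_boundary <- function(pts, poly) {
  poly <- as_polygon(poly)
  pts <- rbind(as.matrix(pts))
  n <- nrow(poly)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == n) 1L else i + 1L, ]
    e <- p2 - p1
    L2 <- sum(e^2)
    if (L2 == 0) next
    t <- pmin(1, pmax(0, ((pts[, 1] - p1[1]) * e[1] + (pts[, 2] - p1[2]) * e[2]) / L2))
    dx <- p1[1] + t * e[1] - pts[, 1]
    dy <- p1[2] + t * e[2] - pts[, 2]
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  dmin
}

## Signed-ish distance from points to a polygon: 0 inside, boundary distance
## outside.
dist_to_polygon <- function(pts, poly) {
  d <- dist_to_boundary(pts, poly)
  inside <- points_in_polygon(pts, poly)
  d[inside] <- 0
  d
}

## Resample a closed polygon boundary at (approximately) equal arc steps.
densify_polygon <- function(poly, step) {
  poly <- as_polygon(poly)
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  out <- list()
  for (i in seq_len(nrow(poly))) {
    k <- max(1L, ceiling(seg[i] / step))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(closed[i, 1] + t * (closed[i + 1, 1] - closed[i, 1]),
                      closed[i, 2] + t * (closed[i + 1, 2] - closed[i, 2]))
  }
  do.call(rbind, out)
}

#' Rasterize a filled polygon
#'
#' @param poly n x 2 vertex matrix (physical units).
#' @param res pixel size.
#' @param pad margin added around the bounding box, in pixels.
#' @return List: `mask` logical matrix (rows = y, cols = x), `x0`, `y0` the
#'   physical coordinates of the center of pixel (1, 1), `res`.
#' @export
rasterize_polygon <- function(poly, res = 0.1, pad = 2L) {
  poly <- as_polygon(poly)
  x0 <- min(poly[, 1]) - pad * res
  y0 <- min(poly[, 2]) - pad * res
  nx <- ceiling((max(poly[, 1]) - x0) / res) + pad
  ny <- ceiling((max(poly[, 2]) - y0) / res) + pad
  xs <- x0 + (seq_len(nx) - 1L) * res
  ys <- y0 + (seq_len(ny) - 1L) * res
  pts <- cbind(rep(xs, each = ny), rep(ys, nx))
  mask <- matrix(points_in_polygon(pts, poly), nrow = ny, ncol = nx)
  list(mask = mask, x0 = x0, y0 = y0, res = res)
}

## Trace the outer boundary of a connected region in a logical matrix
## (Moore-neighbour tracing). Returns pixel-index coordinates (row, col) of the
## boundary path. The region is assumed 8-connected and to contain >= 1 pixel.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  ## pad to avoid border checks
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  ## start: first TRUE pixel in column-major scan
  idx <- which(m)[1]
  if (is.na(idx)) eht_stop("eht_geometry_error", "empty mask")
  start <- c((idx - 1) %% (nr + 2) + 1, (idx - 1) %/% (nr + 2) + 1)
  ## Moore neighbourhood, clockwise starting from west
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  path <- list(start)
  cur <- start
  enter <- 1L  # direction we came from (west)
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- ((enter - 1L + s) %% 8L) + 1L
      cand <- cur + nb[k, ]
      if (m[cand[1], cand[2]]) {
        ## next search starts from the neighbour counter-clockwise of the move
        enter <- ((k - 1L + 6L) %% 8L) + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && length(path) > 2) break
    path[[length(path) + 1L]] <- cur
    if (length(path) > 8L * (nr * nc)) break  # safety
  }
  do.call(rbind, path) - 1L  # un-pad
}

## Maximal caliper length of a polygon: the diameter of its vertex set (the
## polygon diameter is attained at hull vertices, a subset of the vertices).
caliper_length <- function(poly) {
  poly <- as_polygon(poly)
  max(stats::dist(poly))
}

#' Exact second-order moments of a polygon
#'
#' Closed-form surface integrals (Green's theorem), no rasterization. Returns
#' the area, centroid and the normalized central second moments, plus the
#' equivalent-ellipse descriptors derived from them.
#' @param poly n x 2 vertex matrix.
#' @return List: area, centroid, mu20, mu02, mu11, elongation,
#'   orientation_deg (major axis vs x, in [0, 180)), major_axis_length,
#'   minor_axis_length (full equivalent-ellipse diameters).
#' @export
polygon_moments <- function(poly) {
  poly <- as_polygon(poly)
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (A <= 0) eht_stop("eht_geometry_error", "polygon has zero area")
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Iy <- sum((x^2 + x * xn + xn^2) * cr) / 12   # integral of x^2 dA
  Ix <- sum((y^2 + y * yn + yn^2) * cr) / 12   # integral of y^2 dA
  Ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  mu20 <- Iy / A - cx^2
  mu02 <- Ix / A - cy^2
  mu11 <- Ixy / A - cx * cy
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  l2 <- max(l2, .Machine$double.eps)
  theta <- atan2(2 * mu11, mu20 - mu02) / 2 * 180 / pi
  theta <- theta %% 180
  list(area = A, centroid = c(cx, cy), mu20 = mu20, mu02 = mu02, mu11 = mu11,
       elongation = sqrt(l1 / l2), orientation_deg = theta,
       major_axis_length = 4 * sqrt(l1), minor_axis_length = 4 * sqrt(l2))
}
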