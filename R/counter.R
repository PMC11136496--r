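## Hematopoietic cell counter for dual-channel stacks. Circulating
## thrombocytes move faster than the acquisition and appear as single-plane
## outliers; a rolling median over ~20 planes (the approximate cell depth)
## removes them while preserving objects spanning 15-20 planes. The retained
## signal is contrast-stretched, background-subtracted (rolling ball),
## blurred, segmented by white top-hat + threshold, split by
## distance-transform watershed, measured on the raw data and classified by
## per-channel intensity thresholds. Arrays are (y, x, plane).

## ---- rolling median over planes ------------------------------------------

## medians of the rows of an n x w matrix, via one vectorized sort
row_medians <- function(M) {
  w <- ncol(M)
  if (w == 1) return(M[, 1])
  o <- order(row(M), M)
  S <- matrix(M[o], ncol = w, byrow = TRUE)
  if (w %% 2 == 1) S[, (w + 1) / 2] else (S[, w / 2] + S[, w / 2 + 1]) / 2
}

#' Rolling-median filter along the plane axis
#'
#' Replace mode substitutes every plane with the centered rolling median over
#' `window` planes (edge-truncated), removing objects present in a single
#' plane while keeping objects spanning at least ~window planes. Subtract
#' mode subtracts the rolling median and clips negatives (retains the
#' transient component instead).
#'
#' @param arr 3D array (y, x, plane).
#' @param window window size in planes (approximate cell depth).
#' @param mode "replace" or "subtract".
#' @return Filtered array, same dims.
#' @export
temporal_median <- function(arr, window = 20L, mode = c("replace", "subtract")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  if (length(d) != 3) eht_stop("eht_config_error", "expected a 3D array")
  if (window < 1 || window > d[3]) {
    eht_stop("eht_window_error", "window must be between 1 and the plane count")
  }
  half_lo <- floor(window / 2); half_hi <- ceiling(window / 2) - 1L
  npix <- d[1] * d[2]
  flat <- matrix(arr, npix, d[3])
  med <- matrix(0, npix, d[3])
  for (k in seq_len(d[3])) {
    lo <- max(1L, k - half_lo); hi <- min(d[3], k + half_hi)
    med[, k] <- row_medians(flat[, lo:hi, drop = FALSE])
  }
  out <- if (mode == "replace") med else pmax(flat - med, 0)
  array(out, d)
}

## ---- grayscale morphology with ball / disc structuring elements ----------

ball_offsets <- function(r, three_d = TRUE) {
  s <- -r:r
  if (three_d) {
    g <- expand.grid(dy = s, dx = s, dz = s)
    g[g$dy^2 + g$dx^2 + g$dz^2 <= r^2, , drop = FALSE]
  } else {
    g <- expand.grid(dy = s, dx = s)
    g$dz <- 0L
    g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  }
}

shift3 <- function(a, dy, dx, dz, fill) {
  d <- dim(a)
  out <- array(fill, d)
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[ys, xs, zs] <- a[ys - dy, xs - dx, zs - dz]
  out
}

gray_morph <- function(a, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  fill <- if (op == "erode") Inf else -Inf
  acc <- NULL
  for (i in seq_len(nrow(offsets))) {
    sh <- shift3(a, offsets$dy[i], offsets$dx[i], offsets$dz[i], fill)
    acc <- if (is.null(acc)) sh else if (op == "erode") pmin(acc, sh) else pmax(acc, sh)
  }
  acc[!is.finite(acc)] <- 0
  acc
}

## separable erosion/dilation with a box SE of per-axis radii (y, x, z):
## iterated 1-voxel shifts along each axis (edge-truncated)
gray_morph_box <- function(a, radii, op = c("erode", "dilate")) {
  op <- match.arg(op)
  fill <- if (op == "erode") Inf else -Inf
  comb <- if (op == "erode") pmin else pmax
  radii <- rep_len(radii, 3)
  for (ax in 1:3) {
    r <- radii[ax]
    if (r <= 0) next
    base <- a
    for (s in c(seq_len(r), -seq_len(r))) {
      off <- c(0L, 0L, 0L); off[ax] <- s
      a <- comb(a, shift3(base, off[1], off[2], off[3], fill))
    }
  }
  a[!is.finite(a)] <- 0
  a
}

#' White top-hat transform
#'
#' Image minus its grayscale opening. The structuring element is, by
#' default, a separable box with per-axis radii (y, x, z); `shape = "ball"`
#' uses an exact ellipsoidal element (slower). For cell segmentation the
#' element must be larger than a cell's in-plane footprint so that the
#' opening removes the cells and the top-hat retains them over a flattened
#' background.
#'
#' @param a 3D array.
#' @param radii per-axis SE radii (y, x, z), voxels; scalar is recycled.
#' @param shape "box" or "ball".
#' @return Top-hat image (>= 0).
#' @export
white_tophat <- function(a, radii, shape = c("box", "ball")) {
  shape <- match.arg(shape)
  radii <- rep_len(radii, 3)
  if (any(2 * radii + 1 > dim(a))) {
    eht_stop("eht_config_error", "structuring element larger than the image")
  }
  opened <- if (shape == "box") {
    gray_morph_box(gray_morph_box(a, radii, "erode"), radii, "dilate")
  } else {
    off <- ball_offsets(max(radii), three_d = radii[3] > 0)
    keep <- (off$dy / max(radii[1], 1))^2 + (off$dx / max(radii[2], 1))^2 +
      (off$dz / max(radii[3], 0.5))^2 <= 1
    off <- off[keep, , drop = FALSE]
    gray_morph(gray_morph(a, off, "erode"), off, "dilate")
  }
  pmax(a - opened, 0)
}

## separable 3D Gaussian blur
gaussian_blur_3d <- function(a, sigma = c(1, 1, 1)) {
  sigma <- rep_len(sigma, 3)
  if (any(sigma < 0)) eht_stop("eht_config_error", "blur sigma must be >= 0")
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s == 0) next
    r <- ceiling(3 * s)
    k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
    m <- switch(ax,
                matrix(a, d[1], d[2] * d[3]),
                matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[3]),
                matrix(aperm(a, c(3, 1, 2)), d[3], d[1] * d[2]))
    n <- nrow(m)
    mp <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1), , drop = FALSE]
    a <- switch(ax,
                array(out, d),
                aperm(array(out, d[c(2, 1, 3)]), c(2, 1, 3)),
                aperm(array(out, d[c(3, 1, 2)]), c(2, 3, 1)))
  }
  a
}

#' Pre-processing chain for the cell counter
#'
#' Percentile contrast stretch, per-plane rolling-ball background
#' subtraction (grayscale opening with a disc), then 3D Gaussian blur, in
#' that order.
#'
#' @param arr 3D array (y, x, plane).
#' @param contrast lower/upper stretch quantiles.
#' @param bg_radius_px rolling-ball radius (per-plane box SE), pixels; must
#'   exceed the cell footprint so cells survive the subtraction; 0 skips.
#' @param blur_sigma_px Gaussian sigmas (y, x, plane), pixels.
#' @return Processed array in [0, 1].
#' @export
preprocess_stack <- function(arr, contrast = c(0.01, 0.999),
                             bg_radius_px = 12L, blur_sigma_px = c(1, 1, 0.7)) {
  if (bg_radius_px < 0) eht_stop("eht_config_error", "bg_radius_px must be >= 0")
  if (any(blur_sigma_px < 0)) eht_stop("eht_config_error", "blur sigma must be >= 0")
  q <- stats::quantile(arr, contrast, names = FALSE)
  arr <- if (q[2] > q[1]) pmin(pmax((arr - q[1]) / (q[2] - q[1]), 0), 1) else arr * 0
  if (bg_radius_px > 0 && any(arr > 0)) {
    opened <- gray_morph_box(gray_morph_box(arr, c(bg_radius_px, bg_radius_px, 0),
                                            "erode"),
                             c(bg_radius_px, bg_radius_px, 0), "dilate")
    arr <- pmax(arr - opened, 0)
  }
  if (any(blur_sigma_px > 0)) arr <- gaussian_blur_3d(arr, blur_sigma_px)
  arr
}

## 3D connected-component labeling: 2D labeling per plane (EBImage) merged
## across planes with union-find.
label3d <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    l <- EBImage::bwlabel(mask[, , z] * 1)
    l[l > 0] <- l[l > 0] + offset
    labs[, , z] <- l
    offset <- max(offset, max(l))
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (z in seq_len(d[3] - 1)) {
    a <- labs[, , z]; b <- labs[, , z + 1]
    both <- a > 0 & b > 0
    if (!any(both)) next
    prs <- unique(cbind(a[both], b[both]))
    for (r in seq_len(nrow(prs))) {
      ra <- find(prs[r, 1]); rb <- find(prs[r, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(offset), find, 0L)
  relab <- match(root, unique(root))
  labs[labs > 0] <- relab[labs[labs > 0]]
  labs
}

## Split touching objects within each connected component, using the exact
## Euclidean inner distance (distance to the nearest background voxel, which
## always lies 6-adjacent to the mask): seeds are the connected clusters of
## voxels deeper than (component max depth - tolerance); components with > 1
## seed cluster are reallocated to the nearest seed centroid (ties resolved
## toward the lowest label id by the ordering of seeds).
watershed_split <- function(labs, tolerance = 0.5) {
  d <- dim(labs)
  mask <- labs > 0
  ## background voxels 6-adjacent to the mask
  dil <- mask
  dil[-1, , ] <- dil[-1, , ] | mask[-d[1], , ]
  dil[-d[1], , ] <- dil[-d[1], , ] | mask[-1, , ]
  dil[, -1, ] <- dil[, -1, ] | mask[, -d[2], ]
  dil[, -d[2], ] <- dil[, -d[2], ] | mask[, -1, ]
  dil[, , -1] <- dil[, , -1] | mask[, , -d[3]]
  dil[, , -d[3]] <- dil[, , -d[3]] | mask[, , -1]
  bg_surf <- which(dil & !mask)
  coord3 <- function(idx) cbind((idx - 1) %% d[1] + 1,
                                ((idx - 1) %/% d[1]) %% d[2] + 1,
                                (idx - 1) %/% (d[1] * d[2]) + 1)
  bgc <- coord3(bg_surf)
  out <- labs
  nxt <- max(labs)
  for (id in seq_len(max(labs))) {
    sel <- which(labs == id)
    if (!length(sel)) next
    vox_all <- coord3(sel)
    ## restrict background surface to this component's neighborhood
    rng <- apply(vox_all, 2, range)
    near <- bgc[, 1] >= rng[1, 1] - 1 & bgc[, 1] <= rng[2, 1] + 1 &
      bgc[, 2] >= rng[1, 2] - 1 & bgc[, 2] <= rng[2, 2] + 1 &
      bgc[, 3] >= rng[1, 3] - 1 & bgc[, 3] <= rng[2, 3] + 1
    bl <- bgc[near, , drop = FALSE]
    depth_sel <- vapply(seq_len(nrow(vox_all)), function(i) {
      sqrt(min((bl[, 1] - vox_all[i, 1])^2 + (bl[, 2] - vox_all[i, 2])^2 +
                 (bl[, 3] - vox_all[i, 3])^2))
    }, 0)
    ## smooth the depth field so boundary digitization noise (about half a
    ## voxel of relief) does not seed spurious basins
    lo <- apply(vox_all, 2, min) - 2L; hi <- apply(vox_all, 2, max) + 2L
    loc <- array(0, hi - lo + 1L)
    loc[cbind(vox_all[, 1] - lo[1] + 1L, vox_all[, 2] - lo[2] + 1L,
              vox_all[, 3] - lo[3] + 1L)] <- depth_sel
    loc <- gaussian_blur_3d(loc, c(0.5, 0.5, 0.5))
    depth_sel <- loc[cbind(vox_all[, 1] - lo[1] + 1L, vox_all[, 2] - lo[2] + 1L,
                           vox_all[, 3] - lo[3] + 1L)]
    ## flood from the deepest voxels down; basins merge unless both peaks
    ## rise more than `tolerance` above the saddle where they meet
    ord <- order(depth_sel, decreasing = TRUE)
    key <- vox_all[, 1] + (vox_all[, 2] - 1) * d[1] + (vox_all[, 3] - 1) * d[1] * d[2]
    pos <- integer(0); pos[key] <- seq_along(sel)   # sparse lookup
    basin <- integer(length(sel))
    parent <- integer(0); peak <- numeric(0)
    find_root <- function(b) { while (parent[b] != b) b <- parent[b]; b }
    nb_off <- c(-1, 1, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
    for (v in ord) {
      kv <- key[v]
      nb <- kv + nb_off
      nb <- nb[nb >= 1 & nb <= length(pos)]
      nb_i <- pos[nb]
      nb_b <- basin[nb_i[!is.na(nb_i) & nb_i > 0]]
      nb_b <- unique(nb_b[nb_b > 0])
      if (length(nb_b)) nb_b <- unique(vapply(nb_b, find_root, 0L))
      if (length(nb_b) == 0) {
        parent <- c(parent, length(parent) + 1L)
        peak <- c(peak, depth_sel[v])
        basin[v] <- length(parent)
      } else if (length(nb_b) == 1) {
        basin[v] <- nb_b
      } else {
        keep_b <- nb_b[which.max(peak[nb_b])]
        for (b in setdiff(nb_b, keep_b)) {
          if (peak[b] - depth_sel[v] < tolerance) {
            parent[b] <- keep_b
            peak[keep_b] <- max(peak[keep_b], peak[b])
          }
        }
        basin[v] <- keep_b
      }
    }
    roots <- vapply(basin, find_root, 0L)
    u <- unique(roots)
    if (length(u) <= 1) next
    ren <- match(roots, u)
    out[sel] <- ifelse(ren == 1L, id, nxt + ren - 1L)
    nxt <- nxt + length(u) - 1L
  }
  ## compact labels
  u <- sort(unique(out[out > 0]))
  out[out > 0] <- match(out[out > 0], u)
  out
}

#' Segment objects by top-hat + threshold + watershed
#'
#' White top-hat with a spherical structuring element, global threshold,
#' connected components, and (optionally) distance-transform watershed to
#' split touching objects, followed by a minimum-size filter.
#'
#' @param arr preprocessed 3D array.
#' @param tophat_radii_px structuring-element radii (y, x, plane), voxels;
#'   the in-plane radii must exceed a cell's footprint.
#' @param threshold absolute threshold on the top-hat image, or `"auto"`
#'   (median + 4 SD).
#' @param min_size_vox minimum object size.
#' @param watershed_tolerance basin-depth suppression (h-minima analogue) of
#'   the watershed split; lower splits more.
#' @param split_touching apply the watershed split.
#' @return List: `labels` (int array), `table` data.frame (id, n_vox,
#'   centroid_y/x/z in voxels).
#' @export
segment_objects <- function(arr, tophat_radii_px = c(9, 9, 2),
                            threshold = "auto",
                            min_size_vox = 50L, watershed_tolerance = 0.5,
                            split_touching = TRUE) {
  th <- white_tophat(arr, tophat_radii_px)
  thr <- if (identical(threshold, "auto")) {
    stats::median(th) + 4 * stats::sd(th)
  } else as.numeric(threshold)
  mask <- th > thr
  empty <- list(labels = array(0L, dim(arr)),
                table = data.frame(id = integer(0), n_vox = integer(0),
                                   centroid_y = numeric(0), centroid_x = numeric(0),
                                   centroid_z = numeric(0)))
  if (!any(mask)) return(empty)
  labs <- label3d(mask)
  if (split_touching) labs <- watershed_split(labs, tolerance = watershed_tolerance)
  cnt <- tabulate(labs[labs > 0])
  keep <- which(cnt >= min_size_vox)
  if (!length(keep)) return(empty)
  relab <- integer(length(cnt)); relab[keep] <- seq_along(keep)
  labs[labs > 0] <- relab[labs[labs > 0]]
  idx <- which(labs > 0, arr.ind = TRUE)
  id <- labs[labs > 0]
  table <- data.frame(
    id = seq_along(keep),
    n_vox = as.integer(tabulate(id, length(keep))),
    centroid_y = as.numeric(tapply(idx[, 1], id, mean)),
    centroid_x = as.numeric(tapply(idx[, 2], id, mean)),
    centroid_z = as.numeric(tapply(idx[, 3], id, mean)))
  list(labels = labs, table = table)
}

#' Measure segmented objects on the raw data
#'
#' Per-object, per-channel total intensity from the unfiltered stack, with
#' background correction total - mean(background) * voxel count.
#'
#' @param labels integer label array from [segment_objects()].
#' @param raw named list of raw 3D arrays (e.g. `list(green = ..., red =
#'   ...)`), same dims as `labels`.
#' @param background_roi logical array marking background voxels, or NULL
#'   (totals returned uncorrected and flagged).
#' @return data.frame of class `object_table`: id, n_vox, centroids, and per
#'   channel `total_<ch>` / `corr_<ch>`; attribute `background_corrected`.
#' @export
measure_objects <- function(labels, raw, background_roi = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    eht_stop("eht_input_error", "no labeled objects to measure")
  }
  for (ch in names(raw)) {
    if (!identical(dim(raw[[ch]]), dim(labels))) {
      eht_stop("eht_input_error",
               sprintf("raw channel '%s' dims do not match labels", ch))
    }
  }
  sel <- labels > 0
  id <- labels[sel]
  idx <- which(sel, arr.ind = TRUE)
  nv <- tabulate(id, max(ids))[ids]
  out <- data.frame(id = ids, n_vox = as.integer(nv),
                    centroid_y = as.numeric(tapply(idx[, 1], id, mean)),
                    centroid_x = as.numeric(tapply(idx[, 2], id, mean)),
                    centroid_z = as.numeric(tapply(idx[, 3], id, mean)))
  corrected <- !is.null(background_roi)
  for (ch in names(raw)) {
    tot <- as.numeric(tapply(raw[[ch]][sel], id, sum))
    out[[paste0("total_", ch)]] <- tot
    if (corrected) {
      bg <- mean(raw[[ch]][background_roi])
      out[[paste0("corr_", ch)]] <- tot - bg * out$n_vox
    } else {
      out[[paste0("corr_", ch)]] <- NA_real_
    }
  }
  if (!corrected) {
    eht_warn("eht_no_background", "no background ROI: totals left uncorrected")
  }
  attr(out, "background_corrected") <- corrected
  class(out) <- c("object_table", class(out))
  out
}

#' Classify objects by per-channel thresholds
#'
#' Double-positive (green+ red+) objects are hemogenic cells; green-only
#' objects are hematopoietic (HSPC); anything else is "other".
#'
#' @param table an `object_table` from [measure_objects()].
#' @param thresholds named numeric, `green` and `red`, applied to the
#'   background-corrected totals (falls back to raw totals when correction
#'   was unavailable).
#' @return `table` with a `class` column; attribute `counts` (per class).
#' @export
classify_objects <- function(table, thresholds) {
  if (!all(c("green", "red") %in% names(thresholds))) {
    eht_stop("eht_classification_error", "thresholds must name green and red")
  }
  val <- function(ch) {
    v <- table[[paste0("corr_", ch)]]
    if (is.null(v) || all(is.na(v))) v <- table[[paste0("total_", ch)]]
    if (is.null(v)) eht_stop("eht_classification_error",
                             sprintf("channel '%s' missing from the table", ch))
    v
  }
  g <- val("green") > thresholds[["green"]]
  r <- val("red") > thresholds[["red"]]
  table$class <- ifelse(g & r, "hemogenic", ifelse(g & !r, "hspc", "other"))
  attr(table, "counts") <- table(factor(table$class,
                                        levels = c("hemogenic", "hspc", "other")))
  table
}

#' Suggest a channel threshold from a bimodal intensity split
#'
#' Two-means split of the values; the threshold is the midpoint between the
#' largest value of the lower group and the smallest value of the upper
#' group.
#' @param values per-object intensities.
#' @return Suggested threshold.
#' @export
suggest_threshold <- function(values) {
  if (length(values) < 2 || stats::sd(values) == 0) return(min(values) - 1)
  km <- stats::kmeans(values, centers = range(values))
  lo <- which.min(km$centers)
  mean(c(max(values[km$cluster == lo]), min(values[km$cluster != lo])))
}
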