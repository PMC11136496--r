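test_that("moment-ellipse descriptors match analytic shapes", {
  md <- compute_morphometrics(disk_poly(10))
  expect_equal(md$elongation, 1, tolerance = 0.02)
  expect_equal(md$area_um2, 100 * pi, tolerance = 0.02 * 100 * pi)
  mr <- compute_morphometrics(rect_poly(40, 10))
  expect_equal(mr$elongation, 4, tolerance = 0.02 * 4)
  expect_lt(min(mr$orientation_deg, 180 - mr$orientation_deg), 1)
  expect_equal(mr$major_length_um, 40, tolerance = 0.02 * 40)
  expect_equal(mr$area_um2, 400)
})

test_that("orientation is equivariant and elongation invariant under rotation", {
  for (ang in c(30, 75, 120)) {
    m <- compute_morphometrics(rotate_poly(rect_poly(40, 10), ang))
    expect_equal(m$orientation_deg, ang %% 180, tolerance = 1)
    expect_equal(m$elongation, 4, tolerance = 0.02 * 4)
  }
  ## scale invariance of elongation
  m2 <- compute_morphometrics(rect_poly(40, 10) * 0.31)
  expect_equal(m2$elongation, 4, tolerance = 0.02 * 4)
})

test_that("degenerate polygons are rejected", {
  expect_error(compute_morphometrics(cbind(c(0, 1, 2), c(0, 0, 0))),
               class = "eht_geometry_error")
})

test_that("paving refinement recovers eroded interior cells (Jaccard >= 0.9)", {
  set.seed(9)
  seeds <- cbind(runif(8, 5, 55), runif(8, 5, 35))
  vp <- voronoi_paving(seeds, c(0, 60, 0, 40))
  interior <- vapply(vp$polygons, function(p) {
    all(p[, 1] > 1e-6 & p[, 1] < 60 - 1e-6 & p[, 2] > 1e-6 & p[, 2] < 40 - 1e-6)
  }, TRUE)
  eroded <- lapply(vp$polygons, shrink_polygon, d = 1.5)
  ref <- refine_paving(eroded, carto = NULL, raster_res_um = 0.25,
                       max_dilate_um = 3)
  js <- vapply(which(interior), function(i) {
    jaccard_polygons(ref[[i]]$polygon, vp$polygons[[i]])
  }, 0)
  expect_true(all(js >= 0.9))
})

test_that("a single seed comes back unchanged up to raster snapping", {
  p <- rect_poly(12, 8)
  out <- refine_paving(list(p), raster_res_um = 0.2)
  expect_length(out, 1)
  expect_gt(jaccard_polygons(out[[1]]$polygon, p), 0.95)
})

test_that("overlapping seeds beyond tolerance raise a paving error with ids", {
  a <- rect_poly(10, 10)
  b <- a; b[, 1] <- b[, 1] + 4
  err <- tryCatch(refine_paving(list(a, b), overlap_tol_um2 = 0.5),
                  error = function(e) e)
  expect_s3_class(err, "eht_paving_error")
  expect_length(err$ids, 1)
})

test_that("snake refinement pulls seed contours onto the junction ridge", {
  ## paint a synthetic junction image of a voronoi paving and refine
  ## under-sized seeds against it
  set.seed(21)
  seeds <- cbind(runif(6, 8, 40), runif(6, 8, 28))
  vp <- voronoi_paving(seeds, c(0, 48, 0, 36))
  res <- 0.5
  xs <- seq(0, 48, by = res); ys <- seq(0, 36, by = res)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  D <- sapply(vp$polygons, function(p) ehtkit:::dist_to_boundary(pts, p))
  img <- matrix(200 * exp(-(apply(D, 1, min) / 0.8)^2), length(ys), length(xs))
  eroded <- lapply(vp$polygons, shrink_polygon, d = 1.2)
  ref <- refine_paving(eroded, carto = img, raster_res_um = res,
                       max_dilate_um = 3)
  interior <- vapply(vp$polygons, function(p) {
    all(p[, 1] > 1e-6 & p[, 1] < 48 - 1e-6 & p[, 2] > 1e-6 & p[, 2] < 36 - 1e-6)
  }, TRUE)
  js <- vapply(which(interior), function(i) {
    jaccard_polygons(ref[[i]]$polygon, vp$polygons[[i]])
  }, 0)
  expect_true(all(js >= 0.85))
})

test_that("neighbor counting matches definitions and the construction oracle", {
  tri <- voronoi_paving(rbind(c(0, 0), c(2, 0), c(1, 2)), c(-3, 5, -3, 5))
  expect_equal(unname(count_neighbors(tri$polygons)$counts), c(2, 2, 2))
  grid4 <- list(rect_poly(1, 1),
                rect_poly(1, 1) + cbind(rep(1, 4), 0),
                rect_poly(1, 1) + cbind(rep(0, 4), 1),
                rect_poly(1, 1) + cbind(rep(1, 4), 1))
  cn <- count_neighbors(grid4, min_shared_um = 1e-6)
  expect_equal(unname(cn$counts), c(2, 2, 2, 2))  # diagonal corner contact excluded
  ## random voronoi pavings vs the half-plane construction ledger
  set.seed(5)
  for (rep in 1:25) {
    seeds <- cbind(runif(12, 0, 60), runif(12, 0, 40))
    vp <- voronoi_paving(seeds, c(0, 60, 0, 40))
    cn <- count_neighbors(vp$polygons, min_shared_um = 1e-6)
    adj <- vp$adjacency[vp$adjacency$shared_length > 1e-6, ]
    oracle <- table(factor(adj$i, levels = 1:12)) + table(factor(adj$j, levels = 1:12))
    expect_equal(unname(cn$counts), as.integer(oracle))
  }
})

test_that("disjoint polygons warn and fall back to distance adjacency", {
  a <- rect_poly(10, 10)
  b <- a; b[, 1] <- b[, 1] + 10.3   # 0.3 um gap
  expect_warning(cn <- count_neighbors(list(a, b), contact_tol_um = 0.6),
                 class = "eht_not_a_paving")
  expect_equal(unname(cn$counts), c(1, 1))
})

test_that("classification follows the rule cascade", {
  P <- 157  # perimeter; floor at Y ~ 0, roof at Y ~ P/2
  mk <- function(y0, flags) cell_roi(rect_poly(30, 8) + cbind(rep(0, 4), y0),
                                     id = 1, flags = flags)
  morph_of <- function(roi) compute_morphometrics(roi, raster_res_um = 0.25)
  ## roof sector -> endothelial regardless of elongation
  roi <- mk(P / 2 - 4, list(nucleus_thick = TRUE))
  expect_equal(classify_cell_type(roi, morph_of(roi), P)$type, "endothelial")
  ## floor + inward bending -> EHT pol+
  roi <- mk(-4, list(inward_bending = TRUE))
  expect_equal(classify_cell_type(roi, morph_of(roi), P)$type, "EHT_pol_plus")
  ## floor + rounded outward + short axis -> EHT pol-
  roi <- cell_roi(t(t(disk_poly(4)) + c(10, 0)), id = 1,
                  flags = list(inward_bending = FALSE, outward_round = TRUE,
                               nucleus_thick = TRUE))
  expect_equal(classify_cell_type(roi, morph_of(roi), P)$type, "EHT_pol_minus")
  ## floor + elongated + thick nucleus -> hemogenic
  roi <- mk(-4, list(inward_bending = FALSE, outward_round = FALSE,
                     nucleus_thick = TRUE))
  cl <- classify_cell_type(roi, morph_of(roi), P)
  expect_equal(cl$type, "hemogenic")
  expect_false(cl$low_confidence)
  ## flat nucleus -> endothelial; missing flags -> low confidence
  roi <- mk(-4, list(inward_bending = FALSE, outward_round = FALSE,
                     nucleus_thick = FALSE))
  expect_equal(classify_cell_type(roi, morph_of(roi), P)$type, "endothelial")
  roi <- mk(-4, list())
  expect_true(classify_cell_type(roi, morph_of(roi), P)$low_confidence)
})

test_that("phantom ledger types are recovered from true polygons and flags", {
  cfg <- scaled_tube_config(n_cells = 24, floor_fraction_hemogenic = 0.8,
                            seed = 6)
  ph <- make_tube_phantom(cfg)
  tr <- ph$truth
  pred <- vapply(seq_len(nrow(tr$cells)), function(i) {
    roi <- cell_roi(tr$polygons[[i]], id = i,
                    flags = list(nucleus_thick = tr$cells$nucleus_thick[i],
                                 inward_bending = FALSE, outward_round = FALSE))
    m <- compute_morphometrics(roi, raster_res_um = 0.2)
    classify_cell_type(roi, m, perimeter_um = tr$perimeter_um)$type
  }, "")
  expect_gte(mean(pred == tr$cells$type), 0.95)
  expect_gt(sum(tr$cells$type == "hemogenic"), 0)
})

test_that("segment summaries conserve totals and match the ledger", {
  cfg <- scaled_tube_config(n_cells = 24, floor_fraction_hemogenic = 0.8,
                            seed = 6)
  tr <- make_tube_phantom(cfg)$truth
  rois <- lapply(seq_len(nrow(tr$cells)), function(i) {
    cell_roi(tr$polygons[[i]], id = i, type = tr$cells$type[i],
             region = tr$cells$region[i])
  })
  s <- summarize_segment(rois)
  expect_equal(sum(s$counts), length(rois))
  expect_equal(unname(rowSums(s$counts)["hemogenic"]),
               sum(tr$cells$type == "hemogenic"))
  ## empty input -> all-zero table
  s0 <- summarize_segment(list())
  expect_equal(sum(s0$counts), 0)
  ## uncharacterized folded into hemogenic when requested
  s2 <- summarize_segment(rois, count_uncharacterized_as_hemogenic = TRUE)
  expect_equal(unname(rowSums(s2$counts)["hemogenic"]),
               sum(tr$cells$type %in% c("hemogenic", "uncharacterized")))
})
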