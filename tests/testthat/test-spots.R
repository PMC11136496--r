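test_that("spot compartments match a brute-force point-in-mask oracle", {
  sc <- make_spot_scene(small_scene_config(seed = 11, n_spots = 200))
  ss <- classify_spots(sc$spots, sc$cells)
  ## oracle: loop over per-cell masks directly (no label array)
  cls <- sc$cells$classes
  aortic_ids <- cls$id[cls$class %in% c("roof_endothelial", "hemogenic_EHT")]
  vox <- ehtkit:::spot_voxel(sc$spots, sc$cells)
  oracle <- vapply(seq_len(nrow(vox)), function(i) {
    lab <- sc$cells$labels[vox[i, 1], vox[i, 2], vox[i, 3]]
    if (lab > 0 && lab %in% aortic_ids) "aortic_cell"
    else if (!sc$cells$aorta_mask[vox[i, 1], vox[i, 2], vox[i, 3]]) "extra_aortic"
    else "unassigned"
  }, "")
  expect_identical(ss$compartment, oracle)
  ## conservation of compartments
  expect_equal(sum(table(ss$compartment)), nrow(sc$spots))
  ## ledger agreement
  expect_identical(ss$compartment, sc$truth$compartment)
})

test_that("a spot at a cell centroid is aortic and parented to that cell", {
  sc <- make_spot_scene(small_scene_config(seed = 2))
  he <- sc$cell_truth[sc$cell_truth$class == "hemogenic_EHT", ][1, ]
  ss <- classify_spots(rbind(c(he$x, he$y, he$z)), sc$cells)
  expect_equal(ss$compartment, "aortic_cell")
  expect_equal(ss$parent_id, he$id)
})

test_that("overlapping explicit cell masks are rejected with ids", {
  m1 <- array(FALSE, c(4, 4, 4)); m1[1:3, 1:3, 1:3] <- TRUE
  m2 <- array(FALSE, c(4, 4, 4)); m2[3:4, 3:4, 3:4] <- TRUE
  err <- tryCatch(combine_cell_masks(list(a = m1, b = m2)), error = function(e) e)
  expect_s3_class(err, "eht_input_error")
  expect_equal(length(err$ids), 2)
})

test_that("per-cell spot counts reconcile with parent assignments", {
  sc <- make_spot_scene(small_scene_config(seed = 13))
  ss <- classify_spots(sc$spots, sc$cells)
  cnt <- count_spots_per_cell(ss, sc$cells)
  he_ids <- sc$cells$classes$id[sc$cells$classes$class == "hemogenic_EHT"]
  expect_equal(sum(cnt$per_cell$n_spots),
               sum(ss$parent_id %in% he_ids, na.rm = TRUE))
  expect_equal(sum(cnt$histogram), length(he_ids))
  ## no spots -> all zeros
  cnt0 <- count_spots_per_cell(ss[0, ], sc$cells)
  expect_true(all(cnt0$per_cell$n_spots == 0))
})

test_that("attraction distances follow the lower-quantile definition", {
  expect_equal(attraction_distance(c(1, 2, 3, 4), 0.5), 2)
  expect_equal(attraction_distance(c(1, 2, 3, 4), 0.75), 3)
  ## ties
  expect_equal(attraction_distance(c(0, 0, 5, 9), 0.5), 0)
})

test_that("distance profiles match the sort-based oracle over random scenes", {
  for (s in 1:40) {
    sc <- make_spot_scene(small_scene_config(seed = 100 + s))
    dp <- distance_profile(classify_spots(sc$spots, sc$cells), sc$cells)
    expect_identical(dp$d50, sorted_quantile(dp$distances, 0.5))
    expect_identical(dp$d75, sorted_quantile(dp$distances, 0.75))
    expect_true(all(diff(dp$F) >= 0))
  }
})

test_that("a spot inside a target cell has distance zero", {
  sc <- make_spot_scene(small_scene_config(seed = 2))
  he <- sc$cell_truth[sc$cell_truth$class == "hemogenic_EHT", ][1, ]
  dp <- distance_profile(rbind(c(he$x, he$y, he$z)), sc$cells)
  expect_equal(dp$distances, 0)
  expect_error(distance_profile(rbind(c(1, 1, 1)), sc$cells,
                                target_class = "no_such_class"),
               class = "eht_input_error")
})

test_that("adding a target cell never increases attraction distances", {
  sc <- make_spot_scene(small_scene_config(seed = 17))
  ss <- classify_spots(sc$spots, sc$cells)
  dp_all <- distance_profile(ss, sc$cells)
  ## drop one hemogenic cell from the targets by relabeling it sub-aortic
  cells2 <- sc$cells
  he_ids <- cells2$classes$id[cells2$classes$class == "hemogenic_EHT"]
  cells2$classes$class[cells2$classes$id == he_ids[1]] <- "sub_aortic"
  dp_less <- distance_profile(ss, cells2)
  expect_true(all(dp_all$distances <= dp_less$distances + 1e-12))
  expect_lte(dp_all$d50, dp_less$d50)
  expect_lte(dp_all$d75, dp_less$d75)
})

test_that("scene summaries compute correlations and flag degenerate covariates", {
  seg <- data.frame(n_he_cells = c(3, 5, 8, 11), n_spots = c(30, 50, 80, 110),
                    d50 = 14 - c(3, 5, 8, 11), d75 = c(9, 9, 9, 9))
  sm <- summarize_scene(seg)
  co <- sm$correlations
  expect_equal(co$R[co$covariate == "n_spots"], 1, tolerance = 1e-12)
  expect_equal(co$R[co$covariate == "d50"], -1, tolerance = 1e-12)
  expect_false(co$applicable[co$covariate == "d75"])
  expect_error(summarize_scene(seg[1:2, ]), class = "eht_input_error")
})

test_that("clustered scenes show the built-in negative d50 dependence on cell count", {
  ## more hemogenic cells -> spots (clustered around them) sit closer
  set.seed(1)
  segs <- do.call(rbind, lapply(1:8, function(k) {
    n_he <- sample(2:6, 1)
    sc <- make_spot_scene(small_scene_config(seed = 300 + k))
    sc2 <- make_spot_scene(spot_scene_config(
      n_roof = 3, n_hemogenic = n_he, n_sub_aortic = 2, n_spots = 60,
      clustering_scale_um = 4, fraction_extra_aortic = 0.1,
      cell_radius_um = 2.5, aorta_radius_um = 7,
      box_um = c(x = 30, y = 20, z = 24), spacing_um = 1.0, seed = 700 + k))
    dp <- distance_profile(classify_spots(sc2$spots, sc2$cells), sc2$cells)
    data.frame(n_he_cells = n_he, n_spots = nrow(sc2$spots), d50 = dp$d50,
               d75 = dp$d75)
  }))
  sm <- summarize_scene(segs)
  expect_lt(sm$correlations$R[sm$correlations$covariate == "d50"], 0)
})
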