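test_that("generators are deterministic: same config and seed, identical output", {
  c1 <- scaled_tube_config(n_cells = 10, seed = 5, segment_length_um = 30)
  expect_identical(make_tube_phantom(c1)$stack$data, make_tube_phantom(c1)$stack$data)
  f1 <- frap_sim_config(n_traces = 3, noise_sd = 0.05, seed = 5)
  expect_identical(make_frap_dataset(f1)$traces[[2]]$roi,
                   make_frap_dataset(f1)$traces[[2]]$roi)
  s1 <- small_scene_config(seed = 5)
  expect_identical(make_spot_scene(s1)$spots, make_spot_scene(s1)$spots)
  t1 <- flow_timelapse_config(noise_sd = 5, seed = 5)
  expect_identical(make_flow_timelapse(t1)$green, make_flow_timelapse(t1)$green)
  q1 <- ct_sim_config(tech_sd = 0.1, n_outliers = 1, seed = 5)
  expect_identical(make_ct_table(q1)$table$ct, make_ct_table(q1)$table$ct)
})

test_that("tube phantom axial extent follows segment length / pixel size", {
  cfg <- tube_phantom_config(radius_um = 3, segment_length_um = 330,
                             pixel_xy_um = 0.27, step_z_um = 0.3,
                             n_cells = 0, margin_um = 2, seed = 1)
  ph <- make_tube_phantom(cfg)
  expect_equal(dim(ph$stack$data)[3], ceiling(330 / 0.27))
  expect_equal(dim(ph$stack$data)[3], 1223)
})

test_that("tube radius exceeding a fixed field of view is a configuration error", {
  expect_error(tube_phantom_config(radius_um = 25, fov_um = 40),
               class = "eht_config_error")
})

test_that("noise-free FRAP traces equal the model exactly after normalization", {
  ds <- make_frap_dataset(frap_sim_config(A_true = 0.45, tau_true = 0.012,
                                          noise_sd = 0, n_traces = 2, seed = 1))
  expect_equal(nrow(ds$truth), 2)
  nm <- normalize_trace(ds$traces[[1]])
  expected <- 0.45 * (1 - exp(-nm$times * 0.012))
  expect_equal(nm$i_fsn, expected, tolerance = 1e-12)
})

test_that("FRAP phase design yields 30 prebleach, 180 fast and 21 slow samples", {
  tr <- make_frap_dataset(frap_sim_config(seed = 1))$traces[[1]]
  expect_equal(as.integer(table(tr$phase)[c("prebleach", "fast", "slow")]),
               c(30L, 180L, 21L))
})

test_that("spot scenes respect the extra-aortic fraction and clustering error", {
  sc <- make_spot_scene(small_scene_config(seed = 3, fraction_extra_aortic = 0))
  expect_true(all(sc$truth$compartment != "extra_aortic"))
  expect_error(make_spot_scene(spot_scene_config(n_hemogenic = 0,
                                                 clustering_scale_um = 2)),
               class = "eht_config_error")
})

test_that("uniform spot placement matches a Monte-Carlo attraction-distance oracle", {
  cfgs <- small_scene_config(seed = 8, clustering_scale_um = 0,
                             fraction_extra_aortic = 0, n_spots = 120)
  sc <- make_spot_scene(cfgs)
  dp <- distance_profile(classify_spots(sc$spots, sc$cells), sc$cells)
  ## oracle: resimulate uniform placement many times with independent code
  ## (analytic sphere distances from the cell ledger) and bracket d50
  ctr <- sc$cell_truth[sc$cell_truth$class == "hemogenic_EHT", ]
  set.seed(99)
  d50s <- replicate(200, {
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < 120) {
      p <- c(runif(1, 0, 24), runif(1, 10 - 7, 10 + 7), runif(1, 15 - 7, 15 + 7))
      if ((p[2] - 10)^2 + (p[3] - 15)^2 <= 49) pts <- rbind(pts, p)
    }
    d <- apply(pts, 1, function(q) {
      max(0, sqrt(min((ctr$x - q[1])^2 + (ctr$y - q[2])^2 + (ctr$z - q[3])^2)) - 2.5)
    })
    sorted_quantile(d, 0.5)
  })
  expect_gt(dp$d50, quantile(d50s, 0.005))
  expect_lt(dp$d50, quantile(d50s, 0.995))
})

test_that("flow time-lapse ledger records stated spans and classes", {
  tl <- make_flow_timelapse(flow_timelapse_config(n_transient = 5,
                                                  n_persistent = 5, seed = 4))
  expect_equal(nrow(tl$ledger), 10)
  expect_true(all(tl$ledger$span[tl$ledger$class == "transient"] == 1))
  sp <- tl$ledger$span[tl$ledger$class == "persistent"]
  expect_true(all(sp >= 15 & sp <= 20))
  expect_error(flow_timelapse_config(dims_px = c(y = 64, x = 64, planes = 30)),
               class = "eht_config_error")
})

test_that("zero-noise Ct tables invert exactly through delta-delta-Ct", {
  gen <- make_ct_table(ct_sim_config(genes = "gene1", fold_changes = 4,
                                     tech_sd = 0, bio_sd = 0, seed = 1))
  res <- delta_delta_ct(gen$table, "ef1a", "control")
  expect_equal(res$fold_change[res$condition == "treated"], rep(4, 3),
               tolerance = 1e-12)
})

test_that("injected gross outliers are gated in the zero-noise case", {
  gen <- make_ct_table(ct_sim_config(genes = "gene1", fold_changes = 2,
                                     tech_sd = 0, bio_sd = 0,
                                     n_outliers = 2, outlier_shift = 5, seed = 2))
  res <- delta_delta_ct(gen$table, "ef1a", "control")
  expect_equal(sum(res$n_removed), 2)
  ## fold changes are unaffected by the gated outliers
  expect_equal(res$fold_change[res$condition == "treated"], rep(2, 3),
               tolerance = 1e-12)
})

test_that("volume stacks round-trip through multi-page TIFF", {
  arr <- array(runif(6 * 5 * 4 * 2, 0, 500), c(6, 5, 4, 2))
  st <- volume_stack(arr, spacing = c(y = 0.27, z = 0.3, x = 0.27))
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(st, f)
  st2 <- read_stack_tiff(f)
  expect_equal(st2$spacing, st$spacing)
  ## 16-bit quantization bounds the round-trip error
  expect_lt(max(abs(st2$data - st$data)), max(arr) / 65535 * 1.01)
  unlink(c(f, paste0(f, ".meta.csv")))
})
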