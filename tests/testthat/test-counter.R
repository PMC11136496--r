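test_that("rolling median suppresses single-plane objects and keeps deep ones", {
  tl <- make_flow_timelapse(flow_timelapse_config(seed = 2))
  filt <- temporal_median(tl$green, window = 20, mode = "replace")
  led <- tl$ledger
  for (i in which(led$class == "transient")) {
    v0 <- tl$green[round(led$y_px[i]), round(led$x_px[i]), led$z0[i]]
    v1 <- filt[round(led$y_px[i]), round(led$x_px[i]), led$z0[i]]
    expect_lt(v1, 0.1 * v0)
  }
  for (i in which(led$class == "persistent")) {
    zc <- led$z0[i] + floor(led$span[i] / 2)
    v0 <- tl$green[round(led$y_px[i]), round(led$x_px[i]), zc]
    expect_gte(filt[round(led$y_px[i]), round(led$x_px[i]), zc], 0.95 * v0)
  }
  expect_error(temporal_median(tl$green, window = 100),
               class = "eht_window_error")
})

test_that("replace-mode median is idempotent when all objects span >= window", {
  tl <- make_flow_timelapse(flow_timelapse_config(
    n_transient = 0L, n_persistent = 4L, span_range = c(26L, 30L),
    dims_px = c(y = 64, x = 64, planes = 52), median_window = 20, seed = 3))
  ## odd window: no tie-averaging in full windows, so the filter is a
  ## projection away from the stack ends (truncated windows there can have
  ## even length and tie-average)
  f1 <- temporal_median(tl$green, 21, "replace")
  f2 <- temporal_median(f1, 21, "replace")
  interior <- 11:42
  expect_equal(f2[, , interior], f1[, , interior], tolerance = 1e-12)
})

test_that("subtract mode retains the transient component instead", {
  tl <- make_flow_timelapse(flow_timelapse_config(seed = 2))
  sub <- temporal_median(tl$green, 20, "subtract")
  led <- tl$ledger
  i <- which(led$class == "transient")[1]
  expect_gt(sub[round(led$y_px[i]), round(led$x_px[i]), led$z0[i]],
            0.9 * led$total_green[i] / sum(sub >= 0) * 0)  # > 0 retained
  expect_gt(sub[round(led$y_px[i]), round(led$x_px[i]), led$z0[i]], 50)
  j <- which(led$class == "persistent")[1]
  zc <- led$z0[j] + floor(led$span[j] / 2)
  expect_lt(sub[round(led$y_px[j]), round(led$x_px[j]), zc], 10)
})

test_that("preprocessing maps degenerate stacks to zero", {
  z <- array(0, c(32, 32, 24))
  expect_true(all(preprocess_stack(z) == 0))
  cst <- array(7, c(32, 32, 24))
  expect_true(all(preprocess_stack(cst) == 0))
  expect_error(preprocess_stack(z, blur_sigma_px = -1),
               class = "eht_config_error")
})

test_that("preprocessing improves blob SNR on the phantom", {
  tl <- make_flow_timelapse(flow_timelapse_config(
    n_transient = 0L, n_persistent = 4L, noise_sd = 10,
    dims_px = c(y = 64, x = 64, planes = 48), seed = 6))
  led <- tl$ledger
  peak_bg <- function(a) {
    pk <- mean(vapply(seq_len(nrow(led)), function(i) {
      a[round(led$y_px[i]), round(led$x_px[i]), led$z0[i] + 5]
    }, 0))
    pk / stats::sd(a[1:10, 1:10, ])
  }
  expect_gt(peak_bg(preprocess_stack(tl$green)), peak_bg(tl$green / max(tl$green)))
})

test_that("segmentation finds well-separated blobs with sub-voxel centroids", {
  set.seed(1)
  b <- array(0, c(48, 48, 30))
  for (ctr in list(c(14, 24, 15), c(34, 24, 15))) {
    for (z in 1:30) {
      b[, , z] <- b[, , z] + 100 * exp(-((row(b[, , z]) - ctr[1])^2 +
                                           (col(b[, , z]) - ctr[2])^2) / 18 -
                                         (z - ctr[3])^2 / 18)
    }
  }
  b <- pmax(b + rnorm(length(b), 0, 10), 0)
  seg <- segment_objects(b / max(b), tophat_radii_px = c(9, 9, 2),
                         min_size_vox = 30)
  expect_equal(nrow(seg$table), 2)
  expect_lt(max(abs(sort(seg$table$centroid_y) - c(14, 34))), 1)
  expect_lt(max(abs(seg$table$centroid_x - 24)), 1)
})

test_that("pure noise yields no objects; touching blobs are split by the watershed", {
  set.seed(2)
  noise <- array(abs(rnorm(48 * 48 * 24, 0, 1)), c(48, 48, 24))
  seg0 <- segment_objects(noise / max(noise))
  expect_equal(nrow(seg0$table), 0)
  a <- array(0, c(40, 40, 30))
  for (ctr in list(c(16, 20, 15), c(24, 20, 15))) {
    for (z in 1:30) {
      a[, , z] <- a[, , z] + 10 * exp(-((row(a[, , z]) - ctr[1])^2 +
                                          (col(a[, , z]) - ctr[2])^2) / 18 -
                                        (z - ctr[3])^2 / 18)
    }
  }
  seg <- segment_objects(a / max(a), tophat_radii_px = c(9, 9, 2),
                         threshold = 0.5, min_size_vox = 20)
  expect_equal(nrow(seg$table), 2)
  seg_nosplit <- segment_objects(a / max(a), tophat_radii_px = c(9, 9, 2),
                                 threshold = 0.5, min_size_vox = 20,
                                 split_touching = FALSE)
  expect_equal(nrow(seg_nosplit$table), 1)
})

test_that("object totals match the painted ledger and background algebra", {
  tl <- make_flow_timelapse(flow_timelapse_config(
    n_transient = 0L, n_persistent = 5L, n_double_positive = 2L,
    dims_px = c(y = 96, x = 96, planes = 48), noise_sd = 0, seed = 8))
  ## ground-truth labels: every painted voxel, so totals are exact
  labels <- ehtkit:::label3d(tl$green > 0)
  ## uniform background b added to the raw data: corrected total = S - b V
  b0 <- 3
  mo <- measure_objects(labels, list(green = tl$green + b0, red = tl$red),
                        background_roi = labels == 0 & tl$green == 0)
  expect_equal(nrow(mo), 5)
  led <- tl$ledger
  match_id <- vapply(seq_len(nrow(mo)), function(i) {
    which.min((led$y_px - mo$centroid_y[i])^2 + (led$x_px - mo$centroid_x[i])^2)
  }, 0L)
  expect_equal(mo$corr_green, led$total_green[match_id], tolerance = 1e-9)
  expect_equal(mo$total_green, led$total_green[match_id] + b0 * mo$n_vox,
               tolerance = 1e-9)
  seg <- segment_objects(preprocess_stack(tl$green))
  expect_equal(nrow(seg$table), 5)
  ## dimension mismatch
  expect_error(measure_objects(seg$labels, list(green = tl$green[, , 1:10])),
               class = "eht_input_error")
  ## missing background flags the totals
  expect_warning(mo2 <- measure_objects(seg$labels, list(green = tl$green)),
                 class = "eht_no_background")
  expect_false(attr(mo2, "background_corrected"))
})

test_that("classification follows the double/single-positive rules and monotonicity", {
  tab <- data.frame(id = 1:3, n_vox = 100,
                    corr_green = c(500, 600, 5), corr_red = c(400, 5, 3),
                    total_green = c(500, 600, 5), total_red = c(400, 5, 3))
  cl <- classify_objects(tab, c(green = 50, red = 50))
  expect_equal(cl$class, c("hemogenic", "hspc", "other"))
  ## raising the red threshold never increases the red-positive count
  n_pos <- function(thr) sum(classify_objects(tab, c(green = 50, red = thr))$class == "hemogenic")
  expect_true(all(diff(vapply(c(1, 100, 500, 1000), n_pos, 0)) <= 0))
  expect_error(classify_objects(tab, c(green = 50)),
               class = "eht_classification_error")
})

test_that("the full counting pipeline recovers ledger classes exactly", {
  tl <- make_flow_timelapse(flow_timelapse_config(
    dims_px = c(y = 144, x = 144, planes = 48), n_transient = 0L,
    n_persistent = 32L, n_double_positive = 12L, noise_sd = 10,
    min_sep_px = 16, seed = 2))
  seg <- segment_objects(preprocess_stack(tl$green))
  mo <- measure_objects(seg$labels, list(green = tl$green, red = tl$red),
                        background_roi = seg$labels == 0)
  cl <- classify_objects(mo, c(green = 0, red = suggest_threshold(mo$corr_red)))
  counts <- attr(cl, "counts")
  expect_equal(as.integer(counts[c("hemogenic", "hspc")]), c(12L, 20L))
})
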