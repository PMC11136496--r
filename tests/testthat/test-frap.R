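make_phase_recordings <- function() {
  list(prebleach = data.frame(time = 0:29, roi = 110, background = 10),
       fast = data.frame(time = 0:179, roi = 60, background = 10),
       slow = data.frame(time = seq(0, 400, by = 20), roi = 80, background = 10))
}

test_that("trace assembly builds the stated five-phase time base", {
  tr <- assemble_trace(make_phase_recordings(), list(first_post_s = 0))
  expect_equal(as.integer(table(tr$phase)[c("prebleach", "fast", "slow")]),
               c(30L, 180L, 21L))
  expect_equal(max(tr$times[tr$phase == "prebleach"]), -1)
  expect_equal(min(tr$times[tr$phase == "fast"]), 0)
  expect_true(all(diff(tr$times) > 0))
})

test_that("assembly rejects missing phases and overlapping timestamps", {
  rec <- make_phase_recordings()
  expect_error(assemble_trace(rec[c("prebleach", "fast")]),
               class = "eht_assembly_error")
  expect_error(assemble_trace(rec, list(slow_start_s = 100)),
               class = "eht_assembly_error")
  bad <- rec; bad$fast$time[5] <- 2
  expect_error(assemble_trace(bad), class = "eht_assembly_error")
})

test_that("drift-flagged recordings keep only pre-bleach and fast samples", {
  tr <- assemble_trace(make_phase_recordings(), list(drift = TRUE))
  expect_true(tr$drift)
  expect_false("slow" %in% tr$phase)
  expect_equal(sum(tr$phase == "fast"), 180)
})

test_that("the normalization chain follows the worked example", {
  n <- 35
  tr <- frap_trace(times = c(-(5:1), 1:30),
                   roi = c(rep(110, 5), rep(50, 30)),
                   background = rep(10, n),
                   phase = c(rep("prebleach", 5), rep("fast", 30)))
  nm <- normalize_trace(tr)
  expect_equal(nm$i_norm, rep(0.4, 30))
  expect_equal(nm$i_fsn, rep(0, 30))  # at the minimum sample
  ## scaling identity: min = 0 => i_fsn == i_norm
  tr2 <- frap_trace(times = c(-(5:1), 1:30),
                    roi = c(rep(110, 5), seq(10, 68, by = 2)),
                    background = rep(10, n),
                    phase = c(rep("prebleach", 5), rep("fast", 30)))
  nm2 <- normalize_trace(tr2)
  expect_equal(nm2$i_min, 0)
  expect_equal(nm2$i_fsn, nm2$i_norm)
})

test_that("normalization failure modes raise typed errors", {
  n <- 35
  base <- list(times = c(-(5:1), 1:30), phase = c(rep("prebleach", 5), rep("fast", 30)),
               background = rep(10, n))
  ## post equal to prebleach -> no bleach
  tr <- frap_trace(base$times, rep(110, n), base$background, base$phase)
  expect_error(normalize_trace(tr), class = "eht_no_bleach")
  ## background >= prebleach ROI
  tr2 <- frap_trace(base$times, c(rep(5, 5), rep(50, 30)), base$background, base$phase)
  expect_error(normalize_trace(tr2), class = "eht_nonpositive_prebleach")
})

test_that("noise-free fits recover generating parameters to solver tolerance", {
  for (p in list(c(0.6, 0.01), c(0.3, 0.02), c(0.9, 0.005))) {
    ds <- make_frap_dataset(frap_sim_config(A_true = p[1], tau_true = p[2],
                                            noise_sd = 0, seed = 1))
    f <- fit_recovery(normalize_trace(ds$traces[[1]]))
    expect_lt(abs(f$A - p[1]), 1e-4)
    expect_lt(abs(f$tau - p[2]), 1e-6)
    expect_equal(f$t_half * f$tau, log(2), tolerance = 1e-12)
  }
})

test_that("a flat zero trace fits a near-zero amplitude", {
  n_pre <- 5
  tr <- frap_trace(times = c(-(n_pre:1), 1:60),
                   roi = c(rep(1010, n_pre), rep(10.5, 60)),
                   background = rep(10, n_pre + 60),
                   phase = c(rep("prebleach", n_pre), rep("fast", 60)))
  f <- fit_recovery(normalize_trace(tr))
  expect_lt(f$A, 0.01)
})

test_that("parameter recovery under noise meets simulation tolerances", {
  ds <- make_frap_dataset(frap_sim_config(A_true = 0.5, tau_true = 0.005,
                                          noise_sd = 0.05, n_traces = 60,
                                          seed = 7))
  fits <- lapply(ds$traces, function(t) fit_recovery(normalize_trace(t)))
  errA <- vapply(fits, function(f) abs(f$A - 0.5) / 0.5, 0)
  errT <- vapply(fits, function(f) abs(f$tau - 0.005) / 0.005, 0)
  expect_lt(median(errA), 0.05)
  expect_lt(median(errT), 0.10)
  ## T_half relation holds for every fit
  expect_true(all(vapply(fits, function(f) abs(f$t_half * f$tau - log(2)), 0) < 1e-12))
})

test_that("error spread shrinks as noise decreases", {
  med_err <- vapply(c(0.1, 0.05, 0.01), function(s) {
    ds <- make_frap_dataset(frap_sim_config(A_true = 0.5, tau_true = 0.01,
                                            noise_sd = s, n_traces = 25, seed = 3))
    stats::median(vapply(ds$traces, function(t) {
      abs(fit_recovery(normalize_trace(t))$A - 0.5) / 0.5
    }, 0))
  }, 0)
  expect_true(all(diff(med_err) < 0))
})

test_that("early slope equals closed-form least squares", {
  ## exact line
  n_pre <- 5
  t_post <- 0:40
  tr <- frap_trace(c(-(n_pre:1), t_post + 1e-9),
                   roi = c(rep(1010, n_pre), 10 + 1000 * pmin(0.02 * (t_post), 1)),
                   background = rep(10, n_pre + length(t_post)),
                   phase = c(rep("prebleach", n_pre), rep("fast", length(t_post))))
  nm <- normalize_trace(tr)
  sel <- nm$times <= 30
  expect_equal(early_slope(nm, 30), ols_slope(nm$times[sel], nm$i_fsn[sel]),
               tolerance = 1e-9)
  ## noise-free exponential: equals OLS slope of the model values
  ds <- make_frap_dataset(frap_sim_config(A_true = 0.5, tau_true = 0.01,
                                          noise_sd = 0, seed = 1))
  nm2 <- normalize_trace(ds$traces[[1]])
  sel2 <- nm2$times >= 0 & nm2$times <= 30
  oracle <- ols_slope(nm2$times[sel2], 0.5 * (1 - exp(-0.01 * nm2$times[sel2])))
  expect_equal(early_slope(nm2, 30), oracle, tolerance = 1e-9)
  ## too few samples in the window
  expect_error(early_slope(nm2, 0.5), class = "eht_window_error")
})

test_that("group summaries preserve generated ordering and detect differences", {
  mk_group <- function(A, jt, seed) {
    ds <- make_frap_dataset(frap_sim_config(A_true = A, tau_true = 0.01,
                                            noise_sd = 0.05, n_traces = 30,
                                            junction_type = jt, seed = seed))
    lapply(ds$traces, function(t) fit_recovery(normalize_trace(t)))
  }
  fits <- c(mk_group(0.50, "polplus-EC", 21), mk_group(0.39, "polminus-EC", 22))
  tab <- fits_to_table(fits)
  gs <- summarize_groups(tab)
  med <- gs$summary$median_A[match(c("polplus-EC/control", "polminus-EC/control"),
                                   gs$summary$group)]
  expect_gt(med[1], med[2])
  pA <- gs$tests$p[gs$tests$metric == "A"]
  expect_lt(pA, 0.05)
})

test_that("degenerate group inputs are handled", {
  expect_equal(nrow(summarize_groups(data.frame())$summary), 0)
  tab <- data.frame(A = c(0.5, 0.4, 0.45, 0.3), t_half = c(60, 70, 65, 80),
                    junction_type = c("EC-EC", "EC-EC", "EC-EC", "HE-EC"),
                    condition = "control")
  gs <- summarize_groups(tab)
  expect_true(all(is.na(gs$tests$p)))
  expect_true(all(gs$tests$method == "not-applicable"))
})

test_that("slow-phase z-stacks are reduced to one value per time point", {
  rec <- make_phase_recordings()
  ## three z-planes per slow time point, focus plane brightest
  slow3 <- do.call(rbind, lapply(seq_len(nrow(rec$slow)), function(i) {
    data.frame(time = rec$slow$time[i], roi = rec$slow$roi[i] - c(10, 0, 5),
               background = rec$slow$background[i])
  }))
  tr <- assemble_trace(list(prebleach = rec$prebleach, fast = rec$fast,
                            slow = slow3), list())
  expect_equal(sum(tr$phase == "slow"), nrow(rec$slow))
  expect_true(all(tr$roi[tr$phase == "slow"] == 80))   # max over the stack
  tr2 <- assemble_trace(list(prebleach = rec$prebleach, fast = rec$fast,
                             slow = slow3), list(slow_reduce = "mean"))
  expect_equal(unique(tr2$roi[tr2$phase == "slow"]), 75)
})
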