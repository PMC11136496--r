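## FRAP (fluorescence recovery after photobleaching) analysis of junctional
## reporter signal. Acquisition design has five phases; the three intensity
## phases are: 30 s pre-bleach at 1 Hz, 3 min fast post-bleach at 1 Hz, and
## 7 min slow post-bleach at one 8-um z-stack every 20 s. Analysis chain:
## background subtraction, normalization to the pre-bleach mean, full-scale
## rescaling against the post-bleach minimum, then a single-exponential fit
## F(t) = A (1 - exp(-t tau)), with A the mobile fraction and
## T_half = ln(2) / tau.

FRAP_JUNCTION_TYPES <- c("EC-EC", "EC-EC-EC", "HE-EC", "HE-EC-EC", "HE-HE-EC",
                         "polplus-EC", "polminus-EC")

#' Construct a FRAP trace
#'
#' @param times seconds; t = 0 at bleach, pre-bleach times negative; strictly
#'   increasing.
#' @param roi raw ROI intensities.
#' @param background background ROI intensities (same length).
#' @param phase character vector in {"prebleach", "fast", "slow"}; phases must
#'   be contiguous and in that order.
#' @param junction_type one of the junction-type labels (bi/tri-junctions
#'   between endothelial (EC), hemogenic (HE) and EHT pol+/- cells).
#' @param condition condition label (e.g. "control", "morphant").
#' @param drift TRUE when the acquisition drifted during the slow phase; such
#'   traces are kept for early-recovery analysis only.
#' @return Object of class `frap_trace`.
#' @export
frap_trace <- function(times, roi, background, phase,
                       junction_type = "EC-EC", condition = "control",
                       drift = FALSE) {
  n <- length(times)
  if (length(roi) != n || length(background) != n || length(phase) != n) {
    eht_stop("eht_assembly_error", "times, roi, background, phase lengths differ")
  }
  if (any(diff(times) <= 0)) {
    eht_stop("eht_assembly_error", "timestamps must be strictly increasing")
  }
  if (!all(phase %in% c("prebleach", "fast", "slow"))) {
    eht_stop("eht_assembly_error", "unknown phase label")
  }
  r <- rle(phase)$values
  if (!identical(r, intersect(c("prebleach", "fast", "slow"), r))) {
    eht_stop("eht_assembly_error",
             "phases must be contiguous in order prebleach, fast, slow")
  }
  if (sum(phase == "prebleach") < 3) {
    eht_stop("eht_assembly_error", "at least 3 prebleach samples required")
  }
  structure(list(times = times, roi = roi, background = background,
                 phase = phase, junction_type = junction_type,
                 condition = condition, drift = isTRUE(drift)),
            class = "frap_trace")
}

#' Assemble phase recordings into a single trace
#'
#' Joins the three intensity phases onto one time base with t = 0 at the
#' bleach. Phase recordings are data.frames with columns `time` (seconds from
#' the start of their own phase), `roi` and `background`. The pre-bleach
#' phase is shifted to end just before the bleach; the fast phase starts at
#' `metadata$first_post_s` (from acquisition metadata; 1 s when absent, the
#' fast-phase frame interval); the slow phase is appended one slow interval
#' after the last fast sample unless `metadata$slow_start_s` says otherwise.
#' A drift-flagged recording keeps only pre-bleach + fast samples.
#'
#' @param phases named list with elements `prebleach`, `fast`, `slow`.
#' @param metadata list: junction_type, condition, first_post_s,
#'   slow_start_s, drift.
#' @return A [frap_trace()].
#' @export
assemble_trace <- function(phases, metadata = list()) {
  need <- c("prebleach", "fast", "slow")
  if (!all(need %in% names(phases))) {
    eht_stop("eht_assembly_error",
             paste("missing phase:", paste(setdiff(need, names(phases)), collapse = ", ")))
  }
  pre <- phases$prebleach; fast <- phases$fast; slow <- phases$slow
  ## slow-phase recordings may carry one row per z-plane and time point
  ## (small z-stack per frame): reduce to one value per time point first
  if (anyDuplicated(slow$time)) {
    red <- match.arg(metadata$slow_reduce %||% "max", c("max", "mean"))
    f <- if (red == "max") max else mean
    agg <- lapply(split(slow, slow$time), function(s) {
      data.frame(time = s$time[1], roi = f(s$roi), background = mean(s$background))
    })
    slow <- do.call(rbind, agg)
    slow <- slow[order(slow$time), ]
  }
  for (p in list(prebleach = pre, fast = fast, slow = slow)) {
    if (any(diff(p$time) <= 0)) {
      eht_stop("eht_assembly_error", "non-monotone timestamps in a phase")
    }
  }
  dt_pre <- stats::median(diff(pre$time))
  first_post <- metadata$first_post_s %||% stats::median(diff(fast$time))
  t_pre <- pre$time - max(pre$time) - dt_pre
  t_fast <- fast$time - min(fast$time) + first_post
  dt_slow <- stats::median(diff(slow$time))
  slow_start <- metadata$slow_start_s %||% (max(t_fast) + dt_slow)
  if (slow_start <= max(t_fast)) {
    eht_stop("eht_assembly_error", "fast and slow phases overlap in time")
  }
  t_slow <- slow$time - min(slow$time) + slow_start
  drift <- isTRUE(metadata$drift)
  if (drift) {
    times <- c(t_pre, t_fast)
    roi <- c(pre$roi, fast$roi)
    bg <- c(pre$background, fast$background)
    phase <- c(rep("prebleach", nrow(pre)), rep("fast", nrow(fast)))
  } else {
    times <- c(t_pre, t_fast, t_slow)
    roi <- c(pre$roi, fast$roi, slow$roi)
    bg <- c(pre$background, fast$background, slow$background)
    phase <- c(rep("prebleach", nrow(pre)), rep("fast", nrow(fast)),
               rep("slow", nrow(slow)))
  }
  frap_trace(times, roi, bg, phase,
             junction_type = metadata$junction_type %||% "EC-EC",
             condition = metadata$condition %||% "control",
             drift = drift)
}

#' Normalize a FRAP trace
#'
#' Three-step chain: background subtraction
#' (I_bgnorm = I_roi - I_background), normalization of post-bleach samples to
#' the pre-bleach mean (I_norm = I_bgnorm / mean(pre-bleach I_bgnorm)), and
#' full-scale rescaling I_fsn = (I_norm - min) / (1 - min), the minimum taken
#' over post-bleach samples (pre-bleach noise must not set the scale floor).
#'
#' @param trace a [frap_trace()].
#' @return Object of class `normalized_trace`: post-bleach `times`, `i_norm`,
#'   `i_fsn`, the floor `i_min`, plus carried metadata.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- trace$phase == "prebleach"
  bgnorm <- trace$roi - trace$background
  pre_mean <- mean(bgnorm[pre])
  if (!is.finite(pre_mean) || pre_mean <= 0) {
    eht_stop("eht_nonpositive_prebleach",
             "background >= ROI intensity in the pre-bleach phase")
  }
  post <- !pre
  i_norm <- bgnorm[post] / pre_mean
  i_min <- min(i_norm)
  if (i_min >= 1) {
    eht_stop("eht_no_bleach", "no bleach detected: post-bleach minimum >= 1")
  }
  structure(list(
    times = trace$times[post], i_norm = i_norm,
    i_fsn = (i_norm - i_min) / (1 - i_min), i_min = i_min,
    phase = trace$phase[post],
    prebleach_times = trace$times[pre], prebleach_bgnorm = bgnorm[pre],
    junction_type = trace$junction_type, condition = trace$condition,
    drift = trace$drift), class = "normalized_trace")
}

#' Fit the single-exponential recovery model
#'
#' Least-squares fit of F(t) = A (1 - exp(-t tau)) to the full-scale
#' normalized post-bleach signal. Initialization is a multistart grid over
#' (A, tau); every start is scored by its model SSE and the best
#' `refine_top` starts are polished with bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]); the best converged fit wins.
#'
#' With `refine_floor = TRUE` (default) the model carries a nuisance
#' intercept, y = c + (1 - c) A (1 - exp(-t tau)), c >= 0. The empirical
#' post-bleach minimum used by the full-scale normalization lies below the
#' true bleach floor in noisy traces (the minimum of n noisy samples
#' undershoots), which shifts the rescaled signal upward by a constant the
#' forced-through-zero model cannot absorb; c re-estimates that floor error
#' within the fit and is exactly 0 on noise-free data.
#'
#' @param norm a [normalized_trace()].
#' @param n_starts numeric(2): grid size over A (linear in `bounds_A`) and
#'   tau (log-spaced in `bounds_tau`).
#' @param refine_top number of starts polished with the full optimizer.
#' @param bounds_A,bounds_tau box constraints; A may exceed 1 to accommodate
#'   overshoot, tau in 1/s.
#' @param refine_floor fit the scale-floor nuisance intercept.
#' @return Object of class `frap_fit`: `A` (mobile fraction), `tau` (1/s),
#'   `t_half` = ln(2)/tau (s), `floor_shift` (the fitted nuisance intercept),
#'   `rms` residual, `converged`, `n_post`, carried metadata.
#' @export
fit_recovery <- function(norm, n_starts = c(5, 5), refine_top = 3,
                         bounds_A = c(0, 1.5), bounds_tau = c(1e-5, 1),
                         refine_floor = TRUE) {
  stopifnot(inherits(norm, "normalized_trace"))
  t <- norm$times[norm$times >= 0]
  y <- norm$i_fsn[norm$times >= 0]
  if (length(t) < 10) {
    eht_stop("eht_fit_failed", "fewer than 10 post-bleach samples")
  }
  if (stats::sd(y) == 0) {
    ## degenerate flat signal: no recovery, amplitude zero
    return(structure(list(
      A = 0, tau = bounds_tau[1], t_half = log(2) / bounds_tau[1],
      floor_shift = 0, rms = 0, converged = TRUE, n_post = length(t),
      junction_type = norm$junction_type, condition = norm$condition,
      drift = norm$drift), class = "frap_fit"))
  }
  A0 <- seq(max(bounds_A[1], 0.05), min(bounds_A[2], 1.4), length.out = n_starts[1])
  tau0 <- exp(seq(log(max(bounds_tau[1], 1e-4)), log(min(bounds_tau[2], 0.5)),
                  length.out = n_starts[2]))
  grid <- expand.grid(A = A0, tau = tau0)
  sse0 <- vapply(seq_len(nrow(grid)), function(i) {
    sum((y - grid$A[i] * (1 - exp(-t * grid$tau[i])))^2)
  }, 0)
  ord <- order(sse0)[seq_len(min(refine_top, nrow(grid)))]
  dat <- data.frame(t = t, y = y)
  best <- NULL
  for (i in ord) {
    fit <- tryCatch(suppressWarnings(
      if (refine_floor) {
        minpack.lm::nlsLM(
          y ~ c + (1 - c) * A * (1 - exp(-t * tau)), data = dat,
          start = list(c = 0.02, A = grid$A[i], tau = grid$tau[i]),
          lower = c(0, bounds_A[1], bounds_tau[1]),
          upper = c(0.5, bounds_A[2], bounds_tau[2]),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ A * (1 - exp(-t * tau)), data = dat,
          start = list(A = grid$A[i], tau = grid$tau[i]),
          lower = c(bounds_A[1], bounds_tau[1]),
          upper = c(bounds_A[2], bounds_tau[2]),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }), error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(A = unname(cf["A"]), tau = unname(cf["tau"]),
                   floor_shift = if (refine_floor) unname(cf["c"]) else 0,
                   sse = sse)
    }
  }
  if (is.null(best)) {
    eht_stop("eht_fit_failed", "no multistart fit converged",
             diagnostics = list(grid_sse = sse0))
  }
  structure(list(
    A = best$A, tau = best$tau, t_half = log(2) / best$tau,
    floor_shift = best$floor_shift,
    rms = sqrt(best$sse / length(t)), converged = TRUE, n_post = length(t),
    junction_type = norm$junction_type, condition = norm$condition,
    drift = norm$drift), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> A = %.3f, tau = %.4g /s, T_half = %.1f s (rms %.3g)\n",
              x$A, x$tau, x$t_half, x$rms))
  invisible(x)
}

#' Early recovery slope
#'
#' Ordinary least-squares line through the full-scale normalized signal over
#' the first `window_s` seconds post-bleach; the slope is the early recovery
#' speed (1/s).
#' @param norm a [normalized_trace()].
#' @param window_s window length, s.
#' @return Slope (1/s).
#' @export
early_slope <- function(norm, window_s = 30) {
  stopifnot(inherits(norm, "normalized_trace"))
  sel <- norm$times >= 0 & norm$times <= window_s
  if (sum(sel) < 3) {
    eht_stop("eht_window_error", "fewer than 3 samples in the early window")
  }
  unname(stats::coef(stats::lm(y ~ t, data = data.frame(
    t = norm$times[sel], y = norm$i_fsn[sel])))[2])
}

#' Group summary of FRAP fits
#'
#' Medians of the mobile fraction, half-time and early slope per
#' junction-type x condition group, with pairwise two-sided rank-sum tests
#' between groups for each metric.
#'
#' @param fit_table data.frame with columns `A`, `t_half`, `early_slope`
#'   (optional), `junction_type`, `condition`; see [fits_to_table()].
#' @return List: `summary` (per-group medians and n), `tests` (pairwise
#'   rank-sum p-values; NA with method "not-applicable" when a group has a
#'   single observation).
#' @export
summarize_groups <- function(fit_table) {
  if (is.null(fit_table) || nrow(fit_table) == 0) {
    return(list(summary = data.frame(), tests = data.frame()))
  }
  fit_table$group <- paste(fit_table$junction_type, fit_table$condition, sep = "/")
  metrics <- intersect(c("A", "t_half", "early_slope"), names(fit_table))
  groups <- unique(fit_table$group)
  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- fit_table[fit_table$group == g, , drop = FALSE]
    out <- data.frame(group = g, n = nrow(sub))
    for (m in metrics) out[[paste0("median_", m)]] <- stats::median(sub[[m]])
    out
  }))
  tests <- list()
  if (length(groups) > 1) {
    for (gi in seq_along(groups)[-length(groups)]) {
      for (gj in (gi + 1):length(groups)) {
        a <- fit_table[fit_table$group == groups[gi], , drop = FALSE]
        b <- fit_table[fit_table$group == groups[gj], , drop = FALSE]
        for (m in metrics) {
          if (nrow(a) < 2 || nrow(b) < 2) {
            tests[[length(tests) + 1L]] <- data.frame(
              group1 = groups[gi], group2 = groups[gj], metric = m,
              p = NA_real_, method = "not-applicable")
          } else {
            w <- wilcoxon_rank_sum(a[[m]], b[[m]])
            tests[[length(tests) + 1L]] <- data.frame(
              group1 = groups[gi], group2 = groups[gj], metric = m,
              p = w$p, method = w$method)
          }
        }
      }
    }
  }
  list(summary = summ,
       tests = if (length(tests)) do.call(rbind, tests) else data.frame())
}

#' Collect fits into a flat table
#' @param fits list of [fit_recovery()] results.
#' @param early_slopes optional numeric vector of matching [early_slope()]
#'   values.
#' @return data.frame with one row per fit.
#' @export
fits_to_table <- function(fits, early_slopes = NULL) {
  out <- do.call(rbind, lapply(fits, function(f) data.frame(
    A = f$A, tau = f$tau, t_half = f$t_half,
    junction_type = f$junction_type, condition = f$condition)))
  if (!is.null(early_slopes)) out$early_slope <- early_slopes
  out
}
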