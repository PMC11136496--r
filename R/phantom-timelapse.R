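## Flow time-lapse phantom for the cell counter: a dual-channel z-stack
## containing persistent objects whose depth spans 15-20 planes (non-moving
## cells) and single-plane transient objects (circulating thrombocytes
## crossing the field between frames). A subset of persistent objects is
## double positive (green + red); transients are green-only.

#' Configuration for the flow time-lapse phantom
#'
#' @param dims_px stack size, named (y, x, planes).
#' @param n_transient single-plane objects.
#' @param n_persistent objects spanning `span_range` planes.
#' @param n_double_positive persistent objects also painted in the red
#'   channel (<= n_persistent).
#' @param span_range inclusive range of persistent plane spans.
#' @param amplitude green in-plane peak intensity.
#' @param red_amplitude red peak intensity of double positives.
#' @param sigma_px in-plane Gaussian radius of objects, pixels.
#' @param noise_sd additive Gaussian noise SD (0 = noise-free; SNR =
#'   amplitude / noise_sd).
#' @param min_sep_px minimum in-plane center separation between objects.
#' @param median_window reference window of the downstream rolling median;
#'   the stack depth must be at least twice this.
#' @param spacing_um voxel spacing (y, x, plane) um.
#' @param seed RNG seed.
#' @return List of class `flow_timelapse_config`.
#' @export
flow_timelapse_config <- function(dims_px = c(y = 96, x = 96, planes = 48),
                                  n_transient = 5L, n_persistent = 5L,
                                  n_double_positive = 0L,
                                  span_range = c(15L, 20L),
                                  amplitude = 100, red_amplitude = 80,
                                  sigma_px = 2.5, noise_sd = 0,
                                  min_sep_px = 16, median_window = 20L,
                                  spacing_um = c(y = 0.27, x = 0.27, z = 0.3),
                                  seed = 1L) {
  if (dims_px[["planes"]] < 2 * median_window) {
    eht_stop("eht_config_error",
             "stack depth must be at least twice the median window")
  }
  if (n_double_positive > n_persistent) {
    eht_stop("eht_config_error", "n_double_positive exceeds n_persistent")
  }
  stopifnot_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "flow_timelapse_config"
  cfg
}

#' Generate the flow time-lapse phantom
#'
#' @param cfg a [flow_timelapse_config()].
#' @return List: `green`, `red` (3D arrays, y x plane), `ledger` data.frame
#'   (id, class, y_px, x_px, z0, span, total_green, total_red,
#'   red_positive), `spacing_um`.
#' @export
make_flow_timelapse <- function(cfg) {
  stopifnot(inherits(cfg, "flow_timelapse_config"))
  with_seed(cfg$seed, {
    d <- c(cfg$dims_px[["y"]], cfg$dims_px[["x"]], cfg$dims_px[["planes"]])
    green <- array(0, d); red <- array(0, d)
    n_tot <- cfg$n_transient + cfg$n_persistent
    margin <- ceiling(3 * cfg$sigma_px) + 2
    ## rejection-sample well-separated in-plane centers
    centers <- matrix(NA_real_, 0, 2)
    guard <- 0L
    while (nrow(centers) < n_tot && guard < 20000L) {
      guard <- guard + 1L
      p <- c(stats::runif(1, margin, d[1] - margin),
             stats::runif(1, margin, d[2] - margin))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= cfg$min_sep_px) {
        centers <- rbind(centers, p)
      }
    }
    if (nrow(centers) < n_tot) {
      eht_stop("eht_config_error",
               "could not place objects with the requested separation")
    }
    spans <- c(rep(1L, cfg$n_transient),
               sample(seq(cfg$span_range[1], cfg$span_range[2]),
                      cfg$n_persistent, replace = TRUE))
    classes <- rep(c("transient", "persistent"),
                   c(cfg$n_transient, cfg$n_persistent))
    red_pos <- rep(FALSE, n_tot)
    if (cfg$n_double_positive > 0) {
      red_pos[cfg$n_transient +
                sample(cfg$n_persistent, cfg$n_double_positive)] <- TRUE
    }
    ledger <- data.frame(id = seq_len(n_tot), class = classes,
                         y_px = centers[, 1], x_px = centers[, 2],
                         z0 = NA_integer_, span = spans,
                         total_green = 0, total_red = 0,
                         red_positive = red_pos)
    r3 <- ceiling(3 * cfg$sigma_px)
    for (i in seq_len(n_tot)) {
      z0 <- if (spans[i] == 1L) sample(d[3], 1) else
        sample(d[3] - spans[i] + 1L, 1)
      ledger$z0[i] <- z0
      iy <- max(1, round(centers[i, 1]) - r3):min(d[1], round(centers[i, 1]) + r3)
      ix <- max(1, round(centers[i, 2]) - r3):min(d[2], round(centers[i, 2]) + r3)
      g2 <- outer(exp(-(iy - centers[i, 1])^2 / (2 * cfg$sigma_px^2)),
                  exp(-(ix - centers[i, 2])^2 / (2 * cfg$sigma_px^2)))
      g2[g2 < exp(-4.5)] <- 0
      for (z in z0:(z0 + spans[i] - 1L)) {
        green[iy, ix, z] <- green[iy, ix, z] + cfg$amplitude * g2
        if (red_pos[i]) red[iy, ix, z] <- red[iy, ix, z] + cfg$red_amplitude * g2
      }
      ledger$total_green[i] <- cfg$amplitude * sum(g2) * spans[i]
      ledger$total_red[i] <- if (red_pos[i]) cfg$red_amplitude * sum(g2) * spans[i] else 0
    }
    if (cfg$noise_sd > 0) {
      green <- pmax(green + stats::rnorm(length(green), 0, cfg$noise_sd), 0)
      red <- pmax(red + stats::rnorm(length(red), 0, cfg$noise_sd), 0)
    }
    list(green = green, red = red, ledger = ledger,
         spacing_um = cfg$spacing_um)
  })
}
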