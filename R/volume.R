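## Multi-channel 3D intensity volumes.
##
## Axis convention used throughout: the vessel (aorta) axis runs along x, so a
## cross-section at fixed x is a (y, z) plane. Arrays are stored with
## dimensions (y, z, x, channel), and physical voxel spacing in micrometres is
## carried per axis. Time-lapse / plain z-stacks used by the cell counter use
## the same container with axes (y, x, plane, channel).

#' Construct a volume stack
#'
#' @param data 4D numeric array, dimensions (y, z, x, channel). A 3D array is
#'   promoted to a single channel.
#' @param spacing named numeric: voxel spacing in um for `y`, `z`, `x`.
#' @param channels optional character vector of channel names.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, spacing, channels = NULL) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4) {
    eht_stop("eht_config_error", "volume data must be a 3D or 4D array")
  }
  spacing <- unlist(spacing)
  if (!all(c("y", "z", "x") %in% names(spacing))) {
    eht_stop("eht_config_error", "spacing must name y, z and x")
  }
  if (any(spacing <= 0)) eht_stop("eht_config_error", "spacing must be > 0")
  if (any(data < 0, na.rm = TRUE)) {
    eht_stop("eht_config_error", "intensities must be non-negative")
  }
  channels <- channels %||% paste0("ch", seq_len(dim(data)[4]))
  structure(list(data = data, spacing = spacing[c("y", "z", "x")],
                 channels = channels),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %d x %d x %d voxels (y,z,x), %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing (um): y=%.3g z=%.3g x=%.3g\n",
              x$spacing["y"], x$spacing["z"], x$spacing["x"]))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

## cross-section (y, z) matrix at axial index ix for a channel
vol_slice <- function(stack, ix, channel = 1L) {
  stack$data[, , ix, channel]
}

#' Write a volume stack as a multi-page TIFF
#'
#' Pages iterate over axial position within channel (channel-major). Voxel
#' spacing is written to a CSV sidecar (`<file>.meta.csv`), since the plain
#' TIFF writer carries no physical calibration.
#' @param stack a [volume_stack()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_stack_tiff <- function(stack, file) {
  d <- dim(stack$data)
  mx <- max(stack$data, 1)
  pages <- list()
  for (c in seq_len(d[4])) for (ix in seq_len(d[3])) {
    pages[[length(pages) + 1L]] <- stack$data[, , ix, c] / mx
  }
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  meta <- data.frame(axis = c("y", "z", "x"),
                     spacing_um = as.numeric(stack$spacing),
                     n = d[1:3])
  meta$scale <- mx
  meta$n_channels <- d[4]
  utils::write.csv(meta, paste0(file, ".meta.csv"), row.names = FALSE)
  invisible(file)
}

#' Read a volume stack written by [write_stack_tiff()]
#' @param file TIFF path (with `<file>.meta.csv` sidecar alongside).
#' @return A [volume_stack()].
#' @export
read_stack_tiff <- function(file) {
  meta <- utils::read.csv(paste0(file, ".meta.csv"))
  pages <- tiff::readTIFF(file, all = TRUE)
  nc <- meta$n_channels[1]
  nx <- meta$n[meta$axis == "x"]
  arr <- array(0, c(meta$n[meta$axis == "y"], meta$n[meta$axis == "z"], nx, nc))
  k <- 1L
  for (c in seq_len(nc)) for (ix in seq_len(nx)) {
    arr[, , ix, c] <- pages[[k]] * meta$scale[1]
    k <- k + 1L
  }
  volume_stack(arr, spacing = stats::setNames(meta$spacing_um, meta$axis))
}
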