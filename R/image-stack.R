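#' Multi-channel volumetric image stack
#'
#' Container for calibrated multi-channel (and optionally time-resolved)
#' fluorescence data. The voxel array is stored with the canonical axis
#' order `(time, channel, z, y, x)`; 3D `(z, y, x)` and 4D
#' `(channel, z, y, x)` input arrays are promoted by inserting
#' length-1 axes.
#'
#' @param voxels numeric array with 3, 4 or 5 dimensions (see above).
#'   Intensities must be finite and non-negative.
#' @param calibration a [calibration()] object.
#' @param channel_names optional character vector of channel labels.
#' @param marker_channel index of the channel used for segmentation
#'   (e.g. the Arl13B or acetylated-tubulin staining).
#' @return An object of class `image_stack` with elements `voxels`,
#'   `calibration`, `channel_names`, `marker_channel`.
#' @examples
#' v <- array(runif(2 * 4 * 8 * 8), dim = c(2, 4, 8, 8)) # (c, z, y, x)
#' s <- image_stack(v, calibration(0.2, dz = 0.4), marker_channel = 1)
#' dim(s$voxels) # 1 2 4 8 8
#' @export
image_stack <- function(voxels, calibration, channel_names = NULL,
                        marker_channel = 1L) {
  stopifnot(is.array(voxels), is_calibration(calibration))
  nd <- length(dim(voxels))
  if (nd == 3) {
    dim(voxels) <- c(1L, 1L, dim(voxels))
  } else if (nd == 4) {
    dim(voxels) <- c(1L, dim(voxels))
  } else if (nd != 5) {
    stop("voxels must have 3 (z,y,x), 4 (c,z,y,x) or 5 (t,c,z,y,x) dimensions")
  }
  d <- dim(voxels)
  if (any(d[3:5] < 1)) stop("all spatial dimensions must be >= 1")
  if (anyNA(voxels) || any(!is.finite(voxels)) || any(voxels < 0))
    stop("intensities must be finite and >= 0")
  marker_channel <- as.integer(marker_channel)
  if (marker_channel < 1 || marker_channel > d[2])
    stop("marker_channel out of range")
  if (!is.null(channel_names) && length(channel_names) != d[2])
    stop("channel_names must have one entry per channel")
  structure(list(voxels = voxels, calibration = calibration,
                 channel_names = channel_names,
                 marker_channel = marker_channel),
            class = "image_stack")
}

is_image_stack <- function(x) inherits(x, "image_stack")

#' Stack dimensions
#'
#' @param stack an [image_stack()].
#' @return Named integer vector `(t, c, z, y, x)`.
#' @export
stack_dim <- function(stack) {
  stopifnot(is_image_stack(stack))
  d <- dim(stack$voxels)
  names(d) <- c("t", "c", "z", "y", "x")
  d
}

#' Extract one channel volume
#'
#' @param stack an [image_stack()].
#' @param channel channel index.
#' @param time time-point index (default 1).
#' @return 3D numeric array `(z, y, x)`.
#' @export
channel_volume <- function(stack, channel, time = 1L) {
  stopifnot(is_image_stack(stack))
  d <- dim(stack$voxels)
  channel <- as.integer(channel); time <- as.integer(time)
  if (channel < 1 || channel > d[2]) stop("invalid channel index")
  if (time < 1 || time > d[1]) stop("invalid time index")
  v <- stack$voxels[time, channel, , , , drop = FALSE]
  dim(v) <- d[3:5]
  v
}

#' @export
print.image_stack <- function(x, ...) {
  d <- stack_dim(x)
  cat(sprintf(
    "image_stack: %d time point(s), %d channel(s), volume %d x %d x %d (z,y,x)\n",
    d["t"], d["c"], d["z"], d["y"], d["x"]))
  print(x$calibration)
  if (!is.null(x$channel_names))
    cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("marker channel:", x$marker_channel, "\n")
  invisible(x)
}
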