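#' Voxel calibration
#'
#' Physical voxel edge lengths in micrometers, plus an optional frame
#' interval for time-lapse data. Confocal cilia stacks are typically
#' acquired with an axial step of 0.4--0.5 um and a lateral pixel size of
#' 0.1--0.25 um.
#'
#' @param dx,dy,dz voxel edge lengths along x, y and z, in micrometers;
#'   must be positive. `dy` defaults to `dx`.
#' @param frame_interval time between frames in seconds (time-lapse only).
#' @return An object of class `calibration`.
#' @examples
#' calibration(dx = 0.21, dz = 0.4)
#' @export
calibration <- function(dx, dy = dx, dz, frame_interval = NA_real_) {
  stopifnot(is.numeric(dx), is.numeric(dy), is.numeric(dz),
            length(dx) == 1, length(dy) == 1, length(dz) == 1)
  if (!all(is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0))
    stop("voxel sizes dx, dy, dz must be finite and > 0")
  if (!is.na(frame_interval) && frame_interval <= 0)
    stop("frame_interval must be > 0 seconds")
  structure(list(dx = dx, dy = dy, dz = dz,
                 frame_interval = frame_interval),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: dx = %g, dy = %g, dz = %g um", x$dx, x$dy, x$dz))
  if (!is.na(x$frame_interval))
    cat(sprintf(", frame interval = %g s", x$frame_interval))
  cat("\n")
  invisible(x)
}

is_calibration <- function(x) inherits(x, "calibration")

# voxel volume in um^3
voxel_volume <- function(cal) cal$dx * cal$dy * cal$dz

# calibration of a `factor`-fold upscaled grid
upscaled_calibration <- function(cal, factor) {
  calibration(dx = cal$dx / factor, dy = cal$dy / factor,
              dz = cal$dz / factor, frame_interval = cal$frame_interval)
}
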