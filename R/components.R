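# Cilia as 3D connected components of the segmented marker channel:
# labeling, minimum-volume noise filtering, per-channel intensity means.

new_cilium <- function(id, voxel_indices, calibration = NULL,
                       border_touching = FALSE) {
  n <- nrow(voxel_indices)
  vol_um3 <- NA_real_
  centroid <- c(z = NA_real_, y = NA_real_, x = NA_real_)
  if (!is.null(calibration)) {
    vol_um3 <- n * voxel_volume(calibration)
    d <- c(calibration$dz, calibration$dy, calibration$dx)
    centroid <- (colMeans(voxel_indices) - 1) * d
    names(centroid) <- c("z", "y", "x")
  }
  structure(list(id = as.integer(id),
                 voxel_indices = voxel_indices,  # n x 3 matrix (z, y, x), 1-based
                 n_voxels = n,
                 volume_um3 = vol_um3,
                 centroid_um = centroid,
                 mean_intensity = NULL,
                 skeleton = NULL,
                 length_um = NA_real_,
                 total_skeleton_um = NA_real_,
                 border_touching = border_touching,
                 calibration = calibration),
            class = "cilium")
}

#' @export
print.cilium <- function(x, ...) {
  cat(sprintf("cilium #%d: %d voxels", x$id, x$n_voxels))
  if (!is.na(x$volume_um3)) cat(sprintf(" (%.3f um^3)", x$volume_um3))
  if (!is.na(x$length_um)) cat(sprintf(", length %.2f um", x$length_um))
  if (x$border_touching) cat(" [touches border]")
  cat("\n")
  invisible(x)
}

#' Detect 3D objects in a segmentation mask
#'
#' Partitions the foreground into maximal connected components under the
#' chosen voxel connectivity. Labels follow a deterministic scan order.
#' Objects that touch the stack border are kept but flagged
#' (`border_touching`).
#'
#' @param mask a `segmentation_mask` from [segment_marker()] or a logical
#'   `(z, y, x)` array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26
#'   (faces+edges+corners, default; thin diagonal cilia fragment under 6).
#' @param calibration optional [calibration()]; when given, physical volume
#'   and centroid are filled in.
#' @return List of `cilium` objects.
#' @export
label_components <- function(mask, connectivity = 26L, calibration = NULL) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$foreground
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  labels <- .cc_label3d(mask, as.integer(connectivity))
  n_obj <- max(labels)
  if (n_obj == 0) return(list())
  d <- dim(mask)
  idx <- which(labels > 0)
  lab <- labels[idx]
  z <- (idx - 1) %% d[1] + 1
  y <- ((idx - 1) %/% d[1]) %% d[2] + 1
  x <- (idx - 1) %/% (d[1] * d[2]) + 1
  lapply(seq_len(n_obj), function(i) {
    sel <- lab == i
    vox <- cbind(z = z[sel], y = y[sel], x = x[sel])
    border <- any(vox[, 1] == 1 | vox[, 1] == d[1] |
                  vox[, 2] == 1 | vox[, 2] == d[2] |
                  vox[, 3] == 1 | vox[, 3] == d[3])
    new_cilium(i, vox, calibration, border)
  })
}

#' Convert objects back to an integer label volume
#'
#' @param objects list of `cilium` objects.
#' @param dim_zyx dimensions `(z, y, x)` of the target volume.
#' @return Integer array with each object's voxels set to its id.
#' @export
objects_to_labels <- function(objects, dim_zyx) {
  labels <- array(0L, dim = dim_zyx)
  for (ob in objects) {
    labels[ob$voxel_indices] <- ob$id
  }
  labels
}

#' Remove objects below a minimum voxel volume
#'
#' Noise exclusion: objects whose voxel count is below the size threshold
#' are removed; objects at or above it are retained (default 10 voxels).
#' Order and all measurements of surviving objects are preserved.
#'
#' @param objects list of `cilium` objects.
#' @param min_voxels minimum retained voxel count (default 10).
#' @return Filtered list.
#' @export
filter_by_volume <- function(objects, min_voxels = 10L) {
  objects[vapply(objects, function(o) o$n_voxels >= min_voxels, logical(1))]
}

#' Mean intensity of an object in every channel
#'
#' Arithmetic mean over exactly the object's member voxels, per channel.
#'
#' @param object a `cilium`.
#' @param stack the [image_stack()] the mask came from.
#' @param time time-point index.
#' @return The object with `mean_intensity` filled (named per channel).
#' @export
measure_intensities <- function(object, stack, time = 1L) {
  stopifnot(inherits(object, "cilium"), is_image_stack(stack))
  d <- stack_dim(stack)
  vox <- object$voxel_indices
  if (any(vox[, 1] > d["z"]) || any(vox[, 2] > d["y"]) ||
      any(vox[, 3] > d["x"]) || any(vox < 1))
    stop("object voxel indices out of stack bounds")
  means <- vapply(seq_len(d["c"]), function(ch) {
    v <- channel_volume(stack, ch, time)
    mean(v[vox])
  }, numeric(1))
  names(means) <- if (!is.null(stack$channel_names)) stack$channel_names
                  else paste0("ch", seq_len(d["c"]))
  object$mean_intensity <- means
  object
}

#' Tabulate measured cilium objects
#'
#' @param objects list of `cilium` objects.
#' @return Data frame with one row per object (see [write_object_table()]
#'   for the column set).
#' @export
objects_to_table <- function(objects) {
  n_ch <- max(c(0L, vapply(objects,
                           function(o) length(o$mean_intensity), integer(1))))
  base_cols <- c("id", "n_voxels", "volume_um3",
                 "centroid_z_um", "centroid_y_um", "centroid_x_um")
  int_cols <- if (n_ch > 0) paste0("mean_int_", seq_len(n_ch)) else character()
  cols <- c(base_cols, int_cols,
            "length_um", "total_skeleton_um", "border_touching")
  if (length(objects) == 0) {
    tab <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    tab$border_touching <- logical(0)
    return(tab)
  }
  rows <- lapply(objects, function(o) {
    ints <- rep(NA_real_, n_ch)
    if (!is.null(o$mean_intensity))
      ints[seq_along(o$mean_intensity)] <- o$mean_intensity
    c(list(id = o$id, n_voxels = o$n_voxels, volume_um3 = o$volume_um3,
           centroid_z_um = unname(o$centroid_um["z"]),
           centroid_y_um = unname(o$centroid_um["y"]),
           centroid_x_um = unname(o$centroid_um["x"])),
      stats::setNames(as.list(ints), int_cols),
      list(length_um = o$length_um, total_skeleton_um = o$total_skeleton_um,
           border_touching = o$border_touching))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
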