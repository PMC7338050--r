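# Per-cilium downstream analysis: control background subtraction,
# expression gating, normalization to control cells, length-vs-expression
# regression, and frame-to-frame object linking for time-lapse recordings.

#' Expression-gate parameters
#'
#' Cilia whose (background-subtracted) intensity in the gate channel is at
#' or above the threshold are excluded; the default 7.5 a.u. keeps the low
#' expression regime in which ectopic ciliary expression does not itself
#' change cilium length.
#'
#' @param gate_channel channel index the gate is applied to.
#' @param gate_threshold strict upper bound in arbitrary units
#'   (default 7.5).
#' @param control_background per-channel background (a.u.) to subtract
#'   before gating (default 0).
#' @return An object of class `gate_params`.
#' @export
gate_params <- function(gate_channel, gate_threshold = 7.5,
                        control_background = 0) {
  stopifnot(gate_threshold > 0, all(control_background >= 0))
  structure(list(gate_channel = as.integer(gate_channel),
                 gate_threshold = gate_threshold,
                 control_background = control_background),
            class = "gate_params")
}

#' Subtract the mean ciliary fluorescence of control cells
#'
#' Reduces each object's mean intensity in `channel` by the arithmetic
#' mean over the control objects' ciliary means in the same channel
#' (e.g. non-transfected control cells).
#'
#' @param objects list of measured `cilium` objects.
#' @param control_objects nonempty list of measured control objects.
#' @param channel channel index.
#' @return `objects` with corrected intensities.
#' @export
subtract_control_background <- function(objects, control_objects, channel) {
  if (length(control_objects) == 0) stop("control_objects must be nonempty")
  bg <- mean(vapply(control_objects,
                    function(o) o$mean_intensity[[channel]], numeric(1)))
  lapply(objects, function(o) {
    o$mean_intensity[[channel]] <- o$mean_intensity[[channel]] - bg
    o
  })
}

#' Gate objects by expression level
#'
#' Keeps exactly the objects whose gate-channel intensity (after
#' subtracting `control_background`, if set) is strictly below the gate
#' threshold; the boundary value itself is excluded.
#'
#' @param objects list of measured `cilium` objects.
#' @param params a [gate_params()].
#' @return Filtered list.
#' @export
gate_by_expression <- function(objects, params) {
  stopifnot(inherits(params, "gate_params"))
  bg <- params$control_background
  if (length(bg) > 1) bg <- bg[params$gate_channel]
  keep <- vapply(objects, function(o) {
    v <- o$mean_intensity[[params$gate_channel]] - bg
    v < params$gate_threshold
  }, logical(1))
  objects[keep]
}

#' Normalize cilium lengths to control cells
#'
#' @param treated numeric vector of cilium lengths (um).
#' @param control nonempty numeric vector of control lengths (um) with a
#'   positive mean.
#' @return Treated lengths as percent of the control mean.
#' @export
normalize_lengths_to_control <- function(treated, control) {
  if (length(control) == 0 || mean(control) <= 0)
    stop("control lengths must be nonempty with positive mean")
  treated * 100 / mean(control)
}

#' Length versus expression regression
#'
#' Ordinary least-squares fit of cilium length on gate-channel intensity,
#' with the standard test of the slope against zero. Used to establish in
#' which expression regime ciliary length is independent of expression.
#'
#' @param objects list of >= 3 measured `cilium` objects with defined
#'   lengths.
#' @param channel intensity channel index.
#' @return List: `slope`, `intercept`, `correlation` (Pearson r),
#'   `p_value` (zero-slope test), `n`.
#' @export
length_intensity_fit <- function(objects, channel) {
  len <- vapply(objects, function(o) o$length_um, numeric(1))
  int <- vapply(objects, function(o) o$mean_intensity[[channel]], numeric(1))
  ok <- is.finite(len) & is.finite(int)
  len <- len[ok]; int <- int[ok]
  if (length(len) < 3) stop("need at least 3 objects with defined lengths")
  if (stats::var(int) == 0)
    stop("intensity is constant; slope undefined")
  fit <- stats::lm(len ~ int)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       correlation = unname(stats::cor(int, len)),
       p_value = unname(sm$coefficients[2, 4]),
       n = length(len))
}

#' Link per-frame objects into tracks
#'
#' Greedy nearest-centroid frame-to-frame linking: candidate pairs between
#' the previous frame's track heads and the current frame's objects are
#' assigned in order of increasing centroid distance, up to a maximum
#' displacement. Unlinked objects start new tracks; a track that finds no
#' match ends (no gap closing). Every object observation belongs to
#' exactly one track.
#'
#' @param frames list of per-time-point lists of measured `cilium`
#'   objects (each frame segmented independently).
#' @param max_displacement_um maximum allowed centroid displacement
#'   between consecutive frames (default 2 um).
#' @return Data frame with columns `track_id`, `frame`, `object_id`,
#'   centroid coordinates and the per-channel mean intensities.
#' @export
track_over_time <- function(frames, max_displacement_um = 2) {
  rows <- list()
  next_track <- 0L
  prev <- list()  # track heads: list of (track_id, centroid)
  for (fi in seq_along(frames)) {
    objs <- frames[[fi]]
    assigned_track <- rep(NA_integer_, length(objs))
    if (length(prev) > 0 && length(objs) > 0) {
      cand <- expand.grid(p = seq_along(prev), o = seq_along(objs))
      cand$d <- mapply(function(p, o)
        sqrt(sum((prev[[p]]$centroid - objs[[o]]$centroid_um)^2)),
        cand$p, cand$o)
      cand <- cand[cand$d <= max_displacement_um, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_p <- logical(length(prev)); used_o <- logical(length(objs))
      for (k in seq_len(nrow(cand))) {
        p <- cand$p[k]; o <- cand$o[k]
        if (used_p[p] || used_o[o]) next
        used_p[p] <- TRUE; used_o[o] <- TRUE
        assigned_track[o] <- prev[[p]]$track_id
      }
    }
    heads <- list()
    for (o in seq_along(objs)) {
      if (is.na(assigned_track[o])) {
        next_track <- next_track + 1L
        assigned_track[o] <- next_track
      }
      ob <- objs[[o]]
      ints <- if (is.null(ob$mean_intensity)) numeric(0) else ob$mean_intensity
      row <- data.frame(track_id = assigned_track[o], frame = fi,
                        object_id = ob$id,
                        centroid_z_um = unname(ob$centroid_um["z"]),
                        centroid_y_um = unname(ob$centroid_um["y"]),
                        centroid_x_um = unname(ob$centroid_um["x"]))
      for (ci in seq_along(ints))
        row[[paste0("mean_int_", ci)]] <- unname(ints[ci])
      rows[[length(rows) + 1L]] <- row
      heads[[length(heads) + 1L]] <- list(track_id = assigned_track[o],
                                          centroid = ob$centroid_um)
    }
    prev <- heads
  }
  if (length(rows) == 0)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      object_id = integer(0)))
  do.call(rbind, rows)
}
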