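# Synthetic multi-channel stacks containing tube-shaped cilia with known
# ground truth: curved centerlines, disk cross-sections, channel-correlated
# cargo intensities, optional optical blur and Poisson/Gaussian noise.
# Ground truth (centerline, arc length, radius, amplitudes, footprint) is
# recorded before blur and noise, so recovery tolerances absorb both the
# optics and the algorithm's own bias.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic cilium field
#'
#' Defaults emulate confocal cilia imaging: tubes of 2--8 um arc length and
#' 0.1--0.3 um radius lying close to the imaging plane, a 0.21 um lateral
#' pixel (so the skeletonization blur of 3 upscaled pixels corresponds to
#' 0.21 um) with a 0.4 um axial step, a dim background, moderate optical
#' blur, and Poisson shot noise plus Gaussian read noise.
#'
#' @param n_cilia number of cilia to place (default 5).
#' @param length_range arc-length interval in um (default `c(2, 8)`).
#' @param radius_range tube radius interval in um (default `c(0.1, 0.3)`).
#' @param curvature maximum bend in radians per um of arc (default 0.3).
#' @param marker_amplitude marker-channel tube intensity, a.u.
#' @param cargo_amplitudes list of per-cargo-channel amplitude ranges
#'   `c(min, max)`; one cargo channel by default. Each cilium draws its
#'   amplitude uniformly from the range, so channels are correlated with
#'   the marker footprint but vary per cilium (enabling expression-gating
#'   tests). `list()` for a marker-only stack.
#' @param background_level background intensity, a.u.
#' @param psf_sigma optical blur sigma in um (0 disables).
#' @param noise list with `gaussian_sd` (a.u.; 0 disables) and `poisson`
#'   (logical shot-noise flag).
#' @param stack_shape volume dimensions `(z, y, x)` in voxels.
#' @param calibration a [calibration()].
#' @param seed integer seed fixing everything.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cilia = 5L,
                           length_range = c(2, 8),
                           radius_range = c(0.1, 0.3),
                           curvature = 0.3,
                           marker_amplitude = 200,
                           cargo_amplitudes = list(c(20, 100)),
                           background_level = 2,
                           psf_sigma = 0.15,
                           noise = list(gaussian_sd = 2, poisson = TRUE),
                           stack_shape = c(14L, 96L, 96L),
                           calibration = ciliaquant::calibration(
                             dx = 0.21, dz = 0.4),
                           seed = 1L) {
  stopifnot(n_cilia >= 1, all(length_range > 0), all(radius_range > 0),
            curvature >= 0, marker_amplitude > 0, background_level >= 0,
            psf_sigma >= 0, length(stack_shape) == 3)
  structure(list(n_cilia = as.integer(n_cilia),
                 length_range = length_range, radius_range = radius_range,
                 curvature = curvature,
                 marker_amplitude = marker_amplitude,
                 cargo_amplitudes = cargo_amplitudes,
                 background_level = background_level,
                 psf_sigma = psf_sigma, noise = noise,
                 stack_shape = as.integer(stack_shape),
                 calibration = calibration, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample a curved 3D centerline of exact arc length
#'
#' Arc-length-parameterized polyline: fixed step size with a random
#' direction change of at most `curvature * step` radians per step. The
#' summed segment length equals the requested length exactly (the step is
#' `length / n_steps`).
#'
#' @param length arc length in um (> 0).
#' @param curvature maximum bend in radians per um.
#' @param seed optional seed (otherwise the ambient RNG stream is used).
#' @param step_um nominal step size in um (default 0.1).
#' @param start optional start point `(z, y, x)` in um (default origin).
#' @param direction optional initial unit direction `(z, y, x)`.
#' @return Matrix (n x 3) of `(z, y, x)` points in um with attribute
#'   `arc_length`.
#' @export
sample_centerline <- function(length, curvature = 0, seed = NULL,
                              step_um = 0.1, start = c(0, 0, 0),
                              direction = NULL) {
  stopifnot(length > 0, curvature >= 0, step_um > 0)
  with_local_seed(seed, {
    n_steps <- max(1L, ceiling(length / step_um))
    step <- length / n_steps
    if (is.null(direction)) {
      direction <- stats::rnorm(3)
      direction <- direction / sqrt(sum(direction^2))
    }
    pts <- matrix(0, nrow = n_steps + 1, ncol = 3,
                  dimnames = list(NULL, c("z", "y", "x")))
    pts[1, ] <- start
    d <- direction
    for (i in seq_len(n_steps)) {
      if (curvature > 0) {
        # random perpendicular axis, bend by at most curvature * step
        p <- stats::rnorm(3)
        p <- p - sum(p * d) * d
        nrm <- sqrt(sum(p^2))
        if (nrm > 1e-12) {
          p <- p / nrm
          theta <- stats::runif(1, 0, curvature * step)
          d <- cos(theta) * d + sin(theta) * p
          d <- d / sqrt(sum(d^2))
        }
      }
      pts[i + 1, ] <- pts[i, ] + step * d
    }
    attr(pts, "arc_length") <- sum(sqrt(rowSums(diff(pts)^2)))
    pts
  })
}

#' Render a tube around a centerline into a canvas volume
#'
#' Sets every voxel whose center lies within `radius` of the centerline to
#' `amplitude` (other voxels are unchanged). As a minimum footprint, the
#' voxel nearest to each polyline vertex is always set, so sub-voxel
#' radii still leave a connected trace.
#'
#' @param centerline n x 3 matrix of `(z, y, x)` points in um.
#' @param radius tube radius in um.
#' @param amplitude intensity written into the tube.
#' @param canvas numeric `(z, y, x)` array to draw into.
#' @param calibration a [calibration()].
#' @return List: updated `canvas` and the logical `footprint` of the tube.
#' @export
render_tube <- function(centerline, radius, amplitude, canvas, calibration) {
  d <- dim(canvas)
  vs <- c(calibration$dz, calibration$dy, calibration$dx)
  extent_lo <- (c(1, 1, 1) - 1) * vs
  extent_hi <- (d - 1) * vs
  if (any(apply(centerline, 2, min) < extent_lo - radius) ||
      any(apply(centerline, 2, max) > extent_hi + radius))
    stop("tube extends outside the canvas")
  lo <- pmax(floor((apply(centerline, 2, min) - radius) / vs) + 1, 1)
  hi <- pmin(ceiling((apply(centerline, 2, max) + radius) / vs) + 1, d)
  grid <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
  pts <- cbind((grid$z - 1) * vs[1], (grid$y - 1) * vs[2], (grid$x - 1) * vs[3])
  mind <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(centerline) - 1)) {
    a <- centerline[i, ]; b <- centerline[i + 1, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    ap <- sweep(pts, 2, a, `-`)
    t <- if (ab2 > 0) pmin(1, pmax(0, (ap %*% ab) / ab2)) else 0
    proj <- sweep(t %*% t(ab), 2, -a, `-`) # a + t * ab
    dd <- sqrt(rowSums((pts - proj)^2))
    mind <- pmin(mind, dd)
  }
  inside <- mind <= radius
  footprint <- array(FALSE, dim = d)
  if (any(inside))
    footprint[cbind(grid$z[inside], grid$y[inside], grid$x[inside])] <- TRUE
  # minimum footprint: nearest voxel to each vertex
  nearest <- cbind(pmin(pmax(round(centerline[, 1] / vs[1]) + 1, 1), d[1]),
                   pmin(pmax(round(centerline[, 2] / vs[2]) + 1, 1), d[2]),
                   pmin(pmax(round(centerline[, 3] / vs[3]) + 1, 1), d[3]))
  footprint[nearest] <- TRUE
  canvas[footprint] <- amplitude
  list(canvas = canvas, footprint = footprint)
}

#' Generate a synthetic cilium field with ground truth
#'
#' Places non-overlapping curved tubes in the marker channel, renders
#' correlated cargo channels on the same footprints with per-cilium
#' amplitudes, then applies optional optical blur and Poisson/Gaussian
#' noise. Identical spec and seed give a bit-identical stack.
#'
#' @param spec a [synthetic_spec()].
#' @param max_tries placement retries per cilium before giving up.
#' @return List: `stack` (an [image_stack()]), `truth` (per-cilium list:
#'   `centerline`, `arc_length_um`, `radius_um`, `amplitudes`,
#'   `footprint` voxel matrix), and `spec`.
#' @export
generate_cilium_field <- function(spec, max_tries = 200L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cal <- spec$calibration
  d <- spec$stack_shape
  vs <- c(cal$dz, cal$dy, cal$dx)
  extent <- (d - 1) * vs
  n_cargo <- length(spec$cargo_amplitudes)
  n_ch <- 1L + n_cargo

  with_local_seed(spec$seed, {
    channels <- lapply(seq_len(n_ch), function(i)
      array(spec$background_level, dim = d))
    truth <- list()
    placed_pts <- NULL
    placed_r <- numeric(0)
    clearance <- 2 * max(vs)
    for (ci in seq_len(spec$n_cilia)) {
      len <- stats::runif(1, spec$length_range[1], spec$length_range[2])
      rad <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        margin <- rad + 2 * vs
        start <- c(stats::runif(1, margin[1], extent[1] - margin[1]),
                   stats::runif(1, margin[2], extent[2] - margin[2]),
                   stats::runif(1, margin[3], extent[3] - margin[3]))
        # near-planar orientation: cilia lie close to the coverslip plane
        uz <- stats::runif(1, -0.2, 0.2)
        phi <- stats::runif(1, 0, 2 * pi)
        dirv <- c(uz, sqrt(1 - uz^2) * sin(phi), sqrt(1 - uz^2) * cos(phi))
        cl <- sample_centerline(len, spec$curvature, step_um = 0.1,
                                start = start, direction = dirv)
        if (any(sweep(cl, 2, margin, `<`)) ||
            any(sweep(cl, 2, extent - margin, `>`))) next
        if (!is.null(placed_pts)) {
          mind <- min(apply(cl, 1, function(p)
            sqrt(min(rowSums(sweep(placed_pts, 2, p, `-`)^2)))))
          if (mind <= rad + max(placed_r) + clearance) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place ", spec$n_cilia,
                    " non-overlapping cilia after ", max_tries, " tries")
      amps <- c(marker = spec$marker_amplitude)
      rt <- render_tube(cl, rad, spec$marker_amplitude, channels[[1]], cal)
      channels[[1]] <- rt$canvas
      for (k in seq_len(n_cargo)) {
        rng <- spec$cargo_amplitudes[[k]]
        a <- stats::runif(1, rng[1], rng[2])
        amps <- c(amps, a)
        channels[[k + 1]][rt$footprint] <- a
      }
      fp_idx <- which(rt$footprint)
      fz <- (fp_idx - 1) %% d[1] + 1
      fy <- ((fp_idx - 1) %/% d[1]) %% d[2] + 1
      fx <- (fp_idx - 1) %/% (d[1] * d[2]) + 1
      truth[[ci]] <- list(centerline = cl,
                          arc_length_um = attr(cl, "arc_length"),
                          radius_um = rad,
                          amplitudes = amps,
                          footprint = cbind(z = fz, y = fy, x = fx))
      placed_pts <- rbind(placed_pts, cl)
      placed_r <- c(placed_r, rad)
    }

    # optics, then noise (ground truth stays pre-blur, pre-noise)
    if (spec$psf_sigma > 0) {
      sig_px <- spec$psf_sigma / vs  # (z, y, x) pixels
      channels <- lapply(channels, function(ch)
        .gaussian_blur3d(ch, sig_px[1], sig_px[2], sig_px[3]))
    }
    for (i in seq_len(n_ch)) {
      ch <- channels[[i]]
      if (isTRUE(spec$noise$poisson))
        ch <- array(stats::rpois(length(ch), pmax(ch, 0)), dim = d)
      sd <- spec$noise$gaussian_sd
      if (!is.null(sd) && sd > 0)
        ch <- ch + array(stats::rnorm(length(ch), 0, sd), dim = d)
      channels[[i]] <- pmax(ch, 0)
    }
    voxels <- array(0, dim = c(n_ch, d))
    for (i in seq_len(n_ch)) voxels[i, , , ] <- channels[[i]]
    stack <- image_stack(voxels, cal,
                         channel_names = c("marker",
                                           if (n_cargo > 0)
                                             paste0("cargo", seq_len(n_cargo))),
                         marker_channel = 1L)
    list(stack = stack, truth = truth, spec = spec)
  })
}

#' Generate a synthetic time-lapse of a static cilium field
#'
#' Replicates one synthetic field over `n_frames` frames, scaling each
#' channel per frame (e.g. a step response), with fresh noise per frame.
#'
#' @param spec a [synthetic_spec()].
#' @param n_frames number of frames.
#' @param channel_scale numeric matrix (frames x channels) of per-frame
#'   amplitude scale factors applied to the signal above background;
#'   default all 1 (stationary).
#' @return List: `stack` (time-resolved [image_stack()]), `truth`, `spec`.
#' @export
generate_cilium_timelapse <- function(spec, n_frames,
                                      channel_scale = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), n_frames >= 2)
  base_spec <- spec
  base_spec$noise <- list(gaussian_sd = 0, poisson = FALSE)
  base_psf <- spec$psf_sigma
  base_spec$psf_sigma <- 0
  field <- generate_cilium_field(base_spec)
  d <- spec$stack_shape
  n_ch <- stack_dim(field$stack)["c"]
  if (is.null(channel_scale))
    channel_scale <- matrix(1, nrow = n_frames, ncol = n_ch)
  stopifnot(nrow(channel_scale) == n_frames, ncol(channel_scale) == n_ch)
  vs <- c(spec$calibration$dz, spec$calibration$dy, spec$calibration$dx)
  with_local_seed(spec$seed + 1L, {
    voxels <- array(0, dim = c(n_frames, n_ch, d))
    for (t in seq_len(n_frames)) for (ch in seq_len(n_ch)) {
      v <- channel_volume(field$stack, ch)
      sig <- pmax(v - spec$background_level, 0) * channel_scale[t, ch]
      v <- sig + spec$background_level
      if (base_psf > 0) {
        sp <- base_psf / vs
        v <- .gaussian_blur3d(v, sp[1], sp[2], sp[3])
      }
      if (isTRUE(spec$noise$poisson))
        v <- array(stats::rpois(length(v), pmax(v, 0)), dim = d)
      sd <- spec$noise$gaussian_sd
      if (!is.null(sd) && sd > 0)
        v <- v + array(stats::rnorm(length(v), 0, sd), dim = d)
      voxels[t, ch, , , ] <- pmax(v, 0)
    }
    cal <- spec$calibration
    if (is.na(cal$frame_interval)) cal$frame_interval <- 1
    stack <- image_stack(voxels, cal,
                         channel_names = field$stack$channel_names,
                         marker_channel = 1L)
    list(stack = stack, truth = field$truth, spec = spec)
  })
}

#' Tabulate synthetic ground truth
#'
#' @param truth the `truth` element of [generate_cilium_field()].
#' @return Data frame: `id`, `arc_length_um`, `radius_um`, `n_voxels`, one
#'   `amplitude_*` column per channel.
#' @export
truth_to_table <- function(truth) {
  do.call(rbind, lapply(seq_along(truth), function(i) {
    tr <- truth[[i]]
    row <- data.frame(id = i, arc_length_um = tr$arc_length_um,
                      radius_um = tr$radius_um,
                      n_voxels = nrow(tr$footprint))
    for (k in seq_along(tr$amplitudes))
      row[[paste0("amplitude_", k)]] <- unname(tr$amplitudes[k])
    row
  }))
}
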