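# Global segmentation threshold: Renyi-entropy selection on a 256-bin
# histogram of the marker channel's maximum-intensity projection, applied
# once to the full 3D stack.

#' Maximum-intensity projection
#'
#' @param stack an [image_stack()].
#' @param channel channel index (default: the marker channel).
#' @param time time-point index.
#' @return 2D numeric matrix `(y, x)`; pixel = max over z.
#' @export
max_project <- function(stack, channel = stack$marker_channel, time = 1L) {
  v <- channel_volume(stack, channel, time)
  apply(v, c(2, 3), max)
}

#' 256-bin intensity histogram
#'
#' Values are min--max scaled to the 0--255 gray-level range and binned by
#' rounding, mirroring how 256-level automatic thresholding operates on
#' higher-bit-depth data. `bin_centers` map bins back to original
#' intensities. A constant image yields a single occupied bin.
#'
#' @param values numeric vector, matrix or array of intensities.
#' @param n_bins number of bins (default 256).
#' @return An `intensity_histogram`: `counts`, `bin_centers`, `n_bins`,
#'   `min`, `max`.
#' @export
build_histogram <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  stopifnot(length(v) > 0, all(is.finite(v)))
  mn <- min(v); mx <- max(v)
  if (mx > mn) {
    idx <- floor((v - mn) / (mx - mn) * (n_bins - 1) + 0.5)
  } else {
    idx <- rep(0L, length(v))
  }
  counts <- tabulate(idx + 1L, nbins = n_bins)
  structure(list(counts = counts,
                 bin_centers = mn + (seq_len(n_bins) - 1) / (n_bins - 1) *
                   (mx - mn),
                 n_bins = as.integer(n_bins), min = mn, max = mx),
            class = "intensity_histogram")
}

# threshold bin maximizing the summed Renyi entropy of order `rho` of the
# background/foreground partition; candidates restricted to splits with
# probability mass on both sides; ties broken toward the lowest bin
renyi_best_bin <- function(p, P1, rho) {
  n <- length(p)
  cand <- which(P1 > 0 & P1 < 1)          # 1-based bin positions
  if (length(cand) == 0) stop("histogram has fewer than 2 occupied bins")
  crit <- vapply(cand, function(t) {
    pb <- p[1:t]; pf <- p[(t + 1):n]
    if (abs(rho - 1) < 1e-12) {
      hb <- -sum(ifelse(pb > 0, pb / P1[t] * log(pb / P1[t]), 0))
      hf <- -sum(ifelse(pf > 0, pf / (1 - P1[t]) * log(pf / (1 - P1[t])), 0))
    } else {
      hb <- log(sum((pb / P1[t])^rho)) / (1 - rho)
      hf <- log(sum((pf / (1 - P1[t]))^rho)) / (1 - rho)
    }
    hb + hf
  }, numeric(1))
  cand[which.max(crit)] - 1L              # 0-based bin index
}

#' Renyi-entropy automatic threshold
#'
#' Selects the threshold bin by maximizing the summed Renyi entropies of the
#' background and foreground partitions at orders 1/2, 1 (Shannon limit) and
#' 2, then combining the three sorted candidates with the published
#' weighting rule (weights depend on whether the sorted candidates fall
#' within 5 gray levels of each other). Deterministic: ties within each
#' order go to the lowest bin. Semantics are "foreground strictly above
#' threshold", so the returned intensity sits on the upper edge of the
#' selected bin.
#'
#' @param hist an `intensity_histogram` from [build_histogram()], or a bare
#'   vector of bin counts (bins then map to gray levels `0..n-1`).
#' @return Threshold intensity (numeric scalar) with attribute `bin`
#'   (0-based selected gray level).
#' @export
renyi_entropy_threshold <- function(hist) {
  if (!inherits(hist, "intensity_histogram")) {
    counts <- as.numeric(hist)
    centers <- seq_along(counts) - 1
  } else {
    counts <- as.numeric(hist$counts)
    centers <- hist$bin_centers
  }
  total <- sum(counts)
  if (total <= 0) stop("empty histogram")
  if (sum(counts > 0) < 2)
    stop("histogram has fewer than 2 occupied bins; no separation possible")
  p <- counts / total
  P1 <- cumsum(p)

  t1 <- renyi_best_bin(p, P1, 0.5)
  t2 <- renyi_best_bin(p, P1, 1)
  t3 <- renyi_best_bin(p, P1, 2)
  ts <- sort(c(t1, t2, t3))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]

  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
  } else {
    if (abs(t2 - t3) <= 5) { b <- c(3, 1, 0) } else { b <- c(1, 2, 1) }
  }
  omega <- P1[t3 + 1] - P1[t1 + 1]
  t_star <- t1 * (P1[t1 + 1] + 0.25 * omega * b[1]) +
    0.25 * t2 * omega * b[2] +
    t3 * (1 - P1[t3 + 1] + 0.25 * omega * b[3])
  bin <- as.integer(floor(t_star))

  # threshold on the intensity scale: upper edge of the selected bin, so
  # that `value > threshold` matches `gray level > bin`
  step <- if (length(centers) > 1) centers[2] - centers[1] else 1
  structure(centers[bin + 1] + step / 2, bin = bin)
}

#' Binarize one channel of a stack at a global threshold
#'
#' Foreground is strictly greater than the threshold, in every z-slice.
#'
#' @param stack an [image_stack()].
#' @param channel channel index.
#' @param threshold intensity threshold.
#' @param time time-point index.
#' @return A `segmentation_mask`: logical `foreground` `(z, y, x)`,
#'   `threshold_used`, `source_channel`.
#' @export
apply_threshold <- function(stack, channel, threshold, time = 1L) {
  v <- channel_volume(stack, channel, time)
  structure(list(foreground = v > threshold,
                 threshold_used = as.numeric(threshold),
                 source_channel = as.integer(channel)),
            class = "segmentation_mask")
}

#' Segment the ciliary marker channel
#'
#' Computes the Renyi-entropy threshold on the maximum-intensity projection
#' of the marker channel and applies it to the full 3D volume. The
#' segmented marker mask then serves as the cilia mask for all channels.
#'
#' @param stack an [image_stack()].
#' @param channel channel to segment (default: marker channel).
#' @param manual_threshold optional user-supplied intensity threshold that
#'   bypasses the automatic method.
#' @param time time-point index.
#' @return A `segmentation_mask`.
#' @export
segment_marker <- function(stack, channel = stack$marker_channel,
                           manual_threshold = NULL, time = 1L) {
  if (!is.null(manual_threshold))
    return(apply_threshold(stack, channel, manual_threshold, time))
  proj <- max_project(stack, channel, time)
  thr <- renyi_entropy_threshold(build_histogram(proj))
  apply_threshold(stack, channel, thr, time)
}
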