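# Ratiometric biosensor trace math: background subtraction, FRET
# bleed-through/cross-excitation correction, ratio construction, baseline
# normalization and plate-reader calcium normalization.

#' Fluorescence time-series trace
#'
#' Per-ROI, per-channel fluorescence over frames, with the stimulus frame
#' and a baseline window that ends before it. The default baseline window
#' is every frame strictly before the stimulus frame (e.g. stimulation
#' after 120 s at 5-s frames gives a 24-frame baseline).
#'
#' @param values numeric vector (one channel) or matrix (frames x
#'   channels); column names label the channels.
#' @param frame_times frame acquisition times in seconds, strictly
#'   increasing.
#' @param stimulus_frame index of the first post-stimulus frame.
#' @param baseline_window integer vector of baseline frame indices; must
#'   be nonempty and precede `stimulus_frame`.
#' @return An object of class `ts_trace`.
#' @export
ts_trace <- function(values, frame_times = seq_len(NROW(values)),
                     stimulus_frame = NROW(values) + 1L,
                     baseline_window = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1,
                                          dimnames = list(NULL, "ch1"))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("ch", seq_len(ncol(values)))
  n <- nrow(values)
  stopifnot(length(frame_times) == n, all(diff(frame_times) > 0))
  stimulus_frame <- as.integer(stimulus_frame)
  if (is.null(baseline_window))
    baseline_window <- seq_len(min(stimulus_frame - 1L, n))
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0 || any(baseline_window >= stimulus_frame))
    stop("baseline_window must be nonempty and precede stimulus_frame")
  structure(list(values = values, frame_times = as.numeric(frame_times),
                 stimulus_frame = stimulus_frame,
                 baseline_window = baseline_window),
            class = "ts_trace")
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("ts_trace: %d frame(s), %d channel(s), stimulus at frame %d\n",
              nrow(x$values), ncol(x$values), x$stimulus_frame))
  invisible(x)
}

#' Subtract a per-channel background constant
#'
#' @param trace a [ts_trace()].
#' @param background numeric scalar or one value per channel.
#' @return The background-subtracted trace.
#' @export
background_subtract <- function(trace, background) {
  stopifnot(inherits(trace, "ts_trace"))
  if (length(background) == 1)
    background <- rep(background, ncol(trace$values))
  stopifnot(length(background) == ncol(trace$values))
  trace$values <- sweep(trace$values, 2, background, `-`)
  trace
}

#' FRET bleed-through / cross-excitation parameters
#'
#' Defaults are the constants determined for the cerulean/citrine FRET pair
#' of the mlCNBD-FRET cAMP sensor: 0.75 per unit of donor (cerulean)
#' bleed-through and 0.02 per unit of acceptor (citrine) cross-excitation.
#'
#' @param alpha donor bleed-through fraction (default 0.75).
#' @param beta acceptor cross-excitation fraction (default 0.02).
#' @return An object of class `bleedthrough_params`.
#' @export
bleedthrough_params <- function(alpha = 0.75, beta = 0.02) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "bleedthrough_params")
}

#' Correct a raw FRET signal for bleed-through and cross-excitation
#'
#' `FRET_corrected = FRET - alpha * cerulean - beta * citrine`.
#'
#' @param fret_raw raw acceptor-channel signal under donor excitation.
#' @param cerulean donor-channel signal.
#' @param citrine acceptor-channel signal under acceptor excitation.
#' @param params a [bleedthrough_params()].
#' @return Corrected FRET signal (same length as the inputs).
#' @examples
#' fret_bleedthrough_correct(100, 40, 50) # 100 - 0.75*40 - 0.02*50 = 69
#' @export
fret_bleedthrough_correct <- function(fret_raw, cerulean, citrine,
                                      params = bleedthrough_params()) {
  fret_raw - params$alpha * cerulean - params$beta * citrine
}

#' Estimate bleed-through constants from single-fluorophore controls
#'
#' Least-squares slope through the origin of the contaminated channel
#' against the source channel, an approximation of correlation-based
#' bleed-through calibration.
#'
#' @param contaminated signal in the channel receiving the leakage.
#' @param source signal of the fluorophore causing it.
#' @return Estimated bleed-through fraction (scalar).
#' @export
estimate_bleedthrough <- function(contaminated, source) {
  stopifnot(length(contaminated) == length(source), any(source != 0))
  sum(contaminated * source) / sum(source^2)
}

#' Framewise ratio of two channel traces
#'
#' Frames with a zero denominator are flagged invalid (`NA`) rather than
#' returned as infinities; invalid frames are excluded from downstream
#' summaries, never interpolated.
#'
#' @param numerator,denominator numeric vectors of equal length.
#' @return Numeric vector with attribute `invalid_frames` (indices with
#'   zero denominator).
#' @export
ratio_trace <- function(numerator, denominator) {
  stopifnot(length(numerator) == length(denominator))
  bad <- which(denominator == 0)
  out <- numerator / denominator
  out[bad] <- NA_real_
  attr(out, "invalid_frames") <- bad
  out
}

#' Normalize a trace to its mean pre-stimulus baseline
#'
#' Every frame is divided by the mean over the baseline window (per
#' channel for multi-channel traces), so the normalized baseline mean is 1.
#' Idempotent.
#'
#' @param x a [ts_trace()] or a numeric vector.
#' @param baseline_window frame indices of the baseline (required for
#'   numeric input; taken from the trace otherwise).
#' @return Same type as the input, normalized.
#' @export
baseline_normalize <- function(x, baseline_window = NULL) {
  UseMethod("baseline_normalize")
}

#' @export
baseline_normalize.ts_trace <- function(x, baseline_window = NULL) {
  if (is.null(baseline_window)) baseline_window <- x$baseline_window
  for (ch in seq_len(ncol(x$values))) {
    m <- mean(x$values[baseline_window, ch], na.rm = TRUE)
    if (!is.finite(m) || m == 0)
      stop("zero or undefined baseline mean in channel ", ch)
    x$values[, ch] <- x$values[, ch] / m
  }
  x
}

#' @export
baseline_normalize.numeric <- function(x, baseline_window = NULL) {
  stopifnot(!is.null(baseline_window))
  m <- mean(x[baseline_window], na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("zero or undefined baseline mean")
  x / m
}

#' Plate-reader calcium response normalization
#'
#' `(F - F_baseline) / (F_ionomycin - F_baseline)`, optionally divided by
#' the fraction of reporter-positive cells. The ionomycin saturation level
#' anchors the response at 1 for fully responding, fully positive wells.
#'
#' @param F raw fluorescence (scalar or vector).
#' @param F_baseline pre-stimulus fluorescence.
#' @param F_ionomycin post-ionomycin saturation fluorescence; must differ
#'   from `F_baseline`.
#' @param positive_fraction fraction of reporter-positive cells in (0, 1];
#'   omit (`NULL`) to skip the per-fraction division.
#' @return Normalized response.
#' @export
plate_reader_normalize <- function(F, F_baseline, F_ionomycin,
                                   positive_fraction = NULL) {
  if (F_ionomycin == F_baseline)
    stop("F_ionomycin must differ from F_baseline")
  out <- (F - F_baseline) / (F_ionomycin - F_baseline)
  if (!is.null(positive_fraction)) {
    stopifnot(positive_fraction > 0, positive_fraction <= 1)
    out <- out / positive_fraction
  }
  out
}
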