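# Savitzky-Golay smoothing/differentiation and 5%-of-peak event detection.

#' Savitzky-Golay filter configuration
#'
#' Defaults match the analysis scheme: a 41-point fourth-order filter (20
#' neighbouring samples on each side) at 100 Hz.
#'
#' @param window_length odd window length in samples (default 41).
#' @param poly_order polynomial order, strictly less than the window length
#'   (default 4).
#' @param sample_interval sampling interval in seconds (default 0.01).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(window_length = 41L, poly_order = 4L,
                          sample_interval = 0.01) {
  window_length <- as.integer(window_length)
  poly_order <- as.integer(poly_order)
  if (window_length %% 2L != 1L) stop("window_length must be odd")
  if (poly_order >= window_length)
    stop("poly_order must be smaller than window_length")
  if (sample_interval <= 0) stop("sample_interval must be positive")
  structure(list(window_length = window_length, poly_order = poly_order,
                 sample_interval = sample_interval), class = "filter_config")
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: at each sample the output is the
#' centre value of the polynomial fit over the surrounding window. The first
#' and last half-windows use polynomial fits of the same order on the
#' available asymmetric window, so no samples are discarded at trial
#' boundaries.
#'
#' @param x numeric series, length at least `cfg$window_length`.
#' @param cfg a [filter_config()].
#' @return smoothed series of the same length.
#' @export
savgol_smooth <- function(x, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (length(x) < cfg$window_length)
    stop(sprintf("series length %d is shorter than the filter window (%d)",
                 length(x), cfg$window_length))
  as.numeric(signal::sgolayfilt(x, p = cfg$poly_order, n = cfg$window_length))
}

#' Savitzky-Golay velocity and speed
#'
#' Differentiates each coordinate of a position series using the first-order
#' derivative of the local polynomial fit, scaled by the sampling interval;
#' speed is the Euclidean norm of the velocity vector.
#'
#' @param position `n x 3` matrix (or numeric vector for 1D) of positions in
#'   meters.
#' @param cfg a [filter_config()].
#' @return list with `velocity` (`n x 3` matrix, m/s) and `speed`
#'   (length-`n` vector, m/s).
#' @export
savgol_velocity <- function(position, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (is.null(dim(position))) position <- matrix(position, ncol = 1)
  position <- as.matrix(position)
  if (nrow(position) < cfg$window_length)
    stop(sprintf("series length %d is shorter than the filter window (%d)",
                 nrow(position), cfg$window_length))
  v <- apply(position, 2, function(x)
    signal::sgolayfilt(x, p = cfg$poly_order, n = cfg$window_length,
                       m = 1, ts = cfg$sample_interval))
  v <- matrix(v, nrow = nrow(position))
  list(velocity = v, speed = sqrt(rowSums(v^2)))
}

#' Movement-onset detection (backward 5%-of-peak search)
#'
#' Searches backward from the speed peak and returns the last sample at or
#' before the peak whose speed is at or below `fraction` of the peak speed.
#' If no sample qualifies the series start is returned with a warning and the
#' attribute `"found" = FALSE`.
#'
#' @param speed numeric speed series (m/s).
#' @param peak_index index of the speed peak.
#' @param fraction threshold fraction of peak speed (default 0.05).
#' @return onset sample index (attribute `"found"` indicates whether the
#'   threshold was actually crossed).
#' @export
detect_onset <- function(speed, peak_index, fraction = 0.05) {
  check_event_args(speed, peak_index, fraction)
  thr <- fraction * speed[peak_index]
  below <- which(speed[seq_len(peak_index)] <= thr)
  if (length(below) == 0L) {
    warning("speed never drops to the onset threshold before the peak; returning series start")
    return(structure(1L, found = FALSE))
  }
  structure(max(below), found = TRUE)
}

#' Target-contact detection (forward 5%-of-peak search)
#'
#' Mirror of [detect_onset()]: searches forward from the peak and returns the
#' first sample at or after the peak with speed at or below the threshold;
#' the series end (with a warning) if none.
#'
#' @inheritParams detect_onset
#' @return contact sample index (attribute `"found"` as in [detect_onset()]).
#' @export
detect_contact <- function(speed, peak_index, fraction = 0.05) {
  check_event_args(speed, peak_index, fraction)
  thr <- fraction * speed[peak_index]
  ahead <- which(speed[peak_index:length(speed)] <= thr)
  if (length(ahead) == 0L) {
    warning("speed never drops to the contact threshold after the peak; returning series end")
    return(structure(length(speed), found = FALSE))
  }
  structure(peak_index + min(ahead) - 1L, found = TRUE)
}

check_event_args <- function(speed, peak_index, fraction) {
  if (length(speed) == 0L) stop("empty speed series")
  if (anyNA(speed)) stop("speed series contains missing values")
  if (peak_index < 1L || peak_index > length(speed))
    stop("peak_index outside the series")
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  invisible(TRUE)
}

#' Index of the speed peak within a trial window
#'
#' Global maximum of the speed series restricted to `window` (a length-2
#' index range); ties resolve to the earliest sample.
#'
#' @param speed numeric speed series.
#' @param window `c(first, last)` sample indices; default the whole series.
#' @return peak sample index (in the full-series indexing).
#' @export
find_speed_peak <- function(speed, window = c(1L, length(speed))) {
  a <- max(1L, as.integer(window[1])); b <- min(length(speed), as.integer(window[2]))
  if (a > b) stop("empty peak-search window")
  a + which.max(speed[a:b]) - 1L
}

#' Reach event
#'
#' Bundles the onset, peak-speed and contact sample indices of one
#' interception trial.
#'
#' @param onset_index,peak_index,contact_index sample indices with
#'   `onset <= peak <= contact`.
#' @param peak_speed peak speed in m/s (positive).
#' @return list of class `reach_event`.
#' @export
reach_event <- function(onset_index, peak_index, contact_index, peak_speed) {
  if (!(onset_index <= peak_index && peak_index <= contact_index))
    stop("event indices must satisfy onset <= peak <= contact")
  if (!is.finite(peak_speed) || peak_speed <= 0)
    stop("peak_speed must be positive")
  structure(list(onset_index = as.integer(onset_index),
                 peak_index = as.integer(peak_index),
                 contact_index = as.integer(contact_index),
                 peak_speed = peak_speed),
            class = "reach_event")
}

#' Movement time of a reach event
#'
#' Onset-to-contact duration in milliseconds.
#'
#' @param ev a [reach_event()].
#' @param sample_rate sampling rate in Hz.
#' @return movement time in ms.
#' @export
movement_time <- function(ev, sample_rate) {
  stopifnot(inherits(ev, "reach_event"), sample_rate > 0)
  (ev$contact_index - ev$onset_index) / sample_rate * 1000
}
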