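#' Intracranial EEG recording container
#'
#' A minimal channels-by-samples container with sampling rate and a per
#' (channel, 2-s window) artifact mask. The mask starts all-clear; windows are
#' flagged by [reject_artifacts()] and honoured by the network estimators.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel identifiers (default ch1..chN).
#' @param window_s artifact-mask window length in seconds.
#' @return a `recording` object.
#' @export
recording <- function(signal, fs, channel_names = NULL, window_s = 2) {
  signal <- as.matrix(signal)
  if (nrow(signal) == 0L || ncol(signal) == 0L) stop("empty recording")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(signal)))
  stopifnot(length(channel_names) == nrow(signal))
  n_win <- floor(ncol(signal) / (window_s * fs))
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 window_s = window_s,
                 artifact_mask = matrix(FALSE, nrow(signal), n_win)),
            class = "recording")
}

# index vectors for complete non-overlapping windows of window_s seconds
window_indices <- function(n_samples, fs, window_s) {
  len <- round(window_s * fs)
  n_win <- floor(n_samples / len)
  lapply(seq_len(n_win), function(w) ((w - 1L) * len + 1L):(w * len))
}

#' Mask artifact-heavy and flat 2-s windows
#'
#' A (channel, window) cell is masked when the window's peak absolute
#' amplitude exceeds `amp_thresh` (gross artifact) or its peak-to-peak range
#' falls below `flat_thresh` (disconnected/flat channel). Masked windows are
#' excluded from all downstream network and spike averages.
#'
#' @param rec a [recording()].
#' @param amp_thresh amplitude threshold in microvolts.
#' @param flat_thresh minimum peak-to-peak range in microvolts.
#' @return the recording with an updated `artifact_mask`.
#' @export
reject_artifacts <- function(rec, amp_thresh = 1000, flat_thresh = 0.1) {
  stopifnot(inherits(rec, "recording"))
  if (amp_thresh <= 0 || flat_thresh <= 0) stop("thresholds must be positive")
  win <- window_indices(ncol(rec$signal), rec$fs, rec$window_s)
  if (length(win) == 0L) stop("recording shorter than one window")
  mask <- matrix(FALSE, nrow(rec$signal), length(win))
  for (w in seq_along(win)) {
    seg <- rec$signal[, win[[w]], drop = FALSE]
    peak <- apply(abs(seg), 1, max)
    rng <- apply(seg, 1, max) - apply(seg, 1, min)
    mask[, w] <- peak > amp_thresh | rng < flat_thresh
  }
  rec$artifact_mask <- mask
  rec
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels from
#' each channel. The output's channel-mean is identically zero.
#'
#' @param rec a [recording()] with at least two channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$signal) < 2L) stop("common average reference needs >= 2 channels")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

#' Notch and bandpass filtering
#'
#' Zero-phase (forward-backward) IIR filtering: a Butterworth band-stop
#' around `notch_hz` (line noise) followed by a Butterworth bandpass over
#' `band`. Filtering is zero-phase via `signal::filtfilt`, so the effective
#' magnitude response is the squared design response; the default 2nd-order
#' sections give > 20 dB attenuation at the notch and < 3 dB loss in the
#' passband interior.
#'
#' @param rec a [recording()].
#' @param notch_hz line-noise frequency to remove (Hz); NULL skips the notch.
#' @param band length-2 passband in Hz, inside (0, fs/2).
#' @param notch_halfwidth_hz half-width of the stop band (Hz).
#' @param order Butterworth design order for each stage.
#' @return the filtered recording.
#' @export
filter_signals <- function(rec, notch_hz = 60, band = c(1, 70),
                           notch_halfwidth_hz = 2, order = 2) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    stop("band must lie inside (0, fs/2)")
  }
  bp <- signal::butter(order, band / nyq, type = "pass")
  filters <- list(bp)
  if (!is.null(notch_hz)) {
    if (notch_hz + notch_halfwidth_hz >= nyq) stop("notch above Nyquist")
    bs <- signal::butter(order, c(notch_hz - notch_halfwidth_hz,
                                  notch_hz + notch_halfwidth_hz) / nyq,
                         type = "stop")
    filters <- list(bs, bp)
  }
  x <- rec$signal
  for (f in filters) {
    for (ch in seq_len(nrow(x))) {
      x[ch, ] <- signal::filtfilt(f, x[ch, ])
    }
  }
  rec$signal <- x
  rec
}
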