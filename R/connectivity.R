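#' Time-averaged Pearson correlation network
#'
#' Divides the recording into non-overlapping `window_s`-second windows,
#' computes the signed Pearson correlation between every channel pair within
#' each non-masked window, averages windows within each `segment_s`-second
#' segment, and finally averages segment networks into a single time-averaged
#' network. Edges with zero usable windows are undefined (NA) and never
#' imputed.
#'
#' @param rec a [recording()], ideally after artifact masking.
#' @param window_s correlation window length in seconds.
#' @param segment_s segment length in seconds over which windows are first
#'   averaged.
#' @return a `functional_network`: list with symmetric `adjacency` (NA
#'   diagonal), `metric`, `band`, `n_windows_used` (per-edge counts) and
#'   `channel_names`.
#' @export
pearson_network <- function(rec, window_s = 2, segment_s = 60) {
  stopifnot(inherits(rec, "recording"))
  n <- nrow(rec$signal)
  if (n < 2L) stop("need >= 2 channels")
  win <- window_indices(ncol(rec$signal), rec$fs, window_s)
  if (length(win) == 0L) stop("recording shorter than one window")
  mask <- rec$artifact_mask
  if (ncol(mask) < length(win)) {
    # mask built on a different windowing; treat absent columns as clean
    mask <- cbind(mask, matrix(FALSE, n, length(win) - ncol(mask)))
  }
  win_per_seg <- max(1L, round(segment_s / window_s))
  seg_id <- ceiling(seq_along(win) / win_per_seg)
  n_seg <- max(seg_id)
  seg_sum <- array(0, c(n, n, n_seg))
  seg_cnt <- array(0L, c(n, n, n_seg))
  total_cnt <- matrix(0L, n, n)
  for (w in seq_along(win)) {
    ok <- !mask[, w]
    if (sum(ok) < 2L) next
    cw <- suppressWarnings(stats::cor(t(rec$signal[ok, win[[w]], drop = FALSE])))
    full <- matrix(NA_real_, n, n)
    full[ok, ok] <- cw
    def <- !is.na(full)
    s <- seg_id[w]
    tmp <- seg_sum[, , s]
    tmp[def] <- tmp[def] + full[def]
    seg_sum[, , s] <- tmp
    seg_cnt[, , s] <- seg_cnt[, , s] + def
    total_cnt <- total_cnt + def
  }
  seg_mean <- seg_sum / seg_cnt          # NaN where a segment has no windows
  seg_mean[seg_cnt == 0L] <- NA_real_
  adjacency <- apply(seg_mean, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  diag(adjacency) <- NA_real_
  diag(total_cnt) <- 0L
  if (all(is.na(adjacency[upper.tri(adjacency)]))) {
    warning("all windows masked: network undefined")
  }
  dimnames(adjacency) <- list(rec$channel_names, rec$channel_names)
  structure(list(adjacency = adjacency, metric = "pearson", band = "broadband",
                 n_windows_used = total_cnt, channel_names = rec$channel_names),
            class = "functional_network")
}

#' Canonical EEG frequency bands
#'
#' @return named list of (low, high) band edges in Hz: delta 0.5-4, theta
#'   4-8, alpha 8-12, beta 12-30, gamma 30-80.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 80))
}

#' Band-averaged magnitude-squared coherence networks
#'
#' Welch-style magnitude-squared coherence per channel pair (hamming window
#' of `window_s` seconds, `overlap_s` seconds overlap), averaged over the
#' frequency bins falling inside each requested band. Segments overlapping
#' any masked artifact window (on any channel) are dropped. Band edges above
#' Nyquist are truncated; a band entirely above Nyquist is an error.
#'
#' @param rec a [recording()].
#' @param bands named list of c(low, high) Hz pairs; see [eeg_bands()].
#' @param window_s,overlap_s Welch segmentation parameters in seconds.
#' @return named list of `functional_network` objects, one per band, with
#'   `metric = "coherence"` and values in \[0, 1\].
#' @export
coherence_network <- function(rec, bands = eeg_bands(), window_s = 2,
                              overlap_s = 1) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  nyq <- fs / 2
  for (b in bands) {
    if (b[1] >= nyq) stop("band entirely above Nyquist")
  }
  n <- nrow(rec$signal)
  nfft <- round(window_s * fs)
  step <- round((window_s - overlap_s) * fs)
  starts <- seq(1L, ncol(rec$signal) - nfft + 1L, by = step)
  if (length(starts) < 2L) stop("recording too short for Welch estimation")
  # drop Welch segments overlapping a masked artifact window on any channel
  if (any(rec$artifact_mask)) {
    wlen <- round(rec$window_s * fs)
    bad_win <- which(apply(rec$artifact_mask, 2, any))
    bad_samples <- unlist(lapply(bad_win, function(w) ((w - 1L) * wlen + 1L):(w * wlen)))
    keep <- vapply(starts, function(s) !any(seq(s, s + nfft - 1L) %in% bad_samples),
                   logical(1))
    starts <- starts[keep]
    if (length(starts) < 2L) stop("too few artifact-free segments")
  }
  taper <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  nf <- nfft %/% 2 + 1L
  n_seg <- length(starts)
  X <- array(0 + 0i, c(nf, n, n_seg))
  for (s in seq_len(n_seg)) {
    idx <- starts[s]:(starts[s] + nfft - 1L)
    seg <- t(rec$signal[, idx, drop = FALSE]) * taper
    seg <- sweep(seg, 2, colMeans(seg))   # detrend (constant) per segment
    F <- stats::mvfft(seg)
    X[, , s] <- F[seq_len(nf), , drop = FALSE]
  }
  Pxx <- apply(Mod(X)^2, c(1, 2), sum)
  msc <- array(NA_real_, c(n, n, nf))
  for (f in seq_len(nf)) {
    A <- t(X[f, , , drop = TRUE])            # segments x channels
    if (n_seg == 1L) A <- matrix(A, nrow = 1L)
    Sxy <- t(Conj(A)) %*% A                  # cross-spectral sums
    denom <- outer(Pxx[f, ], Pxx[f, ])
    msc[, , f] <- Mod(Sxy)^2 / denom
  }
  freqs <- (seq_len(nf) - 1L) * fs / nfft
  out <- list()
  for (bn in names(bands)) {
    b <- bands[[bn]]
    sel <- which(freqs >= b[1] & freqs <= min(b[2], nyq))
    if (length(sel) == 0L) stop("band ", bn, " contains no frequency bins")
    adjacency <- apply(msc[, , sel, drop = FALSE], c(1, 2), mean)
    diag(adjacency) <- NA_real_
    dimnames(adjacency) <- list(rec$channel_names, rec$channel_names)
    out[[bn]] <- structure(
      list(adjacency = adjacency, metric = "coherence", band = bn,
           n_windows_used = matrix(n_seg, n, n), channel_names = rec$channel_names),
      class = "functional_network")
  }
  out
}

#' Per-electrode average connectivity
#'
#' Mean of each node's edges to all other nodes, excluding the diagonal and
#' undefined edges.
#'
#' @param net a `functional_network`.
#' @return named numeric vector, one value per electrode (NA when a node has
#'   no defined edges).
#' @export
node_average_connectivity <- function(net) {
  adj <- net$adjacency
  if (nrow(adj) < 2L) stop("need >= 2 electrodes")
  vals <- rowMeans(adj, na.rm = TRUE)
  vals[rowSums(!is.na(adj)) == 0L] <- NA_real_
  vals
}

#' Within-patient z-normalization
#'
#' Standardizes a per-electrode measure across the patient's electrodes:
#' subtract the mean, divide by the standard deviation. The population SD
#' convention (divide by n) is used; NA entries are ignored in the moments
#' and preserved in the output.
#'
#' @param values numeric vector of per-electrode values.
#' @return standardized vector (mean 0, population SD 1 over non-NA entries).
#' @export
znormalize_within_patient <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("need >= 2 values to normalize")
  s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))
  if (s == 0) stop("zero variance: normalization undefined")
  (values - mean(v)) / s
}
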