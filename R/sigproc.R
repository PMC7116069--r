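# Pre-processing and syllable segmentation: band-pass filtering,
# moving-average detrend, short-time Fourier transform, normalised power
# contour, and iterative peak-tracking detection of syllable intervals.

#' Default segmentation parameters
#'
#' Band 30-160 kHz (upper cutoff configurable up to just below Nyquist, so
#' the 180 kHz robustness check is legal at 375 kHz), 7th-order Butterworth,
#' Hamming window 1024 with 75% overlap, 30 ms median filter on the power
#' contour, detection threshold `mean + 0.01 * SD` of the filtered contour,
#' seed peaks additionally required to reach `seed_rel` times the contour
#' mean (power concentration well above the epoch average; `seed_rel = 0`
#' disables this guard and recovers the bare threshold rule), 5 ms minimum
#' syllable duration, 5 s epochs.
#'
#' @return Named list of parameters.
#' @export
segmentation_params <- function() {
  list(band_low_hz = 30000, band_high_hz = 160000, filter_order = 7,
       detrend_pts = 10, window = 1024, overlap = 0.75,
       medfilt_ms = 30, thresh_k = 0.01, seed_rel = 2, min_dur_ms = 5,
       epoch_s = 5, merge_gap_frames = 2)
}

#' Butterworth band-pass filter (zero-phase)
#'
#' Removes energy below `low_hz` and above `high_hz` with an order-`order`
#' Butterworth band-pass applied forward and backward (zero phase, so
#' syllable onsets are not shifted).
#'
#' @param x Signal vector.
#' @param fs Sampling rate (Hz).
#' @param low_hz,high_hz Band edges (defaults 30 and 160 kHz).
#' @param order Filter order (default 7).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, low_hz = 30000, high_hz = 160000, order = 7) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("need 0 < low_hz < high_hz < fs/2 (Nyquist = ", fs / 2, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Moving-average high-pass detrend
#'
#' Subtracts a centred `window_pts`-point moving average from the signal,
#' removing slow trends while preserving ultrasonic content. Even window
#' lengths are centred asymmetrically (one extra point on the left);
#' edges use reflection padding.
#'
#' @param x Signal vector.
#' @param window_pts Moving-average length in samples (default 10).
#' @return Detrended signal, same length.
#' @export
highpass_detrend <- function(x, window_pts = 10) {
  stopifnot(window_pts >= 1)
  w <- as.integer(window_pts)
  if (w == 1) return(x - x)
  n <- length(x)
  L <- ceiling((w - 1) / 2); R <- floor((w - 1) / 2)
  xp <- c(rev(x[seq_len(L)]), x, rev(x[seq(n - R + 1, n)]))
  cs <- cumsum(c(0, xp))
  ma <- (cs[(w + 1):(n + w)] - cs[1:n]) / w
  x - ma
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Hamming window of length `window` with fractional `overlap`; hop is
#' `window * (1 - overlap)` samples (256 at the defaults). Frames cover
#' `floor((n - window)/hop) + 1` positions.
#'
#' @param x Signal vector (one epoch).
#' @param fs Sampling rate (Hz).
#' @param window Window length in samples (default 1024).
#' @param overlap Fractional overlap (default 0.75).
#' @return Object of class `usv_spectrogram`: list with `mag` (freq bins x
#'   frames), `freq_hz`, `time_s` (frame centres), `window`, `hop`, `fs`,
#'   `n_samples`.
#' @export
stft_spectrogram <- function(x, fs, window = 1024, overlap = 0.75) {
  hop <- round(window * (1 - overlap))
  n <- length(x)
  if (n < window) {
    warning("signal shorter than one window: empty spectrogram")
    nf <- 0L
    mag <- matrix(numeric(0), nrow = window / 2 + 1, ncol = 0)
  } else {
    nf <- floor((n - window) / hop) + 1L
    ham <- 0.54 - 0.46 * cos(2 * pi * (0:(window - 1)) / (window - 1))
    idx <- outer(seq_len(window), (seq_len(nf) - 1L) * hop, "+")
    frames <- matrix(x[idx], nrow = window) * ham
    mag <- abs(mvfft(frames))[seq_len(window / 2 + 1), , drop = FALSE]
  }
  out <- list(mag = mag,
              freq_hz = (seq_len(window / 2 + 1) - 1) * fs / window,
              time_s = ((seq_len(nf) - 1) * hop + window / 2) / fs,
              window = window, hop = hop, fs = fs, n_samples = n)
  class(out) <- "usv_spectrogram"
  out
}

# round, then force odd upward (a median filter needs an odd window):
# 43.9 frames -> 44 -> 45 at the default hop
round_odd <- function(x) {
  k <- max(1L, round(x))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

#' Normalised power contour of a spectrogram
#'
#' Per-frame power divided by the total power over all frames (the raw
#' contour sums to 1), median filtered over a window spanning `medfilt_ms`
#' milliseconds (rounded to the nearest odd number of frames; 45 frames at
#' the default 256-sample hop and 375 kHz). The detection threshold
#' `mean + thresh_k * SD` of the filtered contour is recorded.
#'
#' @param spec A `usv_spectrogram`.
#' @param medfilt_ms Median filter span in ms (default 30).
#' @param thresh_k Threshold multiplier on the contour SD (default 0.01).
#' @return Object of class `usv_contour`: list with `raw`, `filtered`,
#'   `threshold`, `medfilt_frames`, `hop_s`, `time_s`.
#' @export
power_contour <- function(spec, medfilt_ms = 30, thresh_k = 0.01) {
  stopifnot(inherits(spec, "usv_spectrogram"), ncol(spec$mag) > 0)
  pwr <- colSums(spec$mag^2)
  raw <- pwr / sum(pwr)
  hop_s <- spec$hop / spec$fs
  k <- round_odd(medfilt_ms / 1000 / hop_s)
  filtered <- if (length(raw) >= k) as.numeric(runmed(raw, k)) else raw
  out <- list(raw = raw, filtered = filtered,
              threshold = mean(filtered) + thresh_k * sd(filtered),
              medfilt_frames = k, hop_s = hop_s, time_s = spec$time_s,
              window = spec$window, fs = spec$fs)
  class(out) <- "usv_contour"
  out
}

# strict local maxima; plateaus contribute their leftmost sample
local_peaks <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_pk <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  starts[mid][is_pk]
}

#' Detect syllables by iterative peak tracking on the power contour
#'
#' Local maxima of the filtered contour above the threshold are visited in
#' decreasing height order; each is expanded left and right until the
#' contour drops below the threshold (or reaches frames already claimed by
#' an earlier, taller peak), and the expanded span becomes one syllable.
#' Contiguous detections are merged and detections shorter than
#' `min_dur_ms` discarded. Because the threshold sits barely above the
#' contour mean, seed peaks must additionally reach `seed_rel` times the
#' mean: a true syllable concentrates power far above the epoch average,
#' while an epoch of pure background never does (this is what returns zero
#' syllables on silent input).
#'
#' @param contour A `usv_contour`.
#' @param min_dur_ms Minimum syllable duration (default 5 ms).
#' @param seed_rel Seed-peak floor as a multiple of the contour mean
#'   (default 2; 0 disables).
#' @return Data frame with `onset_s`, `offset_s`, `frame_on`, `frame_off`
#'   (frames, 1-based), time-ordered and disjoint. Zero rows when nothing
#'   exceeds the threshold.
#' @export
detect_syllables <- function(contour, min_dur_ms = 5, seed_rel = 2) {
  stopifnot(inherits(contour, "usv_contour"))
  v <- contour$filtered
  thr <- contour$threshold
  pk <- local_peaks(v)
  pk <- pk[v[pk] >= thr & v[pk] >= seed_rel * mean(v)]
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      frame_on = integer(0), frame_off = integer(0))
  if (!length(pk)) return(empty)
  pk <- pk[order(v[pk], decreasing = TRUE)]
  claimed <- logical(length(v))
  spans <- list()
  for (p in pk) {
    if (claimed[p]) next
    l <- p; r <- p
    while (l > 1 && !claimed[l - 1] && v[l - 1] >= thr) l <- l - 1
    while (r < length(v) && !claimed[r + 1] && v[r + 1] >= thr) r <- r + 1
    claimed[l:r] <- TRUE
    spans[[length(spans) + 1L]] <- c(l, r)
  }
  sp <- do.call(rbind, spans)
  sp <- sp[order(sp[, 1]), , drop = FALSE]
  # merge contiguous spans (separated by less than one sub-threshold frame)
  merged <- list(sp[1, ])
  if (nrow(sp) > 1) for (i in 2:nrow(sp)) {
    last <- merged[[length(merged)]]
    if (sp[i, 1] <= last[2] + 1L) merged[[length(merged)]] <- c(last[1], max(last[2], sp[i, 2]))
    else merged[[length(merged) + 1L]] <- sp[i, ]
  }
  sp <- do.call(rbind, merged)
  hop_s <- contour$hop_s
  onset <- (sp[, 1] - 1) * hop_s
  offset <- (sp[, 2] - 1) * hop_s + contour$window / contour$fs
  keep <- (offset - onset) * 1000 >= min_dur_ms
  if (!any(keep)) return(empty)
  data.frame(onset_s = onset[keep], offset_s = offset[keep],
             frame_on = sp[keep, 1], frame_off = sp[keep, 2])
}

#' Segment a recording into syllable intervals
#'
#' Full pre-processing and segmentation chain: band-pass filter (30-160 kHz
#' Butterworth order 7, zero phase), 10-point moving-average detrend, 5 s
#' epochs, per-epoch STFT (Hamming 1024, 75% overlap), normalised power
#' contour (30 ms median filter), and iterative peak-tracking detection
#' with threshold `mean + 0.01 * SD`. Detections touching an epoch
#' boundary are merged across it, so bouts and syllables are not split by
#' the 5 s processing unit.
#'
#' @param x Signal vector, or a path to a WAV file.
#' @param fs Sampling rate (ignored when `x` is a path). A warning is
#'   issued when it is not the 375 kHz the defaults are tuned for.
#' @param params Parameter list, see [segmentation_params()].
#' @param prefiltered Set TRUE when `x` has already been band-passed and
#'   detrended (skips the filtering stage).
#' @return Data frame of syllable intervals with `onset_s`, `offset_s`,
#'   `epoch` (1-based index of the epoch the onset falls in).
#' @export
segment_recording <- function(x, fs = NULL, params = segmentation_params(),
                              prefiltered = FALSE) {
  if (is.character(x)) {
    wav <- read_wav(x)
    x <- wav$samples; fs <- wav$fs
  }
  if (is.null(fs)) stop("fs required when x is a sample vector")
  if (fs != 375000) warning("sampling rate ", fs, " Hz differs from the ",
                            "375 kHz the default parameters are tuned for")
  p <- utils::modifyList(segmentation_params(), params)
  if (!prefiltered) {
    x <- bandpass(x, fs, p$band_low_hz, p$band_high_hz, p$filter_order)
    x <- highpass_detrend(x, p$detrend_pts)
  }
  epoch_len <- round(p$epoch_s * fs)
  n <- length(x)
  starts <- seq(1L, n, by = epoch_len)
  out <- list()
  for (ei in seq_along(starts)) {
    seg <- x[starts[ei]:min(n, starts[ei] + epoch_len - 1L)]
    if (length(seg) < p$window) next
    spec <- stft_spectrogram(seg, fs, p$window, p$overlap)
    ct <- power_contour(spec, p$medfilt_ms, p$thresh_k)
    det <- detect_syllables(ct, p$min_dur_ms, p$seed_rel)
    if (nrow(det) == 0) next
    det$onset_s <- det$onset_s + (starts[ei] - 1L) / fs
    det$offset_s <- det$offset_s + (starts[ei] - 1L) / fs
    det$epoch <- ei
    out[[length(out) + 1L]] <- det
  }
  if (!length(out))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      epoch = integer(0)))
  det <- do.call(rbind, out)
  det <- det[order(det$onset_s), c("onset_s", "offset_s", "epoch")]
  rownames(det) <- NULL
  # merge detections split by an epoch boundary
  gap_s <- p$merge_gap_frames * round(p$window * (1 - p$overlap)) / fs +
    p$window / fs
  if (nrow(det) > 1) {
    keep <- rep(TRUE, nrow(det))
    for (i in 2:nrow(det)) {
      j <- max(which(keep[1:(i - 1)]))
      if (det$epoch[i] != det$epoch[j] &&
          det$onset_s[i] - det$offset_s[j] < gap_s) {
        det$offset_s[j] <- det$offset_s[i]
        keep[i] <- FALSE
      }
    }
    det <- det[keep, ]
    rownames(det) <- NULL
  }
  det
}
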