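# Pitch-jump syllable classification: broadband (N) check on spectral
# spread, harmonic (H) check on integer-multiple spectral peaks, then
# S/J/O by the number of pitch discontinuities found with a Sobel
# gradient operator on the spectrogram patch.

#' Default classification parameters
#'
#' `broadband_khz`: robust spectral-spread threshold above which a frame
#' counts as broadband. `harmonic_frames`: minimum number of frames with
#' harmonically related peaks for an H call. `harmonic_peak_rel`: a
#' spectral peak is significant when it exceeds this multiple of the
#' frame's median magnitude. `harmonic_ratio_tol`: relative tolerance for
#' integer frequency ratios. `jump_thresh`: pitch-gradient peaks must
#' exceed `median + jump_thresh * 1.4826 MAD` of the gradient contour (a
#' robust z-score, so the peaks themselves do not inflate the spread).
#' `jump_rel_floor`: and also exceed this multiple of the contour median
#' (absolute guard against near-constant contours). `edge_frames`: frames
#' dropped at each patch edge before jump counting (onset/offset
#' transients look like discontinuities). `jump_merge_frames`: significant
#' contour peaks closer than this count as one discontinuity (a jump
#' smears over about window/hop frames in the STFT).
#'
#' @return Named list of parameters.
#' @export
classification_params <- function() {
  list(broadband_khz = 15, harmonic_frames = 3, harmonic_peak_rel = 6,
       harmonic_ratio_tol = 0.05, jump_thresh = 3, jump_rel_floor = 1.5,
       edge_frames = 2, jump_merge_frames = 4, frame_power_rel = 0.1)
}

# per-frame robust spectral spread in kHz: 1.4826 * power-weighted median
# absolute deviation of frequency about the power-weighted median.
# A robust spread separates genuinely broadband energy from a stack of
# discrete harmonic lines, which a plain weighted SD does not.
frame_spread_khz <- function(mag, freq_khz) {
  w <- mag^2
  apply(w, 2, function(col) {
    tot <- sum(col)
    if (tot <= 0) return(0)
    cw <- cumsum(col) / tot
    med <- freq_khz[which(cw >= 0.5)[1]]
    dev <- abs(freq_khz - med)
    o <- order(dev)
    cd <- cumsum(col[o]) / tot
    1.4826 * dev[o][which(cd >= 0.5)[1]]
  })
}

#' Is a spectrogram patch broadband (N-type)?
#'
#' Uses the variance of the frequency content per frame: the median (over
#' frames carrying appreciable power) of the robust spectral spread must
#' exceed `broadband_khz`. Band-limited noise over 30-160 kHz has spread
#' of tens of kHz; tones, sweeps and harmonic stacks stay in the low
#' single digits.
#'
#' @param patch Magnitude matrix (freq bins x frames) of one syllable.
#' @param freq_khz Frequencies of the rows, in kHz.
#' @param params See [classification_params()].
#' @return Logical.
#' @export
is_noisy <- function(patch, freq_khz, params = classification_params()) {
  p <- utils::modifyList(classification_params(), params)
  stopifnot(nrow(patch) == length(freq_khz), ncol(patch) >= 1)
  pw <- colSums(patch^2)
  keep <- pw >= p$frame_power_rel * max(pw)
  spread <- frame_spread_khz(patch[, keep, drop = FALSE], freq_khz)
  median(spread) > p$broadband_khz
}

# significant spectral peaks of one frame: local maxima above
# rel * median magnitude, returned as frequencies (kHz)
frame_peaks_khz <- function(col, freq_khz, rel) {
  thr <- rel * median(col)
  pk <- local_peaks(col)
  pk <- pk[col[pk] > thr]
  freq_khz[pk]
}

#' Does a patch contain harmonic structure (H-type)?
#'
#' True when at least `harmonic_frames` frames each contain two or more
#' significant spectral peaks whose frequencies are integer multiples of
#' the lowest peak within `harmonic_ratio_tol` relative tolerance.
#'
#' @inheritParams is_noisy
#' @return Logical.
#' @export
is_harmonic <- function(patch, freq_khz, params = classification_params()) {
  p <- utils::modifyList(classification_params(), params)
  n_harm <- 0L
  for (j in seq_len(ncol(patch))) {
    pks <- frame_peaks_khz(patch[, j], freq_khz, p$harmonic_peak_rel)
    if (length(pks) < 2) next
    f0 <- min(pks)
    ratios <- pks[pks > f0] / f0
    mult <- round(ratios)
    if (any(mult >= 2 & abs(ratios - mult) <= p$harmonic_ratio_tol * mult)) {
      n_harm <- n_harm + 1L
      if (n_harm >= p$harmonic_frames) return(TRUE)
    }
  }
  FALSE
}

# 3x3 Sobel gradients of a matrix (rows = freq, cols = time), zero-padded
sobel_gradients <- function(m) {
  pad <- function(a) {
    a <- rbind(a[1, , drop = FALSE], a, a[nrow(a), , drop = FALSE])
    cbind(a[, 1, drop = FALSE], a, a[, ncol(a), drop = FALSE])
  }
  mp <- pad(m)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) mp[(1 + dr):(nr + dr), (1 + dc):(nc + dc), drop = FALSE]
  # time gradient: [-1 0 1; -2 0 2; -1 0 1] across columns
  gt <- (sh(1, 2) - sh(1, 0)) * 2 + (sh(0, 2) - sh(0, 0)) + (sh(2, 2) - sh(2, 0))
  # frequency gradient: transpose kernel, across rows
  gf <- (sh(2, 1) - sh(0, 1)) * 2 + (sh(2, 0) - sh(0, 0)) + (sh(2, 2) - sh(0, 2))
  list(gt = gt, gf = gf)
}

#' Count pitch jumps in a spectrogram patch
#'
#' Applies 3x3 Sobel operators along the time and frequency axes, forms
#' the joint gradient magnitude, and collapses it to a per-frame
#' pitch-gradient contour by summing over frequency. An instantaneous
#' pitch discontinuity redistributes energy across many frequency bins in
#' one frame and so produces a dominant column in this contour; smooth
#' sweeps spread their gradient evenly. Significant contour peaks (robust
#' z-score above `jump_thresh`, value above `jump_rel_floor` times the
#' contour median, outside the `edge_frames` transient margin) are merged
#' when closer than `jump_merge_frames` and counted as jumps: 0 jumps is
#' an S syllable, 1 a J, 2 or more an O.
#'
#' @inheritParams is_noisy
#' @return Integer jump count (0 for patches narrower than 3 frames).
#' @export
count_pitch_jumps <- function(patch, freq_khz = NULL,
                              params = classification_params()) {
  p <- utils::modifyList(classification_params(), params)
  if (ncol(patch) < 3) return(0L)
  g <- sobel_gradients(patch)
  gm <- sqrt(g$gt^2 + g$gf^2)
  contour <- colSums(gm)
  lo <- p$edge_frames + 1L
  hi <- length(contour) - p$edge_frames
  if (hi - lo < 2) return(0L)
  inner <- contour[lo:hi]
  med <- median(inner)
  thr <- med + p$jump_thresh * 1.4826 * stats::mad(inner, constant = 1)
  floor_thr <- p$jump_rel_floor * med
  pk <- local_peaks(inner)
  pk <- pk[inner[pk] > thr & inner[pk] > floor_thr]
  if (!length(pk)) return(0L)
  # adjacent significant peaks from the same smeared discontinuity
  sum(diff(c(-Inf, pk)) > p$jump_merge_frames)
}

#' Classify one spectrogram patch into the five syllable types
#'
#' Precedence follows the pitch-jump scheme: broadband energy first (N),
#' then harmonic structure (H), then the number of pitch jumps (0 = S,
#' 1 = J, >= 2 = O).
#'
#' @inheritParams is_noisy
#' @return List with `label`, `n_jumps`, `peak_khz` (frequency of the
#'   patch's global magnitude maximum).
#' @export
classify_patch <- function(patch, freq_khz, params = classification_params()) {
  p <- utils::modifyList(classification_params(), params)
  peak_khz <- freq_khz[(which.max(patch) - 1) %% nrow(patch) + 1]
  if (is_noisy(patch, freq_khz, p))
    return(list(label = "N", n_jumps = NA_integer_, peak_khz = peak_khz))
  if (is_harmonic(patch, freq_khz, p))
    return(list(label = "H", n_jumps = NA_integer_, peak_khz = peak_khz))
  nj <- count_pitch_jumps(patch, freq_khz, p)
  list(label = if (nj == 0) "S" else if (nj == 1) "J" else "O",
       n_jumps = nj, peak_khz = peak_khz)
}

#' Segment and classify a whole recording
#'
#' Runs [segment_recording()] and classifies every detected syllable from
#' its spectrogram patch (band-limited to the analysis band). This is the
#' audio half of the pipeline; its output feeds the bout and sequence
#' analyses.
#'
#' @param x Signal vector or WAV path.
#' @param fs Sampling rate (ignored for a path).
#' @param seg_params Segmentation parameters ([segmentation_params()]).
#' @param cls_params Classification parameters ([classification_params()]).
#' @return Data frame with `onset_s`, `offset_s`, `epoch`, `label`,
#'   `n_jumps`, `peak_khz`, `duration_ms`.
#' @export
classify_recording <- function(x, fs = NULL,
                               seg_params = segmentation_params(),
                               cls_params = classification_params()) {
  if (is.character(x)) {
    wav <- read_wav(x)
    x <- wav$samples; fs <- wav$fs
  }
  sp <- utils::modifyList(segmentation_params(), seg_params)
  xf <- highpass_detrend(bandpass(x, fs, sp$band_low_hz, sp$band_high_hz,
                                  sp$filter_order), sp$detrend_pts)
  det <- segment_recording(xf, fs, sp, prefiltered = TRUE)
  det$label <- character(nrow(det))
  det$n_jumps <- NA_integer_
  det$peak_khz <- NA_real_
  if (nrow(det)) {
    for (i in seq_len(nrow(det))) {
      i0 <- max(1L, round(det$onset_s[i] * fs))
      i1 <- min(length(xf), round(det$offset_s[i] * fs))
      spec <- stft_spectrogram(xf[i0:i1], fs, sp$window, sp$overlap)
      if (ncol(spec$mag) == 0) { det$label[i] <- "S"; next }
      band <- spec$freq_hz >= sp$band_low_hz & spec$freq_hz <= sp$band_high_hz
      cl <- classify_patch(spec$mag[band, , drop = FALSE],
                           spec$freq_hz[band] / 1000, cls_params)
      det$label[i] <- cl$label
      det$n_jumps[i] <- cl$n_jumps
      det$peak_khz[i] <- cl$peak_khz
    }
  }
  det$duration_ms <- (det$offset_s - det$onset_s) * 1000
  det
}
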