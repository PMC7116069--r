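# Pre-processing and segmentation: filter responses, detrend arithmetic,
# STFT geometry, power contour, peak-tracking detection.

fs <- 375000

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  t <- seq(0, 0.05, by = 1 / fs)
  edge <- round(0.01 * fs)
  core <- function(v) v[edge:(length(v) - edge)]
  rms <- function(v) sqrt(mean(v^2))
  expect_equal(bandpass(numeric(1000), fs), numeric(1000))
  x70 <- sin(2 * pi * 70e3 * t)
  expect_lt(abs(20 * log10(rms(core(bandpass(x70, fs))) / rms(core(x70)))), 1)
  x10 <- sin(2 * pi * 10e3 * t)
  expect_lt(20 * log10(rms(core(bandpass(x10, fs))) / rms(core(x10))), -40)
  expect_error(bandpass(x70, fs, high_hz = 190e3), "Nyquist")
  # 180 kHz upper cutoff is legal at 375 kHz sampling
  expect_silent(bandpass(x70, fs, high_hz = 180e3))
})

test_that("moving-average detrend: constants vanish, hand example, tone preserved", {
  expect_equal(highpass_detrend(rep(3.7, 50)), rep(0, 50))
  # window 2, reflect padding: ma = (x[i-1]+x[i])/2 with x[0] := x[1]
  expect_equal(highpass_detrend(c(0, 0, 10, 0, 0), 2), c(0, 0, 5, -5, 0))
  # slow ramp suppressed; 100 kHz tone passes with the gain predicted by
  # the moving-average frequency response |1 - H_ma(f) e^{-i pi f / fs}|
  # (half-sample delay from the asymmetric centring of an even window)
  t <- (0:49999) / fs
  ramp <- seq(0, 1, length.out = length(t))
  tone <- sin(2 * pi * 100e3 * t)
  out <- highpass_detrend(ramp + tone, 10)
  w <- 10; f <- 100e3
  H <- sin(pi * f * w / fs) / (w * sin(pi * f / fs))
  gain <- Mod(1 - H * exp(-1i * pi * f / fs))
  expect_equal(sqrt(mean(out[100:49900]^2)), gain * sqrt(0.5), tolerance = 0.01)
  # ramp residual is far below the tone
  expect_lt(sqrt(mean(highpass_detrend(ramp, 10)[100:49900]^2)), 0.001)
})

test_that("STFT geometry: frame count, bin mapping, zero input", {
  x <- sin(2 * pi * 93750 * (0:(5 * fs - 1)) / fs)
  sp <- stft_spectrogram(x, fs)
  expect_equal(ncol(sp$mag), 7321)   # floor((1875000-1024)/256)+1
  expect_equal(sp$hop, 256)
  # 93.75 kHz = bin 256 exactly (93.75/375*1024)
  expect_true(all(apply(sp$mag, 2, which.max) == 257))
  z <- stft_spectrogram(numeric(10000), fs)
  expect_true(all(z$mag == 0))
  expect_warning(stft_spectrogram(numeric(100), fs), "shorter")
})

test_that("power contour: normalisation, median window arithmetic, impulse robustness", {
  x <- rnorm(fs)  # 1 s
  sp <- stft_spectrogram(x, fs)
  ct <- power_contour(sp)
  expect_equal(sum(ct$raw), 1, tolerance = 1e-9)
  expect_equal(ct$medfilt_frames, 45)  # round(30 ms / 0.6827 ms) = 44 -> odd 45
  # equal-power frames: every value 1/F
  spe <- sp; spe$mag <- matrix(1, 4, 100); class(spe) <- "usv_spectrogram"
  cte <- power_contour(spe)
  expect_equal(cte$raw, rep(1 / 100, 100))
  expect_equal(cte$filtered, rep(1 / 100, 100))
  # single-frame impulse removed by the 45-frame median filter
  spi <- sp; spi$mag <- matrix(1e-3, 4, 200); spi$mag[, 100] <- 10
  class(spi) <- "usv_spectrogram"
  cti <- power_contour(spi)
  expect_lt(max(cti$filtered) / median(cti$filtered), 1.01)
})

test_that("detection: hand-traced bumps, sub-threshold silence, ordering", {
  mk_contour <- function(v, hop_s = 256 / fs) {
    structure(list(raw = v / sum(v), filtered = v / sum(v),
                   threshold = mean(v / sum(v)) + 0.01 * sd(v / sum(v)),
                   medfilt_frames = 1, hop_s = hop_s,
                   time_s = seq_along(v) * hop_s, window = 1024, fs = fs),
              class = "usv_contour")
  }
  # two rectangular bumps separated by a sub-threshold gap
  v <- c(rep(1, 50), rep(100, 30), rep(1, 40), rep(100, 25), rep(1, 50))
  det <- detect_syllables(mk_contour(v))
  expect_equal(nrow(det), 2)
  expect_equal(det$frame_on, c(51, 121), tolerance = 1)
  expect_equal(det$frame_off, c(80, 145), tolerance = 1)
  expect_true(all(det$offset_s > det$onset_s))
  expect_true(all(diff(det$onset_s) > 0))
  # flat contour: nothing above threshold
  expect_equal(nrow(detect_syllables(mk_contour(rep(1, 200)))), 0)
  # detected spans sit above threshold at their seeds
  ct <- mk_contour(v)
  expect_true(all(ct$filtered[det$frame_on] >= ct$threshold))
})

test_that("segmentation is deterministic and robust to the upper-cutoff change", {
  spec <- synth_spec(n_pups_per_group = 1, groups = "G", bouts_per_pup = 4,
                     seed = 31)
  ac <- generate_audio_cohort(spec)
  x <- ac$audio[[1]]
  d1 <- segment_recording(x, fs)
  d2 <- segment_recording(x, fs)
  expect_identical(d1, d2)
  # no synthetic energy above 160 kHz: widening the band must not change detection
  d3 <- segment_recording(x, fs, list(band_high_hz = 180000))
  expect_equal(nrow(d1), nrow(d3))
  expect_equal(d1$onset_s, d3$onset_s, tolerance = 1e-3)
})

test_that("synthetic syllables are recovered with small onset/offset error", {
  spec <- synth_spec(n_pups_per_group = 1, groups = "G", bouts_per_pup = 8,
                     seed = 32)
  ac <- generate_audio_cohort(spec)
  gt <- ac$ground_truth
  det <- segment_recording(ac$audio[[1]], fs)
  expect_gte(nrow(det), 0.95 * nrow(gt))
  m <- vapply(seq_len(nrow(gt)), function(i) {
    j <- which.min(abs(det$onset_s - gt$onset_s[i])); j
  }, integer(1))
  on_err <- abs(det$onset_s[m] - gt$onset_s) * 1000
  off_err <- abs(det$offset_s[m] - gt$offset_s) * 1000
  expect_gte(mean(on_err < 5 & off_err < 5), 0.95)
})
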