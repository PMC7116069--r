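# Synthetic cohort generator: symbolic sequences, audio rendering,
# analytic Markov-chain MI oracle.

test_that("degenerate self-transition chain yields homogeneous bouts", {
  ident <- diag(5); dimnames(ident) <- list(SYLLABLE_TYPES, SYLLABLE_TYPES)
  spec <- synth_spec(n_pups_per_group = 2, groups = "G", markov = ident,
                     bout_length_dist = c(0, 0, 1), bouts_per_pup = 10,
                     seed = 5)
  gt <- generate_symbolic_cohort(spec)
  for (key in unique(paste(gt$pup_id, gt$bout_id))) {
    b <- gt$type[paste(gt$pup_id, gt$bout_id) == key]
    expect_length(b, 3)
    expect_length(unique(b), 1)
  }
})

test_that("empirical transitions of a uniform chain converge to 1/5 per cell", {
  spec <- synth_spec(n_pups_per_group = 4, groups = "G", markov = markov_uniform(),
                     initial_dist = rep(0.2, 5),
                     bout_length_dist = c(0, 0, 0, 0, 0, 0, 0, 1),
                     bouts_per_pup = 700, seed = 6)
  gt <- generate_symbolic_cohort(spec)
  expect_gt(nrow(gt), 10000)
  bouts <- bout_sequences(split_bouts(gt, 350))
  pr <- pairs_successive(lapply(bouts, picseq:::type_codes))
  emp <- table(factor(pr[, 1], levels = 1:5), factor(pr[, 2], levels = 1:5))
  trans <- emp / rowSums(emp)     # conditional transition matrix
  expect_lt(max(abs(trans - 0.2)), 0.02)
})

test_that("same spec and seed reproduce identical symbolic and audio output", {
  spec <- synth_spec(n_pups_per_group = 1, groups = "G", bouts_per_pup = 5, seed = 7)
  a <- generate_symbolic_cohort(spec)
  b <- generate_symbolic_cohort(spec)
  expect_identical(a, b)
  wa <- generate_audio_cohort(spec)
  wb <- generate_audio_cohort(spec)
  expect_identical(wa$audio, wb$audio)
})

test_that("invalid stochastic matrices are rejected naming the offending row", {
  bad <- markov_uniform(); bad[3, 1] <- 0.5
  expect_error(synth_spec(markov = bad, seed = 1), "row\\(s\\) 3")
  expect_error(analytic_mi(bad), "row\\(s\\) 3")
})

test_that("ground-truth timing is ordered and bout-separable", {
  spec <- synth_spec(n_pups_per_group = 2, groups = c("A", "B"),
                     bouts_per_pup = 15, seed = 8)
  gt <- generate_symbolic_cohort(spec)
  for (pup in unique(gt$pup_id)) {
    d <- gt[gt$pup_id == pup, ]
    expect_true(all(diff(d$onset_s) > 0))
    expect_true(all(d$offset_s > d$onset_s))
    sil <- (d$onset_s[-1] - d$offset_s[-nrow(d)]) * 1000
    ends <- d$bout_id[-1] != d$bout_id[-nrow(d)]
    expect_true(all(sil[ends] >= 400))  # bout-ending silences exceed 400 ms
  }
  # recovered bout partition matches ground truth at the 350 ms threshold
  bt <- split_bouts(gt, 350)
  expect_identical(unname(tapply(bt$bout, bt$pup_id, function(x) x)),
                   unname(tapply(gt$bout_id, gt$pup_id, function(x) x)))
})

test_that("analytic_mi worked examples and limits", {
  expect_equal(analytic_mi(markov_uniform(), rep(0.2, 5), 1), 0, tolerance = 1e-12)
  P <- diag(5)[, c(2, 3, 4, 5, 1)]
  expect_equal(analytic_mi(P, rep(0.2, 5), 1), log2(5), tolerance = 1e-12)
  M2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  # direct 4-term summation oracle
  joint <- 0.5 * M2
  expect_equal(analytic_mi(M2, c(0.5, 0.5), 1), brute_mi(joint), tolerance = 1e-12)
  expect_equal(analytic_mi(M2, c(0.5, 0.5), 1), 0.531, tolerance = 1e-3)
  # MI decays monotonically to 0 with lag for a mixing chain
  M <- markov_structured()
  mis <- vapply(1:10, function(k) analytic_mi(M, k = k), numeric(1))
  expect_true(all(diff(mis) < 1e-12))
  expect_lt(analytic_mi(M, k = 30), 1e-3)
})

test_that("stationary distribution is a fixed point of the chain", {
  for (M in list(markov_structured(), markov_mixture(0.4))) {
    pi0 <- stationary_distribution(M)
    expect_equal(as.numeric(pi0 %*% M), as.numeric(pi0), tolerance = 1e-12)
    expect_equal(sum(pi0), 1, tolerance = 1e-12)
  }
})

test_that("rendered harmonic stack shows partials at integer multiples in every frame", {
  set.seed(9)
  ac <- default_acoustic()
  ac$H$f0_khz <- c(50, 50); ac$H$sweep_khz <- 0
  w <- render_syllable("H", 0.05, acoustic = ac)
  sp <- stft_spectrogram(w, 375000)
  mid <- sp$mag[, 10:(ncol(sp$mag) - 10)]
  f_khz <- sp$freq_hz / 1000
  bin_khz <- f_khz[2] - f_khz[1]
  hits <- vapply(seq_len(ncol(mid)), function(j) {
    pks <- f_khz[picseq:::local_peaks(mid[, j])]
    pks <- pks[mid[picseq:::local_peaks(mid[, j]), j] > 6 * median(mid[, j])]
    all(vapply(c(50, 100, 150), function(f) any(abs(pks - f) <= bin_khz), logical(1)))
  }, logical(1))
  expect_true(all(hits))
})

test_that("audio cohort annotations line up with requested syllables", {
  spec <- synth_spec(n_pups_per_group = 1, groups = "G",
                     bout_length_dist = c(0, 0, 1), bouts_per_pup = 1,
                     snr_db = Inf, seed = 10)
  ac <- generate_audio_cohort(spec)
  gt <- ac$ground_truth
  expect_equal(nrow(gt), 3)
  x <- ac$audio[[1]]
  fs <- ac$fs
  for (i in seq_len(nrow(gt))) {
    seg <- x[round(gt$onset_s[i] * fs + 1):round(gt$offset_s[i] * fs)]
    expect_gt(sqrt(mean(seg^2)), 0.05)      # energy where annotated
  }
  # silence elsewhere (noiseless render)
  gap <- x[round((gt$offset_s[1] + 0.02) * fs):round((gt$onset_s[2] - 0.02) * fs)]
  expect_lt(max(abs(gap)), 1e-6)
})

test_that("silence-only audio yields zero detected syllables", {
  x <- rnorm(375000) * 0.001
  det <- suppressWarnings(segment_recording(x, 375000))
  expect_equal(nrow(det), 0)
})

test_that("WAV round trip preserves samples to 16-bit precision", {
  tmp <- tempfile(fileext = ".wav")
  x <- sin(2 * pi * 70000 * (0:9999) / 375000) * 0.8
  write_wav(x, 375000, tmp)
  back <- read_wav(tmp)
  expect_equal(back$fs, 375000)
  expect_lt(max(abs(back$samples - x)), 1 / 32767)
  unlink(tmp)
})
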