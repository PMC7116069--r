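# Independent oracles and small fixture builders used across the suite.

# brute-force MI by explicit double loop (independent of the package path)
brute_mi <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    if (joint[i, j] > 0) s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  }
  s
}

# sample n successive pairs from a stationary Markov chain over 1..k states
chain_pairs <- function(M, n, init = NULL) {
  k <- nrow(M)
  if (is.null(init)) init <- stationary_distribution(M)
  x <- integer(n + 1)
  x[1] <- sample.int(k, 1, prob = init)
  for (t in seq_len(n)) x[t + 1] <- sample.int(k, 1, prob = M[x[t], ])
  cbind(x[seq_len(n)], x[seq_len(n) + 1])
}

# embed a 2-state chain into the 5-type alphabet (states 1,2 -> types 2,4)
embed_2state <- function(pairs2) {
  map <- c(2L, 4L)
  cbind(map[pairs2[, 1]], map[pairs2[, 2]])
}

# interpolate uniform -> permutation to hit a target analytic MI (bits)
chain_with_mi <- function(target_bits, k = 5) {
  P <- diag(k)[, c(2:k, 1)]          # cyclic permutation
  U <- matrix(1 / k, k, k)
  if (target_bits <= 0) return(U)
  f <- function(a) analytic_mi(a * P + (1 - a) * U, rep(1 / k, k), 1) - target_bits
  a <- uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  a * P + (1 - a) * U
}

# render a syllable and return its band-limited spectrogram patch
wave_to_patch <- function(w, fs = 375000) {
  xf <- picseq:::highpass_detrend(bandpass(w, fs), 10)
  sp <- stft_spectrogram(xf, fs)
  band <- sp$freq_hz >= 30000 & sp$freq_hz <= 160000
  list(patch = sp$mag[band, , drop = FALSE], freq_khz = sp$freq_hz[band] / 1000)
}

# symbolic cohort as a bare list of bouts drawn from one chain
draw_bouts <- function(M, n_bouts, len_probs = c(0, 0.1, 0.2, 0.3, 0.2, 0.1, 0.05, 0.05),
                       init = NULL) {
  k <- nrow(M)
  if (is.null(init)) init <- stationary_distribution(M)
  lens <- sample.int(length(len_probs), n_bouts, replace = TRUE, prob = len_probs)
  lapply(lens, function(L) {
    s <- integer(L)
    s[1] <- sample.int(k, 1, prob = init)
    if (L > 1) for (t in 2:L) s[t] <- sample.int(k, 1, prob = M[s[t - 1], ])
    s
  })
}

# tiny symbolic syllable table with prescribed silences (ms) between rows
syl_table <- function(silences_ms, durations_ms = 50, pup = "p1", group = "G",
                      types = NULL) {
  n <- length(silences_ms) + 1
  durations_ms <- rep_len(durations_ms, n)
  onset <- numeric(n); offset <- numeric(n)
  t <- 0.1
  for (i in seq_len(n)) {
    onset[i] <- t
    offset[i] <- t + durations_ms[i] / 1000
    t <- offset[i] + if (i <= length(silences_ms)) silences_ms[i] / 1000 else 0
  }
  data.frame(pup_id = pup, group = group,
             onset_s = onset, offset_s = offset,
             type = if (is.null(types)) rep_len(SYLLABLE_TYPES, n) else types,
             stringsAsFactors = FALSE)
}
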