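# Synthetic cohort generator: symbolic syllable sequences with known
# first-order Markov structure, ground-truth bout/timing annotations, and
# rendered ultrasonic audio for the five syllable archetypes.

#' Built-in Markov transition matrices for synthetic cohorts
#'
#' `markov_structured()` emulates a wild-type-like ordered repertoire:
#' tonal (S) and multi-jump (O) syllables are followed almost surely by a
#' harmonic (H), and harmonics flow back to S, so bouts carry a strong
#' S-H alternation whose phase is set by the bout-start syllable. This is
#' ordering structure in the strict sense: permuting the syllables within
#' a bout destroys it, so positional mutual information stands well above
#' the within-bout scrambled null several positions into the bout. (A
#' repertoire of sticky same-type runs would not have this property: run
#' composition survives scrambling, and the null absorbs it.)
#' `markov_uniform()` has no sequential structure (all transitions 1/5),
#' emulating the random sequences of the deletion-male phenotype.
#' `markov_mixture(w)` interpolates between them; `w = 0.7` gives
#' dependence detectable about one position less deep than the fully
#' structured chain, emulating the deletion-female phenotype.
#'
#' @param w Mixture weight on the structured matrix (1 = fully structured).
#' @return 5x5 row-stochastic matrix with N,S,J,H,O dimnames.
#' @export
markov_structured <- function() {
  m <- rbind(
    N = c(0.15, 0.60, 0.05, 0.15, 0.05),
    S = c(0.01, 0.04, 0.02, 0.92, 0.01),
    J = c(0.05, 0.50, 0.10, 0.25, 0.10),
    H = c(0.02, 0.80, 0.02, 0.13, 0.03),
    O = c(0.02, 0.08, 0.02, 0.85, 0.03))
  colnames(m) <- SYLLABLE_TYPES
  m
}

#' @rdname markov_structured
#' @export
markov_uniform <- function() {
  m <- matrix(0.2, 5, 5, dimnames = list(SYLLABLE_TYPES, SYLLABLE_TYPES))
  m
}

#' @rdname markov_structured
#' @export
markov_mixture <- function(w) {
  stopifnot(w >= 0, w <= 1)
  w * markov_structured() + (1 - w) * markov_uniform()
}

default_initial_dist <- c(N = 0.20, S = 0.45, J = 0.05, H = 0.10, O = 0.20)

# Per-type acoustic archetypes. Frequencies in kHz, durations in ms.
# Harmonic partial amplitudes decay so the fundamental dominates the
# power-weighted spectrum; all energy stays well inside the 30-160 kHz
# analysis band (3rd partial of a 52 kHz fundamental is 156 kHz).
default_acoustic <- function() {
  list(
    N = list(dur_ms = 45, dur_sd_ms = 5, band_khz = c(40, 100)),
    S = list(dur_ms = 55, dur_sd_ms = 5, f_start_khz = c(60, 75), sweep_khz = 15),
    J = list(dur_ms = 55, dur_sd_ms = 5, f_start_khz = c(60, 75), sweep_khz = 10,
             jump_khz = 15),
    H = list(dur_ms = 55, dur_sd_ms = 5, f0_khz = c(45, 50), sweep_khz = 4,
             n_harmonics = 3, partial_decay = 0.55),
    O = list(dur_ms = 60, dur_sd_ms = 5, f_start_khz = c(60, 70), sweep_khz = 8,
             jump_khz = 15)
  )
}

#' Specification of a synthetic pup-isolation-call cohort
#'
#' Bundles every parameter of the generator: group sizes and labels,
#' per-group first-order Markov transition matrices over the five syllable
#' types, initial distribution, bout-length distribution, inter-syllable
#' silence (ISS) distributions, acoustic archetypes, and the seed.
#'
#' Default timing parameters emulate the regime reported for postnatal-day-5
#' pups, where the pooled inter-syllable silence distribution (within- and
#' between-bout silences together) has mean about 200 ms and SD about
#' 150 ms: within-bout silences are gamma (mean 110 ms, SD 60 ms) truncated
#' below the 350 ms bout threshold so ground-truth bouts are recoverable by
#' construction, and bout-ending silences are at least 400 ms. Syllable
#' durations are 40-60 ms and peak frequencies 60-90 kHz. Bout lengths
#' default to a geometric-like distribution over 1..12 (mean ~4, matching
#' roughly 5 syllables per bout at the reported per-pup totals), so bouts
#' of length 8 and more occur.
#'
#' @param n_pups_per_group Pups per group (recycled over groups).
#' @param groups Group labels.
#' @param markov A single 5x5 row-stochastic matrix, or a named list with
#'   one matrix per group. Defaults: structured for WT-like groups, uniform
#'   for "delM", a 0.7 mixture for "delF".
#' @param initial_dist Length-5 distribution of bout-starting types.
#' @param bout_length_dist Probabilities over bout lengths `1..length()`.
#' @param bouts_per_pup Mean number of bouts per pup (Poisson-ish draw).
#' @param iss_within List `mean_ms`, `sd_ms`, `max_ms` of the (truncated)
#'   within-bout gamma ISS.
#' @param iss_between List `min_ms`, `mean_ms`, `sd_ms`: bout-ending
#'   silences are `min_ms` plus a gamma with the given mean/SD.
#' @param acoustic Per-type archetype parameters (see source for fields).
#' @param pups_per_litter Litter size used to assign litter ids.
#' @param fs Sampling rate (Hz) for rendered audio.
#' @param snr_db Signal-to-noise ratio of rendered audio (dB); `Inf` for
#'   noiseless.
#' @param seed Integer seed (mandatory: the cohort is fully reproducible).
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_pups_per_group = 12,
                       groups = c("WTM", "WTF", "delM", "delF"),
                       markov = NULL,
                       initial_dist = default_initial_dist,
                       bout_length_dist = NULL,
                       bouts_per_pup = 80,
                       iss_within = list(mean_ms = 110, sd_ms = 60, max_ms = 340),
                       iss_between = list(min_ms = 400, mean_ms = 50, sd_ms = 80),
                       acoustic = default_acoustic(),
                       pups_per_litter = 3,
                       fs = 375000,
                       snr_db = 30,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for a synth_spec")
  if (is.null(markov)) {
    markov <- lapply(groups, function(g)
      switch(g, delM = markov_uniform(), delF = markov_mixture(0.7),
             markov_structured()))
    names(markov) <- groups
  }
  if (is.matrix(markov)) {
    markov <- stats::setNames(rep(list(markov), length(groups)), groups)
  }
  if (is.null(bout_length_dist)) {
    # geometric-ish tail over 1..12, mean length ~4
    bout_length_dist <- 0.85 ^ (0:11)
    bout_length_dist <- bout_length_dist / sum(bout_length_dist)
  }
  spec <- list(n_pups_per_group = rep_len(n_pups_per_group, length(groups)),
               groups = groups, markov = markov,
               initial_dist = initial_dist,
               bout_length_dist = bout_length_dist,
               bouts_per_pup = bouts_per_pup,
               iss_within = iss_within, iss_between = iss_between,
               acoustic = acoustic, pups_per_litter = pups_per_litter,
               fs = fs, snr_db = snr_db, seed = as.integer(seed))
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

#' @rdname synth_spec
#' @param spec A `synth_spec`.
#' @export
validate_synth_spec <- function(spec) {
  for (g in names(spec$markov)) {
    m <- spec$markov[[g]]
    if (!is.matrix(m) || any(dim(m) != 5) || any(m < 0))
      stop("markov[", g, "] must be a non-negative 5x5 matrix")
    bad <- which(abs(rowSums(m) - 1) > 1e-12)
    if (length(bad))
      stop("markov[", g, "] rows not stochastic: row(s) ",
           paste(bad, collapse = ", "), " do not sum to 1")
  }
  if (abs(sum(spec$initial_dist) - 1) > 1e-12 || any(spec$initial_dist < 0))
    stop("initial_dist must be a probability vector summing to 1")
  if (abs(sum(spec$bout_length_dist) - 1) > 1e-9)
    stop("bout_length_dist must sum to 1")
  with(spec$iss_within, stopifnot(mean_ms > 0, sd_ms > 0))
  stopifnot(spec$iss_between$min_ms > 0)
  for (ty in names(spec$acoustic)) {
    a <- spec$acoustic[[ty]]
    fr <- unlist(a[grepl("khz", names(a))], use.names = FALSE)
    if (any(fr <= 0)) stop("acoustic[", ty, "]: frequencies must be positive")
  }
  invisible(spec)
}

# gamma parameterised by mean/sd, optionally truncated from above
# (resampling; truncation mass is small for the default parameters)
rgamma_ms <- function(n, mean_ms, sd_ms, max_ms = Inf) {
  shape <- (mean_ms / sd_ms)^2
  x <- rgamma(n, shape = shape, rate = shape / mean_ms)
  while (any(bad <- x > max_ms))
    x[bad] <- rgamma(sum(bad), shape = shape, rate = shape / mean_ms)
  x
}

sample_markov_chain <- function(len, markov, initial) {
  s <- integer(len)
  s[1] <- sample.int(5L, 1L, prob = initial)
  if (len > 1) for (t in 2:len) s[t] <- sample.int(5L, 1L, prob = markov[s[t - 1], ])
  s
}

#' Generate a symbolic syllable cohort with ground truth
#'
#' Draws, for every pup, a sequence of bouts whose within-bout syllable
#' order follows the group's Markov chain; silences between syllables come
#' from the within-bout ISS distribution and bout-ending silences from the
#' shifted between-bout distribution, so ground-truth bouts are unambiguous
#' at the default 350 ms threshold. Fully reproducible for a fixed seed.
#'
#' @param spec A [synth_spec()].
#' @return A data frame (ground truth) with columns `pup_id`, `group`,
#'   `litter`, `syllable_idx`, `onset_s`, `offset_s`, `type`, `bout_id`.
#' @export
generate_symbolic_cohort <- function(spec) {
  validate_synth_spec(spec)
  set.seed(spec$seed)
  per_pup <- list()
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[gi]
    M <- spec$markov[[g]]
    for (p in seq_len(spec$n_pups_per_group[gi])) {
      pup_id <- sprintf("%s_%02d", g, p)
      litter <- sprintf("%s_L%d", g, ((p - 1L) %/% spec$pups_per_litter) + 1L)
      n_bouts <- max(1L, stats::rpois(1, spec$bouts_per_pup))
      lens <- sample.int(length(spec$bout_length_dist), n_bouts,
                         replace = TRUE, prob = spec$bout_length_dist)
      types <- unlist(lapply(lens, sample_markov_chain, markov = M,
                             initial = spec$initial_dist))
      bout_id <- rep.int(seq_len(n_bouts), lens)
      n <- length(types)
      dm <- vapply(spec$acoustic, `[[`, numeric(1), "dur_ms")[SYLLABLE_TYPES[types]]
      ds <- vapply(spec$acoustic, `[[`, numeric(1), "dur_sd_ms")[SYLLABLE_TYPES[types]]
      dur <- pmax(0.010, rnorm(n, dm, ds) / 1000)
      last_of_bout <- c(bout_id[-1] != bout_id[-n], TRUE)
      gap <- ifelse(last_of_bout,
                    (spec$iss_between$min_ms +
                       rgamma_ms(n, spec$iss_between$mean_ms, spec$iss_between$sd_ms)) / 1000,
                    rgamma_ms(n, spec$iss_within$mean_ms, spec$iss_within$sd_ms,
                              spec$iss_within$max_ms %||% Inf) / 1000)
      onset <- rgamma_ms(1, 300, 100) / 1000 + c(0, cumsum(dur + gap))[seq_len(n)]
      per_pup[[length(per_pup) + 1L]] <- data.frame(
        pup_id = pup_id, group = g, litter = litter,
        syllable_idx = seq_len(n),
        onset_s = onset, offset_s = onset + dur,
        type = SYLLABLE_TYPES[types], bout_id = bout_id,
        stringsAsFactors = FALSE)
    }
  }
  gt <- do.call(rbind, per_pup)
  rownames(gt) <- NULL
  gt
}

#' Render one syllable archetype as a waveform
#'
#' Archetypes: `S` a smooth frequency sweep; `J` a sweep with one
#' instantaneous pitch discontinuity; `O` a sweep with two discontinuities;
#' `H` a fundamental plus integer-multiple partials with decaying
#' amplitudes; `N` a band-limited noise burst. All syllables get raised-
#' cosine on/off amplitude ramps (2 ms) to avoid spectral splatter.
#'
#' @param type One of `"N","S","J","H","O"`.
#' @param dur_s Duration in seconds.
#' @param fs Sampling rate (Hz).
#' @param acoustic Archetype parameter list (defaults from
#'   [synth_spec()]); frequencies outside (30, 160) kHz trigger a warning
#'   because such energy is removed by the analysis band-pass.
#' @param amp Peak amplitude (0..1).
#' @return Numeric waveform vector.
#' @export
render_syllable <- function(type, dur_s, fs = 375000,
                            acoustic = default_acoustic(), amp = 0.5) {
  a <- acoustic[[type]]
  n <- max(16L, round(dur_s * fs))
  fr_all <- unlist(a[names(a) %in% c("f_start_khz", "f0_khz", "band_khz")],
                   use.names = FALSE)
  if (any(fr_all < 30 | fr_all > 160))
    warning("archetype frequency outside (30,160) kHz: syllable may be ",
            "removed by the band-pass filter")
  wave <- switch(type,
    N = {
      bw <- a$band_khz * 1000
      bf <- signal::butter(4, bw / (fs / 2), type = "pass")
      as.numeric(signal::filter(bf, rnorm(n)))
    },
    S = {
      f0 <- runif(1, a$f_start_khz[1], a$f_start_khz[2]) * 1000
      f <- f0 + seq(0, a$sweep_khz * 1000, length.out = n)
      sin(2 * pi * cumsum(f) / fs)
    },
    J = {
      f0 <- runif(1, a$f_start_khz[1], a$f_start_khz[2]) * 1000
      f <- f0 + seq(0, a$sweep_khz * 1000, length.out = n)
      jp <- round(runif(1, 0.35, 0.65) * n)
      f[jp:n] <- f[jp:n] + a$jump_khz * 1000
      sin(2 * pi * cumsum(f) / fs)
    },
    O = {
      f0 <- runif(1, a$f_start_khz[1], a$f_start_khz[2]) * 1000
      f <- f0 + seq(0, a$sweep_khz * 1000, length.out = n)
      j1 <- round(0.33 * n); j2 <- round(0.66 * n)
      f[j1:n] <- f[j1:n] + a$jump_khz * 1000
      f[j2:n] <- f[j2:n] - a$jump_khz * 1000
      sin(2 * pi * cumsum(f) / fs)
    },
    H = {
      f0 <- runif(1, a$f0_khz[1], a$f0_khz[2]) * 1000
      f <- f0 + seq(0, a$sweep_khz * 1000, length.out = n)
      ph <- 2 * pi * cumsum(f) / fs
      w <- rep(0, n)
      for (h in seq_len(a$n_harmonics)) w <- w + a$partial_decay^(h - 1) * sin(h * ph)
      w
    },
    stop("unknown syllable type: ", type))
  # raised-cosine 2 ms ramps
  nr <- min(round(0.002 * fs), floor(n / 2))
  ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  env <- rep(1, n); env[seq_len(nr)] <- ramp; env[n + 1 - seq_len(nr)] <- rev(ramp)
  wave <- wave * env
  # equal RMS across archetypes (calls of comparable intensity): a noise
  # burst normalised by its peak would carry ~8x less power than a tone
  # and vanish under the detection threshold
  wave / sqrt(mean(wave^2)) * (amp / sqrt(2))
}

#' Render a symbolic cohort as audio with ground-truth annotations
#'
#' Synthesizes, for every pup of the cohort, a 16-bit mono waveform at the
#' spec's sampling rate containing each annotated syllable at its
#' ground-truth onset, plus Gaussian background noise at the spec's SNR
#' (measured against the mean syllable RMS). If `dir` is given, one WAV
#' per pup and a `ground_truth.csv` are written there.
#'
#' @param spec A [synth_spec()].
#' @param ground_truth Optional pre-generated symbolic cohort (so the same
#'   symbolic draw can be rendered under different acoustic settings);
#'   defaults to `generate_symbolic_cohort(spec)`.
#' @param dir Optional output directory for WAV files.
#' @return List with `audio` (named list of waveforms), `fs`,
#'   `ground_truth`, and `files` (if written).
#' @export
generate_audio_cohort <- function(spec, ground_truth = NULL, dir = NULL) {
  validate_synth_spec(spec)
  if (is.null(ground_truth)) ground_truth <- generate_symbolic_cohort(spec)
  set.seed(spec$seed + 1L)
  fs <- spec$fs
  audio <- list()
  for (pup in unique(ground_truth$pup_id)) {
    gt <- ground_truth[ground_truth$pup_id == pup, ]
    n_total <- ceiling((max(gt$offset_s) + 0.3) * fs)
    x <- numeric(n_total)
    rms_sum <- 0
    for (i in seq_len(nrow(gt))) {
      w <- render_syllable(gt$type[i], gt$offset_s[i] - gt$onset_s[i], fs,
                           acoustic = spec$acoustic)
      i0 <- round(gt$onset_s[i] * fs) + 1L
      idx <- i0:(i0 + length(w) - 1L)
      x[idx] <- x[idx] + w
      rms_sum <- rms_sum + sqrt(mean(w^2))
    }
    if (is.finite(spec$snr_db)) {
      sig_rms <- rms_sum / nrow(gt)
      x <- x + rnorm(n_total, sd = sig_rms / 10^(spec$snr_db / 20))
    }
    x <- x / max(1, max(abs(x)) + 1e-9)
    audio[[pup]] <- x
  }
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(names(audio), function(pup) {
      f <- file.path(dir, paste0(pup, ".wav"))
      write_wav(audio[[pup]], fs, f)
      f
    }, character(1))
    write.csv(ground_truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  list(audio = audio, fs = fs, ground_truth = ground_truth, files = files)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Leading left eigenvector, normalised to sum to 1.
#'
#' @param markov Row-stochastic square matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(markov) {
  check_stochastic(markov)
  e <- eigen(t(markov))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

check_stochastic <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || any(m < -1e-12))
    stop("transition matrix must be square and non-negative")
  bad <- which(abs(rowSums(m) - 1) > 1e-9)
  if (length(bad))
    stop("matrix is not row-stochastic: row(s) ",
         paste(bad, collapse = ", "), " do not sum to 1")
  invisible(m)
}

#' Exact mutual information of a Markov chain at lag k (bits)
#'
#' Direct summation of `p(i,j) log2[p(i,j)/(p(i) p(j))]` over the joint
#' `p(i) * [M^k](i,j)`. Serves as the analytic oracle for the estimators:
#' for a uniform matrix it is 0 for all k, for a permutation matrix with
#' uniform stationary distribution it equals the state entropy, and for an
#' irreducible aperiodic chain it decays to 0 as k grows.
#'
#' @param markov Row-stochastic transition matrix.
#' @param stationary Optional stationary distribution; computed from the
#'   matrix when omitted.
#' @param k Lag (number of steps) between the two positions.
#' @return Mutual information in bits.
#' @export
analytic_mi <- function(markov, stationary = NULL, k = 1L) {
  check_stochastic(markov)
  if (is.null(stationary)) stationary <- stationary_distribution(markov)
  stopifnot(abs(sum(stationary) - 1) < 1e-9, k >= 1)
  Mk <- diag(nrow(markov))
  for (i in seq_len(k)) Mk <- Mk %*% markov
  joint <- stationary * Mk  # row i scaled by pi_i
  mutual_information(joint)
}
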