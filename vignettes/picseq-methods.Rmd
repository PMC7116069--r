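---
title: "Methods: segmentation, classification and sequence analysis of pup isolation calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, classification and sequence analysis of pup isolation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picseq)
```

## The problem

Mouse pups isolated from the nest emit ultrasonic vocalizations (USVs, 30–160 kHz)
in bouts of discrete syllables. Beyond per-call acoustics (rate, duration, peak
frequency), the *order* of syllables within a bout can carry structure: certain
types follow certain others more often than chance. `picseq` implements a complete
pipeline for quantifying that structure — from raw 375 kHz recordings to
information-theoretic summaries of syllable sequences — together with a synthetic
cohort generator with known ground truth, so that every stage is testable without
access to recordings.

The pipeline has six stages, each usable on its own and each communicating with the
next through plain tables:

1. **Segmentation** (`segment_recording`): band-pass filter, spectrogram, power
   contour, iterative peak tracking → syllable intervals.
2. **Classification** (`classify_recording`, `classify_patch`): five syllable
   types — noisy/broadband (N), tonal without pitch jump (S), one pitch jump (J),
   harmonic (H), two or more pitch jumps (O).
3. **Bout parsing** (`iss_stats`, `split_bouts`): maximal runs of syllables
   separated by silences below a threshold derived from the pooled silence
   distribution.
4. **Estimators** (`mutual_information`, `kld`, `bootstrap_debias`,
   `scrambled_null`): Krichevsky–Trofimov smoothed distributions, debiased mutual
   information (MI) and Kullback–Leibler divergence (KLD), confidence intervals,
   and a within-bout scrambled null.
5. **Sequence patterns** (`positional_mi`, `pair_joint`, `triplet_joint`,
   `extract_significant_sequences`): positional MI matrices, transition joint
   distributions, and breadth-first extraction of sequences produced above chance.
6. **Clustering** (`build_tree`, `cut_by_reference`, `cluster_kld`): per-pup
   distribution dendrograms under correlation distance `1 − ρ`, a
   reference-calibrated cluster cut, and cluster-level divergences.

## Signal processing

Recordings are 16-bit mono WAV at 375 kHz. Pre-processing applies a 7th-order
Butterworth band-pass (30–160 kHz) forward and backward (`signal::filtfilt`), so
the filter is zero-phase and syllable onsets are not shifted; a 10-point
moving-average detrend then removes any residual low-frequency drift. The upper
cutoff is configurable up to just below the 187.5 kHz Nyquist; re-running with
180 kHz is the standard negative control that in-band analyses do not depend on
the cutoff.

Each recording is processed in 5 s epochs. The spectrogram uses a Hamming window
of 1024 samples with 75% overlap (hop 256 samples, ~0.68 ms). The per-frame power
divided by total epoch power gives a normalized power contour (it sums to one),
median-filtered over 30 ms — 45 frames at the default hop, rounding the window to
the next odd integer. Median filtering preserves syllable edges while removing
single-frame transients.

Detection tracks local contour maxima in decreasing height order, expanding each
until the contour drops below the threshold `mean + 0.01·SD` of the filtered
contour; claimed frames are excluded from later seeds; detections shorter than
5 ms are discarded. Two guards make the literal rule robust:

* **Seed floor.** The threshold sits barely above the contour mean, so *any*
  epoch — including pure background — has contour peaks above it. Seed peaks must
  additionally reach `seed_rel = 2` times the contour mean. A real syllable
  concentrates power several-fold above the epoch average (at the ~25% duty cycle
  typical of dense calling, syllable frames sit 3–4× above the mean), while a
  silent epoch's contour never strays far from its mean. Setting `seed_rel = 0`
  restores the bare rule.
* **Epoch stitching.** Detections touching a 5 s epoch boundary are merged across
  it, so neither syllables nor bouts are split by the processing unit.

Threshold statistics are computed per epoch, matching the per-epoch processing
unit; the multiplier is exposed as `thresh_k`.

## Classification

Classification follows a strict precedence: broadband first (N), then harmonic
(H), then the pitch-jump count (0 → S, 1 → J, ≥2 → O).

**Broadband (N).** The deciding statistic is the spectral spread of each frame.
A plain magnitude-weighted standard deviation of frequency fails here: a harmonic
stack at 50/100/150 kHz has a weighted SD near 39 kHz — more "broadband" than
band-limited noise — because discrete far-apart lines inflate a variance. We use
a robust spread instead: 1.4826 × the power-weighted median absolute deviation of
frequency about the power-weighted median. Harmonic stacks whose fundamental
holds the majority of power score near zero; 30–160 kHz noise scores near
width/4 × 1.4826 ≈ 20+ kHz. A syllable is N when the median spread over its
frames exceeds `broadband_khz = 15`.

**Harmonic (H).** A frame supports harmonicity when it has at least two spectral
peaks above 6× the frame's median magnitude whose frequencies are integer
multiples (±5%) of the lowest peak — with the multiple required to be ≥ 2, since
window sidelobes adjacent to any tone trivially satisfy a ratio of ~1. Three or
more supporting frames make the syllable H.

**Pitch jumps (S/J/O).** 3×3 Sobel operators along time and frequency give a
joint gradient magnitude, collapsed to a per-frame contour by *summing* over
frequency. The sum, not the maximum, is what separates a jump from a sweep: a
discontinuity of Δf redistributes energy across Δf/bin-width ≈ 40 bins of one
frame, so its column integral stands ~5× above the sweep's own track-edge
gradient, whereas the per-bin maxima of the two cases are comparable. Candidate
peaks must exceed a robust z-score (`median + 3 × 1.4826·MAD`; a plain SD is
inflated by the very peaks being tested) and 1.5× the contour median, the first
and last two frames are excluded (onset/offset transients look like
discontinuities), and significant peaks closer than `window/hop = 4` frames are
merged, because one discontinuity smears over about that many frames. The
remaining peak count is the number of pitch jumps.

## Bouts

Inter-syllable silences (ISS) are measured offset-to-onset and pooled across all
pups; the bout threshold is `T(k) = mean + k·SD` with `k = 1` by default. With
the canonical pooled statistics for postnatal-day-5 pups (mean 200 ms, SD
150 ms), `T(1) = 350 ms` and `T(3) = 650 ms`. The SD uses the population
convention (divide by *n*) by default and is configurable. A silence equal to the
threshold ends a bout (configurable via `strict`). `threshold_sweep` re-runs the
bout parsing and the downstream MI profile over `k = 1 … 3`, using common random
numbers across thresholds so that identical bout sets give identical estimates
and only the threshold effect remains.

## Estimators

Joint distributions over syllable types are estimated from counts with the
Krichevsky–Trofimov correction, `p_i = (n_i + 1/2)/(N + m/2)` — add-half
smoothing that removes zero cells so MI and KLD are always finite. MI is the
standard `Σ p(x,y) log2[p(x,y)/(p(x)p(y))]` in bits; KLD is
`Σ p log2(p/q)`.

Plug-in MI is biased upward by roughly `(m−1)²/(2N ln 2)` for an `m × m` table
with `N` pairs. Debiasing uses bootstrap resampling of the observed pairs (2000
replicates, same size as the original): with `I_BS` the replicate mean, the
debiased estimate is `2·I_raw − I_BS`. Confidence intervals are percentile
(2.5/97.5) intervals of the replicate set.

Significance compares the data against a scrambled null: each null replicate
permutes the syllable order independently within every bout (bout lengths and
type compositions preserved) and recomputes the estimator. The estimate is
significant when the data interval lies strictly above the null interval;
touching intervals count as overlap. Data and null intervals are both percentile
intervals of plug-in replicate sets at the same `N`, so the comparison is
like-with-like. For KLD, which is tested against zero rather than against a
scramble, the percentile interval is re-centred on the debiased value so that
`p = q` yields an interval containing zero; significance is `ci_low > 0`.

Two degenerate cases are worth knowing:

* A bout of identical syllables is invariant under permutation, so a cohort of
  such bouts has a null identical to the data — dependence inside homogeneous
  runs is *undetectable in principle* by this null.
* More generally, within-bout scrambling preserves bout *composition*. Positional
  MI that stems from bouts differing in type composition (e.g., all-H bouts vs
  all-S bouts) survives scrambling and is absorbed into the null; only *ordering*
  structure is detected. This is the intended behaviour of the null and shapes
  the design of the synthetic generator below.

## The synthetic generator

`synth_spec`/`generate_symbolic_cohort` draw, per pup, a sequence of bouts whose
within-bout syllable order follows a group-specific first-order Markov chain
(types N, S, J, H, O), and `generate_audio_cohort` renders each annotated
syllable as audio. What the defaults emulate, and why:

* **Timing.** The pooled ISS distribution of real postnatal-day-5 cohorts has
  mean ≈ 200 ms and SD ≈ 150 ms, *pooling within- and between-bout silences*.
  The generator therefore draws within-bout silences from a gamma with mean
  110 ms, SD 60 ms, truncated below 340 ms, and bout-ending silences as 400 ms
  plus a gamma (mean 50, SD 80). With bout lengths geometric-like over 1–12
  (mean ≈ 4), the pooled silences come out near the target while ground-truth
  bouts remain exactly recoverable at the 350 ms threshold by construction. A
  within-bout draw targeting 200/150 directly would put ~15% of within-bout
  silences above the threshold and make exact bout recovery impossible.
* **Transition structure.** `markov_structured()` (the wild-type-like default)
  encodes a near-deterministic S→H→S alternation (S→H 0.92, H→S 0.80) seeded by
  the bout-start type. This is *ordering* structure: scrambling a bout destroys
  the phase, so positional MI stands far above the null (≈0.5/0.3/0.2 bits at
  positions 2–4 under the default initial distribution) — the regime in which
  wild-type-like cohorts show significant dependence several positions into a
  bout. An earlier design based on sticky same-type runs was abandoned after
  simulation showed the scrambled null absorbs run structure (see above); run-
  heavy repertoires are real, but their structure is composition, not order, and
  this machinery would correctly call them unordered.
  `markov_uniform()` (all transitions 1/5) emulates the unstructured
  deletion-male-like phenotype; `markov_mixture(0.7)` loses roughly one position
  of detectable dependence, emulating the deletion-female-like phenotype.
* **Acoustics.** Archetypes at 40–60 ms and 60–90 kHz: S a smooth sweep, J a
  sweep with one 15 kHz discontinuity, O with two, H a 45–50 kHz fundamental
  with two integer partials at decaying amplitude (the fundamental must dominate
  the power-weighted spectrum for the robust-spread N test to pass it), N a
  40–100 kHz noise burst. All archetypes are normalized to equal RMS — a
  peak-normalized noise burst carries ~8× less power than a tone and would fall
  under the detection threshold. Raised-cosine 2 ms ramps prevent spectral
  splatter from being classified as broadband. Background noise is added at a
  configurable SNR (default 30 dB against mean syllable RMS).
* **Group sizes.** Defaults follow the scale of real cohorts (12 pups per group,
  ~80 bouts per pup, litters of 3).

What the generator does **not** emulate: overlapping or truncated syllables,
amplitude variation within and across pups, frequency-dependent microphone
response, reverberation, and non-stationary background (scratching, movement
noise). Passing tests on synthetic audio therefore demonstrate that the
implementation is faithful to the stated method and recovers known structure
under clean conditions; they do not certify detection performance on noisy real
recordings.

`analytic_mi` provides the closed-form MI of a chain at lag *k* by direct
summation over the 25-cell joint `π_i·[M^k]_{ij}` — the oracle against which the
estimators are validated (uniform chain → 0; permutation chain → log2 5;
interpolated chains → any target in between).

## Clustering

Each pup is summarized by its distribution over the 5 types (or the flattened
bout-start pair/triplet joints — the same machinery runs on all three feature
sets). Distance is `1 − ρ` with Pearson ρ on the raw probability vectors (no
smoothing: zero cells are informative here); trees are built with average
linkage (monotone and standard for correlation distances; single and complete
are available, as is Spearman ρ). The maximum merge height of the designated
reference group's tree — the group that merges into a single cluster — becomes
the cut height for every other group. Clusters of size 1 are flagged and
excluded from downstream divergence analysis.

A caveat established in simulation: when the reference group and a target
subgroup carry the same sampling noise, the reference maximum height and the
subgroup's internal merge heights concentrate on the same value, so the cut
oversplits a homogeneous subgroup in roughly half of the runs — singletons and
small satellite clusters alongside the dominant ones. This mirrors how the cut
behaves on real data and is why the downstream analysis works with the dominant
clusters and drops singletons; recovery of a planted two-profile split is
therefore judged by cluster purity and the two dominant clusters realising the
split, not by an exact two-cluster count.

`litter_effect_report` adds a label-permutation test (Cramér's V) of
cluster–litter association, an explicit-test extension of the usual by-eye
argument that cluster structure is not litter specific.

## Numerical choices and defaults

| Parameter | Default | Where | Why |
|---|---|---|---|
| band | 30–160 kHz, order 7 | `bandpass` | USV band; zero-phase application |
| window / overlap | 1024 / 75% | `stft_spectrogram` | ~0.37 kHz × 0.68 ms resolution at 375 kHz |
| median filter | 30 ms (45 frames) | `power_contour` | removes transients, keeps edges |
| detection threshold | mean + 0.01·SD | `power_contour` | exposed as `thresh_k` |
| seed floor | 2× contour mean | `detect_syllables` | rejects silent-epoch false peaks |
| min duration | 5 ms | `detect_syllables` | sub-syllable noise |
| broadband spread | 15 kHz (robust MAD) | `is_noisy` | tones/sweeps ≪, noise ≫ |
| harmonic peaks | 6× median, ±5%, ≥3 frames, multiple ≥2 | `is_harmonic` | sidelobe-proof |
| jump threshold | robust z > 3 and >1.5× median, merge ≤4 frames | `count_pitch_jumps` | see classification section |
| bout threshold | T(1) = mean + SD | `iss_stats` | 350 ms at canonical statistics |
| bootstrap | 2000 replicates, percentile 95% CI | `bootstrap_debias` | stable CIs |
| min pairs / prefix | 20 / 10 | `positional_mi`, extraction | cells below are reported missing |
| linkage | average (UPGMA) | `build_tree` | monotone on 1 − ρ |

Problem sizes used in the package's own validation: MI calibration on 100
cohorts of 500 pairs and recovery chains of 2000 pairs; audio validation on a
3-pup, ~230-syllable cohort at 30 dB SNR; sequence-contrast cohorts of 1500
bouts; clustering on 17 + 12 pups with 300 syllables each. These sizes match the
scale of the real cohorts the pipeline targets while keeping the full validation
suite fast.

## Known limitations

* The within-bout scrambled null is blind to composition structure by design
  (see above); repertoires whose only structure is same-type runs will test as
  unordered.
* The segmentation threshold is per epoch; an epoch consisting almost entirely
  of continuous vocalization would raise its own threshold and could clip weak
  syllables.
* Pitch-jump counting assumes a single dominant frequency track per frame;
  simultaneous two-voice syllables would need the harmonic test to fire first.
* KT smoothing biases very small-sample distributions toward uniform; cells with
  fewer than `min_pairs` observations are reported missing rather than
  estimated.
* The classifier's thresholds were set against the synthetic archetypes and the
  stated acoustic regime; real recordings may need `classification_params()`
  retuned.
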