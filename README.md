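# picseq

Segmentation, classification and sequence analysis of mouse pup isolation calls.

Isolated mouse pups emit ultrasonic vocalizations (USVs, 30–160 kHz) in bouts of
discrete syllables. `picseq` asks whether the *order* of syllables within those
bouts carries structure — whether certain syllable types follow others above
chance — and quantifies it with information theory. The package is aimed at
behavioural-bioacoustics groups comparing vocal sequence structure across
genotypes or sexes (e.g. autism-model cohorts), where differences can live in
sequence order rather than in per-call acoustics.

## What it computes

From a 375 kHz recording (or a pre-segmented syllable table):

1. **Syllables** — Butterworth band-pass (30–160 kHz, order 7, zero phase),
   Hamming-window STFT (1024, 75% overlap), normalized power contour median
   filtered over 30 ms, iterative peak tracking with threshold
   `mean + 0.01·SD`.
2. **Types** — each syllable becomes one of N (broadband), S (tonal, no pitch
   jump), J (one pitch jump), H (harmonic), O (≥ 2 jumps), by spectral-spread,
   harmonic-peak and Sobel pitch-gradient tests.
3. **Bouts** — maximal runs separated by silences below
   `T(k) = mean + k·SD` of the pooled inter-syllable silence distribution
   (350 ms at the canonical mean 200 / SD 150 ms).
4. **Sequence structure** — Krichevsky–Trofimov smoothed joint distributions;
   mutual information between bout positions, debiased as
   `2·I_raw − I_BS` with 2000 bootstrap resamples:

   `MI(X;Y) = Σ_x Σ_y P(x,y) log2[ P(x,y) / (P(x)P(y)) ]`

   with significance against a null that scrambles syllable order within every
   bout; Kullback–Leibler divergences `Σ p log2(p/q)` between groups; pair and
   triplet transition matrices; breadth-first extraction of syllable sequences
   produced above chance.
5. **Clustering** — per-pup distribution dendrograms under correlation distance
   `1 − ρ`, cut at the reference group's maximum merge height, with
   cluster-level divergences and a litter-association permutation test.

A synthetic-cohort generator (`synth_spec`, `generate_symbolic_cohort`,
`generate_audio_cohort`) produces symbolic sequences with known Markov structure
and renders them as annotated 375 kHz audio, so the whole pipeline is testable
against ground truth; `analytic_mi` gives the exact chain MI as an oracle.

## Worked example

Generate a structured (wild-type-like) and an unstructured cohort, parse bouts,
and test positional dependence:

```r
library(picseq)

spec <- synth_spec(n_pups_per_group = 4, groups = c("WTM", "delM"),
                   bouts_per_pup = 40, seed = 7)
gt <- generate_symbolic_cohort(spec)

st <- iss_stats(gt)
st
#> ISS: n = 1556, mean 181.3 ms, SD 153.0 ms, T(1) = 334.4 ms

bt <- split_bouts(gt, st$threshold_ms)
wt_bouts <- bout_sequences(bt[bt$group == "WTM", ])
prof <- positional_mi_profile(wt_bouts, max_pos = 4, n_boot = 2000)
prof
#>   position n_pairs mi_debiased ci_low ci_high null_high significant
#> 1        2     147       0.559  0.496   0.735     0.172        TRUE
#> 2        3     124       0.266  0.205   0.466     0.141        TRUE
#> 3        4     105       0.123  0.092   0.306     0.151       FALSE
```

The pooled silences reproduce the expected regime (mean ≈ 200 ms, SD ≈ 150 ms,
threshold ≈ 350 ms). The bout-start syllable of the structured group carries
0.56 bits about position 2 and 0.27 bits about position 3 — both confidence
intervals clear of the scrambled-sequence null — while at position 4 this
cohort (147 bouts) is too small to separate from the null. The same profile on
the `delM` group's uniform sequences is non-significant everywhere.

```r
extract_significant_sequences(wt_bouts, n_boot = 2000)
#> N-S-H (14 bouts)
#> N-J (4 bouts)
#> S-H-S-H-S-H-S-H (9 bouts)
#> O-H-S (10 bouts)
```

Sequence extraction recovers the generator's tonal–harmonic alternation: bouts
opening with S run `S-H-S-H…`, each extension occurring above the overall
type frequencies at 95% confidence.

The full pipeline (segmentation → classification → bouts → information
analysis → clustering, with every table written to disk) runs as

```r
run_pipeline(list(mode = "symbolic", input = spec, out_dir = "out", seed = 7))
```

or from a shell via `inst/cli/picseq.R`; audio mode takes a directory of WAV
files (`mode = "wav_dir"`).

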