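# Positional MI matrices, pair/triplet joints, group divergences,
# significant-sequence extraction.

test_that("copy chain: MI(1,2) equals the positional entropy", {
  set.seed(61)
  # position 2 copies position 1 (uniform start); a random third syllable
  # lets the within-bout scramble actually break the dependence
  bouts <- replicate(600, c(rep(sample.int(5, 1), 2), sample.int(5, 1)),
                     simplify = FALSE)
  pm <- positional_mi(bouts, max_pos = 2, n_boot = 200)
  expect_equal(pm$mi[1, 2], pm$mi[1, 1], tolerance = 0.08)
  expect_equal(pm$mi[1, 1], log2(5), tolerance = 0.05)
  expect_true(pm$significant[1, 2])
})

test_that("within-bout scrambling cannot detect dependence in two-syllable copy bouts", {
  set.seed(75)
  # degenerate but instructive: every bout is (x, x); any permutation of a
  # bout leaves it unchanged, so the scrambled null reproduces the data
  bouts <- replicate(200, rep(sample.int(5, 1), 2), simplify = FALSE)
  est <- mi_with_null(bouts, function(b) pairs_at_positions(b, 1, 2),
                      n_boot = 150, n_scrambles = 150)
  expect_false(est$significant)
  expect_equal(unname(est$null_ci[2]), est$raw, tolerance = 1e-9)
})

test_that("MI of significant cells never exceeds the positional entropy", {
  set.seed(62)
  bouts <- draw_bouts(markov_structured(), 400,
                      init = c(0.1, 0.45, 0.1, 0.15, 0.2))
  pm <- positional_mi(bouts, max_pos = 4, n_boot = 300)
  for (m in 1:3) for (n in (m + 1):4) {
    if (isTRUE(pm$significant[m, n]))
      expect_lte(pm$mi[m, n], pm$mi[n, n] + 0.02)
  }
})

test_that("structured chains show significant early positions; uniform chains none", {
  set.seed(63)
  wt <- draw_bouts(markov_structured(), 400, init = c(0.1, 0.45, 0.1, 0.15, 0.2))
  pm_wt <- positional_mi_profile(wt, max_pos = 4, n_boot = 400)
  expect_true(all(pm_wt$significant[pm_wt$position <= 3]))
  un <- draw_bouts(markov_uniform(), 400)
  pm_un <- positional_mi_profile(un, max_pos = 4, n_boot = 400)
  expect_false(any(pm_un$significant))
})

test_that("pair and triplet counting identities", {
  bouts <- list(c("S", "H", "H"))
  pj_s <- pair_joint(bouts, "bout_start", significance = FALSE)
  expect_equal(pj_s$n, 1)
  expect_equal(pj_s$counts["S", "H"], 1)
  pj_a <- pair_joint(bouts, "anywhere", significance = FALSE)
  expect_equal(pj_a$n, 2)
  expect_equal(pj_a$counts["S", "H"], 1)
  expect_equal(pj_a$counts["H", "H"], 1)
  b2 <- list(c("S", "H", "H", "H"))
  tj_s <- triplet_joint(b2, "bout_start", significance = FALSE)
  expect_equal(tj_s$n, 1)
  expect_equal(tj_s$counts["SH", "H"], 1)
  tj_a <- triplet_joint(b2, "anywhere", significance = FALSE)
  expect_equal(tj_a$n, 2)
  expect_equal(tj_a$counts["HH", "H"], 1)
  # anywhere-mode totals: sum(len-1) pairs, sum(max(len-2,0)) triplets
  set.seed(64)
  bts <- draw_bouts(markov_uniform(), 100)
  lens <- lengths(bts)
  expect_equal(pair_joint(bts, "anywhere", significance = FALSE)$n,
               sum(lens - 1))
  expect_equal(triplet_joint(bts, "anywhere", significance = FALSE)$n,
               sum(pmax(lens - 2, 0)))
})

test_that("triplet probabilities factorise for a first-order chain", {
  set.seed(65)
  M <- markov_structured()
  init <- stationary_distribution(M)
  bouts <- draw_bouts(M, 3500, len_probs = c(0, 0, 0, 1), init = init)
  tj <- triplet_joint(bouts, "bout_start", significance = FALSE)
  pred <- matrix(0, 25, 5)
  for (a in 1:5) for (b in 1:5) pred[(a - 1) * 5 + b, ] <- init[a] * M[a, b] * M[b, ]
  expect_lt(max(abs(tj$prob - pred)), 0.02)
  # uniform chain: all cells near 1/125
  bu <- draw_bouts(markov_uniform(), 3000, len_probs = c(0, 0, 0, 1))
  tju <- triplet_joint(bu, "bout_start", significance = FALSE)
  expect_lt(max(abs(tju$prob - 1 / 125)), 0.02)
})

test_that("anywhere-mode pair cells track the chain's stationary flow", {
  set.seed(66)
  M <- markov_structured()
  pi0 <- stationary_distribution(M)
  bouts <- draw_bouts(M, 2500, len_probs = c(0, 0, 0, 0, 0.5, 0.5), init = pi0)
  pj <- pair_joint(bouts, "anywhere", significance = FALSE)
  expect_lt(max(abs(pj$prob - pi0 * M)), 0.01)
})

test_that("group KLD matrix: self-zero, same-chain non-significant, different chains significant", {
  set.seed(67)
  mk <- function(M, n) encode_tuples(draw_bouts(M, n), 1)
  samples <- list(g1 = mk(markov_structured(), 1200),
                  g2 = mk(markov_structured(), 1200),
                  g3 = mk(markov_uniform(), 1200))
  res <- group_kld_matrix(samples, n_cells = 5, n_boot = 400)
  expect_equal(unname(diag(res$kld)), rep(0, 3))
  expect_false(res$significant["g1", "g2"])
  expect_true(res$significant["g1", "g3"])
  expect_gt(res$kld["g1", "g3"], res$kld["g1", "g2"])
})

test_that("sequence extraction recovers a planted S,H,H,H opening", {
  set.seed(68)
  # bouts start S,H,H,H with p=0.9 against an S-dominated overall distribution
  planted <- replicate(200, {
    if (runif(1) < 0.9) c(2L, 4L, 4L, 4L, sample.int(5, 2, replace = TRUE))
    else sample.int(5, 6, replace = TRUE, prob = c(0.1, 0.5, 0.1, 0.15, 0.15))
  }, simplify = FALSE)
  overall <- c(0.15, 0.40, 0.15, 0.15, 0.15)
  seqs <- extract_significant_sequences(planted, overall, n_boot = 400)
  expect_gte(length(seqs), 1)
  flat <- vapply(seqs, function(s) paste(s[1:4], collapse = ""), character(1))
  expect_true(any(flat == "SHHH"))
})

test_that("iid uniform bouts rarely produce sequences of length >= 2", {
  set.seed(69)
  hits <- 0
  for (r in 1:10) {
    bouts <- draw_bouts(markov_uniform(), 250)
    seqs <- extract_significant_sequences(bouts, rep(0.2, 5), n_boot = 300)
    if (any(lengths(seqs) >= 2)) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("structured chain yields long tonal-harmonic sequences", {
  set.seed(70)
  bouts <- draw_bouts(markov_structured(), 500,
                      len_probs = c(0, 0, 0.1, 0.2, 0.3, 0.2, 0.1, 0.1),
                      init = c(0.2, 0.45, 0.05, 0.1, 0.2))
  seqs <- extract_significant_sequences(bouts, n_boot = 400)
  expect_gte(length(seqs), 1)
  # at least one long recovered sequence carries the S->H progression
  good <- vapply(seqs, function(s)
    length(s) >= 4 && any(s[-length(s)] == "S" & s[-1] == "H"), logical(1))
  expect_true(any(good))
})
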