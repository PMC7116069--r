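# Estimator core: KT smoothing, MI, entropy, KLD, bootstrap debiasing,
# scrambled nulls and the CI-separation significance rule.

test_that("KT smoothing adds half a count per cell", {
  expect_equal(kt_estimate(c(3, 0, 1)), c(3.5, 0.5, 1.5) / 5.5)
  # symmetry: uniform counts stay exactly uniform
  expect_equal(kt_estimate(rep(7, 5)), rep(0.2, 5))
  # limit: converges to empirical proportions
  big <- kt_estimate(c(6e5, 3e5, 1e5))
  expect_equal(big, c(0.6, 0.3, 0.1), tolerance = 1e-4)
  expect_true(all(kt_estimate(c(10, 0, 0, 0)) > 0))
  expect_error(kt_estimate(c(0, 0)), "all-zero")
})

test_that("mutual information matches brute-force summation on random joints", {
  set.seed(11)
  for (rep in 1:20) {
    j <- matrix(rexp(25), 5, 5); j <- j / sum(j)
    expect_equal(mutual_information(j), brute_mi(j), tolerance = 1e-12)
  }
  # independence and perfect dependence
  p <- c(0.1, 0.2, 0.3, 0.25, 0.15); q <- c(0.3, 0.3, 0.2, 0.1, 0.1)
  expect_equal(mutual_information(outer(p, q)), 0, tolerance = 1e-12)
  expect_equal(mutual_information(diag(2) / 2), 1)
  expect_equal(mutual_information(matrix(c(0.4, 0.1, 0.1, 0.4), 2)),
               0.8 * log2(1.6) + 0.2 * log2(0.4), tolerance = 1e-12)
})

test_that("entropy and KLD worked examples", {
  expect_equal(shannon_entropy(rep(0.2, 5)), log2(5))
  expect_equal(shannon_entropy(c(1, 0, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25, 0, 0)), 1.5)
  expect_equal(kld(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kld(c(0.5, 0.5), c(0.75, 0.25)), 0.5 * log2(2 / 3) + 0.5)
  # asymmetry
  expect_equal(kld(c(0.75, 0.25), c(0.5, 0.5)), 0.75 * log2(1.5) - 0.25)
  expect_error(kld(c(0.5, 0.5), c(1, 0)), "zero mass")
})

test_that("MI is bounded by the marginal entropies on random joints", {
  set.seed(12)
  for (rep in 1:20) {
    j <- matrix(rexp(25), 5, 5); j <- j / sum(j)
    mi <- mutual_information(j)
    expect_gte(mi, 0)
    expect_lte(mi, min(shannon_entropy(rowSums(j)), shannon_entropy(colSums(j))) + 1e-12)
  }
})

test_that("KLD is non-negative, zero only at equality", {
  set.seed(13)
  for (rep in 1:20) {
    p <- kt_estimate(rmultinom(1, 200, rexp(5))[, 1])
    q <- kt_estimate(rmultinom(1, 200, rexp(5))[, 1])
    expect_gte(kld(p, q), 0)
  }
  p <- kt_estimate(c(5, 3, 2, 1, 9))
  expect_equal(kld(p, p), 0)
})

test_that("bootstrap debiasing: constant estimator is a fixed point", {
  set.seed(1)
  est <- bootstrap_debias(rep(1:5, 4), rep(1:5, 4), n_boot = 200,
                          estimator = function(x, y, m) 0.7)
  expect_equal(est$raw, 0.7)
  expect_equal(est$debiased, 0.7)
  expect_equal(unname(est$ci), c(0.7, 0.7))
})

test_that("debiasing removes the positive plug-in bias on independent data", {
  set.seed(21)
  raws <- numeric(30); debs <- numeric(30)
  for (r in 1:30) {
    x <- sample.int(5, 500, replace = TRUE)
    y <- sample.int(5, 500, replace = TRUE)
    est <- bootstrap_debias(x, y, n_boot = 200)
    raws[r] <- est$raw; debs[r] <- est$debiased
  }
  # plug-in MI of independent 5x5 data is biased up by ~(5-1)^2/(2N ln2)
  expect_gt(mean(raws), 0.01)
  expect_lt(abs(mean(debs)), abs(mean(raws)))
})

test_that("debiased MI CI covers the analytic chain value", {
  set.seed(22)
  M2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  truth <- analytic_mi(M2, c(0.5, 0.5), 1)
  expect_equal(truth, 0.9 * log2(1.8) + 0.1 * log2(0.2), tolerance = 1e-12)
  cover <- 0
  for (r in 1:10) {
    pr <- embed_2state(chain_pairs(M2, 2000))
    est <- bootstrap_debias(pr[, 1], pr[, 2], n_boot = 300)
    cover <- cover + (truth >= est$ci[1] && truth <= est$ci[2])
  }
  expect_gte(cover, 9)
})

test_that("scrambled null: single-type bouts give a degenerate null at the data value", {
  set.seed(3)
  bouts <- replicate(30, rep(2L, 4), simplify = FALSE)
  nul <- scrambled_null(bouts, pairs_successive, n_scrambles = 50)
  pr <- pairs_successive(bouts)
  obs <- picseq:::mi_from_pairs(pr[, 1], pr[, 2])
  expect_equal(unname(nul$ci), c(obs, obs))
})

test_that("scrambled null flags Markov dependence and not iid data", {
  set.seed(23)
  M <- markov_structured()
  bouts <- draw_bouts(M, 250, init = c(0.1, 0.45, 0.1, 0.15, 0.2))
  est <- mi_with_null(bouts, function(b) pairs_at_positions(b, 1, 2),
                      n_boot = 400, n_scrambles = 400)
  expect_true(est$significant)
  iid <- draw_bouts(markov_uniform(), 250)
  est0 <- mi_with_null(iid, function(b) pairs_at_positions(b, 1, 2),
                       n_boot = 400, n_scrambles = 400)
  expect_false(est0$significant)
})

test_that("significance rule: strict separation of intervals, overlap inclusive", {
  expect_true(is_significant(list(ci = c(0.2, 0.4)), c(0.0, 0.1)))
  expect_false(is_significant(list(ci = c(0.05, 0.2)), c(0.0, 0.1)))
  expect_false(is_significant(list(ci = c(0.1, 0.2)), c(0.0, 0.1)))  # touching
})

test_that("debiased KLD between same-source samples straddles zero, differing sources do not", {
  set.seed(24)
  p <- c(0.35, 0.3, 0.15, 0.1, 0.1)
  x <- sample.int(5, 800, replace = TRUE, prob = p)
  y <- sample.int(5, 800, replace = TRUE, prob = p)
  same <- kld_debiased(x, y, n_boot = 400)
  expect_false(same$significant)
  z <- sample.int(5, 800, replace = TRUE, prob = rep(0.2, 5))
  diff <- kld_debiased(x, z, n_boot = 400)
  expect_true(diff$significant)
  expect_gt(diff$debiased, 0)
})
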