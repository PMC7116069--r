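# Core information-theoretic estimators: Krichevsky-Trofimov smoothing,
# mutual information, entropy, Kullback-Leibler divergence, bootstrap
# debiasing and scrambled-sequence null models.

#' Krichevsky-Trofimov estimate of a categorical distribution
#'
#' Adds 1/2 to every cell count before normalising, so that unobserved
#' categories receive non-zero probability: `p_i = (n_i + 1/2) / (N + m/2)`
#' with `m` the number of cells. This is the standard add-half smoothing
#' used to remove zeros from empirical joint distributions before computing
#' mutual information or divergences.
#'
#' @param counts Non-negative integer vector, matrix or array of counts.
#' @return Probabilities with the same shape as `counts`, summing to 1,
#'   all strictly positive.
#' @examples
#' kt_estimate(c(3, 0, 1))  # (3.5, 0.5, 1.5) / 5.5
#' @export
kt_estimate <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("all-zero counts: nothing to estimate")
  m <- length(counts)
  p <- (counts + 0.5) / (n + m / 2)
  p
}

#' Shannon entropy of a categorical distribution (bits)
#'
#' @param p Probability vector (or matrix, treated as a flat distribution);
#'   must sum to 1. Zero cells contribute zero.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a joint distribution (bits)
#'
#' Computes `sum_xy p(x,y) log2[ p(x,y) / (p(x) p(y)) ]` with marginals
#' taken from the joint by row and column sums. Zero joint cells contribute
#' zero; with Krichevsky-Trofimov smoothed input all cells are positive.
#'
#' @param joint Matrix of joint probabilities summing to 1.
#' @return Mutual information in bits (non-negative up to round-off).
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  stopifnot(abs(sum(joint) - 1) < 1e-9)
  px <- rowSums(joint)
  py <- colSums(joint)
  ref <- outer(px, py)
  ok <- joint > 0
  sum(joint[ok] * log2(joint[ok] / ref[ok]))
}

#' Kullback-Leibler divergence between two distributions (bits)
#'
#' `KLD(p || q) = sum_x p(x) log2[ p(x)/q(x) ]`. Asymmetric in its
#' arguments. `q` must be strictly positive wherever `p` is (guaranteed
#' when both are Krichevsky-Trofimov smoothed).
#'
#' @param p,q Probability vectors (or matrices) on a common support.
#' @return Divergence in bits.
#' @export
kld <- function(p, q) {
  p <- as.vector(p); q <- as.vector(q)
  stopifnot(length(p) == length(q),
            abs(sum(p) - 1) < 1e-9, abs(sum(q) - 1) < 1e-9)
  ok <- p > 0
  if (any(q[ok] <= 0))
    stop("q has zero mass where p is positive; smooth counts first (kt_estimate)")
  sum(p[ok] * log2(p[ok] / q[ok]))
}

# Fast path used by the resampling loops: plug-in (KT-smoothed) MI from
# integer pair codes. `x`, `y` in 1..m.
mi_from_pairs <- function(x, y, m = 5L) {
  counts <- tabulate((x - 1L) * m + y, nbins = m * m)
  n <- length(x)
  p <- (counts + 0.5) / (n + m * m / 2)
  jm <- matrix(p, nrow = m, byrow = TRUE)
  px <- rowSums(jm)
  py <- colSums(jm)
  sum(jm * log2(jm / outer(px, py)))
}

#' Joint distribution of paired observations
#'
#' Tabulates integer- or label-coded pairs into an `m x m` count matrix and
#' its Krichevsky-Trofimov smoothed probability matrix.
#'
#' @param x,y Paired observations (type labels or integer codes 1..m).
#' @param n_types Alphabet size (default 5).
#' @return List with `counts`, `prob` (KT-smoothed), `n`.
#' @export
pair_distribution <- function(x, y, n_types = 5L) {
  x <- type_codes(x, n_types); y <- type_codes(y, n_types)
  stopifnot(length(x) == length(y))
  counts <- matrix(tabulate((x - 1L) * n_types + y, nbins = n_types * n_types),
                   nrow = n_types, byrow = TRUE,
                   dimnames = if (n_types == 5L)
                     list(SYLLABLE_TYPES, SYLLABLE_TYPES) else NULL)
  list(counts = counts, prob = kt_estimate(counts) , n = length(x))
}

#' Bootstrap-debiased estimate of mutual information (or any statistic)
#'
#' Resamples the observed pairs with replacement (same number as the
#' original), recomputes the plug-in estimate for each replicate, and
#' returns the debiased value `2 * I_raw - I_BS`, where `I_BS` is the mean
#' over replicates, together with a percentile 95% confidence interval of
#' the replicate set. The default number of replicates is 2000.
#'
#' @param x,y Paired observations (labels or integer codes).
#' @param n_types Alphabet size.
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level for the percentile interval.
#' @param estimator Function `(x, y, m)` returning a scalar; defaults to
#'   the KT-smoothed plug-in mutual information.
#' @return Object of class `info_estimate`: list with `raw`, `boot_mean`,
#'   `debiased`, `ci` (length 2), `replicates`, `n`, `n_boot`.
#' @export
bootstrap_debias <- function(x, y, n_types = 5L, n_boot = 2000L,
                             conf = 0.95, estimator = mi_from_pairs) {
  x <- type_codes(x, n_types); y <- type_codes(y, n_types)
  n <- length(x)
  if (n < 2) stop("need at least 2 observed pairs")
  if (n_boot < 100) warning("n_boot < 100: confidence interval will be unstable")
  raw <- estimator(x, y, n_types)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    estimator(x[idx], y[idx], n_types)
  }, numeric(1))
  boot_mean <- mean(reps)
  alpha <- (1 - conf) / 2
  est <- list(raw = raw,
              boot_mean = boot_mean,
              debiased = 2 * raw - boot_mean,
              ci = unname(quantile(reps, c(alpha, 1 - alpha))),
              replicates = reps,
              n = n, n_boot = n_boot, conf = conf)
  class(est) <- "info_estimate"
  est
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("info_estimate: raw %.4f, debiased %.4f bits (n = %d, %d boots)\n",
              x$raw, x$debiased, x$n, x$n_boot))
  cat(sprintf("  %.0f%% CI [%.4f, %.4f]\n", 100 * x$conf, x$ci[1], x$ci[2]))
  if (!is.null(x$null_ci))
    cat(sprintf("  null CI [%.4f, %.4f] -> %s\n", x$null_ci[1], x$null_ci[2],
                if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}

#' Scrambled-sequence null distribution of a sequence statistic
#'
#' Estimates the no-dependence baseline by repeatedly permuting the order
#' of syllables independently within every bout (bout lengths and type
#' counts are preserved), re-extracting the pairs under study and
#' recomputing the statistic. Returns the percentile confidence interval
#' of the null replicate set.
#'
#' @param bouts List of integer vectors (type codes per bout, in emission
#'   order), or a list of character vectors of labels.
#' @param pair_fun Function mapping a bout list to a 2-column matrix of
#'   integer pair codes (e.g. successive pairs, or positions m and n).
#' @param n_types Alphabet size.
#' @param n_scrambles Number of scramble replicates.
#' @param conf Confidence level.
#' @param estimator Statistic on pairs, as in [bootstrap_debias()].
#' @return List with `ci`, `replicates`, `n_scrambles`.
#' @export
scrambled_null <- function(bouts, pair_fun, n_types = 5L,
                           n_scrambles = 2000L, conf = 0.95,
                           estimator = mi_from_pairs) {
  bouts <- lapply(bouts, type_codes, n_types = n_types)
  # flattened representation: each replicate permutes within every bout
  # with a single order(bout, runif) call; extractors that advertise a
  # flat form (attribute "flat") avoid rebuilding the bout list
  flat <- unlist(bouts, use.names = FALSE)
  lens <- lengths(bouts)
  bid <- rep.int(seq_along(bouts), lens)
  starts <- cumsum(c(1L, lens))[seq_along(lens)]
  ff <- attr(pair_fun, "flat")
  nn <- length(flat)
  reps <- vapply(seq_len(n_scrambles), function(b) {
    fp <- flat[order(bid, runif(nn))]
    pr <- if (!is.null(ff)) ff(fp, bid, starts, lens)
    else pair_fun(unname(split(fp, bid)))
    if (is.null(pr) || nrow(pr) < 2) return(NA_real_)
    estimator(pr[, 1], pr[, 2], n_types)
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  ci <- if (length(reps)) unname(quantile(reps, c(alpha, 1 - alpha))) else c(NA_real_, NA_real_)
  list(ci = ci, replicates = reps, n_scrambles = n_scrambles)
}

#' Pair extractor: successive within-bout pairs
#'
#' @param bouts List of integer vectors.
#' @param k Step size (pairs are positions `t` and `t + k`).
#' @return 2-column matrix of pairs (possibly 0 rows).
#' @export
pairs_successive <- function(bouts, k = 1L) {
  out <- lapply(bouts, function(v) {
    n <- length(v)
    if (n <= k) return(NULL)
    cbind(v[seq_len(n - k)], v[seq_len(n - k) + k])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  out
}
attr(pairs_successive, "flat") <- function(fp, bid, starts, lens, k = 1L) {
  i <- seq_len(length(fp) - k)
  i <- i[bid[i] == bid[i + k]]
  cbind(fp[i], fp[i + k])
}

#' Pair extractor: fixed bout positions
#'
#' Extracts the pair (position `m`, position `n`) from every bout of
#' length at least `n`. `position_pair_fun(m, n)` returns a one-argument
#' extractor suitable for [scrambled_null()] / [mi_with_null()].
#'
#' @param bouts List of integer vectors.
#' @param m,n Positions from the bout start (1-based), `m < n` typically.
#' @return 2-column matrix of pairs.
#' @export
pairs_at_positions <- function(bouts, m, n) {
  keep <- vapply(bouts, length, integer(1)) >= max(m, n)
  out <- t(vapply(bouts[keep], function(v) c(v[m], v[n]), integer(2)))
  if (length(out) == 0) out <- matrix(integer(0), ncol = 2)
  out
}

#' @rdname pairs_at_positions
#' @export
position_pair_fun <- function(m, n) {
  f <- function(bouts) pairs_at_positions(bouts, m, n)
  attr(f, "flat") <- function(fp, bid, starts, lens) {
    s <- starts[lens >= max(m, n)]
    cbind(fp[s + m - 1L], fp[s + n - 1L])
  }
  f
}

#' Significance by confidence-interval separation
#'
#' An estimate is significant when the lower bound of its confidence
#' interval lies strictly above the upper bound of the scrambled-null
#' interval; touching intervals count as overlapping.
#'
#' @param est An `info_estimate` (or any list with a `ci` element), or a
#'   numeric length-2 interval.
#' @param null_ci Numeric length-2 null interval, or the list returned by
#'   [scrambled_null()].
#' @return Logical.
#' @export
is_significant <- function(est, null_ci) {
  ci <- if (is.list(est)) est$ci else est
  nci <- if (is.list(null_ci)) null_ci$ci else null_ci
  if (anyNA(ci) || anyNA(nci)) return(FALSE)
  ci[1] > nci[2]
}

#' Debiased mutual information with scrambled-sequence significance
#'
#' Convenience wrapper combining [bootstrap_debias()] on the extracted
#' pairs with [scrambled_null()] on the bouts, attaching the null interval
#' and significance flag to the estimate.
#'
#' @inheritParams scrambled_null
#' @inheritParams bootstrap_debias
#' @return `info_estimate` with extra fields `null_ci`, `significant`.
#' @export
mi_with_null <- function(bouts, pair_fun, n_types = 5L, n_boot = 2000L,
                         n_scrambles = n_boot, conf = 0.95) {
  bouts <- lapply(bouts, type_codes, n_types = n_types)
  pr <- pair_fun(bouts)
  if (nrow(pr) < 2) stop("fewer than 2 pairs extracted from bouts")
  est <- bootstrap_debias(pr[, 1], pr[, 2], n_types = n_types,
                          n_boot = n_boot, conf = conf)
  nul <- scrambled_null(bouts, pair_fun, n_types = n_types,
                        n_scrambles = n_scrambles, conf = conf)
  est$null_ci <- nul$ci
  est$significant <- is_significant(est, nul$ci)
  est
}

#' Bootstrap-debiased Kullback-Leibler divergence between two samples
#'
#' Both samples are resampled with replacement, each replicate's KT-smoothed
#' distributions give a replicate divergence, and the debiased value is
#' `2 * KLD_raw - mean(replicates)`. The reported confidence interval is the
#' percentile interval of the replicates re-centred on the debiased value,
#' so that a divergence compatible with zero yields an interval containing
#' zero; significance is `ci_low > 0`.
#'
#' @param x,y Observations (labels or integer codes) from the two groups.
#'   Tuples (pairs/triplets) should be pre-encoded as integers over the
#'   product alphabet with `n_cells` set accordingly.
#' @param n_cells Number of support cells.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @return List with `raw`, `debiased`, `ci`, `significant`, `n_x`, `n_y`.
#' @export
kld_debiased <- function(x, y, n_cells = 5L, n_boot = 2000L, conf = 0.95) {
  x <- as.integer(x); y <- as.integer(y)
  stopifnot(all(x >= 1L & x <= n_cells), all(y >= 1L & y <= n_cells))
  pq <- function(v, n) kt_estimate(tabulate(v, nbins = n_cells))
  raw <- kld(pq(x), pq(y))
  nx <- length(x); ny <- length(y)
  reps <- vapply(seq_len(n_boot), function(b) {
    kld(pq(x[sample.int(nx, nx, replace = TRUE)]),
        pq(y[sample.int(ny, ny, replace = TRUE)]))
  }, numeric(1))
  debiased <- 2 * raw - mean(reps)
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha))) - mean(reps) + debiased
  list(raw = raw, debiased = debiased, ci = ci,
       significant = ci[1] > 0, n_x = nx, n_y = ny, n_boot = n_boot)
}
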