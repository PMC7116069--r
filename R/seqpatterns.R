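# Sequence-level analyses: positional mutual-information matrices,
# pair/triplet transition joint distributions (bout-start and anywhere
# modes), between-group divergence matrices, and extraction of syllable
# sequences produced above chance.

as_bout_codes <- function(bouts) {
  if (is.data.frame(bouts)) bouts <- bout_sequences(bouts)
  lapply(bouts, type_codes)
}

#' Positional mutual information profile from one anchor position
#'
#' Debiased MI between the syllable at position `from` and each later
#' position, with the within-bout scrambled null, over bouts long enough
#' to contribute.
#'
#' @param bouts List of bouts (vectors of type labels/codes) or a
#'   [split_bouts()] data frame.
#' @param from Anchor position (1 = bout start).
#' @param max_pos Last position tested.
#' @param n_boot Bootstrap (and scramble) replicates.
#' @param min_pairs Minimum qualifying bouts per position (default 20);
#'   positions with fewer are reported as missing.
#' @param conf Confidence level.
#' @return Data frame with `position`, `n_pairs`, `mi_raw`,
#'   `mi_debiased`, `ci_low`, `ci_high`, `null_low`, `null_high`,
#'   `significant`.
#' @export
positional_mi_profile <- function(bouts, from = 1, max_pos = 8,
                                  n_boot = 2000, min_pairs = 20,
                                  conf = 0.95) {
  bouts <- as_bout_codes(bouts)
  out <- list()
  for (n in seq(from + 1, max_pos)) {
    pr <- pairs_at_positions(bouts, from, n)
    if (nrow(pr) < min_pairs) {
      out[[length(out) + 1L]] <- data.frame(
        position = n, n_pairs = nrow(pr), mi_raw = NA_real_,
        mi_debiased = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        null_low = NA_real_, null_high = NA_real_, significant = NA)
      next
    }
    est <- mi_with_null(bouts, position_pair_fun(from, n),
                        n_boot = n_boot, conf = conf)
    out[[length(out) + 1L]] <- data.frame(
      position = n, n_pairs = est$n, mi_raw = est$raw,
      mi_debiased = est$debiased, ci_low = est$ci[1], ci_high = est$ci[2],
      null_low = est$null_ci[1], null_high = est$null_ci[2],
      significant = est$significant)
  }
  do.call(rbind, out)
}

#' Positional mutual-information matrix
#'
#' Upper-triangular matrix of debiased MI between bout positions `m < n`,
#' with the positional entropy on the diagonal and per-cell significance
#' against the within-bout scrambled null. Only bouts of length at least
#' `n` contribute to cells involving position `n`.
#'
#' @inheritParams positional_mi_profile
#' @param max_pos Number of positions (matrix is `max_pos x max_pos`).
#' @return Object of class `positional_mi`: list with `mi` (matrix, bits;
#'   diagonal = entropies), `significant` (logical matrix), `n_pairs`,
#'   `profiles` (list of data frames per anchor).
#' @export
positional_mi <- function(bouts, max_pos = 6, n_boot = 2000,
                          min_pairs = 20, conf = 0.95) {
  bouts <- as_bout_codes(bouts)
  mi <- matrix(NA_real_, max_pos, max_pos)
  sig <- matrix(NA, max_pos, max_pos)
  npr <- matrix(0L, max_pos, max_pos)
  lens <- vapply(bouts, length, integer(1))
  for (m in seq_len(max_pos)) {
    at_m <- vapply(bouts[lens >= m], `[`, integer(1), m)
    if (length(at_m) >= min_pairs)
      mi[m, m] <- shannon_entropy(kt_estimate(tabulate(at_m, nbins = 5)))
    npr[m, m] <- length(at_m)
  }
  for (m in seq_len(max_pos - 1)) {
    prof <- positional_mi_profile(bouts, from = m, max_pos = max_pos,
                                  n_boot = n_boot, min_pairs = min_pairs,
                                  conf = conf)
    for (r in seq_len(nrow(prof))) {
      n <- prof$position[r]
      mi[m, n] <- prof$mi_debiased[r]
      sig[m, n] <- prof$significant[r]
      npr[m, n] <- prof$n_pairs[r]
    }
  }
  structure(list(mi = mi, significant = sig, n_pairs = npr,
                 max_pos = max_pos), class = "positional_mi")
}

#' @export
print.positional_mi <- function(x, ...) {
  cat("Positional MI matrix (bits; diagonal = entropy):\n")
  print(round(x$mi, 3))
  cat("Significant cells (vs scrambled null):\n")
  print(x$significant)
  invisible(x)
}

collect_ngrams <- function(bouts, n, mode = c("bout_start", "anywhere")) {
  mode <- match.arg(mode)
  out <- lapply(bouts, function(v) {
    if (length(v) < n) return(NULL)
    if (mode == "bout_start") return(matrix(v[seq_len(n)], nrow = 1))
    t(vapply(seq_len(length(v) - n + 1), function(i) v[i:(i + n - 1)],
             integer(n)))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- matrix(integer(0), ncol = n)
  out
}

ngram_names <- function(n) {
  if (n == 2) list(SYLLABLE_TYPES, SYLLABLE_TYPES)
  else list(as.vector(outer(SYLLABLE_TYPES, SYLLABLE_TYPES,
                            function(a, b) paste0(a, b))), SYLLABLE_TYPES)
}

joint_from_ngrams <- function(ng, n) {
  if (n == 2) {
    counts <- matrix(tabulate((ng[, 1] - 1L) * 5L + ng[, 2], nbins = 25),
                     nrow = 5, byrow = TRUE, dimnames = ngram_names(2))
  } else {
    cell <- ((ng[, 1] - 1L) * 5L + (ng[, 2] - 1L)) * 5L + ng[, 3]
    counts <- matrix(tabulate(cell, nbins = 125), nrow = 25, byrow = TRUE)
    nm <- ngram_names(3)
    # rows ordered first-type-major to match the tabulation above
    rownames(counts) <- as.vector(t(outer(SYLLABLE_TYPES, SYLLABLE_TYPES, paste0)))
    colnames(counts) <- nm[[2]]
  }
  counts
}

#' Pair (and triplet) transition joint distributions
#'
#' Counts successive syllable-type pairs either from the first two
#' positions of each bout (`bout_start`) or over all successive positions
#' within bouts (`anywhere`), and returns the Krichevsky-Trofimov smoothed
#' joint distribution. Per-cell significance (optional) marks cells whose
#' bootstrap confidence interval excludes the independent-marginals
#' expectation for that cell.
#'
#' @param bouts List of bouts or a [split_bouts()] data frame.
#' @param mode `"bout_start"` or `"anywhere"`.
#' @param significance Compute per-cell significance (default TRUE).
#' @param n_boot Bootstrap replicates for cell significance.
#' @param conf Confidence level.
#' @return List with `counts` (5x5), `prob` (KT-smoothed), `n`,
#'   `significant` (5x5 logical or NULL), `mode`.
#' @export
pair_joint <- function(bouts, mode = c("bout_start", "anywhere"),
                       significance = TRUE, n_boot = 2000, conf = 0.95) {
  mode <- match.arg(mode)
  bouts <- as_bout_codes(bouts)
  ng <- collect_ngrams(bouts, 2, mode)
  counts <- joint_from_ngrams(ng, 2)
  res <- list(counts = counts, prob = kt_estimate(counts), n = nrow(ng),
              significant = NULL, mode = mode)
  if (significance && nrow(ng) >= 2)
    res$significant <- cell_significance(ng, 2, n_boot, conf)
  res
}

#' @rdname pair_joint
#' @return For `triplet_joint`: the same structure with 25x5 matrices
#'   (rows = ordered first-two-type pairs, columns = third type).
#' @export
triplet_joint <- function(bouts, mode = c("bout_start", "anywhere"),
                          significance = TRUE, n_boot = 2000, conf = 0.95) {
  mode <- match.arg(mode)
  bouts <- as_bout_codes(bouts)
  ng <- collect_ngrams(bouts, 3, mode)
  counts <- joint_from_ngrams(ng, 3)
  res <- list(counts = counts, prob = kt_estimate(counts), n = nrow(ng),
              significant = NULL, mode = mode)
  if (significance && nrow(ng) >= 2)
    res$significant <- cell_significance(ng, 3, n_boot, conf)
  res
}

# bootstrap CI per cell probability; significant where the CI excludes the
# independence expectation (product of KT marginals over tuple positions)
cell_significance <- function(ng, n, n_boot, conf) {
  N <- nrow(ng)
  probs <- replicate(n_boot, {
    idx <- sample.int(N, N, replace = TRUE)
    kt_estimate(joint_from_ngrams(ng[idx, , drop = FALSE], n))
  })
  dim(probs) <- c(if (n == 2) 5 else 25, 5, n_boot)
  alpha <- (1 - conf) / 2
  lo <- apply(probs, c(1, 2), quantile, probs = alpha)
  hi <- apply(probs, c(1, 2), quantile, probs = 1 - alpha)
  marg <- lapply(seq_len(n), function(j) kt_estimate(tabulate(ng[, j], nbins = 5)))
  expect <- if (n == 2) {
    outer(marg[[1]], marg[[2]])
  } else {
    # rows are first-type-major: tuple (i,j) sits in row (i-1)*5 + j
    outer(as.vector(t(outer(marg[[1]], marg[[2]]))), marg[[3]])
  }
  sig <- expect < lo | expect > hi
  dimnames(sig) <- dimnames(joint_from_ngrams(ng, n))
  sig
}

#' Pairwise divergence matrix between group distributions
#'
#' Debiased Kullback-Leibler divergence between every ordered pair of
#' groups' syllable(-tuple) samples, with bootstrap confidence intervals
#' and significance (interval excluding zero).
#'
#' @param samples Named list: per group, an integer vector of observed
#'   cells (type codes, or tuple codes over a product alphabet).
#' @param n_cells Number of support cells (5 for single types, 25 for
#'   pairs, 125 for triplets).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @return List with `kld` (matrix, rows = p, cols = q), `significant`
#'   (logical matrix), `ci_low`, `ci_high`.
#' @export
group_kld_matrix <- function(samples, n_cells = 5, n_boot = 2000, conf = 0.95) {
  gs <- names(samples)
  k <- length(gs)
  m <- matrix(NA_real_, k, k, dimnames = list(gs, gs))
  sig <- matrix(NA, k, k, dimnames = list(gs, gs))
  lo <- m; hi <- m
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { m[i, j] <- 0; sig[i, j] <- FALSE; next }
    est <- kld_debiased(samples[[i]], samples[[j]], n_cells = n_cells,
                        n_boot = n_boot, conf = conf)
    m[i, j] <- est$debiased
    sig[i, j] <- est$significant
    lo[i, j] <- est$ci[1]; hi[i, j] <- est$ci[2]
  }
  list(kld = m, significant = sig, ci_low = lo, ci_high = hi)
}

#' Encode syllable tuples over the product alphabet
#'
#' Maps bout-start pairs or triplets to integer codes (1..25 or 1..125)
#' for use with [group_kld_matrix()].
#'
#' @param bouts List of bouts or [split_bouts()] data frame.
#' @param n Tuple length (1, 2 or 3).
#' @param mode `"bout_start"` or `"anywhere"`.
#' @return Integer vector.
#' @export
encode_tuples <- function(bouts, n = 1, mode = "bout_start") {
  bouts <- as_bout_codes(bouts)
  if (n == 1) return(unlist(bouts, use.names = FALSE))
  ng <- collect_ngrams(bouts, n, mode)
  code <- ng[, 1]
  for (j in seq_len(n - 1)) code <- (code - 1L) * 5L + ng[, j + 1]
  code
}

#' Extract syllable sequences produced above chance
#'
#' Breadth-first search over bout prefixes. At position 1 every type's
#' probability of occurrence at bout starts is tested against its overall
#' probability of occurrence; types whose bootstrap lower confidence bound
#' exceeds the overall probability are significant. Each significant type
#' becomes a prefix: among bouts matching the prefix, the conditional
#' probability of every type at the next position is tested the same way,
#' and the search continues until no type is significant or too few bouts
#' match the prefix. All maximal significant sequences are returned.
#'
#' @param bouts List of bouts or [split_bouts()] data frame.
#' @param overall_dist Overall probability of occurrence of each of the 5
#'   types for the same group (defaults to the pooled distribution over
#'   all syllables in `bouts`).
#' @param n_boot Bootstrap replicates on the conditional proportion.
#' @param conf Confidence level (one-sided, higher).
#' @param min_prefix_count Minimum number of bouts matching a prefix for
#'   the branch to be extended (default 10).
#' @param max_len Safety cap on sequence length.
#' @return List of character vectors (sequences of type labels), each with
#'   attribute `n_bouts` (bouts matching the full sequence). Empty list
#'   when nothing is significant.
#' @export
extract_significant_sequences <- function(bouts, overall_dist = NULL,
                                          n_boot = 2000, conf = 0.95,
                                          min_prefix_count = 10,
                                          max_len = 12) {
  bouts <- as_bout_codes(bouts)
  if (is.null(overall_dist)) {
    allsyl <- unlist(bouts, use.names = FALSE)
    overall_dist <- kt_estimate(tabulate(allsyl, nbins = 5))
  }
  stopifnot(length(overall_dist) == 5)
  alpha <- 1 - conf
  sig_next <- function(prefix) {
    pos <- length(prefix) + 1L
    match_pref <- vapply(bouts, function(v)
      length(v) >= pos && all(v[seq_along(prefix)] == prefix), logical(1))
    cand <- bouts[match_pref]
    if (length(cand) < min_prefix_count) return(integer(0))
    nxt <- vapply(cand, `[`, integer(1), pos)
    n <- length(nxt)
    found <- integer(0)
    for (ty in 1:5) {
      phat <- mean(nxt == ty)
      if (phat <= overall_dist[ty]) next
      reps <- vapply(seq_len(n_boot), function(b)
        mean(nxt[sample.int(n, n, replace = TRUE)] == ty), numeric(1))
      if (quantile(reps, alpha) > overall_dist[ty]) found <- c(found, ty)
    }
    found
  }
  results <- list()
  grow <- function(prefix) {
    nxt <- if (length(prefix) >= max_len) integer(0) else sig_next(prefix)
    if (!length(nxt)) {
      if (length(prefix) > 0) {
        seq_lab <- SYLLABLE_TYPES[prefix]
        n_match <- sum(vapply(bouts, function(v)
          length(v) >= length(prefix) &&
            all(v[seq_along(prefix)] == prefix), logical(1)))
        attr(seq_lab, "n_bouts") <- n_match
        results[[length(results) + 1L]] <<- seq_lab
      }
      return(invisible())
    }
    for (ty in nxt) grow(c(prefix, ty))
  }
  grow(integer(0))
  results
}
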