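# Correlation-distance clustering of pups by their syllable-type (or
# transition) distributions, reference-calibrated cluster cut, cluster-
# level divergence re-analysis, and a litter-association check.

#' Correlation distance between two distributions
#'
#' `1 - rho`, with `rho` the Pearson correlation between the two vectors;
#' ranges over \[0, 2\]. Computed on the raw occurrence probabilities (no
#' smoothing) because zero cells are themselves informative for clustering.
#'
#' @param a,b Equal-length numeric vectors (probability vectors, or
#'   flattened pair/triplet joints).
#' @return Distance in \[0, 2\].
#' @export
correlation_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance distribution: correlation undefined")
  1 - cor(a, b)
}

#' Per-pup distribution matrix
#'
#' Rows are pups, columns the probability of each syllable type (or each
#' tuple cell when `n > 1`).
#'
#' @param syllables [split_bouts()] data frame (needs `pup_id`, `bout`,
#'   type column).
#' @param n Tuple length: 1 for single-type distributions, 2/3 for
#'   bout-start pair/triplet joints (flattened).
#' @param type_col Type-label column.
#' @param mode Tuple mode for `n > 1`.
#' @return Matrix (pups x cells), rows summing to 1; attribute `litter`
#'   carries per-pup litter tags when present in the input.
#' @export
pup_distributions <- function(syllables, n = 1, type_col = "type",
                              mode = "bout_start") {
  pups <- split(syllables, syllables$pup_id)
  n_cells <- 5L^n
  m <- t(vapply(pups, function(d) {
    codes <- if (n == 1) type_codes(d[[type_col]])
    else encode_tuples(bout_sequences(d, type_col), n, mode)
    cnt <- tabulate(codes, nbins = n_cells)
    if (sum(cnt) == 0) rep(NA_real_, n_cells) else cnt / sum(cnt)
  }, numeric(n_cells)))
  rownames(m) <- names(pups)
  if ("litter" %in% names(syllables))
    attr(m, "litter") <- vapply(pups, function(d) as.character(d$litter[1]),
                                character(1))
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Agglomerative clustering of pups on correlation distance
#'
#' Builds a dendrogram by successively merging the minimally distant
#' distributions under the chosen linkage (default average/UPGMA, which is
#' monotone for correlation distances). Ties on merge distance are broken
#' by `stats::hclust`'s deterministic ordering (lowest leaf indices first).
#'
#' @param dists Matrix of per-pup distributions ([pup_distributions()]),
#'   or a `dist` object.
#' @param linkage One of `"average"`, `"single"`, `"complete"`.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return Object of class `pup_tree`: the `hclust` object plus `labels`
#'   and `litter`.
#' @export
build_tree <- function(dists, linkage = c("average", "single", "complete"),
                       method = c("pearson", "spearman")) {
  linkage <- match.arg(linkage)
  method <- match.arg(method)
  if (inherits(dists, "dist")) {
    d <- dists
    litter <- NULL
  } else {
    stopifnot(nrow(dists) >= 2)
    if (any(apply(dists, 1, sd) == 0))
      stop("zero-variance distribution for pup(s): ",
           paste(rownames(dists)[apply(dists, 1, sd) == 0], collapse = ", "))
    d <- as.dist(1 - cor(t(dists), method = method))
    litter <- attr(dists, "litter")
  }
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, labels = hc$labels, litter = litter,
                 linkage = linkage), class = "pup_tree")
}

#' @export
print.pup_tree <- function(x, ...) {
  cat(sprintf("pup_tree: %d leaves, %s linkage, max merge height %.4f\n",
              length(x$labels), x$linkage, max(x$hclust$height)))
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Leaf names are `pup_id|litter` when litter tags are available.
#'
#' @param tree A `pup_tree`.
#' @param path Optional file to write to.
#' @return Newick string, invisibly when written to file.
#' @export
tree_newick <- function(tree, path = NULL) {
  hc <- tree$hclust
  if (!is.null(tree$litter))
    hc$labels <- paste(hc$labels, tree$litter[hc$labels], sep = "|")
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut trees at the reference group's maximum merge height
#'
#' The maximum merge distance observed in the reference group's dendrogram
#' (the wild-type-male analogue, which merges into a single cluster by
#' construction) becomes the cluster threshold for every other group's
#' tree. Clusters of size 1 are flagged: single animals carry too little
#' data for downstream divergence analysis and are excluded there.
#'
#' @param trees Named list of `pup_tree`s, one per group.
#' @param reference Name of the reference group (default `"WTM"`).
#' @return Data frame with `pup_id`, `group`, `cluster` (labelled
#'   `<group>(C1)`, `<group>(C2)`, ... by decreasing size), `singleton`;
#'   attribute `threshold` holds the cut height.
#' @export
cut_by_reference <- function(trees, reference = "WTM") {
  if (!reference %in% names(trees))
    stop("reference group '", reference, "' not among trees")
  ref <- trees[[reference]]
  if (length(ref$labels) < 2) stop("reference group has fewer than 2 pups")
  thr <- max(ref$hclust$height)
  out <- do.call(rbind, lapply(names(trees), function(g) {
    hc <- trees[[g]]$hclust
    cl <- cutree(hc, h = thr)
    sizes <- sort(table(cl), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(sizes), names(sizes))
    cl <- relabel[as.character(cl)]
    data.frame(pup_id = hc$labels, group = g,
               cluster = sprintf("%s(C%d)", g, cl),
               singleton = as.vector(table(cl)[as.character(cl)] == 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Divergence matrix between clusters
#'
#' Pools each non-singleton cluster's syllable observations and delegates
#' to [group_kld_matrix()]: debiased Kullback-Leibler divergence with
#' bootstrap significance for every cluster pair.
#'
#' @param syllables Cohort data frame with `pup_id` and a type column.
#' @param assignment Output of [cut_by_reference()].
#' @param type_col Type-label column.
#' @param n_boot,conf Bootstrap settings.
#' @return As [group_kld_matrix()], clusters ordered as first encountered;
#'   singletons omitted.
#' @export
cluster_kld <- function(syllables, assignment, type_col = "type",
                        n_boot = 2000, conf = 0.95) {
  keep <- assignment[!assignment$singleton, ]
  samples <- lapply(split(keep$pup_id, keep$cluster), function(pids) {
    type_codes(syllables[[type_col]][syllables$pup_id %in% pids])
  })
  samples <- samples[vapply(samples, length, integer(1)) > 0]
  group_kld_matrix(samples, n_cells = 5, n_boot = n_boot, conf = conf)
}

#' Litter composition of clusters and association test
#'
#' Cross-tabulates cluster membership against litter identity and runs a
#' label-permutation test of association (permuting litter labels across
#' pups, comparing Cramer's V). A non-significant association supports the
#' conclusion that cluster structure is not litter specific. This test is
#' an extension beyond visual inspection of the dendrograms.
#'
#' @param assignment Output of [cut_by_reference()] restricted to one
#'   group (or any data frame with `pup_id`, `cluster`).
#' @param litters Named character vector: litter tag per pup id.
#' @param n_perm Number of permutations.
#' @return List with `table` (cluster x litter), `cramers_v`, `p_value`
#'   (NA with a message when only one litter or one cluster is present).
#' @export
litter_effect_report <- function(assignment, litters, n_perm = 1000) {
  lit <- litters[assignment$pup_id]
  cl <- assignment$cluster
  tab <- table(cluster = cl, litter = lit)
  cram <- function(t) {
    t <- as.matrix(t)
    n <- sum(t)
    chi <- suppressWarnings(stats::chisq.test(t, correct = FALSE)$statistic)
    k <- min(nrow(t), ncol(t)) - 1
    if (k == 0 || n == 0) return(NA_real_)
    sqrt(as.numeric(chi) / (n * k))
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(table = tab, cramers_v = NA_real_, p_value = NA_real_,
                note = "association test undefined: need >= 2 clusters and >= 2 litters"))
  v_obs <- cram(tab)
  v_perm <- vapply(seq_len(n_perm), function(b)
    cram(table(cl, sample(lit))), numeric(1))
  list(table = tab, cramers_v = v_obs,
       p_value = (1 + sum(v_perm >= v_obs)) / (1 + n_perm))
}
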