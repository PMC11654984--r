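# Chance-adjusted partition-agreement metrics computed from the contingency
# table, plus the k-means harness and the simulation-fidelity score.

as_partition <- function(x) {
  x <- as.vector(x)
  if (length(x) < 1) stop("empty partition")
  as.integer(factor(x))
}

check_pair <- function(p, t) {
  if (length(p) != length(t)) stop("partitions have different lengths")
}

#' K-means clustering of a cell embedding
#'
#' Runs `stats::kmeans` with `n_init` seeded restarts (best within-cluster
#' sum of squares kept), the protocol used to score dimension-reduction
#' quality.
#'
#' @param z numeric matrix (cells x dimensions) or a `cell_embedding`.
#' @param k number of clusters (typically the number of cell types).
#' @param n_init number of random restarts (default 30).
#' @param seed integer seed.
#' @return integer vector of cluster assignments (1..k).
#' @export
cluster_embedding <- function(z, k, n_init = 30, seed = 1) {
  if (inherits(z, "cell_embedding")) z <- z$z
  z <- as.matrix(z)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(z)) stop("k exceeds the number of cells")
  set.seed(seed)
  fit <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
  as.integer(fit$cluster)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted for chance under
#' the hypergeometric permutation model: 1 for identical partitions, about 0
#' for random assignment, can be negative.
#'
#' @param p,t label vectors of equal length (any label type).
#' @return scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(p, t) {
  p <- as_partition(p); t <- as_partition(t)
  check_pair(p, t)
  n <- length(p)
  if (n < 2) stop("need at least 2 observations")
  tab <- table(p, t)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  -sum(counts / n * log(counts / n))
}

mutual_info_tab <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  nz <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[nz]
  sum(nij / n * log(n * nij / (a[nz[, 1]] * b[nz[, 2]])))
}

#' Normalized mutual information
#'
#' `I(P, T) / max(H(P), H(T))` with natural-log entropies. Two identical
#' single-cluster partitions score 1; if exactly one partition is a single
#' cluster the score is 0.
#'
#' @param p,t label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
normalized_mutual_information <- function(p, t) {
  p <- as_partition(p); t <- as_partition(t)
  check_pair(p, t)
  tab <- table(p, t)
  hp <- entropy_counts(rowSums(tab))
  ht <- entropy_counts(colSums(tab))
  if (hp == 0 && ht == 0) return(1)   # both single-cluster: identical
  if (hp == 0 || ht == 0) return(0)
  mutual_info_tab(tab) / max(hp, ht)
}

# Exact expected mutual information under the hypergeometric model of random
# labelings with fixed marginals.
expected_mutual_info <- function(a, b, n) {
  emi <- 0
  lf <- lfactorial
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_p <- lf(ai) + lf(bj) + lf(n - ai) + lf(n - bj) - lf(n) -
        lf(nij) - lf(ai - nij) - lf(bj - nij) - lf(n - ai - bj + nij)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(log_p))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' `(I - E[I]) / (max(H(P), H(T)) - E[I])` with the exact hypergeometric
#' expected mutual information; about 0 for random labelings, 1 for identical
#' partitions. Degenerate single-cluster cases follow the same convention as
#' [normalized_mutual_information()].
#'
#' @param p,t label vectors of equal length.
#' @return scalar <= 1.
#' @export
adjusted_mutual_information <- function(p, t) {
  p <- as_partition(p); t <- as_partition(t)
  check_pair(p, t)
  tab <- table(p, t)
  a <- rowSums(tab); b <- colSums(tab)
  hp <- entropy_counts(a)
  ht <- entropy_counts(b)
  if (hp == 0 && ht == 0) return(1)
  if (hp == 0 || ht == 0) return(0)
  i_pt <- mutual_info_tab(tab)
  emi <- expected_mutual_info(a, b, sum(tab))
  denom <- max(hp, ht) - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (i_pt - emi) / denom
}

#' Classification accuracy
#'
#' Overall fraction of correct predictions, optionally with per-class recall
#' (fraction of each true class recovered).
#'
#' @param pred,truth label vectors of equal length.
#' @param per_class if `TRUE`, also return a per-class recall table.
#' @return scalar, or `list(overall, per_class)` when `per_class = TRUE`.
#' @export
classification_accuracy <- function(pred, truth, per_class = FALSE) {
  if (length(pred) == 0) stop("empty input")
  check_pair(pred, truth)
  pred <- as.character(pred); truth <- as.character(truth)
  overall <- mean(pred == truth)
  if (!per_class) return(overall)
  classes <- sort(unique(truth))
  recall <- vapply(classes, function(cl) mean(pred[truth == cl] == cl), 0)
  list(overall = overall,
       per_class = data.frame(cell_type = classes, recall = unname(recall),
                              n = as.vector(table(factor(truth, classes)))))
}

#' Simulation fidelity between real and simulated expression
#'
#' Takes the union of the top-`n_top` highly variable features of the real
#' and of the simulated matrix and reports the Pearson correlation of
#' per-feature mean expression between the two over that union, together with
#' the per-feature means for plotting.
#'
#' @param real,sim [omics_matrix()] objects (or plain matrices with column
#'   names) on a shared feature vocabulary, normalized scale.
#' @param n_top number of highly variable features per matrix (default 100).
#' @return list with `pearson`, `features` (the HVG union) and `per_gene`
#'   (data.frame: feature, real_mean, sim_mean).
#' @export
simulation_fidelity <- function(real, sim, n_top = 100) {
  get_vals <- function(x) if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  r <- get_vals(real); s <- get_vals(sim)
  shared <- intersect(colnames(r), colnames(s))
  if (length(shared) < 3) stop("fewer than 3 shared features")
  r <- r[, shared, drop = FALSE]; s <- s[, shared, drop = FALSE]
  top <- function(m) {
    k <- min(n_top, ncol(m))
    colnames(m)[order(hvg_score(m), decreasing = TRUE)[seq_len(k)]]
  }
  feats <- union(top(r), top(s))
  if (length(feats) < 3) stop("fewer than 3 highly variable features")
  rm_ <- colMeans(r[, feats, drop = FALSE])
  sm_ <- colMeans(s[, feats, drop = FALSE])
  list(pearson = stats::cor(rm_, sm_),
       features = feats,
       per_gene = data.frame(feature = feats, real_mean = unname(rm_),
                             sim_mean = unname(sm_)))
}

#' Clustering/classification metrics report
#'
#' Convenience wrapper computing ARI, NMI and AMI between a predicted and a
#' reference partition (and accuracy when both are label vectors over the
#' same vocabulary).
#'
#' @param pred,truth label vectors.
#' @param accuracy include classification accuracy (labels comparable).
#' @return named list of metric values.
#' @export
metrics_report <- function(pred, truth, accuracy = FALSE) {
  out <- list(ari = adjusted_rand_index(pred, truth),
              nmi = normalized_mutual_information(pred, truth),
              ami = adjusted_mutual_information(pred, truth))
  if (accuracy) out$accuracy <- classification_accuracy(pred, truth)
  out
}
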