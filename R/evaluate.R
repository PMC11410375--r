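# Evaluation protocol: Leiden clustering of the joint embedding, external
# agreement metrics over a resolution sweep, Robust Rank Aggregation, and
# graded Gaussian-noise perturbation.

#' Cluster a joint embedding with Leiden
#'
#' kNN graph on the embedding, Leiden with modularity objective.
#' Deterministic given `seed`.
#'
#' @param Z embedding matrix (cells in rows).
#' @param resolution Leiden resolution.
#' @param seed RNG seed.
#' @param n_neighbors kNN budget for the substrate graph (default 15).
#' @return integer cluster labels.
#' @export
cluster_embedding <- function(Z, resolution = 1, seed = 1, n_neighbors = 15) {
  leiden_labels(Z, resolution = resolution, seed = seed,
                n_neighbors = n_neighbors)
}

check_labels <- function(pred, truth) {
  if (length(pred) != length(truth) || !length(pred)) {
    stop("pred and truth must be non-empty and of equal length", call. = FALSE)
  }
}

contingency <- function(pred, truth) {
  table(factor(pred), factor(truth))
}

entropy_counts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Clustering purity
#'
#' Fraction of cells assigned to the majority ground-truth class of their
#' predicted cluster.
#'
#' @param pred,truth label vectors of equal length.
#' @return value in (0, 1].
#' @export
purity_score <- function(pred, truth) {
  check_labels(pred, truth)
  tab <- contingency(pred, truth)
  sum(apply(tab, 1L, max)) / length(pred)
}

#' Homogeneity score
#'
#' `1 - H(truth | pred) / H(truth)`; 1 when every predicted cluster contains
#' a single ground-truth class, and by convention 1 when the ground truth
#' itself has a single class.
#'
#' @param pred,truth label vectors of equal length.
#' @return value in \[0, 1\].
#' @export
homogeneity_score <- function(pred, truth) {
  check_labels(pred, truth)
  tab <- contingency(pred, truth)
  n <- length(pred)
  h_truth <- entropy_counts(colSums(tab))
  if (h_truth == 0) return(1)
  h_cond <- sum(vapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (sum(row) == 0) return(0)
    sum(row) / n * entropy_counts(row)
  }, numeric(1)))
  1 - h_cond / h_truth
}

#' Adjusted Rand index
#'
#' Pair-counting agreement corrected for chance:
#' `(Index - E[Index]) / (Max - E[Index])`.
#'
#' @param pred,truth label vectors of equal length.
#' @return value in \[-1, 1\]; 1 iff the partitions are identical up to
#'   relabelling.
#' @export
ari_score <- function(pred, truth) {
  check_labels(pred, truth)
  tab <- contingency(pred, truth)
  n <- length(pred)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Normalised mutual information
#'
#' `I(pred; truth)` normalised by a mean of the two entropies.  The default
#' arithmetic mean matches the common convention; geometric, min and max
#' normalisations are selectable.  Returns 0 when either partition carries
#' no information.
#'
#' @param pred,truth label vectors of equal length.
#' @param average `"arithmetic"` (default), `"geometric"`, `"min"` or
#'   `"max"`.
#' @return value in \[0, 1\].
#' @export
nmi_score <- function(pred, truth,
                      average = c("arithmetic", "geometric", "min", "max")) {
  average <- match.arg(average)
  check_labels(pred, truth)
  tab <- contingency(pred, truth)
  n <- length(pred)
  hp <- entropy_counts(rowSums(tab))
  ht <- entropy_counts(colSums(tab))
  if (hp == 0 || ht == 0) {
    if (hp == 0 && ht == 0) return(1)  # both single-class: identical
    return(0)
  }
  p <- tab / n
  pr <- rowSums(tab) / n
  pt <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pr[i] * pt[j]))
  }
  denom <- switch(average,
                  arithmetic = (hp + ht) / 2,
                  geometric = sqrt(hp * ht),
                  min = min(hp, ht),
                  max = max(hp, ht))
  unname(as.numeric(mi / denom))
}

#' Robust Rank Aggregation p-values
#'
#' For each method (row), its ranks across ranking lists (columns) are
#' normalised by the number of methods and sorted ascending; the k-th order
#' statistic is compared against its null Beta(k, K - k + 1) distribution
#' (K = number of lists), the minimum tail probability is taken, and a
#' Bonferroni factor K is applied, capped at 1.
#'
#' @param ranks methods x lists numeric matrix; each column must be a
#'   (possibly tie-averaged) permutation of `1..nrow(ranks)`.
#' @return named numeric vector of p-values, one per method.
#' @export
rra_pvalues <- function(ranks) {
  ranks <- as_dense_matrix(ranks, "ranks")
  n_methods <- nrow(ranks)
  K <- ncol(ranks)
  if (n_methods < 2L || K < 1L) {
    stop("need >= 2 methods and >= 1 ranking list", call. = FALSE)
  }
  csum <- colSums(ranks)
  if (any(abs(csum - n_methods * (n_methods + 1) / 2) > 1e-8)) {
    stop("each column must be a permutation of 1..n_methods (ties averaged)",
         call. = FALSE)
  }
  r <- ranks / n_methods
  p <- apply(r, 1L, function(x) {
    x <- sort(x)
    beta <- pbeta(x, seq_len(K), K - seq_len(K) + 1)
    min(1, min(beta) * K)
  })
  names(p) <- rownames(ranks)
  p
}

#' Add graded Gaussian noise to a normalised matrix
#'
#' Adds `Normal(0, (level/100 * s_j)^2)` noise to feature j, where `s_j` is
#' that feature's standard deviation — so "level 10" perturbs every feature
#' by 10% of its own spread.  Deterministic given `seed`.
#'
#' @param X normalised matrix (cells x features).
#' @param level_percent noise level in percent, >= 0.
#' @param seed RNG seed.
#' @return matrix of identical shape.
#' @export
add_gaussian_noise <- function(X, level_percent, seed = 1) {
  X <- as_dense_matrix(X, "X")
  if (!is.numeric(level_percent) || length(level_percent) != 1L ||
      level_percent < 0) {
    stop("level_percent must be a non-negative scalar", call. = FALSE)
  }
  if (level_percent == 0) return(X)
  s <- apply(X, 2L, sd)
  noise <- with_seed(seed, {
    matrix(rnorm(length(X)), nrow(X), ncol(X)) *
      rep(level_percent / 100 * s, each = nrow(X))
  })
  X + noise
}

#' Metric sweep over Leiden resolutions
#'
#' Clusters the embedding at each resolution and scores Purity, Homogeneity,
#' ARI and NMI against the ground truth.
#'
#' @param Z embedding matrix.
#' @param truth ground-truth labels.
#' @param resolutions numeric vector (default 0.1, 0.2, ..., 1.0).
#' @param seed RNG seed for the clustering.
#' @param n_neighbors kNN budget for the clustering substrate.
#' @return data.frame of class `duogate_metrics` with one row per
#'   resolution and columns `resolution`, `n_clusters`, `purity`,
#'   `homogeneity`, `ari`, `nmi`; attribute `"summary"` holds mean and sd
#'   per metric.
#' @export
sweep_and_report <- function(Z, truth, resolutions = seq(0.1, 1, by = 0.1),
                             seed = 1, n_neighbors = 15) {
  Z <- as_dense_matrix(Z, "Z")
  check_labels(truth, truth)
  rows <- lapply(resolutions, function(r) {
    pred <- cluster_embedding(Z, resolution = r, seed = seed,
                              n_neighbors = n_neighbors)
    data.frame(resolution = r, n_clusters = length(unique(pred)),
               purity = purity_score(pred, truth),
               homogeneity = homogeneity_score(pred, truth),
               ari = ari_score(pred, truth),
               nmi = nmi_score(pred, truth))
  })
  out <- do.call(rbind, rows)
  metr <- c("purity", "homogeneity", "ari", "nmi")
  attr(out, "summary") <- data.frame(
    metric = metr,
    mean = vapply(metr, function(mm) mean(out[[mm]]), numeric(1)),
    sd = vapply(metr, function(mm) sd(out[[mm]]), numeric(1)))
  class(out) <- c("duogate_metrics", "data.frame")
  out
}

#' @export
print.duogate_metrics <- function(x, ...) {
  cat("Clustering agreement over a Leiden resolution sweep\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("\nSummary (mean +/- sd over resolutions):\n")
  s <- attr(x, "summary")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
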