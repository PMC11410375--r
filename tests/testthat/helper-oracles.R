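# Brute-force reference implementations used as independent oracles.
# Everything here is written as plain scalar loops, deliberately sharing no
# code path with the package.

# O(m^2) scalar pairwise Euclidean distances
oracle_pairwise <- function(X) {
  m <- nrow(X)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    s <- 0
    for (k in seq_len(ncol(X))) s <- s + (X[i, k] - X[j, k])^2
    D[i, j] <- sqrt(s)
  }
  D
}

# full graph construction: kNN (ties by index), label pruning, W = D * B
oracle_graph <- function(X, n, labels) {
  m <- nrow(X)
  D <- oracle_pairwise(X)
  B <- matrix(0, m, m)
  for (i in seq_len(m)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(n)]
    for (j in nb) if (labels[j] == labels[i]) B[i, j] <- 1
  }
  list(D = D, B = B, W = D * B)
}

# dense per-cell loop implementation of the graph attention layer
oracle_gat <- function(H, B, params, attention, act, slope = 0.2) {
  m <- nrow(H)
  G <- H %*% params$W + matrix(params$b, m, length(params$b), byrow = TRUE)
  out <- matrix(0, m, ncol(G))
  for (i in seq_len(m)) {
    nb <- c(which(B[i, ] != 0), i)   # neighbourhood plus self-loop
    nb <- sort(unique(nb))
    if (attention) {
      e <- numeric(length(nb))
      for (q in seq_along(nb)) {
        j <- nb[q]
        raw <- sum(params$a_src * G[i, ]) + sum(params$a_dst * G[j, ])
        e[q] <- if (raw > 0) raw else slope * raw
      }
      a <- exp(e - max(e)); a <- a / sum(a)
    } else {
      a <- rep(1 / length(nb), length(nb))
    }
    acc <- numeric(ncol(G))
    for (q in seq_along(nb)) acc <- acc + a[q] * G[nb[q], ]
    out[i, ] <- switch(act, relu = pmax(acc, 0), tanh = tanh(acc),
                       linear = acc)
  }
  out
}

# contingency table by loops
oracle_contingency <- function(pred, truth) {
  pu <- sort(unique(pred)); tu <- sort(unique(truth))
  tab <- matrix(0L, length(pu), length(tu))
  for (i in seq_along(pred)) {
    tab[match(pred[i], pu), match(truth[i], tu)] <-
      tab[match(pred[i], pu), match(truth[i], tu)] + 1L
  }
  tab
}

oracle_purity <- function(pred, truth) {
  tab <- oracle_contingency(pred, truth)
  s <- 0
  for (i in seq_len(nrow(tab))) s <- s + max(tab[i, ])
  s / length(pred)
}

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

oracle_homogeneity <- function(pred, truth) {
  tab <- oracle_contingency(pred, truth)
  n <- length(pred)
  ht <- oracle_entropy(colSums(tab))
  if (ht == 0) return(1)
  hc <- 0
  for (i in seq_len(nrow(tab))) {
    if (sum(tab[i, ]) > 0) hc <- hc + sum(tab[i, ]) / n * oracle_entropy(tab[i, ])
  }
  1 - hc / ht
}

# ARI by enumerating every pair of items
oracle_ari <- function(pred, truth) {
  n <- length(pred)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- pred[i] == pred[j]; st <- truth[i] == truth[j]
    if (sp && st) n11 <- n11 + 1
    else if (!sp && !st) n00 <- n00 + 1
    else if (sp && !st) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  idx <- n11
  a <- n11 + n10; b <- n11 + n01
  np <- n * (n - 1) / 2
  exp_idx <- a * b / np
  max_idx <- (a + b) / 2
  if (max_idx == exp_idx) return(1)
  (idx - exp_idx) / (max_idx - exp_idx)
}

oracle_nmi <- function(pred, truth) {
  tab <- oracle_contingency(pred, truth)
  n <- length(pred)
  hp <- oracle_entropy(rowSums(tab)); ht <- oracle_entropy(colSums(tab))
  if (hp == 0 && ht == 0) return(1)
  if (hp == 0 || ht == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij * n^2 / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi / ((hp + ht) / 2)
}

# small paired fixture shared by several files (cheap, well separated)
make_small_sim <- function(seed = 42, m = 150, k = 3) {
  simulate_multiomics(m = m, k = k, n_genes = 60, n_proteins = 15,
                      seed = seed)
}

# random partition labels
random_labels <- function(n, k) sample.int(k, n, replace = TRUE)
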