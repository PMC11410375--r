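test_that("pairwise_euclidean matches the scalar double-loop oracle", {
  expect_equal(pairwise_euclidean(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4)
  D <- pairwise_euclidean(X)
  expect_equal(D, oracle_pairwise(X), tolerance = 1e-12)
  expect_equal(diag(D), rep(0, 10))
  expect_equal(D, t(D))
  expect_error(pairwise_euclidean(matrix(c(1, Inf), 1, 2)), "non-finite")
})

test_that("knn_sets returns the n closest cells with index tie-breaking", {
  # 1-D points at 0, 1, 2, 10
  D <- pairwise_euclidean(cbind(c(0, 1, 2, 10)))
  nb <- knn_sets(D, 2)
  expect_setequal(nb[[1]], c(2L, 3L))
  # exhaustive case n = m - 1
  nb3 <- knn_sets(D, 3)
  for (i in 1:4) expect_setequal(nb3[[i]], setdiff(1:4, i))
  # three equidistant points: tie resolved to the lowest index
  Deq <- matrix(1, 3, 3) - diag(3)
  expect_equal(knn_sets(Deq, 1)[[1]], 2L)
  expect_equal(knn_sets(Deq, 1)[[2]], 1L)
  expect_error(knn_sets(D, 4), "n must satisfy")
  expect_error(knn_sets(D, 0), "n must satisfy")
})

test_that("leiden_labels separates distant clouds and is deterministic", {
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
             matrix(rnorm(60, 20, 0.1), 30, 2))
  lab <- leiden_labels(X, resolution = 1, seed = 5)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(ari_score(lab, rep(1:2, each = 30)), 1)
  expect_identical(lab, leiden_labels(X, resolution = 1, seed = 5))
  # near-zero resolution on one connected blob: a single community
  blob <- matrix(rnorm(80), 40, 2)
  expect_equal(length(unique(leiden_labels(blob, resolution = 0.01,
                                           seed = 1))), 1L)
  expect_equal(leiden_labels(blob[1, , drop = FALSE]), 1L)
})

test_that("prune_neighbors keeps only same-label neighbours, order preserved", {
  sets <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  # single label: identity
  expect_equal(prune_neighbors(sets, c(1, 1, 1)), sets)
  # all neighbours in other communities: empty sets
  expect_equal(lengths(prune_neighbors(sets, c(1, 2, 3))), c(0L, 0L, 0L))
  # mixed 6-cell toy against a per-cell filter
  set.seed(12)
  sets6 <- knn_sets(pairwise_euclidean(matrix(rnorm(12), 6, 2)), 3)
  lab6 <- c(1, 1, 2, 2, 1, 2)
  pruned <- prune_neighbors(sets6, lab6)
  for (i in 1:6) {
    expect_equal(pruned[[i]], Filter(function(j) lab6[j] == lab6[i],
                                     sets6[[i]]))
  }
  expect_error(prune_neighbors(sets, c(1, NA, 2)), "missing")
})

test_that("assemble_graph builds W = D * B with zero diagonal", {
  set.seed(13)
  X <- matrix(rnorm(40), 20, 2)
  D <- pairwise_euclidean(X)
  lab <- random_labels(20, 3)
  g <- assemble_graph(D, prune_neighbors(knn_sets(D, 4), lab), labels = lab)
  ora <- oracle_graph(X, 4, lab)
  expect_equal(as.matrix(g$B), ora$B, ignore_attr = TRUE)
  expect_equal(as.matrix(g$W), ora$W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(as.matrix(g$W)), rep(0, 20))
  # W > 0 iff B = 1 and d > 0
  expect_true(all((as.matrix(g$W) > 0) == (ora$B == 1 & ora$D > 0)))
  expect_true(all(Matrix::rowSums(g$B) <= 4))
  expect_error(assemble_graph(D, list(c(25L))), "mismatch|range")
})

test_that("graph pipeline matches the O(m^2) brute force on random instances", {
  for (rep in 1:20) {
    set.seed(100 + rep)
    m <- 50
    X <- matrix(rnorm(m * 3), m, 3)
    n <- sample(3:8, 1)
    lab <- random_labels(m, sample(2:4, 1))
    D <- pairwise_euclidean(X)
    g <- assemble_graph(D, prune_neighbors(knn_sets(D, n), lab))
    ora <- oracle_graph(X, n, lab)
    expect_equal(as.matrix(g$B), ora$B, label = sprintf("rep %d B", rep),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(g$W), ora$W, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("single-cell graphs are cluster-respecting and modality-specific", {
  sim <- simulate_multiomics(seed = 21)   # default desk-scale fixture
  rn <- select_hvg(normalize_rna(sim$rna), 2000)
  pr <- clr_protein(sim$protein)
  red <- suppressWarnings(pca_reduce(rn, 200))
  # pruning resolution 1.0 here: at this fixture's scale the pruning
  # clustering resolves all three populations in both modalities, which is
  # the regime the edge-purity property describes
  gs <- build_graphs_single_cell(red, pr, n = 15, resolution = 1, seed = 3)
  for (g in gs) {
    expect_s3_class(g, "duogate_graph")
    expect_true(all(g$edges$from != g$edges$to))
    expect_true(all(tabulate(g$edges$from, g$m) <= 15))
    # every retained edge joins cells sharing a pruning label
    expect_true(all(g$labels[g$edges$from] == g$labels[g$edges$to]))
  }
  # >= 90% of surviving RNA edges connect same-truth-cluster cells
  e <- gs$rna$edges
  expect_gte(mean(sim$labels[e$from] == sim$labels[e$to]), 0.9)
  # determinism end to end
  gs2 <- build_graphs_single_cell(red, pr, n = 15, resolution = 1, seed = 3)
  expect_equal(gs, gs2)
  expect_error(build_graphs_single_cell(red[1:10, ], pr), "same cells")
})

test_that("modality-discordant structure yields different graphs", {
  # RNA separates groups A|B, protein separates the same cells differently
  set.seed(22)
  m <- 60
  rna_red <- rbind(matrix(rnorm(m, 0, .2), m / 2, 2),
                   matrix(rnorm(m, 8, .2), m / 2, 2))
  prot <- cbind(rnorm(m, rep(c(0, 8), m / 2), .2),
                rnorm(m, rep(c(8, 0), m / 2), .2))
  gs <- build_graphs_single_cell(rna_red, prot, n = 5, seed = 1)
  key <- function(g) paste(g$edges$from, g$edges$to)
  expect_false(setequal(key(gs$rna), key(gs$protein)))
})

test_that("spatial graphs use coordinate distances and honour pruning flags", {
  # regular 6x6 grid: with n = 4 every interior cell's neighbours are its
  # 4 lattice neighbours (brute-force distance oracle)
  grid <- as.matrix(expand.grid(x = 1:6, y = 1:6))
  m <- nrow(grid)
  sets <- knn_sets(pairwise_euclidean(grid), 4)
  for (i in seq_len(m)) {
    if (all(grid[i, ] %in% 2:5)) {
      lat <- which(abs(grid[, 1] - grid[i, 1]) +
                     abs(grid[, 2] - grid[i, 2]) == 1)
      expect_setequal(sets[[i]], lat)
    }
  }
  sim <- simulate_multiomics(m = m, k = 2, n_genes = 40, n_proteins = 10,
                             grid = c(6, 6), seed = 9)
  rn <- select_hvg(normalize_rna(sim$rna), 40)
  pr <- clr_protein(sim$protein)
  gs <- build_graphs_spatial(sim$coords, rn, pr, n = 4, seed = 2)
  for (g in gs) {
    expect_true(all(tabulate(g$edges$from, g$m) <= 4))
    expect_true(all(g$labels[g$edges$from] == g$labels[g$edges$to]))
  }
  # pruning disabled: both graphs share the spatial kNN edge set exactly
  gs0 <- build_graphs_spatial(sim$coords, rn, pr, n = 4, seed = 2,
                              prune = "none")
  expect_equal(gs0$rna$edges, gs0$protein$edges)
  expect_error(build_graphs_spatial(cbind(c(1, NA), c(2, 3)), rn[1:2, ],
                                    pr[1:2, ], n = 1), "non-finite")
})
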