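#' Pairwise Euclidean distance matrix
#'
#' @param X numeric matrix, observations in rows.
#' @return dense symmetric m x m matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(X) {
  X <- as_dense_matrix(X, "X")
  stop_if_not_finite(X, "pairwise_euclidean input")
  D <- as.matrix(dist(X, method = "euclidean"))
  dimnames(D) <- NULL
  D
}

#' k-nearest-neighbour sets from a distance matrix
#'
#' For each cell the `n` other cells at smallest distance, distance ties
#' broken by ascending cell index.  A cell is never its own neighbour.
#'
#' @param D symmetric distance matrix.
#' @param n neighbour budget, `1 <= n < nrow(D)`.
#' @return list of integer vectors (length n each), one per cell, ordered by
#'   increasing distance.
#' @export
knn_sets <- function(D, n) {
  D <- as_dense_matrix(D, "D")
  m <- nrow(D)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n >= m) {
    stop(sprintf("n must satisfy 1 <= n < m = %d", m), call. = FALSE)
  }
  n <- as.integer(n)
  lapply(seq_len(m), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    # order() is a stable sort on (distance, index): ties -> ascending index
    order(d)[seq_len(n)]
  })
}

#' Leiden community labels on a kNN graph of a feature matrix
#'
#' Builds an unweighted undirected union-kNN graph from `X` and partitions it
#' with the Leiden algorithm (modularity objective).  Deterministic given
#' `seed`.
#'
#' @param X numeric matrix, cells in rows.
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed RNG seed.
#' @param n_neighbors kNN budget for the graph substrate (default 15,
#'   clipped to m - 1).
#' @return integer vector of 1-based community labels.
#' @export
leiden_labels <- function(X, resolution = 1, seed = 1, n_neighbors = 15) {
  X <- as_dense_matrix(X, "X")
  stop_if_not_finite(X, "leiden_labels input")
  m <- nrow(X)
  if (m < 2L) return(rep.int(1L, m))
  k <- min(as.integer(n_neighbors), m - 1L)
  nb <- knn_sets(pairwise_euclidean(X), k)
  el <- cbind(rep(seq_len(m), each = k), unlist(nb))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           n_iterations = 3)$membership
  })
  as.integer(memb)
}

#' Prune neighbour sets by community label agreement
#'
#' Keeps, for each cell, only the neighbours that share its community label;
#' neighbour order is preserved.
#'
#' @param sets list of integer neighbour vectors as from [knn_sets()].
#' @param labels integer label per cell, covering every index in `sets`.
#' @return list of (possibly empty) pruned integer vectors.
#' @export
prune_neighbors <- function(sets, labels) {
  m <- length(sets)
  labels <- as.integer(labels)
  if (length(labels) != m || anyNA(labels)) {
    stop("labels must cover all cells with no missing values", call. = FALSE)
  }
  lapply(seq_len(m), function(i) {
    nb <- sets[[i]]
    nb[labels[nb] == labels[i]]
  })
}

#' Assemble the weighted neighbourhood graph
#'
#' Builds the directed graph whose binary indicator B has `B[i, j] = 1` iff
#' cell j is in the pruned neighbour set of cell i, and whose weights are
#' `W = D * B` (elementwise).  Both matrices are sparse; the diagonal is
#' zero.
#'
#' @param D distance matrix.
#' @param pruned list of pruned neighbour index vectors.
#' @param labels optional pruning labels to carry along (used downstream for
#'   triplet negative sampling).
#' @param symmetrize if TRUE, take the union of each edge and its reverse
#'   (weights from D).  Off by default: the construction is directed.
#' @return object of class `duogate_graph`: list with sparse `W`, `B`,
#'   `edges` data.frame (from, to, dist), `n` = max out-degree requested,
#'   `m`, `labels`.
#' @export
assemble_graph <- function(D, pruned, labels = NULL, symmetrize = FALSE) {
  D <- as_dense_matrix(D, "D")
  m <- nrow(D)
  if (length(pruned) != m) stop("pruned sets/distance size mismatch", call. = FALSE)
  from <- rep(seq_len(m), lengths(pruned))
  to <- as.integer(unlist(pruned))
  if (length(to) && (min(to) < 1L || max(to) > m)) {
    stop("neighbour index out of range", call. = FALSE)
  }
  if (any(from == to)) stop("a cell cannot neighbour itself", call. = FALSE)
  if (symmetrize && length(from)) {
    key <- paste(c(from, to), c(to, from))
    keep <- !duplicated(key)
    both <- cbind(c(from, to), c(to, from))[keep, , drop = FALSE]
    from <- both[, 1L]; to <- both[, 2L]
  }
  B <- sparseMatrix(i = from, j = to, x = 1, dims = c(m, m))
  W <- sparseMatrix(i = from, j = to, x = D[cbind(from, to)], dims = c(m, m))
  structure(list(W = W, B = B,
                 edges = data.frame(from = from, to = to,
                                    dist = D[cbind(from, to)]),
                 n = max(lengths(pruned), 0L), m = m,
                 labels = if (is.null(labels)) NULL else as.integer(labels)),
            class = "duogate_graph")
}

#' @export
print.duogate_graph <- function(x, ...) {
  cat(sprintf("duogate_graph: %d cells, %d directed edges (max out-degree %d)\n",
              x$m, nrow(x$edges), x$n))
  if (!is.null(x$labels)) {
    cat(sprintf("pruning labels: %d communities\n", length(unique(x$labels))))
  }
  invisible(x)
}

build_one_graph <- function(D, label_source, n, resolution, seed,
                            n_neighbors_leiden = n, symmetrize = FALSE) {
  labels <- leiden_labels(label_source, resolution = resolution, seed = seed,
                          n_neighbors = n_neighbors_leiden)
  sets <- knn_sets(D, n)
  pruned <- prune_neighbors(sets, labels)
  assemble_graph(D, pruned, labels = labels, symmetrize = symmetrize)
}

#' Build the two neighbourhood graphs from single-cell expression profiles
#'
#' Transcriptome graph: kNN on the PCA-reduced RNA representation, pruned by
#' RNA-derived Leiden labels.  Proteome graph: kNN on the normalised protein
#' matrix, pruned by protein-derived Leiden labels.
#'
#' @param rna_reduced PCA-reduced RNA matrix (cells x components).
#' @param protein_norm CLR-normalised protein matrix (same cells, same order).
#' @param n neighbour budget (default 15).
#' @param resolution Leiden resolution for the pruning clustering
#'   (default 0.5).
#' @param seed RNG seed for Leiden.
#' @param symmetrize union-symmetrize the directed graphs (default FALSE).
#' @return list with elements `rna` and `protein`, each a `duogate_graph`.
#' @export
build_graphs_single_cell <- function(rna_reduced, protein_norm, n = 15,
                                     resolution = 0.5, seed = 1,
                                     symmetrize = FALSE) {
  rna_reduced <- as_dense_matrix(rna_reduced, "rna_reduced")
  protein_norm <- as_dense_matrix(protein_norm, "protein_norm")
  if (nrow(rna_reduced) != nrow(protein_norm)) {
    stop("modalities must cover the same cells in the same order", call. = FALSE)
  }
  Dt <- pairwise_euclidean(rna_reduced)
  Dp <- pairwise_euclidean(protein_norm)
  list(rna = build_one_graph(Dt, rna_reduced, n, resolution, seed,
                             symmetrize = symmetrize),
       protein = build_one_graph(Dp, protein_norm, n, resolution, seed,
                                 symmetrize = symmetrize))
}

#' Build the two neighbourhood graphs from spatial coordinates
#'
#' Both modalities share the coordinate-derived kNN structure and distances;
#' pruning still uses modality-specific expression-derived Leiden labels
#' (`prune = "expression"`), or can be disabled (`prune = "none"`), in which
#' case the two graphs are identical.
#'
#' @param coords cells x 2 coordinate matrix, finite.
#' @param rna_norm normalised RNA matrix (for pruning labels).
#' @param protein_norm normalised protein matrix (for pruning labels).
#' @param n,resolution,seed,symmetrize as in [build_graphs_single_cell()].
#' @param prune `"expression"` (default) or `"none"`.
#' @return list with `duogate_graph` elements `rna` and `protein`.
#' @export
build_graphs_spatial <- function(coords, rna_norm, protein_norm, n = 15,
                                 resolution = 0.5, seed = 1,
                                 prune = c("expression", "none"),
                                 symmetrize = FALSE) {
  prune <- match.arg(prune)
  coords <- as_dense_matrix(coords, "coords")
  stop_if_not_finite(coords, "spatial coordinates")
  rna_norm <- as_dense_matrix(rna_norm, "rna_norm")
  protein_norm <- as_dense_matrix(protein_norm, "protein_norm")
  m <- nrow(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns", call. = FALSE)
  if (nrow(rna_norm) != m || nrow(protein_norm) != m) {
    stop("coordinates and modalities must cover the same cells", call. = FALSE)
  }
  D <- pairwise_euclidean(coords)
  sets <- knn_sets(D, n)
  one <- function(label_source) {
    labels <- if (prune == "none") rep.int(1L, m) else {
      leiden_labels(label_source, resolution = resolution, seed = seed,
                    n_neighbors = n)
    }
    assemble_graph(D, prune_neighbors(sets, labels), labels = labels,
                   symmetrize = symmetrize)
  }
  list(rna = one(rna_norm), protein = one(protein_norm))
}
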