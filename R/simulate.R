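# Seeded generator of paired RNA + protein count matrices with known
# cluster structure, optionally laid out as contiguous spatial regions.
# Cluster identities live in a shared latent space; modality-specific
# linear maps produce expected expression; RNA counts are negative binomial
# with per-cell library sizes and Bernoulli dropout (sparse,
# high-dimensional), protein counts are Poisson around a high baseline
# (dense, low-dimensional) — mimicking the RNA/ADT asymmetry of CITE-seq.

#' Simulate paired transcriptome and proteome counts
#'
#' @param m number of cells (default 600).
#' @param k number of ground-truth clusters (default 3).
#' @param n_genes RNA features (default 200).
#' @param n_proteins protein features (default 30).
#' @param separation standard deviation of cluster centres in the shared
#'   latent space, in units of the within-cluster spread (default 3: well
#'   separated cell types).
#' @param latent_dim dimension of the shared latent space (default 10).
#' @param within_sd within-cluster latent spread (default 1).
#' @param logfc_scale per-feature log-expression spread contributed by the
#'   latent space, after scaling (default 1).
#' @param base_sd spread of per-gene baseline abundances (default 1.5),
#'   which drives realistic RNA sparsity through library composition.
#' @param dispersion negative-binomial dispersion for RNA (default 0.5,
#'   i.e. `size = 2`).
#' @param dropout Bernoulli dropout probability applied to RNA counts
#'   (default 0.3).
#' @param libsize_range uniform range of per-cell RNA library sizes
#'   (default 2500..7500).
#' @param protein_scale Poisson baseline mean for proteins (default 50,
#'   keeping the protein zero-fraction under 10%).
#' @param grid optional `c(nx, ny)` lattice dimensions for spatial mode;
#'   requires `nx * ny >= m`.  Cells occupy the first `m` lattice positions
#'   (row-major) with positional jitter, and ground-truth labels form
#'   contiguous regions (nearest of k well-spread region seeds).
#' @param jitter positional jitter half-width in spatial mode (default 0.3).
#' @param seed RNG seed; the whole dataset is bitwise-reproducible.
#' @return object of class `duogate_sim`: list with integer matrices `rna`
#'   (m x n_genes) and `protein` (m x n_proteins), integer `labels`,
#'   `coords` (m x 2, spatial mode only, else NULL), `latent_means`
#'   (per-cell latent cluster centres) and a `manifest` of every parameter.
#' @export
simulate_multiomics <- function(m = 600, k = 3, n_genes = 200,
                                n_proteins = 30, separation = 3,
                                latent_dim = 10, within_sd = 1,
                                logfc_scale = 1, base_sd = 1.5,
                                dispersion = 0.5, dropout = 0.3,
                                libsize_range = c(2500, 7500),
                                protein_scale = 50, grid = NULL,
                                jitter = 0.3, seed = 1) {
  stopifnot(m >= k, k >= 1, n_genes >= n_proteins, n_proteins >= 1,
            dropout >= 0, dropout <= 1, dispersion > 0, separation >= 0)
  if (!is.null(grid)) {
    stopifnot(length(grid) == 2L, all(grid >= 1))
    if (prod(grid) < m) stop("grid too small for m cells", call. = FALSE)
  }
  with_seed(seed, {
    coords <- NULL
    if (is.null(grid)) {
      labels <- sample(rep_len(seq_len(k), m))
    } else {
      pos <- as.matrix(expand.grid(x = seq_len(grid[1]),
                                   y = seq_len(grid[2])))[seq_len(m), ,
                                                          drop = FALSE]
      # farthest-point sampling keeps region seeds well separated
      seeds <- integer(k)
      seeds[1] <- sample.int(m, 1L)
      if (k > 1L) {
        dmin <- sqrt(rowSums((pos - rep(pos[seeds[1], ], each = m))^2))
        for (j in 2:k) {
          seeds[j] <- which.max(dmin)
          dj <- sqrt(rowSums((pos - rep(pos[seeds[j], ], each = m))^2))
          dmin <- pmin(dmin, dj)
        }
      }
      dseed <- sapply(seeds, function(s) {
        sqrt(rowSums((pos - rep(pos[s, ], each = m))^2))
      })
      labels <- max.col(-dseed, ties.method = "first")
      coords <- pos + matrix(runif(2 * m, -jitter, jitter), m, 2)
      colnames(coords) <- c("x", "y")
    }
    mu <- matrix(rnorm(k * latent_dim, sd = separation), k, latent_dim)
    latent <- mu[labels, , drop = FALSE] +
      matrix(rnorm(m * latent_dim, sd = within_sd), m, latent_dim)
    map_scale <- logfc_scale / sqrt(latent_dim * (separation^2 + within_sd^2))
    A_t <- matrix(rnorm(latent_dim * n_genes, sd = map_scale),
                  latent_dim, n_genes)
    A_p <- matrix(rnorm(latent_dim * n_proteins, sd = map_scale),
                  latent_dim, n_proteins)
    g0 <- rnorm(n_genes, sd = base_sd)

    # RNA: library-composition model -> NB counts -> dropout
    w <- exp(latent %*% A_t + rep(g0, each = m))
    prob <- w / rowSums(w)
    lib <- runif(m, libsize_range[1], libsize_range[2])
    mu_rna <- prob * lib
    rna <- matrix(rnbinom(m * n_genes, mu = as.vector(mu_rna),
                          size = 1 / dispersion), m, n_genes)
    if (dropout > 0) {
      keep <- matrix(runif(m * n_genes) >= dropout, m, n_genes)
      rna <- rna * keep
    }
    # protein: dense Poisson around a high baseline
    mu_prot <- protein_scale * exp(latent %*% A_p)
    protein <- matrix(rpois(m * n_proteins, as.vector(mu_prot)),
                      m, n_proteins)

    rownames(rna) <- rownames(protein) <- sprintf("cell_%04d", seq_len(m))
    colnames(rna) <- sprintf("gene_%03d", seq_len(n_genes))
    colnames(protein) <- sprintf("adt_%02d", seq_len(n_proteins))
    if (!is.null(coords)) rownames(coords) <- rownames(rna)

    structure(list(rna = rna, protein = protein, labels = labels,
                   coords = coords,
                   latent_means = mu[labels, , drop = FALSE],
                   manifest = list(m = m, k = k, n_genes = n_genes,
                                   n_proteins = n_proteins,
                                   separation = separation,
                                   latent_dim = latent_dim,
                                   within_sd = within_sd,
                                   logfc_scale = logfc_scale,
                                   base_sd = base_sd,
                                   dispersion = dispersion,
                                   dropout = dropout,
                                   libsize_range = libsize_range,
                                   protein_scale = protein_scale,
                                   grid = grid, jitter = jitter,
                                   seed = seed)),
              class = "duogate_sim")
  })
}

#' @export
print.duogate_sim <- function(x, ...) {
  mf <- x$manifest
  cat(sprintf("duogate_sim: %d cells, %d clusters, %d genes, %d proteins%s\n",
              mf$m, mf$k, mf$n_genes, mf$n_proteins,
              if (is.null(x$coords)) "" else
                sprintf(", spatial %dx%d grid", mf$grid[1], mf$grid[2])))
  cat(sprintf("RNA zero-fraction %.2f, protein zero-fraction %.2f\n",
              mean(x$rna == 0), mean(x$protein == 0)))
  invisible(x)
}
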