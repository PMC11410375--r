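# End-to-end orchestration: preprocess -> neighbourhood graphs (single-cell
# or spatial mode) -> dual-path GATE training -> joint embedding.

#' Decide between single-cell and spatial mode
#'
#' Spatial iff a finite cells x 2 coordinate table is supplied; partial or
#' non-finite coordinates are an error (pass an explicit mode instead).
#'
#' @param coords NULL or a cells x 2 numeric matrix.
#' @return `"single_cell"` or `"spatial"`.
#' @export
detect_mode <- function(coords) {
  if (is.null(coords)) return("single_cell")
  coords <- as_dense_matrix(coords, "coords")
  if (ncol(coords) != 2L || any(!is.finite(coords))) {
    stop("coordinates are present but not a finite cells x 2 table; ",
         "pass mode explicitly", call. = FALSE)
  }
  "spatial"
}

#' Integrate paired RNA and protein profiles with a dual-path
#' graph-attention auto-encoder
#'
#' The main fitting function.  Takes raw paired count matrices, normalises
#' each modality (depth scaling + log1p and highly-variable-gene selection
#' for RNA; centred log-ratio for protein), builds per-modality pruned kNN
#' neighbourhood graphs — from expression profiles in single-cell mode or
#' from spatial coordinates when `coords` is given — and trains the
#' dual-path graph-attention auto-encoder under the combined weighted loss
#' (reconstruction + `lambda` x triplet self-supervision).  Returns the
#' joint embedding `Z = [T_emb | P_emb]` and the fitted model.
#'
#' @param rna raw RNA count matrix, cells in rows.
#' @param protein raw protein (ADT) count matrix, same cells in the same
#'   order.
#' @param coords optional cells x 2 spatial coordinates; switches graph
#'   construction to spatial mode when present (see [detect_mode()]).
#' @param mode `"auto"` (default; coordinate presence decides),
#'   `"single_cell"` or `"spatial"`.
#' @param n_neighbors neighbour budget for graph construction (default 15).
#' @param embedding_dim per-path embedding dimension (default 30).
#' @param hidden_dim hidden layer width (default 256).
#' @param epochs training epochs (default 300).
#' @param lr learning rate (default 0.001).
#' @param lambda balance parameter for the self-supervision terms
#'   (default 0.1).
#' @param margin triplet margin (default 1).
#' @param target_sum RNA depth-scaling total (default 10000).
#' @param n_hvg number of highly variable genes (default 2000).
#' @param pca_components PCA dimension used only for transcriptome
#'   neighbour search (default 200, clipped to the data).
#' @param prune_resolution Leiden resolution of the pruning clustering
#'   (default 0.5).
#' @param clr_variant `"seurat"` (default) or `"classical"` protein CLR.
#' @param spatial_prune `"expression"` (default) or `"none"`: whether
#'   spatial-mode graphs are pruned by expression-derived Leiden labels.
#' @param symmetrize union-symmetrize the directed graphs (default FALSE).
#' @param seed RNG seed controlling Leiden, initialisation and triplet
#'   sampling; identical inputs + seed give identical output.
#' @param verbose print training progress.
#' @return object of class `duogate`.  Key components: `Z` (cells x
#'   2*embedding_dim joint embedding), `T_emb`, `P_emb`, `history`
#'   (per-epoch loss breakdown), `graphs`, `model` (fitted `gate_fit`),
#'   `data` (the normalised matrices fed to the model), `mode`, and
#'   `config` — a manifest of every resolved hyperparameter.
#' @seealso [predict.duogate()], [sweep_and_report()],
#'   [simulate_multiomics()]
#' @examples
#' \donttest{
#' sim <- simulate_multiomics(m = 150, n_genes = 60, n_proteins = 15,
#'                            seed = 7)
#' fit <- duogate(sim$rna, sim$protein, epochs = 50, seed = 7)
#' fit
#' ari_score(predict(fit, type = "clusters", resolution = 1), sim$labels)
#' }
#' @export
duogate <- function(rna, protein, coords = NULL,
                    mode = c("auto", "single_cell", "spatial"),
                    n_neighbors = 15, embedding_dim = 30, hidden_dim = 256,
                    epochs = 300, lr = 0.001, lambda = 0.1, margin = 1,
                    target_sum = 1e4, n_hvg = 2000, pca_components = 200,
                    prune_resolution = 0.5,
                    clr_variant = c("seurat", "classical"),
                    spatial_prune = c("expression", "none"),
                    symmetrize = FALSE, seed = 1, verbose = FALSE) {
  cl <- match.call()
  mode <- match.arg(mode)
  clr_variant <- match.arg(clr_variant)
  spatial_prune <- match.arg(spatial_prune)
  rna <- as_dense_matrix(rna, "rna")
  protein <- as_dense_matrix(protein, "protein")
  if (nrow(rna) != nrow(protein)) {
    stop("rna and protein must cover the same cells in the same order",
         call. = FALSE)
  }
  if (mode == "auto") mode <- detect_mode(coords)
  if (mode == "spatial" && is.null(coords)) {
    stop("spatial mode requires coordinates", call. = FALSE)
  }

  # --- preprocess ----------------------------------------------------------
  rna_norm <- normalize_rna(rna, target_sum = target_sum)
  dropped <- attr(rna_norm, "dropped_cells")
  keep <- rowSums(rna) > 0 & rowSums(protein) > 0
  # a zero-depth cell in either modality is dropped from both to keep pairing
  if (!all(keep)) {
    message(sprintf("duogate: dropping %d cell(s) with zero depth in at least one modality",
                    sum(!keep)))
    rna_norm <- normalize_rna(rna[keep, , drop = FALSE],
                              target_sum = target_sum)
    protein <- protein[keep, , drop = FALSE]
    if (!is.null(coords)) coords <- coords[keep, , drop = FALSE]
  }
  rna_hvg <- select_hvg(rna_norm, n_top = n_hvg)
  protein_norm <- clr_protein(protein, variant = clr_variant)
  rna_red <- pca_reduce(rna_hvg, n_components = pca_components)

  # --- graphs --------------------------------------------------------------
  graphs <- if (mode == "spatial") {
    build_graphs_spatial(coords, rna_hvg, protein_norm, n = n_neighbors,
                         resolution = prune_resolution, seed = seed,
                         prune = spatial_prune, symmetrize = symmetrize)
  } else {
    build_graphs_single_cell(rna_red, protein_norm, n = n_neighbors,
                             resolution = prune_resolution, seed = seed,
                             symmetrize = symmetrize)
  }

  # --- train ---------------------------------------------------------------
  fit <- fit_gate(rna_hvg, protein_norm, graphs,
                  embedding_dim = embedding_dim, hidden_dim = hidden_dim,
                  epochs = epochs, lr = lr, lambda = lambda, margin = margin,
                  seed = seed, verbose = verbose)

  cells <- rownames(rna_hvg)
  if (!is.null(cells)) {
    rownames(fit$Z) <- rownames(fit$T_emb) <- rownames(fit$P_emb) <- cells
  }
  structure(list(Z = fit$Z, T_emb = fit$T_emb, P_emb = fit$P_emb,
                 history = fit$history, model = fit, graphs = graphs,
                 data = list(rna = rna_hvg, protein = protein_norm,
                             rna_reduced = rna_red, coords = coords),
                 mode = mode, cells = cells, dropped_cells = dropped,
                 config = list(mode = mode, n_neighbors = n_neighbors,
                               embedding_dim = embedding_dim,
                               hidden_dim = hidden_dim, epochs = epochs,
                               lr = lr, lambda = lambda, margin = margin,
                               target_sum = target_sum, n_hvg = n_hvg,
                               pca_components = min(pca_components,
                                                    nrow(rna_hvg) - 1L,
                                                    ncol(rna_hvg)),
                               prune_resolution = prune_resolution,
                               clr_variant = clr_variant,
                               spatial_prune = spatial_prune,
                               symmetrize = symmetrize, seed = seed),
                 call = cl),
            class = "duogate")
}
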