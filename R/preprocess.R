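#' Depth-scale and log-transform RNA counts
#'
#' Scales every cell's count vector to a common total (`target_sum`) and then
#' applies `log(1 + x)` — the standard count-depth normalisation for
#' transcriptome profiles.  Cells whose total count is zero cannot be scaled;
#' they are dropped with a message and recorded in the `"dropped_cells"`
#' attribute of the result so the caller can drop the paired modality too.
#'
#' @param counts numeric matrix of non-negative RNA counts, cells in rows.
#' @param target_sum positive total each cell is scaled to.  Default 10000.
#' @return numeric matrix of the same feature dimension, cells with positive
#'   depth only, normalised and log1p-transformed.  Attribute
#'   `"dropped_cells"` lists the row indices (or names) removed.
#' @examples
#' x <- rbind(a = c(2, 0, 0), b = c(1, 1, 2))
#' normalize_rna(x, target_sum = 4)
#' @export
normalize_rna <- function(counts, target_sum = 1e4) {
  counts <- as_dense_matrix(counts, "counts")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(target_sum), length(target_sum) == 1L, target_sum > 0)
  totals <- rowSums(counts)
  keep <- totals > 0
  dropped <- if (!is.null(rownames(counts))) rownames(counts)[!keep] else which(!keep)
  if (any(!keep)) {
    message(sprintf("normalize_rna: dropping %d cell(s) with zero total count",
                    sum(!keep)))
  }
  if (!any(keep)) {
    warning("normalize_rna: all cells have zero total count; empty output")
  }
  out <- counts[keep, , drop = FALSE]
  out <- log1p(out / rowSums(out) * target_sum)
  attr(out, "dropped_cells") <- dropped
  out
}

#' Select highly variable genes by binned normalised dispersion
#'
#' Ranks genes by dispersion (variance/mean of the de-logged expression),
#' standardised within equal-frequency bins of mean expression so that
#' highly expressed genes do not dominate, and keeps the top `n_top`.
#' Output columns keep their original order.
#'
#' @param norm normalised log-expression matrix (cells x genes), as produced
#'   by [normalize_rna()].
#' @param n_top number of genes to keep.  If `n_top >= ncol(norm)` the input
#'   is returned unchanged.
#' @param n_bins number of mean-expression bins used to standardise the
#'   dispersion (default 20).
#' @return the input matrix restricted to the selected genes, original
#'   column order; attribute `"hvg"` holds the selected column indices.
#' @export
select_hvg <- function(norm, n_top = 2000, n_bins = 20) {
  norm <- as_dense_matrix(norm, "norm")
  if (!is.numeric(n_top) || length(n_top) != 1L || n_top < 1) {
    stop("n_top must be a positive integer", call. = FALSE)
  }
  p <- ncol(norm)
  if (n_top >= p) {
    attr(norm, "hvg") <- seq_len(p)
    return(norm)
  }
  expr <- expm1(norm)
  mu <- colMeans(expr)
  v <- apply(expr, 2L, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins on mean expression (>= 10 genes per bin so the
  # within-bin z-score is meaningful); z-score dispersion within bin
  n_bins <- max(1L, min(n_bins, p %/% 10L))
  bins <- if (n_bins == 1L) rep.int(1L, p) else {
    cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  }
  z <- numeric(p)
  for (b in unique(bins)) {
    ix <- which(bins == b)
    m <- mean(disp[ix])
    s <- sd(disp[ix])
    z[ix] <- if (length(ix) > 1L && s > 0) (disp[ix] - m) / s else disp[ix] - m
  }
  # zero-dispersion genes can never outrank genes with positive dispersion
  z[disp == 0] <- -Inf
  sel <- sort(order(z, decreasing = TRUE)[seq_len(n_top)])
  out <- norm[, sel, drop = FALSE]
  attr(out, "hvg") <- sel
  out
}

#' Centred log-ratio normalisation of protein (ADT) counts
#'
#' Per-cell compositional normalisation for antibody-derived-tag counts.
#' The default (`variant = "seurat"`) computes, for cell i,
#' `y_ij = log(1 + x_ij / exp(mean_j log(1 + x_ij)))`, the margin-across-
#' features CLR used by Seurat for ADT data.  `variant = "classical"` is the
#' textbook CLR on pseudocounted values, `log(x + pc) - mean_j log(x + pc)`,
#' which is exactly zero-sum per cell.
#'
#' @param counts non-negative protein count matrix, cells in rows.
#' @param variant `"seurat"` (default) or `"classical"`.
#' @param pseudocount pseudocount for the classical variant (default 1).
#' @return normalised matrix of identical shape.
#' @examples
#' clr_protein(rbind(c(1, 1, 1)))  # all entries log(1 + 1/2)
#' @export
clr_protein <- function(counts, variant = c("seurat", "classical"),
                        pseudocount = 1) {
  counts <- as_dense_matrix(counts, "counts")
  variant <- match.arg(variant)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (variant == "seurat") {
    geo <- exp(rowMeans(log1p(counts)))
    log1p(counts / geo)
  } else {
    lx <- log(counts + pseudocount)
    lx - rowMeans(lx)
  }
}

#' Project a normalised matrix onto its leading principal components
#'
#' Column-centred PCA used to compress the high-dimensional transcriptome
#' before neighbour search.  Components are ordered by non-increasing
#' explained variance.  The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making the projection
#' deterministic.
#'
#' @param norm normalised matrix (cells x features), finite.
#' @param n_components number of components (default 200).  Values above
#'   `min(nrow - 1, ncol)` are clipped with a warning.
#' @return cells x n_components score matrix; attribute `"sdev"` holds the
#'   component standard deviations.
#' @export
pca_reduce <- function(norm, n_components = 200) {
  norm <- as_dense_matrix(norm, "norm")
  stop_if_not_finite(norm, "pca_reduce input")
  kmax <- min(nrow(norm) - 1L, ncol(norm))
  if (n_components > kmax) {
    warning(sprintf("pca_reduce: n_components clipped from %d to %d",
                    n_components, kmax))
    n_components <- kmax
  }
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  pc <- prcomp(norm, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| entry of each rotation column positive
  for (k in seq_len(n_components)) {
    load <- pc$rotation[, k]
    if (load[which.max(abs(load))] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- rownames(norm)
  attr(scores, "sdev") <- pc$sdev[seq_len(n_components)]
  scores
}
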