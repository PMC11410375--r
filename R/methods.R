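# S3 methods for fitted duogate objects.

#' @export
print.duogate <- function(x, ...) {
  cfg <- x$config
  cat("Dual-path graph-attention auto-encoder integration\n")
  cat(sprintf("  mode: %s | cells: %d | RNA features: %d | proteins: %d\n",
              x$mode, nrow(x$Z), ncol(x$data$rna), ncol(x$data$protein)))
  cat(sprintf("  joint embedding: %d x %d (per path %d)\n",
              nrow(x$Z), ncol(x$Z), cfg$embedding_dim))
  h <- x$history
  cat(sprintf("  %d epochs, final loss %.5f (recon %.5f + %.5f, super %.5f + %.5f, lambda %.3g)\n",
              nrow(h), h$total[nrow(h)], h$recon_t[nrow(h)],
              h$recon_p[nrow(h)], h$super_t[nrow(h)], h$super_p[nrow(h)],
              cfg$lambda))
  invisible(x)
}

#' @export
summary.duogate <- function(object, ...) {
  h <- object$history
  gr <- function(g) c(edges = nrow(g$edges),
                      communities = length(unique(g$labels)),
                      isolated = sum(tabulate(g$edges$from, g$m) == 0))
  out <- list(config = object$config, mode = object$mode,
              n_cells = nrow(object$Z), dim_z = ncol(object$Z),
              loss_first = h$total[1], loss_final = h$total[nrow(h)],
              history_tail = utils::tail(h, 3),
              graph_rna = gr(object$graphs$rna),
              graph_protein = gr(object$graphs$protein))
  class(out) <- "summary.duogate"
  out
}

#' @export
print.summary.duogate <- function(x, ...) {
  cat("duogate fit summary\n")
  cat(sprintf("  mode %s, %d cells, joint embedding dim %d\n",
              x$mode, x$n_cells, x$dim_z))
  cat(sprintf("  loss: %.5f (epoch 1) -> %.5f (final)\n",
              x$loss_first, x$loss_final))
  cat(sprintf("  RNA graph: %d edges, %d pruning communities, %d isolated cells\n",
              x$graph_rna["edges"], x$graph_rna["communities"],
              x$graph_rna["isolated"]))
  cat(sprintf("  protein graph: %d edges, %d pruning communities, %d isolated cells\n",
              x$graph_protein["edges"], x$graph_protein["communities"],
              x$graph_protein["isolated"]))
  cat("  last epochs:\n")
  print(x$history_tail, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Extract fitted model parameters
#'
#' @param object a fitted `duogate` object.
#' @param ... unused.
#' @return nested list of parameter matrices: paths `t` and `p`, layers
#'   `enc1`, `enc2`, `dec1`, `dec2`.
#' @export
coef.duogate <- function(object, ...) {
  lapply(object$model$params, function(p) p[c("enc1", "enc2", "dec1", "dec2")])
}

#' Reconstructions of the normalised inputs
#'
#' @param object a fitted `duogate` object.
#' @param ... unused.
#' @return list with matrices `rna` and `protein`: decoder outputs at the
#'   final parameters.
#' @export
fitted.duogate <- function(object, ...) {
  rec_r <- gate_decode(object$T_emb, object$graphs$rna,
                       object$model$params$t)
  rec_p <- gate_decode(object$P_emb, object$graphs$protein,
                       object$model$params$p)
  dimnames(rec_r) <- dimnames(object$data$rna)
  dimnames(rec_p) <- dimnames(object$data$protein)
  list(rna = rec_r, protein = rec_p)
}

#' Reconstruction residuals
#'
#' @param object a fitted `duogate` object.
#' @param ... unused.
#' @return list with matrices `rna` and `protein`: normalised input minus
#'   reconstruction.
#' @export
residuals.duogate <- function(object, ...) {
  f <- fitted(object)
  list(rna = object$data$rna - f$rna,
       protein = object$data$protein - f$protein)
}

#' Joint embedding or cluster labels from a fitted integration
#'
#' `type = "embedding"` returns the joint representation Z (or one path's
#' block); `type = "clusters"` runs Leiden on Z at the requested
#' resolution.
#'
#' @param object a fitted `duogate` object.
#' @param type `"embedding"` (default) or `"clusters"`.
#' @param path for embeddings: `"joint"` (default), `"rna"` or `"protein"`.
#' @param resolution Leiden resolution for `type = "clusters"` (default 1).
#' @param seed RNG seed for the clustering (defaults to the fit seed).
#' @param ... unused.
#' @return matrix (embedding) or integer labels (clusters).
#' @export
predict.duogate <- function(object, type = c("embedding", "clusters"),
                            path = c("joint", "rna", "protein"),
                            resolution = 1, seed = NULL, ...) {
  type <- match.arg(type)
  path <- match.arg(path)
  if (type == "embedding") {
    return(switch(path, joint = object$Z, rna = object$T_emb,
                  protein = object$P_emb))
  }
  if (is.null(seed)) seed <- object$config$seed
  cluster_embedding(object$Z, resolution = resolution, seed = seed,
                    n_neighbors = object$config$n_neighbors)
}

#' Plot the training loss history
#'
#' Total combined loss plus its reconstruction and self-supervision
#' components per epoch.
#'
#' @param x a fitted `duogate` object.
#' @param log_y plot losses on a log scale (default TRUE).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.duogate <- function(x, log_y = TRUE, ...) {
  h <- x$history
  comp <- cbind(total = h$total, recon = h$recon_t + h$recon_p,
                super = h$super_t + h$super_p)
  keep <- colSums(comp > 0) > 0
  graphics::matplot(h$epoch, comp[, keep, drop = FALSE], type = "l",
                    lty = 1, col = seq_len(sum(keep)),
                    log = if (log_y) "y" else "",
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = colnames(comp)[keep],
                   col = seq_len(sum(keep)), lty = 1, bty = "n")
  invisible(x)
}
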