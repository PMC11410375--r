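# Self-supervised training: per-modality MSE reconstruction plus
# per-modality triplet self-supervision evaluated on the joint embedding,
# combined as L = (L_recon_t + L_recon_p) + lambda * (L_super_t + L_super_p).

#' Mean squared error reconstruction loss
#'
#' @param X,X_hat matrices of identical shape.
#' @return mean over all entries of `(X - X_hat)^2`.
#' @export
mse_loss <- function(X, X_hat) {
  X <- as_dense_matrix(X, "X"); X_hat <- as_dense_matrix(X_hat, "X_hat")
  if (!identical(dim(X), dim(X_hat))) stop("shape mismatch", call. = FALSE)
  mean((X - X_hat)^2)
}

#' Sample (anchor, positive, negative) triplets from a pruned graph
#'
#' For every anchor cell with at least one pruned neighbour, positives are
#' drawn uniformly from its pruned neighbours and negatives uniformly from
#' cells carrying a different pruning-cluster label.  Anchors with no valid
#' positive or negative are skipped and counted in the `"skipped"`
#' attribute.  A single-cluster labelling admits no negatives: a warning is
#' raised and an empty set returned.
#'
#' @param graph `duogate_graph` (its edges define the positives).
#' @param labels pruning-cluster labels; defaults to the labels stored in
#'   the graph.
#' @param per_anchor triplets drawn per eligible anchor (default 1).
#' @param seed RNG seed.
#' @return data.frame with columns `anchor`, `positive`, `negative`;
#'   attributes `"skipped"` (anchor count) and `"margin"` unset here.
#' @export
sample_triplets <- function(graph, labels = graph$labels, per_anchor = 1,
                            seed = 1) {
  with_seed(seed, sample_triplets_raw(graph, labels, per_anchor))
}

sample_triplets_raw <- function(graph, labels, per_anchor = 1) {
  m <- graph$m
  labels <- as.integer(labels)
  if (length(labels) != m) stop("labels must cover all cells", call. = FALSE)
  empty <- data.frame(anchor = integer(), positive = integer(),
                      negative = integer())
  if (length(unique(labels)) < 2L) {
    warning("sample_triplets: single-cluster labelling admits no negatives; ",
            "returning empty triplet set")
    attr(empty, "skipped") <- m
    return(empty)
  }
  nbr <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(m)))
  pools <- lapply(seq_len(max(labels)), function(l) which(labels != l))
  eligible <- which(lengths(nbr) > 0L &
                      lengths(pools)[labels] > 0L)
  skipped <- m - length(eligible)
  if (!length(eligible)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  anchor <- rep(eligible, times = per_anchor)
  positive <- vapply(anchor, function(a) {
    nb <- nbr[[a]]
    nb[sample.int(length(nb), 1L)]
  }, integer(1))
  negative <- vapply(anchor, function(a) {
    pool <- pools[[labels[a]]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1))
  out <- data.frame(anchor = anchor, positive = positive, negative = negative)
  attr(out, "skipped") <- skipped
  out
}

# Hinge triplet loss on embedding rows plus its gradient wrt Z.
triplet_loss_grad <- function(Z, triplets, margin = 1, want_grad = TRUE) {
  m <- nrow(Z)
  if (nrow(triplets) == 0L) {
    return(list(loss = 0,
                dZ = if (want_grad) matrix(0, m, ncol(Z)) else NULL))
  }
  a <- triplets$anchor; p <- triplets$positive; n <- triplets$negative
  if (max(a, p, n) > m || min(a, p, n) < 1L) {
    stop("triplet index out of range", call. = FALSE)
  }
  Dap <- Z[a, , drop = FALSE] - Z[p, , drop = FALSE]
  Dan <- Z[a, , drop = FALSE] - Z[n, , drop = FALSE]
  dap <- sqrt(rowSums(Dap^2))
  dan <- sqrt(rowSums(Dan^2))
  h <- dap - dan + margin
  active <- h > 0
  loss <- mean(pmax(h, 0))
  dZ <- NULL
  if (want_grad) {
    dZ <- matrix(0, m, ncol(Z))
    if (any(active)) {
      N <- length(h)
      u_ap <- Dap[active, , drop = FALSE] / pmax(dap[active], 1e-12)
      u_an <- Dan[active, , drop = FALSE] / pmax(dan[active], 1e-12)
      scatter <- function(M, idx, V) {
        R <- rowsum(V, idx)
        ri <- as.integer(rownames(R))
        M[ri, ] <- M[ri, , drop = FALSE] + R
        M
      }
      dZ <- scatter(dZ, a[active], (u_ap - u_an) / N)
      dZ <- scatter(dZ, p[active], -u_ap / N)
      dZ <- scatter(dZ, n[active], u_an / N)
    }
  }
  list(loss = loss, dZ = dZ)
}

#' Triplet self-supervision loss on the joint embedding
#'
#' Mean over triples of `max(0, ||z_a - z_p|| - ||z_a - z_n|| + margin)`.
#' An empty triplet set yields 0 with a warning.
#'
#' @param Z joint embedding matrix (cells in rows).
#' @param triplets data.frame as returned by [sample_triplets()].
#' @param margin hinge margin (default 1).
#' @return non-negative scalar.
#' @export
triplet_loss <- function(Z, triplets, margin = 1) {
  Z <- as_dense_matrix(Z, "Z")
  if (nrow(triplets) == 0L) {
    warning("triplet_loss: empty triplet set; returning 0")
    return(0)
  }
  triplet_loss_grad(Z, triplets, margin, want_grad = FALSE)$loss
}

#' Combined weighted training loss
#'
#' `L = (l_recon_t + l_recon_p) + lambda * (l_super_t + l_super_p)`.
#'
#' @param l_recon_t,l_recon_p per-modality reconstruction losses.
#' @param l_super_t,l_super_p per-modality self-supervision losses.
#' @param lambda non-negative balance parameter (default 0.1).
#' @return scalar total loss.
#' @export
combined_loss <- function(l_recon_t, l_recon_p, l_super_t, l_super_p,
                          lambda = 0.1) {
  stopifnot(lambda >= 0)
  (l_recon_t + l_recon_p) + lambda * (l_super_t + l_super_p)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) NULL, how = "list")  # placeholder; built lazily
}

# Walk a gate_params object and its gradient twin, updating with Adam.
# State is kept in an environment keyed by "path.layer.tensor".
adam_step <- function(params, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^step
  c2 <- 1 - beta2^step
  for (path in c("t", "p")) {
    for (layer in c("enc1", "enc2", "dec1", "dec2")) {
      for (tensor in names(grads[[path]][[layer]])) {
        key <- paste(path, layer, tensor, sep = ".")
        g <- grads[[path]][[layer]][[tensor]]
        st <- state[[key]]
        if (is.null(st)) st <- list(m = g * 0, v = g * 0)
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        state[[key]] <- st
        params[[path]][[layer]][[tensor]] <-
          params[[path]][[layer]][[tensor]] -
          lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      }
    }
  }
  params
}

# --- full training loop ----------------------------------------------------

#' Train the dual-path graph-attention auto-encoder
#'
#' Full-batch gradient training with Adam.  Each epoch encodes both
#' modalities, concatenates the per-path embeddings into the joint
#' representation Z, decodes each path, and minimises the combined weighted
#' loss: per-modality MSE reconstruction plus `lambda` times per-modality
#' triplet self-supervision.  Both triplet terms are evaluated on Z; they
#' differ only in which modality's pruned graph supplies the triplets.
#' Triplets are resampled every epoch from a seeded stream, so the whole run
#' is deterministic given `seed`.
#'
#' @param rna normalised (HVG-restricted) RNA matrix, cells in rows.
#' @param protein normalised protein matrix, same cells in the same order.
#' @param graphs list with `duogate_graph` elements `rna` and `protein`
#'   (e.g. from [build_graphs_single_cell()]).
#' @param embedding_dim per-path embedding dimension (default 30; the joint
#'   embedding has twice as many columns).
#' @param hidden_dim hidden layer width (default 256).
#' @param epochs number of training epochs (default 300); no early stopping.
#' @param lr Adam learning rate (default 0.001).
#' @param lambda balance parameter weighting self-supervision (default 0.1).
#' @param margin triplet hinge margin (default 1).
#' @param per_anchor triplets per anchor per epoch (default 1).
#' @param self_supervision set `FALSE` for a reconstruction-only objective
#'   (no triplet sampling at all).
#' @param seed RNG seed controlling initialisation and triplet sampling.
#' @param verbose print the loss every 50 epochs.
#' @return list of class `gate_fit`: `params` (per-path `gate_params`),
#'   `T_emb`, `P_emb`, `Z` (post-training forward pass), `history`
#'   (data.frame: epoch, recon_t, recon_p, super_t, super_p, total), and the
#'   resolved hyperparameters in `config`.
#' @export
fit_gate <- function(rna, protein, graphs, embedding_dim = 30,
                     hidden_dim = 256, epochs = 300, lr = 0.001,
                     lambda = 0.1, margin = 1, per_anchor = 1,
                     self_supervision = TRUE, seed = 1, verbose = FALSE) {
  rna <- as_dense_matrix(rna, "rna")
  protein <- as_dense_matrix(protein, "protein")
  m <- nrow(rna)
  if (nrow(protein) != m) stop("modalities must be paired", call. = FALSE)
  stopifnot(inherits(graphs$rna, "duogate_graph"),
            inherits(graphs$protein, "duogate_graph"),
            graphs$rna$m == m, graphs$protein$m == m,
            epochs >= 1, lr > 0, lambda >= 0)
  if (self_supervision &&
      (is.null(graphs$rna$labels) || is.null(graphs$protein$labels))) {
    stop("graphs carry no pruning labels (needed for triplet negatives); ",
         "build them with build_graphs_single_cell()/build_graphs_spatial() ",
         "or set self_supervision = FALSE", call. = FALSE)
  }
  ed_t <- model_edges(graphs$rna)
  ed_p <- model_edges(graphs$protein)
  d <- as.integer(embedding_dim)

  with_seed(seed, {
    params <- list(t = gate_init_raw(ncol(rna), hidden_dim, d),
                   p = gate_init_raw(ncol(protein), hidden_dim, d))
    state <- new.env(parent = emptyenv())
    hist <- matrix(NA_real_, epochs, 5,
                   dimnames = list(NULL, c("recon_t", "recon_p", "super_t",
                                           "super_p", "total")))
    warned_empty <- FALSE
    for (ep in seq_len(epochs)) {
      enc_t <- encode_path(rna, ed_t, params$t)
      enc_p <- encode_path(protein, ed_p, params$p)
      Z <- cbind(enc_t$emb, enc_p$emb)
      dec_t <- decode_path(enc_t$emb, ed_t, params$t)
      dec_p <- decode_path(enc_p$emb, ed_p, params$p)

      l_rt <- mean((rna - dec_t$recon)^2)
      l_rp <- mean((protein - dec_p$recon)^2)
      if (self_supervision) {
        trip_t <- suppressWarnings(
          sample_triplets_raw(graphs$rna, graphs$rna$labels, per_anchor))
        trip_p <- suppressWarnings(
          sample_triplets_raw(graphs$protein, graphs$protein$labels,
                              per_anchor))
        if (!warned_empty && (nrow(trip_t) == 0L || nrow(trip_p) == 0L)) {
          warning("fit_gate: empty triplet set in at least one modality; ",
                  "its self-supervision term is 0")
          warned_empty <- TRUE
        }
        st <- triplet_loss_grad(Z, trip_t, margin)
        sp <- triplet_loss_grad(Z, trip_p, margin)
        l_st <- st$loss; l_sp <- sp$loss
        dZ <- lambda * (st$dZ + sp$dZ)
      } else {
        l_st <- 0; l_sp <- 0
        dZ <- NULL
      }
      total <- (l_rt + l_rp) + lambda * (l_st + l_sp)
      hist[ep, ] <- c(l_rt, l_rp, l_st, l_sp, total)
      if (!is.finite(total)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
             call. = FALSE)
      }
      if (verbose && (ep %% 50L == 0L || ep == 1L)) {
        message(sprintf("epoch %4d  L = %.5f  (recon %.5f + %.5f, super %.5f + %.5f)",
                        ep, total, l_rt, l_rp, l_st, l_sp))
      }

      # backward: reconstruction path
      grads <- list(t = list(), p = list())
      back_path <- function(X, recon, enc, dec) {
        dR <- 2 * (recon - X) / length(X)
        b2 <- gat_backward(dec$caches$d2, dR)
        b1 <- gat_backward(dec$caches$d1, b2$dH)
        list(dec2 = b2$grads, dec1 = b1$grads, dEmb = b1$dH)
      }
      bt <- back_path(rna, dec_t$recon, enc_t, dec_t)
      bp <- back_path(protein, dec_p$recon, enc_p, dec_p)
      dT <- bt$dEmb
      dP <- bp$dEmb
      if (!is.null(dZ)) {
        dT <- dT + dZ[, seq_len(d), drop = FALSE]
        dP <- dP + dZ[, d + seq_len(d), drop = FALSE]
      }
      enc_back <- function(enc, dEmb) {
        b2 <- gat_backward(enc$caches$e2, dEmb)
        b1 <- gat_backward(enc$caches$e1, b2$dH)
        list(enc2 = b2$grads, enc1 = b1$grads)
      }
      et <- enc_back(enc_t, dT)
      epg <- enc_back(enc_p, dP)
      grads$t <- list(enc1 = et$enc1, enc2 = et$enc2,
                      dec1 = bt$dec1, dec2 = bt$dec2)
      grads$p <- list(enc1 = epg$enc1, enc2 = epg$enc2,
                      dec1 = bp$dec1, dec2 = bp$dec2)
      params <- adam_step(params, grads, state, lr, ep)
    }
    # embedding from the final parameters
    T_emb <- encode_path(rna, ed_t, params$t)$emb
    P_emb <- encode_path(protein, ed_p, params$p)$emb
    structure(list(params = params,
                   T_emb = T_emb, P_emb = P_emb,
                   Z = cbind(T_emb, P_emb),
                   history = data.frame(epoch = seq_len(epochs), hist),
                   config = list(embedding_dim = d, hidden_dim = hidden_dim,
                                 epochs = epochs, lr = lr, lambda = lambda,
                                 margin = margin, per_anchor = per_anchor,
                                 self_supervision = self_supervision,
                                 seed = seed)),
              class = "gate_fit")
  })
}
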