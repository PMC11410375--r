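# Dual-path graph attention auto-encoder: layer primitives.
#
# A layer computes out_i = act( sum_j alpha_ij * (W' h_j + b) ) where j runs
# over the cell's pruned neighbours plus a self-loop.  With attention on,
# alpha is a softmax over GAT-style additive scores
#   e_ij = LeakyReLU_{0.2}( a_src . g_i + a_dst . g_j ),  g = W' h + b;
# with attention off, alpha_ij = 1/deg(i) (uniform).  Message passing uses
# the binary graph structure only; stored distance weights are not consumed.
# Both forward and backward passes are written out explicitly so training is
# fully deterministic and dependency-free.

LEAKY_SLOPE <- 0.2

activate <- function(pre, act) {
  switch(act,
         relu = pmax(pre, 0),
         tanh = tanh(pre),
         linear = pre,
         stop("unknown activation ", act))
}

activate_grad <- function(cache) {
  switch(cache$act,
         relu = (cache$pre > 0) * 1,
         tanh = 1 - cache$out^2,
         linear = 1)
}

# Precompute the message-passing edge structure for one graph: directed
# edges (i <- j) plus a self-loop on every cell, sorted by receiver.
model_edges <- function(graph) {
  stopifnot(inherits(graph, "duogate_graph"))
  m <- graph$m
  src <- c(graph$edges$from, seq_len(m))
  dst <- c(graph$edges$to, seq_len(m))
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]
  deg <- tabulate(src, nbins = m)
  list(src = src, dst = dst, m = m, deg = deg,
       split = split(seq_along(src), src),
       A0 = sparseMatrix(i = src, j = dst, x = 1 / deg[src], dims = c(m, m)))
}

init_layer <- function(in_dim, out_dim, attention) {
  lim <- sqrt(6 / (in_dim + out_dim))
  lay <- list(W = matrix(runif(in_dim * out_dim, -lim, lim), in_dim, out_dim),
              b = numeric(out_dim))
  if (attention) {
    la <- sqrt(6 / (out_dim + 1))
    lay$a_src <- runif(out_dim, -la, la)
    lay$a_dst <- runif(out_dim, -la, la)
  }
  lay
}

#' Initialise the parameters of one graph-attention auto-encoder path
#'
#' Encoder: attention layer (input -> hidden, ReLU) then plain aggregation
#' layer (hidden -> embedding, Tanh).  Decoder mirrors the encoder
#' (embedding -> hidden, ReLU; hidden -> input, attention, linear output).
#' Decoder weights are independent parameters, not transposed encoder
#' weights.  Initialisation is Xavier-uniform, seeded.
#'
#' @param input_dim number of input features for this path.
#' @param hidden_dim hidden width (default 256).
#' @param embedding_dim per-path embedding dimension (default 30).
#' @param seed RNG seed.
#' @return object of class `gate_params`: list of layers `enc1`, `enc2`,
#'   `dec1`, `dec2`, each with `W`, `b` and (attention layers) `a_src`,
#'   `a_dst`.
#' @export
gate_init <- function(input_dim, hidden_dim = 256, embedding_dim = 30,
                      seed = 1) {
  stopifnot(embedding_dim >= 1, hidden_dim >= embedding_dim)
  with_seed(seed, gate_init_raw(input_dim, hidden_dim, embedding_dim))
}

gate_init_raw <- function(input_dim, hidden_dim, embedding_dim) {
  structure(list(enc1 = init_layer(input_dim, hidden_dim, TRUE),
                 enc2 = init_layer(hidden_dim, embedding_dim, FALSE),
                 dec1 = init_layer(embedding_dim, hidden_dim, FALSE),
                 dec2 = init_layer(hidden_dim, input_dim, TRUE),
                 dims = c(input = input_dim, hidden = hidden_dim,
                          embedding = embedding_dim)),
            class = "gate_params")
}

gat_forward <- function(H, ed, par, attention, act) {
  G <- H %*% par$W
  G <- G + rep(par$b, each = nrow(G))
  if (attention) {
    s <- as.vector(G %*% par$a_src)
    t_ <- as.vector(G %*% par$a_dst)
    raw <- s[ed$src] + t_[ed$dst]
    lr <- ifelse(raw > 0, raw, LEAKY_SLOPE * raw)
    gmax <- vapply(ed$split, function(ix) max(lr[ix]), numeric(1))
    ex <- exp(lr - gmax[ed$src])
    den <- rowsum(cbind(ex), ed$src)[, 1L]
    alpha <- ex / den[ed$src]
    A <- sparseMatrix(i = ed$src, j = ed$dst, x = alpha, dims = c(ed$m, ed$m))
  } else {
    raw <- NULL; alpha <- NULL
    A <- ed$A0
  }
  pre <- as.matrix(A %*% G)
  out <- activate(pre, act)
  list(out = out,
       cache = list(H = H, G = G, A = A, alpha = alpha, raw = raw, pre = pre,
                    out = out, attention = attention, act = act, par = par,
                    ed = ed))
}

gat_backward <- function(cache, dout) {
  ed <- cache$ed
  par <- cache$par
  dpre <- dout * activate_grad(cache)
  dG <- as.matrix(Matrix::crossprod(cache$A, dpre))
  grads <- list()
  if (cache$attention) {
    # dalpha_ij = <dpre_i, g_j> over edges; one dense BLAS product beats
    # per-edge row indexing at this scale, edgewise fallback for large m
    dalpha <- if (ed$m <= 2000L) {
      tcrossprod(dpre, cache$G)[cbind(ed$src, ed$dst)]
    } else {
      rowSums(dpre[ed$src, , drop = FALSE] *
                cache$G[ed$dst, , drop = FALSE])
    }
    S <- rowsum(cbind(cache$alpha * dalpha), ed$src)[, 1L]
    de <- cache$alpha * (dalpha - S[ed$src])
    draw <- de * ifelse(cache$raw > 0, 1, LEAKY_SLOPE)
    ds <- rowsum(cbind(draw), ed$src)[, 1L]
    dt <- rowsum(cbind(draw), ed$dst)[, 1L]
    dG <- dG + outer(ds, par$a_src) + outer(dt, par$a_dst)
    grads$a_src <- as.vector(crossprod(cache$G, ds))
    grads$a_dst <- as.vector(crossprod(cache$G, dt))
  }
  grads$W <- crossprod(cache$H, dG)
  grads$b <- colSums(dG)
  list(dH = tcrossprod(dG, par$W), grads = grads)
}

#' Apply one graph-attention layer
#'
#' Single forward application of the layer primitive used throughout the
#' model.  A self-loop is added to every cell before aggregation.  With
#' `use_attention = FALSE` the aggregation weights are uniform over the
#' neighbourhood (including the self-loop).
#'
#' @param H cells x in_dim feature matrix.
#' @param graph a `duogate_graph` over the same cells.
#' @param params layer parameter list with `W` (in_dim x out_dim), `b`, and
#'   for attention `a_src`, `a_dst` (length out_dim).
#' @param use_attention logical.
#' @param activation `"relu"`, `"tanh"` or `"linear"`.
#' @return cells x out_dim matrix.  Attribute `"alpha"` carries the edge
#'   data.frame (src, dst, weight) of aggregation weights actually used.
#' @export
attention_layer <- function(H, graph, params, use_attention = TRUE,
                            activation = c("relu", "tanh", "linear")) {
  activation <- match.arg(activation)
  H <- as_dense_matrix(H, "H")
  stop_if_not_finite(H, "attention_layer input")
  ed <- model_edges(graph)
  if (nrow(H) != ed$m) stop("H and graph cell counts differ", call. = FALSE)
  if (ncol(H) != nrow(params$W)) stop("H/params shape mismatch", call. = FALSE)
  fw <- gat_forward(H, ed, params, use_attention, activation)
  w <- if (use_attention) fw$cache$alpha else 1 / ed$deg[ed$src]
  attr(fw$out, "alpha") <- data.frame(src = ed$src, dst = ed$dst, weight = w)
  fw$out
}

encode_path <- function(X, ed, par) {
  e1 <- gat_forward(X, ed, par$enc1, TRUE, "relu")
  e2 <- gat_forward(e1$out, ed, par$enc2, FALSE, "tanh")
  list(emb = e2$out, caches = list(e1 = e1$cache, e2 = e2$cache))
}

decode_path <- function(emb, ed, par) {
  d1 <- gat_forward(emb, ed, par$dec1, FALSE, "relu")
  d2 <- gat_forward(d1$out, ed, par$dec2, TRUE, "linear")
  list(recon = d2$out, caches = list(d1 = d1$cache, d2 = d2$cache))
}

#' Encode one modality into its embedding
#'
#' Two-layer graph-attention encoder: attention + ReLU to the hidden width,
#' then uniform aggregation + Tanh to the embedding.  All outputs lie in
#' \[-1, 1\].
#'
#' @param X normalised cells x features matrix.
#' @param graph `duogate_graph` over the same cells.
#' @param params `gate_params` for this path.
#' @return cells x embedding_dim matrix.
#' @export
gate_encode <- function(X, graph, params) {
  X <- as_dense_matrix(X, "X")
  stop_if_not_finite(X, "encoder input")
  ed <- model_edges(graph)
  enc <- encode_path(X, ed, params)
  if (!all(is.finite(enc$emb))) stop("non-finite encoder output", call. = FALSE)
  enc$emb
}

#' Decode an embedding back to feature space
#'
#' Mirror of [gate_encode()]: uniform aggregation + ReLU to the hidden
#' width, then attention + linear output at the original input dimension.
#'
#' @param emb cells x embedding_dim matrix.
#' @param graph `duogate_graph` over the same cells.
#' @param params `gate_params` for this path.
#' @return cells x input_dim reconstruction.
#' @export
gate_decode <- function(emb, graph, params) {
  emb <- as_dense_matrix(emb, "emb")
  stop_if_not_finite(emb, "decoder input")
  ed <- model_edges(graph)
  dec <- decode_path(emb, ed, params)
  dec$recon
}

#' Concatenate the two modality embeddings into the joint representation
#'
#' @param T_emb transcriptome embedding (cells x d).
#' @param P_emb proteome embedding (same cells, cells x d').
#' @return cells x (d + d') matrix, transcriptome block first.
#' @export
concat_embeddings <- function(T_emb, P_emb) {
  T_emb <- as_dense_matrix(T_emb, "T_emb")
  P_emb <- as_dense_matrix(P_emb, "P_emb")
  if (nrow(T_emb) != nrow(P_emb)) {
    stop("embeddings must cover the same cells", call. = FALSE)
  }
  cbind(T_emb, P_emb)
}
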