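# helpers to build a small graph quickly
toy_graph <- function(X, n = 3, labels = NULL, seed = 1) {
  D <- pairwise_euclidean(X)
  if (is.null(labels)) labels <- rep(1L, nrow(X))
  assemble_graph(D, prune_neighbors(knn_sets(D, n), labels), labels = labels)
}

test_that("attention_layer matches the dense per-cell oracle", {
  set.seed(30)
  m <- 8
  X <- matrix(rnorm(m * 5), m, 5)
  g <- toy_graph(X, 3)
  par <- gate_init(5, hidden_dim = 6, embedding_dim = 2, seed = 7)$enc1
  for (att in c(TRUE, FALSE)) for (act in c("relu", "tanh", "linear")) {
    out <- attention_layer(X, g, par, use_attention = att, activation = act)
    ref <- oracle_gat(X, as.matrix(g$B), par, att, act)
    expect_equal(unclass(out), ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("attention weights are a softmax over the closed neighbourhood", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  g <- toy_graph(X, 3)
  par <- gate_init(4, 8, 2, seed = 1)$enc1
  out <- attention_layer(X, g, par, use_attention = TRUE)
  al <- attr(out, "alpha")
  sums <- as.vector(tapply(al$weight, al$src, sum))
  expect_equal(sums, rep(1, 10), tolerance = 1e-12)
  # uniform weights without attention: cell with two neighbours gets 1/3 each
  out0 <- attention_layer(X, g, par, use_attention = FALSE)
  al0 <- attr(out0, "alpha")
  deg <- table(al0$src)
  expect_equal(unname(al0$weight), 1 / as.vector(deg)[al0$src],
               tolerance = 1e-12)
})

test_that("an isolated cell aggregates only itself", {
  X <- rbind(c(0, 0), c(10, 0), c(10.5, 0))
  D <- pairwise_euclidean(X)
  # cell 1's neighbours all pruned away -> self-loop only at model time
  g <- assemble_graph(D, list(integer(), 3L, 2L))
  par <- gate_init(2, 4, 2, seed = 3)$enc1
  out <- attention_layer(X, g, par, use_attention = TRUE,
                         activation = "linear")
  expect_equal(unclass(out)[1, ],
               as.vector(X[1, , drop = FALSE] %*% par$W + par$b),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("encoder output is Tanh-bounded and zero maps to zero", {
  set.seed(32)
  X <- matrix(rnorm(60), 12, 5)
  g <- toy_graph(X, 4)
  par <- gate_init(5, 8, 3, seed = 2)
  emb <- gate_encode(X, g, par)
  expect_true(all(abs(emb) <= 1))
  expect_equal(dim(emb), c(12L, 3L))
  # zero input, zero biases -> zero embedding and zero reconstruction
  emb0 <- gate_encode(matrix(0, 12, 5), g, par)
  expect_equal(emb0, matrix(0, 12, 3))
  rec0 <- gate_decode(matrix(0, 12, 3), g, par)
  expect_equal(rec0, matrix(0, 12, 5))
})

test_that("decoder mirrors encoder dimensions", {
  set.seed(33)
  X <- matrix(rnorm(100), 20, 5)
  g <- toy_graph(X, 4)
  par <- gate_init(5, 16, 4, seed = 5)
  emb <- gate_encode(X, g, par)
  rec <- gate_decode(emb, g, par)
  expect_equal(dim(rec), dim(X))
})

test_that("the model is equivariant to a joint permutation of cells", {
  set.seed(34)
  m <- 15
  X <- matrix(rnorm(m * 4), m, 4)
  lab <- random_labels(m, 2)
  g <- toy_graph(X, 4, labels = lab)
  par <- gate_init(4, 8, 3, seed = 9)
  emb <- gate_encode(X, g, par)
  perm <- sample(m)
  Xp <- X[perm, ]
  # permute the graph the same way
  inv <- order(perm)
  D <- pairwise_euclidean(Xp)
  sets_p <- lapply(perm, function(i) inv[g$edges$to[g$edges$from == i]])
  gp <- assemble_graph(D, sets_p)
  embp <- gate_encode(Xp, gp, par)
  expect_equal(embp, emb[perm, ], tolerance = 1e-10)
})

test_that("concat_embeddings stacks transcriptome block first", {
  T_emb <- matrix(rnorm(60), 10, 6)
  P_emb <- matrix(rnorm(60), 10, 6)
  Z <- concat_embeddings(T_emb, P_emb)
  expect_equal(ncol(Z), 12L)
  expect_equal(Z[, 1:6], T_emb)
  expect_equal(Z[, 7:12], P_emb)
  Z0 <- concat_embeddings(T_emb, P_emb * 0)
  expect_true(all(Z0[, 7:12] == 0))
  expect_error(concat_embeddings(T_emb, P_emb[1:5, ]), "same cells")
})

test_that("analytic gradients match finite differences through all layers", {
  # a full backward pass over a tiny dual-path instance, checked against
  # central finite differences of the package's own loss
  set.seed(35)
  m <- 10
  rna <- matrix(rnorm(m * 6), m, 6)
  prot <- matrix(rnorm(m * 3), m, 3)
  lab <- rep(1:2, each = 5)
  g_t <- toy_graph(rna, 3, labels = lab)
  g_p <- toy_graph(prot, 3, labels = lab)
  graphs <- list(rna = g_t, protein = g_p)
  ed_t <- duogate:::model_edges(g_t)
  ed_p <- duogate:::model_edges(g_p)
  params <- list(t = duogate:::gate_init_raw(6, 5, 2),
                 p = duogate:::gate_init_raw(3, 5, 2))
  trips_t <- sample_triplets(g_t, per_anchor = 2, seed = 1)
  trips_p <- sample_triplets(g_p, per_anchor = 2, seed = 2)
  lambda <- 0.1; margin <- 1

  loss_fn <- function(params) {
    et <- duogate:::encode_path(rna, ed_t, params$t)
    ep <- duogate:::encode_path(prot, ed_p, params$p)
    Z <- cbind(et$emb, ep$emb)
    dt <- duogate:::decode_path(et$emb, ed_t, params$t)
    dp <- duogate:::decode_path(ep$emb, ed_p, params$p)
    mean((rna - dt$recon)^2) + mean((prot - dp$recon)^2) +
      lambda * (duogate:::triplet_loss_grad(Z, trips_t, margin, FALSE)$loss +
                  duogate:::triplet_loss_grad(Z, trips_p, margin, FALSE)$loss)
  }

  # analytic gradients (same chain as fit_gate)
  et <- duogate:::encode_path(rna, ed_t, params$t)
  ep <- duogate:::encode_path(prot, ed_p, params$p)
  Z <- cbind(et$emb, ep$emb)
  dt <- duogate:::decode_path(et$emb, ed_t, params$t)
  dp <- duogate:::decode_path(ep$emb, ed_p, params$p)
  st <- duogate:::triplet_loss_grad(Z, trips_t, margin)
  sp <- duogate:::triplet_loss_grad(Z, trips_p, margin)
  dZ <- lambda * (st$dZ + sp$dZ)
  back <- function(X, enc, dec, dEmb_extra) {
    b2 <- duogate:::gat_backward(dec$caches$d2, 2 * (dec$recon - X) / length(X))
    b1 <- duogate:::gat_backward(dec$caches$d1, b2$dH)
    e2 <- duogate:::gat_backward(enc$caches$e2, b1$dH + dEmb_extra)
    e1 <- duogate:::gat_backward(enc$caches$e1, e2$dH)
    list(enc1 = e1$grads, enc2 = e2$grads, dec1 = b1$grads, dec2 = b2$grads)
  }
  grads <- list(t = back(rna, et, dt, dZ[, 1:2]),
                p = back(prot, ep, dp, dZ[, 3:4]))

  eps <- 1e-6
  for (path in c("t", "p")) for (layer in c("enc1", "enc2", "dec1", "dec2")) {
    for (tensor in intersect(names(params[[path]][[layer]]),
                             c("W", "b", "a_src", "a_dst"))) {
      th <- params[[path]][[layer]][[tensor]]
      idx <- sample(length(th), min(4, length(th)))
      for (i in idx) {
        pp <- params; pp[[path]][[layer]][[tensor]][i] <- th[i] + eps
        pm <- params; pm[[path]][[layer]][[tensor]][i] <- th[i] - eps
        num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
        ana <- grads[[path]][[layer]][[tensor]][i]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste("grad", path, layer, tensor, i))
      }
    }
  }
})
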