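test_that("attention degenerates correctly on singletons and identity masks", {
  # single node: softmax of a singleton is 1, Z = x Wv
  Wv <- matrix(c(0.5, -2), 1, 2)
  p <- list(Wq = matrix(1, 1, 2), Wk = matrix(1, 1, 2), Wv = Wv)
  X <- matrix(3, 1, 1)
  Z <- masked_attention(X, p)
  expect_equal(unclass(Z), X %*% Wv, ignore_attr = TRUE)
  expect_equal(attr(Z, "weights")[[1]][1, 1], 1)

  # identity mask: every node attends only to itself
  X3 <- matrix(c(0, 1, 2), 3, 1)
  Z3 <- masked_attention(X3, p, diag(3))
  expect_equal(unclass(Z3), X3 %*% Wv, ignore_attr = TRUE)
})

test_that("three-node attention matches the hand computation", {
  X <- matrix(c(0, 1, 2), 3, 1)
  p <- list(Wq = matrix(1), Wk = matrix(1), Wv = matrix(1))
  Z <- masked_attention(X, p)
  # scores s_ij = x_i x_j / sqrt(1); row softmax applied to X
  expected <- vapply(1:3, function(i) {
    e <- exp(X[i, 1] * X[, 1] - max(X[i, 1] * X[, 1]))
    sum((e / sum(e)) * X[, 1])
  }, numeric(1))
  expect_equal(as.numeric(Z), expected, tolerance = 1e-12)
})

test_that("attention matches the brute-force oracle on random graphs", {
  set.seed(71)
  for (trial in 1:100) {
    n <- sample(2:6, 1)
    H <- sample(1:3, 1)
    d <- sample(1:4, 1)
    X <- matrix(runif(n, 0, 2), n, 1)
    p <- random_attention_params(H, d, with_proj = TRUE)
    mask <- random_node_mask(n)
    Z <- masked_attention(X, p, mask)
    Zref <- naive_masked_attention(X, p$Wq, p$Wk, p$Wv, p$Wo, p$bo, mask)
    expect_equal(unclass(Z), Zref, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("mask semantics: zeros where masked, rows sum to one", {
  set.seed(72)
  for (trial in 1:25) {
    n <- sample(2:6, 1)
    X <- matrix(runif(n, 0, 2), n, 1)
    p <- random_attention_params(2, 3, with_proj = FALSE)
    mask <- random_node_mask(n, 0.5)
    W <- attr(masked_attention(X, p, mask), "weights")
    for (h in seq_along(W)) {
      expect_true(all(W[[h]][mask == 0] == 0))
      expect_equal(rowSums(W[[h]]), rep(1, n), tolerance = 1e-6)
    }
    # all-ones mask equals unmasked attention
    Zu <- masked_attention(X, p)
    Zm <- masked_attention(X, p, matrix(1, n, n))
    expect_equal(unclass(Zm), unclass(Zu), ignore_attr = TRUE)
  }
})

test_that("a node with an empty attention row is rejected", {
  X <- matrix(1:2, 2, 1)
  p <- random_attention_params(1, 2, with_proj = FALSE)
  bad <- matrix(c(0, 1, 1, 1), 2, 2)
  expect_error(masked_attention(X, p, bad), "diagonal")
})

test_that("neighbor sampling is uniform, deterministic and a no-op when k is large", {
  s <- sample_neighbors(5, 10)
  expect_true(all(vapply(s, length, 1L) == 5))

  set.seed(9); a <- sample_neighbors(10, 3)
  set.seed(9); b <- sample_neighbors(10, 3)
  expect_identical(a, b)

  set.seed(10)
  hits <- numeric(10)
  for (r in 1:2000) {
    s <- sample_neighbors(10, 2)
    hits <- hits + tabulate(unlist(lapply(seq_along(s), function(i)
      setdiff(s[[i]], i))), 10)
  }
  # each ordered (node, candidate) pair selected w.p. 2/9 per draw
  p_hat <- hits / (2000 * 9)
  se <- sqrt((2 / 9) * (7 / 9) / (2000 * 9))
  expect_true(all(abs(p_hat - 2 / 9) < 4 * se))
})

test_that("graph convolution matches closed forms and is equivariant", {
  # zero adjacency: self-loops only, sym normalization is identity
  Z <- matrix(rnorm(8), 4, 2)
  Wg <- matrix(rnorm(6), 2, 3)
  A0 <- matrix(0, 4, 4)
  expect_equal(gnn_layer(A0, Z, Wg, activation = "identity"), Z %*% Wg)
  expect_equal(gnn_layer(A0, Z, Wg), pmax(Z %*% Wg, 0))

  # two-node path, closed-form symmetric normalization: every entry 1/2
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  Z2 <- matrix(c(1, 3), 2, 1)
  out <- gnn_layer(A2, Z2, matrix(1), activation = "identity")
  expect_equal(as.numeric(out), c((1 + 3) / 2, (1 + 3) / 2))

  # mean aggregation agrees here (degree 2 for both nodes)
  outm <- gnn_layer(A2, Z2, matrix(1), activation = "identity",
                    normalize = "mean")
  expect_equal(as.numeric(outm), c(2, 2))

  # permutation equivariance
  set.seed(5)
  A <- random_node_mask(5, 0.4); diag(A) <- 0
  Z5 <- matrix(rnorm(10), 5, 2)
  perm <- sample(5)
  direct <- gnn_layer(A[perm, perm], Z5[perm, , drop = FALSE], Wg[1:2, ])
  expect_equal(direct, gnn_layer(A, Z5, Wg[1:2, ])[perm, , drop = FALSE])

  expect_error(gnn_layer(A2, Z, Wg), "node count")
})

test_that("sum readout is permutation invariant and linear", {
  Z <- matrix(rnorm(12), 4, 3)
  head <- list(w = c(1, -1, 2), b = 0.5)
  expect_equal(as.numeric(readout_predict(matrix(0, 3, 3), head)), head$b)
  y <- readout_predict(Z, head)
  expect_equal(as.numeric(readout_predict(Z[sample(4), ], head)),
               as.numeric(y))
  head0 <- list(w = head$w, b = 0)
  expect_equal(as.numeric(readout_predict(rbind(Z, Z), head0)),
               2 * as.numeric(readout_predict(Z, head0)))
  expect_error(readout_predict(Z[0, , drop = FALSE], head), "empty")
})

test_that("forward pass composes the stages and respects the ablation flags", {
  co <- small_sim_cohort(12, seed = 41)
  prep <- fit_preprocessing(co)
  g <- build_cohort_graphs(co, "Lab", scaler = prep$scaler,
                           tfidf = prep$tfidf)[[1]]

  mc <- model_config(n_heads = 2, d = 4, d_model = 5, gnn_hidden = 6,
                     k = 100, seed = 3)
  params <- init_graphformer(mc)

  # mask flag off equals mask of all ones
  ones <- prep$mask
  ones$M[] <- 1
  mc_off <- mc; mc_off$use_mask <- FALSE
  f1 <- graphformer_forward(g, ones, mc, params)
  f2 <- graphformer_forward(g, ones, mc_off, params)
  expect_equal(f1$prediction, f2$prediction)

  # full model equals the manual three-stage composition
  nm <- expand_mask_to_nodes(prep$mask, g)
  Z <- masked_attention(g$X, params, nm)
  Zp <- gnn_layer(g$A, Z, params$Wg, bias = params$bg)
  yhat <- readout_predict(Zp, list(w = params$w, b = params$b))
  full <- graphformer_forward(g, prep$mask, mc, params)
  expect_equal(full$prediction, as.numeric(yhat), tolerance = 1e-12)
  expect_equal(full$embedding, attr(yhat, "embedding"), tolerance = 1e-12)

  # GNN-only on an edgeless graph: per-node transform + sum + linear
  mc_g <- model_config(use_transformer = FALSE, gnn_hidden = 6, seed = 3)
  pg <- init_graphformer(mc_g)
  g0 <- g; g0$A[] <- 0
  fg <- graphformer_forward(g0, prep$mask, mc_g, pg)
  manual <- sum(colSums(pmax(sweep(g$X %*% pg$Wg, 2, pg$bg, `+`), 0)) * pg$w) +
    pg$b
  expect_equal(fg$prediction, manual, tolerance = 1e-12)

  expect_error(model_config(use_gnn = FALSE, use_transformer = FALSE),
               "at least one")
})

test_that("predictions are invariant to node reordering", {
  co <- small_sim_cohort(6, seed = 42)
  prep <- fit_preprocessing(co)
  g <- build_cohort_graphs(co, "Lab", scaler = prep$scaler,
                           tfidf = prep$tfidf)[[2]]
  mc <- model_config(k = 100, seed = 4)
  params <- init_graphformer(mc)
  base <- graphformer_forward(g, prep$mask, mc, params)
  set.seed(8)
  perm <- sample(nrow(g$X))
  gp <- g
  gp$X <- g$X[perm, , drop = FALSE]
  gp$A <- g$A[perm, perm]
  gp$nodes <- g$nodes[perm, ]
  permuted <- graphformer_forward(gp, prep$mask, mc, params)
  expect_equal(permuted$prediction, base$prediction, tolerance = 1e-10)
  expect_equal(permuted$embedding, base$embedding, tolerance = 1e-10)
})

test_that("the C++ engine reproduces the R forward pass on all variants", {
  co <- small_sim_cohort(10, seed = 43)
  prep <- fit_preprocessing(co)
  graphs <- build_cohort_graphs(co, "Lab", scaler = prep$scaler,
                                tfidf = prep$tfidf)
  y <- vapply(graphs, `[[`, numeric(1), "target")
  y <- (y - mean(y)) / sd(y)
  for (flags in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))) {
    mc <- model_config(n_heads = 2, d = 3, d_model = 4, gnn_hidden = 5,
                       use_transformer = flags[1], use_gnn = flags[2],
                       k = 1000, seed = 7)
    params <- init_graphformer(mc)
    inputs <- graphDBP:::engine_inputs(graphs, prep, mc)
    for (i in seq_along(inputs))
      inputs[[i]]$gate <- inputs[[i]]$base_mask
    res <- graphDBP:::gf_batch_grad(inputs, y, params, mc$use_transformer,
                                    mc$use_gnn, want_grad = FALSE)
    rpreds <- vapply(graphs, function(g)
      graphformer_forward(g, prep$mask, mc, params)$prediction, numeric(1))
    expect_equal(as.numeric(res$preds), unname(rpreds), tolerance = 1e-10)
    expect_equal(res$loss, mean((rpreds - y)^2), tolerance = 1e-10)
  }
})

test_that("analytic gradients agree with numerical differentiation", {
  co <- small_sim_cohort(8, seed = 44)
  prep <- fit_preprocessing(co)
  graphs <- build_cohort_graphs(co, "Lab", scaler = prep$scaler,
                                tfidf = prep$tfidf)[1:4]
  y <- c(-0.5, 0.2, 1.1, -0.8)
  mc <- model_config(n_heads = 2, d = 3, d_model = 4, gnn_hidden = 5,
                     k = 1000, seed = 9)
  params <- init_graphformer(mc)
  inputs <- graphDBP:::engine_inputs(graphs, prep, mc)
  for (i in seq_along(inputs)) inputs[[i]]$gate <- inputs[[i]]$base_mask
  res <- graphDBP:::gf_batch_grad(inputs, y, params, TRUE, TRUE, TRUE)

  rloss <- function(p) {
    preds <- vapply(graphs, function(g)
      graphformer_forward(g, prep$mask, mc, p)$prediction, numeric(1))
    mean((preds - y)^2)
  }
  eps <- 1e-6
  check_leaf <- function(get, set, analytic) {
    val <- get(params)
    idx <- if (length(val) > 3) sample(seq_along(val), 3) else seq_along(val)
    for (i in idx) {
      up <- val; up[i] <- up[i] + eps
      dn <- val; dn[i] <- dn[i] - eps
      num <- (rloss(set(params, up)) - rloss(set(params, dn))) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-5)
    }
  }
  set.seed(12)
  check_leaf(function(p) p$Wq[[1]], function(p, v) { p$Wq[[1]][] <- v; p },
             as.numeric(res$grads$Wq[[1]]))
  check_leaf(function(p) p$Wk[[2]], function(p, v) { p$Wk[[2]][] <- v; p },
             as.numeric(res$grads$Wk[[2]]))
  check_leaf(function(p) p$Wv[[1]], function(p, v) { p$Wv[[1]][] <- v; p },
             as.numeric(res$grads$Wv[[1]]))
  check_leaf(function(p) p$Wo, function(p, v) { p$Wo[] <- v; p },
             as.numeric(res$grads$Wo))
  check_leaf(function(p) p$bo, function(p, v) { p$bo <- v; p },
             as.numeric(res$grads$bo))
  check_leaf(function(p) p$Wg, function(p, v) { p$Wg[] <- v; p },
             as.numeric(res$grads$Wg))
  check_leaf(function(p) p$bg, function(p, v) { p$bg <- v; p },
             as.numeric(res$grads$bg))
  check_leaf(function(p) p$w, function(p, v) { p$w <- v; p },
             as.numeric(res$grads$w))
  check_leaf(function(p) p$b, function(p, v) { p$b <- v; p }, res$grads$b)
})

test_that("masking plus sampling always keeps self-attention alive", {
  set.seed(13)
  n <- 8
  mask <- random_node_mask(n, 0.3)
  samples <- sample_neighbors(n, 2)
  gate <- graphDBP:::combine_mask_samples(mask, samples, n)
  expect_true(all(diag(gate) == 1))
  expect_true(all(gate <= mask | diag(n) == 1))
})
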