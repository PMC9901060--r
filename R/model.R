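#' Graph Transformer model configuration
#'
#' The model composes (i) masked multi-head scaled dot-product
#' self-attention over the patient graph's node features, gated by the
#' cohort co-occurrence mask and by uniform neighbor sampling, (ii) one
#' symmetric-normalized graph convolution over the temporal adjacency, and
#' (iii) a sum readout with a linear forecasting head.  Ablations switch
#' either component off (at least one must stay on).
#'
#' @param n_heads Number of attention heads.
#' @param d Dimensionality of each head (scaling factor is `sqrt(d)`).
#' @param d_model Output dimension of the concatenated-head projection.
#' @param k Neighbor sample size per node during training; a node's
#'   attention is restricted to (sampled neighbors intersected with the
#'   mask-allowed set) plus itself.
#' @param gnn_hidden Width of the graph-convolution layer.
#' @param use_mask Gate attention with the co-occurrence mask.
#' @param use_gnn,use_transformer Component flags for the ablation grid.
#' @param gnn_normalize `"sym"` for symmetric-normalized aggregation with
#'   self-loops, `"mean"` for row-normalized mean aggregation.
#' @param seed Seed for weight initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(n_heads = 4, d = 16, d_model = 16, k = 10,
                         gnn_hidden = 16, use_mask = TRUE, use_gnn = TRUE,
                         use_transformer = TRUE,
                         gnn_normalize = c("sym", "mean"), seed = 1) {
  gnn_normalize <- match.arg(gnn_normalize)
  if (!use_gnn && !use_transformer)
    stop("model_config: at least one of use_gnn/use_transformer must be TRUE")
  stopifnot(n_heads >= 1, d >= 1, d_model >= 1, k >= 1, gnn_hidden >= 1)
  structure(list(n_heads = as.integer(n_heads), d = as.integer(d),
                 d_model = as.integer(d_model), k = as.integer(k),
                 gnn_hidden = as.integer(gnn_hidden), use_mask = use_mask,
                 use_gnn = use_gnn, use_transformer = use_transformer,
                 gnn_normalize = gnn_normalize, seed = as.integer(seed)),
            class = "model_config")
}

## Uniform fan-in-scaled initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_mat <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) / sqrt(nr), nr, nc)
}

#' Initialize Graph Transformer parameters
#'
#' @param config A [model_config()].
#' @param in_dim Node feature dimension (1 for the position-aware scalar
#'   features).
#' @return Named parameter list: per-head projections `Wq`, `Wk`, `Wv`
#'   (lists of `in_dim x d` matrices), output projection `Wo`
#'   (`n_heads*d x d_model`), graph-convolution weight `Wg`, and the linear
#'   head `w`, `b`.
#' @export
init_graphformer <- function(config, in_dim = 1) {
  set.seed(config$seed)
  params <- list()
  if (config$use_transformer) {
    params$Wq <- lapply(seq_len(config$n_heads), function(h)
      init_mat(in_dim, config$d))
    params$Wk <- lapply(seq_len(config$n_heads), function(h)
      init_mat(in_dim, config$d))
    params$Wv <- lapply(seq_len(config$n_heads), function(h)
      init_mat(in_dim, config$d))
    params$Wo <- init_mat(config$n_heads * config$d, config$d_model)
    params$bo <- numeric(config$d_model)
  }
  gnn_in <- if (config$use_transformer) config$d_model else in_dim
  if (config$use_gnn) {
    params$Wg <- init_mat(gnn_in, config$gnn_hidden)
    params$bg <- numeric(config$gnn_hidden)
  }
  out_dim <- if (config$use_gnn) config$gnn_hidden else config$d_model
  params$w <- as.numeric(init_mat(out_dim, 1))
  params$b <- 0
  params
}

#' Masked multi-head scaled dot-product self-attention
#'
#' Per head, scores are `Q K' / sqrt(d)` with masked-out pairs set to
#' `-Inf` before the row softmax, so attention weights are row-stochastic
#' over unmasked entries and exactly zero elsewhere; `Z = weights %*% V`.
#' Head outputs are concatenated and, if an output projection is present,
#' linearly projected.
#'
#' @param X Node feature matrix (|V| x in_dim).
#' @param params List with per-head `Wq`, `Wk`, `Wv` (each a list of
#'   matrices, or a single matrix for one head) and optional `Wo`.
#' @param node_mask Binary |V| x |V| matrix with an all-ones diagonal;
#'   `NULL` means unmasked.
#' @return Z, |V| x d_model; attribute `"weights"` holds the per-head
#'   attention matrices.
#' @export
masked_attention <- function(X, params, node_mask = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("masked_attention: X must be finite")
  Wq <- params$Wq; Wk <- params$Wk; Wv <- params$Wv
  if (is.matrix(Wq)) { Wq <- list(Wq); Wk <- list(Wk); Wv <- list(Wv) }
  n <- nrow(X)
  if (!is.null(node_mask)) {
    stopifnot(nrow(node_mask) == n, ncol(node_mask) == n)
    if (any(diag(node_mask) == 0))
      stop("masked_attention: node_mask diagonal must be all ones")
  }
  heads <- vector("list", length(Wq))
  weights <- vector("list", length(Wq))
  for (h in seq_along(Wq)) {
    Q <- X %*% Wq[[h]]; K <- X %*% Wk[[h]]; V <- X %*% Wv[[h]]
    S <- (Q %*% t(K)) / sqrt(ncol(Q))
    if (!is.null(node_mask)) S[node_mask == 0] <- -Inf
    P <- softmax_rows(S)
    weights[[h]] <- P
    heads[[h]] <- P %*% V
  }
  Z <- do.call(cbind, heads)
  if (!is.null(params$Wo)) {
    Z <- Z %*% params$Wo
    if (!is.null(params$bo)) Z <- sweep(Z, 2, params$bo, `+`)
  }
  attr(Z, "weights") <- weights
  Z
}

softmax_rows <- function(S) {
  mx <- apply(S, 1, max)
  if (any(!is.finite(mx)))
    stop("masked_attention: a node has no unmasked entry to attend to")
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Uniform neighbor sampling for attention
#'
#' For each node, draws `min(k, |V| - 1)` other nodes uniformly without
#' replacement and always includes the node itself.  When `|V| <= k + 1`
#' sampling is a no-op (every node sees all nodes).  Uses R's RNG, so a
#' fixed seed reproduces the samples.
#'
#' @param graph A `patient_graph`, or an integer node count.
#' @param k Sample size (>= 1).
#' @return List of integer index vectors, self first.
#' @export
sample_neighbors <- function(graph, k) {
  n <- if (is.numeric(graph)) as.integer(graph) else nrow(graph$nodes)
  if (k < 1 || n < 1) stop("sample_neighbors: k and |V| must be positive")
  if (n - 1 <= k) return(lapply(seq_len(n), function(i) seq_len(n)))
  lapply(seq_len(n), function(i) {
    idx <- sample.int(n - 1L, k)          # draw from the other n-1 nodes
    idx[idx >= i] <- idx[idx >= i] + 1L
    c(i, idx)
  })
}

## Binary attention gate combining mask and samples: row i allows
## (mask-allowed & sampled) plus self.  Not necessarily symmetric.
combine_mask_samples <- function(node_mask, samples, n) {
  if (is.null(node_mask)) node_mask <- matrix(1, n, n)
  out <- node_mask
  if (!is.null(samples)) {
    sel <- matrix(0, n, n)
    sel[cbind(rep.int(seq_len(n), lengths(samples)), unlist(samples))] <- 1
    out <- out * sel
  }
  diag(out) <- 1
  out
}

#' Graph convolution over the temporal adjacency
#'
#' `Z' = act(N (A) Z Wg)` where `N(A)` is either the symmetric-normalized
#' adjacency with self-loops, `D^{-1/2} (A + I) D^{-1/2}`, or row-normalized
#' mean aggregation `D^{-1} (A + I)`.
#'
#' @param A Symmetric binary adjacency (zero diagonal).
#' @param Z Node representations (|V| x p).
#' @param Wg Weight matrix (p x q).
#' @param bias Optional bias vector (length q).
#' @param activation `"relu"` or `"identity"`.
#' @param normalize `"sym"` or `"mean"`.
#' @return Z', |V| x q.
#' @export
gnn_layer <- function(A, Z, Wg, bias = NULL,
                      activation = c("relu", "identity"),
                      normalize = c("sym", "mean")) {
  activation <- match.arg(activation)
  normalize <- match.arg(normalize)
  Z <- as.matrix(Z)
  if (nrow(A) != nrow(Z)) stop("gnn_layer: A and Z disagree in node count")
  if (ncol(Z) != nrow(Wg)) stop("gnn_layer: Z and Wg dimension mismatch")
  N <- normalized_adjacency(A, normalize)
  out <- N %*% Z %*% Wg
  if (!is.null(bias)) out <- sweep(out, 2, bias, `+`)
  if (activation == "relu") out <- pmax(out, 0)
  out
}

normalized_adjacency <- function(A, normalize = "sym") {
  Ahat <- A + diag(nrow(A))
  deg <- rowSums(Ahat)
  if (normalize == "sym") {
    s <- 1 / sqrt(deg)
    Ahat * outer(s, s)
  } else {
    Ahat / deg
  }
}

#' Sum readout and linear forecast
#'
#' Reads the node representations out into a single graph vector by
#' summation, then applies the linear head: `yhat = w . colSums(Z') + b`.
#'
#' @param Zp Node representations (|V| x q), non-empty.
#' @param head List with weight vector `w` (length q) and scalar `b`.
#' @return Scalar prediction, with the pre-head graph vector as attribute
#'   `"embedding"`.
#' @export
readout_predict <- function(Zp, head) {
  Zp <- as.matrix(Zp)
  if (nrow(Zp) == 0L) stop("readout_predict: empty graph")
  g <- colSums(Zp)
  out <- sum(head$w * g) + head$b
  attr(out, "embedding") <- g
  out
}

#' Full forward pass of the Graph Transformer
#'
#' Composes attention, graph convolution and readout according to the
#' config flags: the full model runs attention then the GNN layer; the
#' Graph-Transformer-only ablation skips the GNN; the GNN-only ablation
#' convolves the raw features `X` directly.
#'
#' @param graph A `patient_graph`.
#' @param mask Optional `cooccurrence_mask`; used when `config$use_mask`.
#' @param config A [model_config()].
#' @param params Parameters from [init_graphformer()].
#' @param samples Optional [sample_neighbors()] result restricting
#'   attention (training-time only; prediction uses the full mask).
#' @return List with `prediction` (scalar, mmHg-scale if the head was
#'   trained on raw targets) and `embedding` (the pre-head sum-readout
#'   vector).
#' @export
graphformer_forward <- function(graph, mask = NULL, config, params,
                                samples = NULL) {
  n <- nrow(graph$X)
  if (config$use_transformer) {
    node_mask <- if (config$use_mask && !is.null(mask))
      expand_mask_to_nodes(mask, graph) else NULL
    gate <- if (is.null(node_mask) && is.null(samples)) NULL
            else combine_mask_samples(node_mask, samples, n)
    Z <- masked_attention(graph$X, params, gate)
  } else {
    Z <- graph$X
  }
  Zp <- if (config$use_gnn)
    gnn_layer(graph$A, Z, params$Wg, bias = params$bg, activation = "relu",
              normalize = config$gnn_normalize)
  else Z
  yhat <- readout_predict(Zp, list(w = params$w, b = params$b))
  list(prediction = as.numeric(yhat), embedding = attr(yhat, "embedding"))
}
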