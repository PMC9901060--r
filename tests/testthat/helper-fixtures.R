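# Fixtures and independent oracles used across the suite.

# Patient whose visits are given as a list of named event vectors; timestamps
# default to 30-day spacing.
toy_patient <- function(id, visit_events, timestamps = NULL, ...) {
  if (is.null(timestamps)) timestamps <- 30 * (seq_along(visit_events) - 1)
  visits <- lapply(seq_along(visit_events), function(i)
    visit(i, timestamps[i], visit_events[[i]]))
  patient_record(id, visits, ...)
}

# Small lab-only cohort with deterministic values.
toy_lab_cohort <- function(n = 3) {
  patients <- lapply(seq_len(n), function(i) {
    toy_patient(paste0("T", i), list(
      c(DBP = 70 + i, SBP = 120 + i, SVR = 1100 + i),
      c(DBP = 72 + i, SBP = 123 + i, SVR = 1103 + i),
      c(DBP = 74 + i, SBP = 126 + i, SVR = 1106 + i)))
  })
  cohort(patients)
}

# Brute-force reference for masked scaled dot-product attention: explicit
# per-entry loops, no shared code with the package implementation.
naive_masked_attention <- function(X, Wq, Wk, Wv, Wo = NULL, bo = NULL,
                                   mask = NULL) {
  X <- as.matrix(X)
  if (is.matrix(Wq)) { Wq <- list(Wq); Wk <- list(Wk); Wv <- list(Wv) }
  n <- nrow(X)
  heads <- list()
  for (h in seq_along(Wq)) {
    d <- ncol(Wq[[h]])
    Q <- X %*% Wq[[h]]; K <- X %*% Wk[[h]]; V <- X %*% Wv[[h]]
    Zh <- matrix(0, n, d)
    for (i in seq_len(n)) {
      allowed <- if (is.null(mask)) seq_len(n) else which(mask[i, ] != 0)
      s <- vapply(allowed, function(j) sum(Q[i, ] * K[j, ]) / sqrt(d), 0)
      e <- exp(s - max(s))
      p <- e / sum(e)
      for (a in seq_along(allowed))
        Zh[i, ] <- Zh[i, ] + p[a] * V[allowed[a], ]
    }
    heads[[h]] <- Zh
  }
  Z <- do.call(cbind, heads)
  if (!is.null(Wo)) {
    Z <- Z %*% Wo
    if (!is.null(bo)) Z <- sweep(Z, 2, bo, `+`)
  }
  Z
}

# Random attention parameters for n-head, dimension-d fixtures.
random_attention_params <- function(n_heads, d, in_dim = 1, d_model = NULL,
                                    with_proj = TRUE) {
  p <- list(
    Wq = lapply(seq_len(n_heads), function(h)
      matrix(rnorm(in_dim * d), in_dim, d)),
    Wk = lapply(seq_len(n_heads), function(h)
      matrix(rnorm(in_dim * d), in_dim, d)),
    Wv = lapply(seq_len(n_heads), function(h)
      matrix(rnorm(in_dim * d), in_dim, d)))
  if (with_proj) {
    if (is.null(d_model)) d_model <- d
    p$Wo <- matrix(rnorm(n_heads * d * d_model), n_heads * d, d_model)
    p$bo <- rnorm(d_model)
  }
  p
}

# Random symmetric binary mask with unit diagonal.
random_node_mask <- function(n, p_allow = 0.6) {
  M <- matrix(rbinom(n * n, 1, p_allow), n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  M
}

# Small simulated cohort shared by training tests (kept tiny for speed).
small_sim_cohort <- function(n = 40, seed = 11, ...) {
  generate_cohort(sim_config(n_patients = n, seed = seed, ...))
}
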