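## Two-layer perceptron baseline trained with the same loss, optimizer and
## batching protocol as the graph model.  Features: the lab values (DBP,
## SBP, SVR) of the last `window` observed visits, normalized with the
## training-fold scaler, zero-padded where a visit or value is missing.

mlp_features <- function(record, window, horizon, scaler) {
  T_vis <- length(record$visits)
  n_obs <- T_vis - horizon
  if (n_obs < 1L || !"DBP" %in% names(record$visits[[n_obs + 1L]]$events))
    return(NULL)
  feats <- numeric(3 * window)
  obs_idx <- seq_len(n_obs)
  use <- tail(obs_idx, window)
  for (j in seq_along(use)) {
    v <- record$visits[[use[j]]]
    for (l in seq_along(LAB_EVENTS)) {
      et <- LAB_EVENTS[l]
      if (et %in% names(v$events))
        feats[(j - 1) * 3 + l] <-
          apply_value_scaler(scaler, et, v$events[[et]])
    }
  }
  list(x = feats, y = unname(record$visits[[n_obs + 1L]]$events[["DBP"]]))
}

mlp_design <- function(cohort, window, horizon, scaler) {
  rows <- lapply(cohort$patients, mlp_features, window = window,
                 horizon = horizon, scaler = scaler)
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("mlp: no trainable patients")
  list(X = do.call(rbind, lapply(rows, `[[`, "x")),
       y = vapply(rows, `[[`, numeric(1), "y"),
       ids = names(rows))
}

mlp_init <- function(p, hidden, seed) {
  set.seed(seed)
  list(W1 = init_mat(p, hidden), b1 = numeric(hidden),
       W2 = as.numeric(init_mat(hidden, 1)), b2 = 0)
}

mlp_forward <- function(params, X) {
  H <- pmax(sweep(X %*% params$W1, 2, params$b1, `+`), 0)
  list(H = H, yhat = as.numeric(H %*% params$W2) + params$b2)
}

mlp_grad <- function(params, X, y) {
  fw <- mlp_forward(params, X)
  n <- length(y)
  dy <- 2 * (fw$yhat - y) / n
  dH <- outer(dy, params$W2) * (fw$H > 0)
  list(loss = mean((fw$yhat - y)^2),
       grads = list(W1 = t(X) %*% dH, b1 = colSums(dH),
                    W2 = as.numeric(t(fw$H) %*% dy), b2 = sum(dy)))
}

mlp_train <- function(X, y, tc, hidden) {
  y_center <- mean(y)
  y_scale <- if (length(y) > 1 && sd(y) > 0) sd(y) else 1
  ys <- (y - y_center) / y_scale
  params <- mlp_init(ncol(X), hidden, tc$seed)
  state <- adam_init(params)
  set.seed(tc$seed)
  n <- nrow(X)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    for (bt in batches) {
      g <- mlp_grad(params, X[bt, , drop = FALSE], ys[bt])
      upd <- adam_step(params, g$grads, state, tc$learning_rate)
      params <- upd$params
      state <- upd$state
    }
  }
  list(params = params, y_center = y_center, y_scale = y_scale)
}

#' MLP baseline under the shared evaluation protocol
#'
#' A 2-layer perceptron on a fixed-length window of recent lab values,
#' trained with the same MSE loss, Adam settings, batching and
#' cross-validation folds as the graph model, for like-for-like
#' comparison.
#'
#' @param cohort An `ehr_cohort`.
#' @param tc A [train_config()] (`mlp_window`, `mlp_hidden` control the
#'   feature window and hidden width).
#' @param horizon Forecast horizon in visits.
#' @return A `fold_metrics` table.
#' @export
mlp_baseline <- function(cohort, tc = train_config(), horizon = 1) {
  cross_validate(cohort, tc = tc, horizon = horizon, predictor = "mlp")
}
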