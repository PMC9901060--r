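#' Training protocol configuration
#'
#' Defaults follow the evaluation protocol: 50 epochs, batch size 4,
#' learning rate 5e-4 (Adam), 10-fold cross-validation.
#'
#' @param epochs Training epochs.
#' @param batch_size Graphs per optimization step.
#' @param learning_rate Adam learning rate.
#' @param folds Cross-validation folds.
#' @param seed Seed governing fold assignment, batching and neighbor
#'   sampling.
#' @param mlp_window,mlp_hidden Window length (visits) and hidden width of
#'   the MLP baseline.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50, batch_size = 4, learning_rate = 5e-4,
                         folds = 10, seed = 1, mlp_window = 3,
                         mlp_hidden = 16) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate >= 0, folds >= 2)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, folds = as.integer(folds),
                 seed = as.integer(seed), mlp_window = as.integer(mlp_window),
                 mlp_hidden = as.integer(mlp_hidden)),
            class = "train_config")
}

#' Fit the preprocessing state on a training fold
#'
#' Everything the model needs beyond its weights is fitted here, on
#' training patients only: the per-event-type value scaler, the tf-idf
#' comorbidity weighting and the event co-occurrence attention mask.
#'
#' @param cohort Training-fold `ehr_cohort`.
#' @param mask_level Co-occurrence granularity, `"visit"` or `"patient"`.
#' @return A `graphdbp_prep` list with `scaler`, `tfidf`, `mask`.
#' @export
fit_preprocessing <- function(cohort, mask_level = "visit") {
  structure(list(scaler = fit_value_scaler(cohort),
                 tfidf = tfidf_fit(cohort),
                 mask = build_cooccurrence_mask(cohort, level = mask_level)),
            class = "graphdbp_prep")
}

## Per-graph tensors consumed by the C++ engine.
engine_inputs <- function(graphs, prep, model_config) {
  lapply(graphs, function(g) {
    inp <- list(X = g$X, n = nrow(g$X))
    if (model_config$use_gnn)
      inp$Nhat <- normalized_adjacency(g$A, model_config$gnn_normalize)
    if (model_config$use_transformer && model_config$use_mask)
      inp$base_mask <- expand_mask_to_nodes(prep$mask, g)
    inp
  })
}

#' Train the Graph Transformer on a cohort
#'
#' Builds the patient graphs and the co-occurrence mask from the (training)
#' cohort, then minimizes the MSE of the DBP forecast with Adam.  Targets
#' are standardized internally with training-fold mean/SD and predictions
#' are reported back in mmHg.  Neighbor samples are redrawn every epoch.
#' Fully deterministic under fixed seeds.
#'
#' @param cohort Training `ehr_cohort`.
#' @param model_config A [model_config()].
#' @param tc A [train_config()].
#' @param source_mode Graph data source (see [build_patient_graph()]).
#' @param horizon Forecast horizon in visits.
#' @param prep Optional pre-fitted [fit_preprocessing()]; fitted on
#'   `cohort` when `NULL`.
#' @return A `graphformer_fit` with the trained `params`, the configs, the
#'   preprocessing state, the target scaling and the per-epoch loss trace
#'   (standardized scale).
#' @export
train <- function(cohort, model_config = graphDBP::model_config(),
                  tc = train_config(), source_mode = "Lab", horizon = 1,
                  prep = NULL) {
  if (is.null(prep)) prep <- fit_preprocessing(cohort)
  graphs <- build_cohort_graphs(cohort, source_mode = source_mode,
                                horizon = horizon, scaler = prep$scaler,
                                tfidf = prep$tfidf)
  if (length(graphs) == 0L) stop("train: no trainable patients")
  y_raw <- vapply(graphs, `[[`, numeric(1), "target")
  y_center <- mean(y_raw)
  y_scale <- if (length(y_raw) > 1 && sd(y_raw) > 0) sd(y_raw) else 1
  y <- (y_raw - y_center) / y_scale

  params <- init_graphformer(model_config, in_dim = ncol(graphs[[1]]$X))
  inputs <- engine_inputs(graphs, prep, model_config)
  n_graph <- length(inputs)
  state <- adam_init(params)
  loss_trace <- numeric(tc$epochs)

  set.seed(tc$seed)
  for (epoch in seq_len(tc$epochs)) {
    if (model_config$use_transformer) {
      for (i in seq_len(n_graph)) {
        n <- inputs[[i]]$n
        samples <- if (n - 1 > model_config$k)
          sample_neighbors(n, model_config$k) else NULL
        base <- inputs[[i]]$base_mask
        inputs[[i]]$gate <- if (is.null(base) && is.null(samples)) NULL
          else combine_mask_samples(base, samples, n)
      }
    }
    ord <- sample(n_graph)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    epoch_loss <- 0
    for (bt in batches) {
      res <- gf_batch_grad(inputs[bt], y[bt], params,
                           model_config$use_transformer,
                           model_config$use_gnn, want_grad = TRUE)
      epoch_loss <- epoch_loss + res$loss * length(bt)
      upd <- adam_step(params, res$grads, state, tc$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    loss_trace[epoch] <- epoch_loss / n_graph
  }

  structure(list(params = params, model_config = model_config,
                 train_config = tc, prep = prep, source_mode = source_mode,
                 horizon = horizon, y_center = y_center, y_scale = y_scale,
                 loss_trace = loss_trace, n_train = n_graph),
            class = "graphformer_fit")
}

#' @export
print.graphformer_fit <- function(x, ...) {
  cat("graphformer_fit: ", x$n_train, " training graphs [", x$source_mode,
      ", horizon ", x$horizon, "]; ", x$train_config$epochs,
      " epochs, final training MSE (standardized) ",
      format(tail(x$loss_trace, 1), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict DBP for a cohort with a trained model
#'
#' Graphs are built with the fit's training-fold preprocessing; attention
#' uses the full co-occurrence mask (no neighbor sampling at prediction
#' time), and predictions are inverted to mmHg.
#'
#' @param fit A `graphformer_fit`.
#' @param cohort An `ehr_cohort`.
#' @param horizon Forecast horizon; defaults to the fit's.
#' @return data.frame `(patient_id, target, prediction)`, one row per
#'   forecastable patient; the pre-head embeddings are in attribute
#'   `"embeddings"` (matrix, rows named by patient) and skip reasons in
#'   attribute `"skipped"`.
#' @export
predict_cohort <- function(fit, cohort, horizon = fit$horizon) {
  graphs <- build_cohort_graphs(cohort, source_mode = fit$source_mode,
                                horizon = horizon,
                                scaler = fit$prep$scaler,
                                tfidf = fit$prep$tfidf)
  if (length(graphs) == 0L)
    stop("predict_cohort: no forecastable patients")
  rows <- lapply(graphs, function(g) {
    fwd <- graphformer_forward(g, mask = fit$prep$mask, fit$model_config,
                               fit$params)
    list(df = data.frame(patient_id = g$patient_id, target = g$target,
                         prediction = fwd$prediction * fit$y_scale +
                           fit$y_center),
         emb = fwd$embedding)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "df"))
  rownames(out) <- NULL
  emb <- do.call(rbind, lapply(rows, `[[`, "emb"))
  rownames(emb) <- out$patient_id
  attr(out, "embeddings") <- emb
  attr(out, "skipped") <- attr(graphs, "skipped")
  out
}

#' @export
predict.graphformer_fit <- function(object, cohort, horizon = object$horizon,
                                    ...) {
  predict_cohort(object, cohort, horizon)
}
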