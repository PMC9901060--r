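## Checkpoints are plain JSON: model weights, configs, the fitted
## preprocessing state and the target scaling, so a trained model reloads
## deterministically anywhere.

enc_node <- function(x) {
  if (is.matrix(x)) list(`.mat` = TRUE, dim = dim(x), data = as.vector(x))
  else if (is.list(x)) lapply(x, enc_node)
  else x
}

dec_node <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.mat))
      matrix(as.numeric(unlist(x$data)), x$dim[[1]], x$dim[[2]])
    else lapply(x, dec_node)
  } else x
}

#' Save a trained model to a JSON checkpoint
#'
#' @param fit A `graphformer_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "graphformer_fit"))
  ck <- list(
    package = "graphDBP", object = "graphformer_fit",
    params = enc_node(fit$params),
    model_config = unclass(fit$model_config),
    train_config = unclass(fit$train_config),
    source_mode = fit$source_mode, horizon = fit$horizon,
    y_center = fit$y_center, y_scale = fit$y_scale,
    loss_trace = fit$loss_trace, n_train = fit$n_train,
    prep = list(
      scaler = lapply(unclass(fit$prep$scaler), as.numeric),
      tfidf = list(codes = fit$prep$tfidf$codes,
                   idf = as.list(fit$prep$tfidf$idf),
                   n_doc = fit$prep$tfidf$n_doc,
                   max_weight = fit$prep$tfidf$max_weight),
      mask = list(vocabulary = fit$prep$mask$vocabulary,
                  M = enc_node(fit$prep$mask$M))))
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `graphformer_fit`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no such file: ", path)
  ck <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(ck$object, "graphformer_fit"))
    stop("load_checkpoint: not a graphformer checkpoint")
  params <- dec_node(ck$params)
  for (nm in intersect(c("bo", "bg", "w"), names(params)))
    params[[nm]] <- as.numeric(unlist(params[[nm]]))
  mc <- do.call(model_config, ck$model_config[setdiff(names(ck$model_config),
                                                      character())])
  tcfg <- do.call(train_config, ck$train_config)
  M <- dec_node(ck$prep$mask$M)
  vocab <- as.character(unlist(ck$prep$mask$vocabulary))
  dimnames(M) <- list(vocab, vocab)
  prep <- structure(list(
    scaler = structure(lapply(ck$prep$scaler, function(v)
      as.numeric(unlist(v))), class = "value_scaler"),
    tfidf = structure(list(codes = as.character(unlist(ck$prep$tfidf$codes)),
                           idf = unlist(ck$prep$tfidf$idf),
                           n_doc = ck$prep$tfidf$n_doc,
                           max_weight = ck$prep$tfidf$max_weight),
                      class = "tfidf_model"),
    mask = structure(list(M = M, vocabulary = vocab),
                     class = "cooccurrence_mask")),
    class = "graphdbp_prep")
  structure(list(params = params, model_config = mc, train_config = tcfg,
                 prep = prep, source_mode = ck$source_mode,
                 horizon = ck$horizon, y_center = ck$y_center,
                 y_scale = ck$y_scale,
                 loss_trace = as.numeric(unlist(ck$loss_trace)),
                 n_train = ck$n_train),
            class = "graphformer_fit")
}
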