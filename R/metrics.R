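#' Mean squared error loss
#'
#' `(1/N) * sum((y - yhat)^2)` — the training objective.
#'
#' @param targets,predictions Equal-length finite numeric vectors.
#' @return Scalar loss.
#' @export
mse_loss <- function(targets, predictions) {
  if (length(targets) != length(predictions))
    stop("mse_loss: length mismatch")
  if (any(!is.finite(targets)) || any(!is.finite(predictions)))
    stop("mse_loss: non-finite inputs")
  mean((targets - predictions)^2)
}

#' Regression error metrics
#'
#' @inheritParams mse_loss
#' @return Named vector `c(MAE, MSE, RMSE)`.
#' @export
regression_metrics <- function(targets, predictions) {
  mse <- mse_loss(targets, predictions)
  c(MAE = mean(abs(targets - predictions)), MSE = mse, RMSE = sqrt(mse))
}

#' Per-fold metric table
#'
#' @param df data.frame with columns `fold`, `n_test`, `MAE`, `MSE`,
#'   `RMSE` (one row per cross-validation fold).
#' @return A `fold_metrics` data.frame whose `summary()`/`print()` report
#'   the across-fold means and standard deviations.
#' @export
fold_metrics <- function(df) {
  stopifnot(all(c("fold", "n_test", "MAE", "MSE", "RMSE") %in% names(df)))
  structure(df, class = c("fold_metrics", "data.frame"))
}

#' @export
summary.fold_metrics <- function(object, ...) {
  m <- c(MAE = mean(object$MAE), MSE = mean(object$MSE),
         RMSE = mean(object$RMSE))
  s <- c(MAE = sd(object$MAE), MSE = sd(object$MSE), RMSE = sd(object$RMSE))
  list(mean = m, sd = s, n_folds = nrow(object))
}

#' @export
print.fold_metrics <- function(x, ...) {
  s <- summary(x)
  cat(s$n_folds, "folds; mean (sd) across folds:\n")
  for (k in c("MAE", "MSE", "RMSE"))
    cat(sprintf("  %-4s %8.4f (%.4f)\n", k, s$mean[[k]],
                if (is.na(s$sd[[k]])) 0 else s$sd[[k]]))
  invisible(x)
}

#' Write a metric table to a delimited file
#'
#' @param metrics A `fold_metrics` (or plain data.frame).
#' @param path Output path.
#' @param stratum Optional stratum label column to prepend.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, stratum = NULL) {
  df <- as.data.frame(metrics)
  if (!is.null(stratum)) df <- cbind(stratum = stratum, df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
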