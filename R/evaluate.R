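#' K-fold cross-validation of a DBP predictor
#'
#' Patients are partitioned into `tc$folds` disjoint near-equal subsets by
#' a seeded shuffle; each fold trains on the rest and is evaluated held
#' out.  All preprocessing state (value scaler, tf-idf, co-occurrence
#' mask) is refitted on each training split, so held-out structure never
#' reaches the model.  Metrics are reported in mmHg.
#'
#' @param cohort An `ehr_cohort` with at least `tc$folds` patients.
#' @param model_config A [model_config()] (graph model only).
#' @param tc A [train_config()].
#' @param source_mode,horizon Passed to graph construction.
#' @param predictor `"graphformer"`, `"mlp"` (baseline) or `"mean"` (the
#'   training-mean constant predictor).
#' @return A `fold_metrics` table; attribute `"folds"` holds the held-out
#'   patient ids per fold and `"predictions"` the pooled per-patient
#'   predictions.
#' @export
cross_validate <- function(cohort, model_config = graphDBP::model_config(),
                           tc = train_config(), source_mode = "Lab",
                           horizon = 1,
                           predictor = c("graphformer", "mlp", "mean")) {
  predictor <- match.arg(predictor)
  n <- n_patients(cohort)
  if (n < tc$folds)
    stop("cross_validate: fewer patients (", n, ") than folds (", tc$folds, ")")
  set.seed(tc$seed)
  fold_id <- sample(rep(seq_len(tc$folds), length.out = n))
  ids <- patient_ids(cohort)

  rows <- vector("list", tc$folds)
  pred_pool <- vector("list", tc$folds)
  for (f in seq_len(tc$folds)) {
    train_co <- subset_cohort(cohort, ids[fold_id != f])
    test_co <- subset_cohort(cohort, ids[fold_id == f])
    preds <- switch(predictor,
      graphformer = {
        fit <- train(train_co, model_config = model_config, tc = tc,
                     source_mode = source_mode, horizon = horizon)
        predict_cohort(fit, test_co, horizon)
      },
      mlp = {
        scaler <- fit_value_scaler(train_co)
        des <- mlp_design(train_co, tc$mlp_window, horizon, scaler)
        m <- mlp_train(des$X, des$y, tc, tc$mlp_hidden)
        tes <- mlp_design(test_co, tc$mlp_window, horizon, scaler)
        yhat <- mlp_forward(m$params, tes$X)$yhat * m$y_scale + m$y_center
        data.frame(patient_id = tes$ids, target = tes$y, prediction = yhat)
      },
      mean = {
        scaler <- fit_value_scaler(train_co)          # parity of protocol
        tr <- mlp_design(train_co, 1, horizon, scaler)
        te <- mlp_design(test_co, 1, horizon, scaler)
        data.frame(patient_id = te$ids, target = te$y,
                   prediction = rep(mean(tr$y), length(te$y)))
      })
    met <- regression_metrics(preds$target, preds$prediction)
    rows[[f]] <- data.frame(fold = f, n_test = nrow(preds),
                            MAE = met[["MAE"]], MSE = met[["MSE"]],
                            RMSE = met[["RMSE"]])
    preds$fold <- f
    pred_pool[[f]] <- preds
  }
  out <- fold_metrics(do.call(rbind, rows))
  attr(out, "folds") <- split(ids, fold_id)
  attr(out, "predictions") <- do.call(rbind, pred_pool)
  out
}

#' Multi-step forecasting evaluation
#'
#' Evaluates a trained model at the last visit (horizon 1, the t-th
#' timestep) and the second-to-last (horizon 2, the (t-1)-th timestep) by
#' independent truncation: each step withholds that many trailing visits
#' and predicts the first withheld DBP.  Patients lacking visit depth for
#' a step are excluded from it, with counts reported.
#'
#' @param cohort Evaluation `ehr_cohort`.
#' @param fit A trained `graphformer_fit`.
#' @param steps Integer horizons, default `c(1, 2)`.
#' @return data.frame `(horizon, n, n_excluded, MAE, MSE, RMSE)`.
#' @export
evaluate_multistep <- function(cohort, fit, steps = c(1, 2)) {
  rows <- lapply(steps, function(h) {
    preds <- predict_cohort(fit, cohort, horizon = h)
    met <- regression_metrics(preds$target, preds$prediction)
    data.frame(horizon = h, n = nrow(preds),
               n_excluded = n_patients(cohort) - nrow(preds),
               MAE = met[["MAE"]], MSE = met[["MSE"]], RMSE = met[["RMSE"]])
  })
  do.call(rbind, rows)
}

#' Stratify a cohort for subgroup evaluation
#'
#' Splits a cohort into (possibly overlapping) named sub-cohorts by
#' medication or heart-failure subtype:
#' \describe{
#'   \item{category}{one stratum per drug category a patient is on}
#'   \item{top_drug}{per category, the most frequent medication}
#'   \item{intra_combo}{pairs of distinct drugs of the same category taken
#'     together (e.g. `ARB:Losartan+Valsartan`)}
#'   \item{inter_combo}{drug pairs spanning two categories
#'     (e.g. `BB:Metoprolol x LD:Furosemide`)}
#'   \item{polypharmacy}{a heart-failure drug combined with a diabetes
#'     medication}
#'   \item{subtype}{HFrEF vs HFpEF}
#' }
#'
#' @param cohort An `ehr_cohort` whose records carry `drugs`,
#'   `drug_categories` and/or `subtype`.
#' @param key One of the strata keys above.
#' @param min_patients Drop strata smaller than this.
#' @return Named list of `ehr_cohort`s; attribute `"counts"` gives the
#'   stratum sizes.
#' @export
stratify <- function(cohort, key = c("category", "top_drug", "intra_combo",
                                     "inter_combo", "polypharmacy",
                                     "subtype"),
                     min_patients = 1) {
  key <- match.arg(key)
  map <- hf_drug_map()
  membership <- list()
  add <- function(stratum, id) {
    membership[[stratum]] <<- c(membership[[stratum]], id)
  }
  for (p in cohort$patients) {
    hf_drugs <- sort(unique(p$drugs[!is.na(drug_category_of(p$drugs, map))]))
    cats <- drug_category_of(hf_drugs, map)
    switch(key,
      category = for (cc in unique(p$drug_categories)) add(cc, p$patient_id),
      top_drug = for (dd in hf_drugs)
        add(paste0(drug_category_of(dd, map), ":", dd), p$patient_id),
      intra_combo = {
        for (cc in unique(cats)) {
          dd <- hf_drugs[cats == cc]
          if (length(dd) >= 2)
            for (pair in utils::combn(dd, 2, simplify = FALSE))
              add(paste0(cc, ":", pair[1], "+", pair[2]), p$patient_id)
        }
      },
      inter_combo = {
        if (length(hf_drugs) >= 2)
          for (pair in utils::combn(seq_along(hf_drugs), 2, simplify = FALSE)) {
            c1 <- cats[pair[1]]; c2 <- cats[pair[2]]
            if (c1 != c2) {
              if (c1 > c2) pair <- rev(pair)
              add(paste0(cats[pair[1]], ":", hf_drugs[pair[1]], " x ",
                         cats[pair[2]], ":", hf_drugs[pair[2]]),
                  p$patient_id)
            }
          }
      },
      polypharmacy = {
        dm <- sort(unique(p$drugs[tolower(p$drugs) %in%
                                    tolower(dm_medications())]))
        for (hd in hf_drugs) for (dd in dm)
          add(paste0(hd, " + ", dd), p$patient_id)
      },
      subtype = if (!is.na(p$subtype)) add(p$subtype, p$patient_id))
  }
  membership <- membership[order(names(membership))]
  membership <- Filter(function(x) length(x) >= min_patients, membership)
  if (key == "top_drug") {
    ## keep only the most frequent medication within each category
    cats_of <- sub(":.*$", "", names(membership))
    keep <- unlist(lapply(split(seq_along(membership), cats_of), function(ix)
      ix[which.max(lengths(membership)[ix])]))
    membership <- membership[sort(keep)]
  }
  strata <- lapply(membership, function(ids) subset_cohort(cohort, ids))
  attr(strata, "counts") <- lengths(membership)
  strata
}

#' Export learned patient embeddings with subtype labels
#'
#' Extracts the pre-head sum-readout vector of every forecastable patient
#' and scores how well the embedding space separates the two
#' heart-failure subtypes with the mean silhouette width (Euclidean
#' distance) — the testable counterpart of projecting embeddings with
#' t-SNE and inspecting the clusters.
#'
#' @param cohort An `ehr_cohort` with subtype labels.
#' @param fit A trained `graphformer_fit`.
#' @param horizon Forecast horizon used to build the graphs.
#' @param path Optional TSV output path (label column + embedding dims).
#' @return data.frame `(patient_id, subtype, e1..eq)`; attribute
#'   `"silhouette"` is the mean silhouette width, or `NA` when fewer than
#'   two subtypes are present.
#' @export
export_embeddings <- function(cohort, fit, horizon = fit$horizon,
                              path = NULL) {
  preds <- predict_cohort(fit, cohort, horizon = horizon)
  emb <- attr(preds, "embeddings")
  subtype <- vapply(preds$patient_id, function(id)
    cohort$patients[[id]]$subtype, character(1))
  out <- data.frame(patient_id = preds$patient_id, subtype = subtype,
                    emb, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("e", seq_len(ncol(emb)))
  lab <- factor(subtype[!is.na(subtype)])
  sil <- NA_real_
  if (nlevels(lab) >= 2 && all(table(lab) >= 2)) {
    d <- stats::dist(emb[!is.na(subtype), , drop = FALSE])
    sil <- mean(cluster::silhouette(as.integer(lab), d)[, "sil_width"])
  }
  attr(out, "silhouette") <- sil
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}
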