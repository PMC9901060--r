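#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)` elementwise.  A constant sequence has zero
#' range and maps to all zeros, which keeps node features bounded and
#' deterministic.
#'
#' @param values Non-empty finite numeric vector.
#' @return Numeric vector of the same length, in \[0, 1\].
#' @examples
#' minmax_normalize(c(100, 120, 140))  # 0, 0.5, 1
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0L) stop("minmax_normalize: empty sequence")
  if (any(!is.finite(values))) stop("minmax_normalize: non-finite values")
  rng <- range(values)
  if (rng[2] == rng[1]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Fit a per-event-type min-max scaler on a (training) cohort
#'
#' Records the observed min/max of every numeric event type so held-out
#' patients can be normalized with training-fold statistics only.  Applied
#' values are clipped to \[0, 1\] when a held-out observation falls outside
#' the training range.
#'
#' @param cohort An `ehr_cohort` (the training fold).
#' @param event_types Event types to fit; default: every non-comorbidity
#'   type in the vocabulary.
#' @return A `value_scaler` object, a named list of `c(min, max)` per type.
#' @export
fit_value_scaler <- function(cohort,
                             event_types = setdiff(cohort$vocabulary,
                                                   COMORBIDITY_EVENTS)) {
  ev <- cohort_events(cohort)
  ev <- ev[ev$event_type %in% event_types, ]
  ranges <- lapply(split(ev$value, ev$event_type), range)
  structure(ranges, class = "value_scaler")
}

## Apply a fitted scaler to a value vector of one event type; falls back to
## 0 (the degenerate-range convention) for unknown types or zero range.
apply_value_scaler <- function(scaler, event_type, values) {
  rng <- scaler[[event_type]]
  if (is.null(rng) || rng[2] == rng[1]) return(rep(0, length(values)))
  pmin(1, pmax(0, (values - rng[1]) / (rng[2] - rng[1])))
}

#' Fit tf-idf weighting of comorbidity codes
#'
#' Each patient's whole history is one document and comorbidity codes are
#' terms.  Term frequency is the raw count of the code across the patient's
#' visits; the inverse document frequency is smoothed,
#' `idf(term) = log((1 + N) / (1 + df(term))) + 1`, so codes present in all
#' documents keep a small positive weight.  Fit on the training fold only
#' and applied to held-out patients to avoid leakage.
#'
#' @param cohort The training `ehr_cohort`.
#' @param comorbidity_codes Codes treated as comorbidity terms; default:
#'   intersection of the vocabulary with the known comorbidity set.
#' @return A `tfidf_model` with the idf table and the training-fold maximum
#'   weight (used to scale node features into \[0, 1\]).
#' @export
tfidf_fit <- function(cohort,
                      comorbidity_codes = intersect(cohort$vocabulary,
                                                    COMORBIDITY_EVENTS)) {
  n_doc <- n_patients(cohort)
  counts <- comorbidity_counts(cohort, comorbidity_codes)
  df <- vapply(comorbidity_codes, function(code)
    sum(counts[, code] > 0), numeric(1))
  idf <- log((1 + n_doc) / (1 + df)) + 1
  w <- sweep(counts, 2, idf, `*`)
  structure(list(codes = comorbidity_codes, idf = idf, n_doc = n_doc,
                 max_weight = if (length(w) && max(w) > 0) max(w) else 1),
            class = "tfidf_model")
}

## patient x code matrix of raw term counts across all visits
comorbidity_counts <- function(cohort, codes) {
  out <- matrix(0, n_patients(cohort), length(codes),
                dimnames = list(patient_ids(cohort), codes))
  if (length(codes) == 0L) return(out)
  for (p in cohort$patients) {
    for (v in p$visits) {
      hit <- intersect(names(v$events), codes)
      ## a comorbidity event counts when present with a nonzero indicator
      hit <- hit[v$events[hit] != 0]
      if (length(hit)) out[p$patient_id, hit] <- out[p$patient_id, hit] + 1
    }
  }
  out
}

#' Per-patient tf-idf comorbidity weights
#'
#' @param cohort An `ehr_cohort` to weight.
#' @param comorbidity_codes See [tfidf_fit()].
#' @param model Optional `tfidf_model` fitted on a training fold; when
#'   `NULL`, the model is fitted on `cohort` itself.
#' @return A data.frame `(patient_id, event_type, weight)` covering every
#'   patient x code pair (absent codes have weight 0), with the fitted model
#'   attached as attribute `"model"`.
#' @export
tfidf_comorbidity <- function(cohort, comorbidity_codes = NULL, model = NULL) {
  if (is.null(model))
    model <- if (is.null(comorbidity_codes)) tfidf_fit(cohort)
             else tfidf_fit(cohort, comorbidity_codes)
  counts <- comorbidity_counts(cohort, model$codes)
  w <- sweep(counts, 2, model$idf, `*`)
  out <- data.frame(
    patient_id = rep(rownames(w), times = ncol(w)),
    event_type = rep(colnames(w), each = nrow(w)),
    weight = as.vector(w), stringsAsFactors = FALSE)
  attr(out, "model") <- model
  out
}

## tf-idf weight of one (patient, code) pair scaled into [0,1] by the
## training-fold maximum; used as the comorbidity node feature.
tfidf_node_value <- function(model, record, code) {
  tf <- sum(vapply(record$visits, function(v)
    code %in% names(v$events) && v$events[[code]] != 0, logical(1)))
  min(1, tf * model$idf[[code]] / model$max_weight)
}
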