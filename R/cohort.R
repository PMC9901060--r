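#' @useDynLib graphDBP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rpois rexp sd setNames predict
#' @importFrom utils head tail
"_PACKAGE"

## Canonical event vocabularies.  Labs are hemodynamic variables; the seven
## comorbidity codes are the high-frequency heart-failure comorbidities used
## as graph nodes.
DEMOGRAPHIC_EVENTS <- c("age", "gender")
LAB_EVENTS <- c("DBP", "SBP", "SVR")
COMORBIDITY_EVENTS <- c(
  "hypertension", "hyperlipidemia", "shortness_of_breath",
  "atrial_fibrillation", "cancer", "diabetes_mellitus", "dyslipidemia"
)
HF_DRUG_CATEGORIES <- c("ACEI", "BB", "ARB", "Statin", "LD")
HF_SUBTYPES <- c("HFrEF", "HFpEF")

#' Clinical event tuple
#'
#' A clinical event is the atomic observation of a longitudinal EHR: the
#' event type (a code from the cohort vocabulary, e.g. `"DBP"`), the observed
#' value, and a timestamp in days since the patient's first visit.
#'
#' @param event_type Character scalar, an event-type code.
#' @param value Finite numeric scalar (a measurement, or a 0/1 indicator for
#'   categorical events such as comorbidity diagnoses).
#' @param timestamp Non-negative numeric scalar, days since first visit.
#' @return A `clinical_event` list with fields `event_type`, `value`,
#'   `timestamp`.
#' @examples
#' clinical_event("DBP", 74, 0)
#' @export
clinical_event <- function(event_type, value, timestamp) {
  stopifnot(is.character(event_type), length(event_type) == 1L)
  if (!is.finite(value)) stop("clinical_event: value must be finite")
  if (!is.finite(timestamp) || timestamp < 0)
    stop("clinical_event: timestamp must be a non-negative real")
  structure(list(event_type = event_type, value = as.numeric(value),
                 timestamp = as.numeric(timestamp)),
            class = "clinical_event")
}

#' Visit: a set of events sharing one encounter
#'
#' All events of a visit share one timestamp and there is at most one event
#' per event type.
#'
#' @param index 1-based position of the visit in the patient sequence.
#' @param timestamp Non-negative numeric, days since the patient's first
#'   visit.
#' @param events Named numeric vector: names are event types, values the
#'   observations.
#' @return A `visit` object.
#' @export
visit <- function(index, timestamp, events) {
  events <- unlist(events)
  if (is.null(names(events)) || any(!nzchar(names(events))))
    stop("visit: events must be a named numeric vector")
  if (anyDuplicated(names(events)))
    stop("visit: at most one event per event type per visit")
  if (!is.finite(timestamp) || timestamp < 0)
    stop("visit: timestamp must be a non-negative real")
  if (any(!is.finite(events))) stop("visit: event values must be finite")
  structure(list(index = as.integer(index), timestamp = as.numeric(timestamp),
                 events = events),
            class = "visit")
}

#' Longitudinal record of a single patient
#'
#' @param patient_id Opaque string identifier.
#' @param visits List of [visit()] objects, strictly increasing in timestamp.
#'   At least two visits are required (the forecasting task withholds at
#'   least one).
#' @param drugs Character vector of medication names (may be empty).
#' @param drug_categories Character subset of
#'   `c("ACEI","BB","ARB","Statin","LD")`; usually derived from `drugs` via
#'   [assign_drug_category()].
#' @param subtype Optional heart-failure subtype, `"HFrEF"` or `"HFpEF"`.
#' @param target_dbp The ground-truth forecasting target: DBP of the last
#'   visit that records one.  Computed if missing.
#' @return A `patient_record` object.
#' @export
patient_record <- function(patient_id, visits, drugs = character(),
                           drug_categories = character(), subtype = NA_character_,
                           target_dbp = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (length(visits) < 2L)
    stop("patient_record '", patient_id, "': at least 2 visits are required")
  ts <- vapply(visits, function(v) v$timestamp, numeric(1))
  if (any(diff(ts) <= 0))
    stop("patient_record '", patient_id,
         "': visit timestamps must be strictly increasing")
  for (i in seq_along(visits)) visits[[i]]$index <- i
  if (is.null(target_dbp)) {
    target_dbp <- NA_real_
    for (v in rev(visits)) {
      if ("DBP" %in% names(v$events)) { target_dbp <- unname(v$events[["DBP"]]); break }
    }
  }
  if (!is.na(subtype) && !subtype %in% HF_SUBTYPES)
    stop("patient_record: unknown subtype ", subtype)
  if (length(drug_categories) &&
      !all(drug_categories %in% HF_DRUG_CATEGORIES))
    stop("patient_record: unknown drug category")
  structure(list(patient_id = patient_id, visits = visits,
                 drugs = as.character(drugs),
                 drug_categories = sort(unique(as.character(drug_categories))),
                 subtype = subtype, target_dbp = as.numeric(target_dbp)),
            class = "patient_record")
}

#' Cohort of patient records
#'
#' @param patients List of [patient_record()] objects.
#' @param vocabulary Ordered character vector of event-type codes; defaults
#'   to the union of codes present, with demographics, labs and the known
#'   comorbidities first.
#' @return An `ehr_cohort` object.
#' @export
cohort <- function(patients, vocabulary = NULL) {
  if (length(patients) == 0L) stop("cohort: at least one patient is required")
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("cohort: duplicate patient ids")
  names(patients) <- ids
  present <- unique(unlist(lapply(patients, function(p)
    unlist(lapply(p$visits, function(v) names(v$events)), use.names = FALSE))))
  if (is.null(vocabulary)) {
    known <- c(DEMOGRAPHIC_EVENTS, LAB_EVENTS, COMORBIDITY_EVENTS)
    vocabulary <- c(intersect(known, present), sort(setdiff(present, known)))
  } else if (!all(present %in% vocabulary)) {
    stop("cohort: vocabulary does not cover event types: ",
         paste(setdiff(present, vocabulary), collapse = ", "))
  }
  structure(list(patients = patients, vocabulary = vocabulary),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  nv <- vapply(x$patients, function(p) length(p$visits), integer(1))
  cat("EHR cohort: ", length(x$patients), " patients, ",
      length(x$vocabulary), " event types, ",
      sprintf("%.2f", mean(nv)), " visits/patient on average\n", sep = "")
  invisible(x)
}

#' @export
print.patient_record <- function(x, ...) {
  cat("patient ", x$patient_id, ": ", length(x$visits), " visits",
      if (!is.na(x$subtype)) paste0(", ", x$subtype),
      if (length(x$drug_categories))
        paste0(", on {", paste(x$drug_categories, collapse = ","), "}"),
      ", target DBP ", format(x$target_dbp), "\n", sep = "")
  invisible(x)
}

#' Number of patients in a cohort
#'
#' @param cohort An `ehr_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) length(cohort$patients)

#' Patient identifiers of a cohort
#'
#' @param cohort An `ehr_cohort`.
#' @return Character vector of patient ids, in cohort order.
#' @export
patient_ids <- function(cohort) names(cohort$patients)

#' Subset a cohort by patient id or index
#'
#' @param cohort An `ehr_cohort`.
#' @param who Character ids or integer/logical index into the patient list.
#' @return An `ehr_cohort` with the selected patients and the same
#'   vocabulary.
#' @export
subset_cohort <- function(cohort, who) {
  cohort$patients <- cohort$patients[who]
  if (length(cohort$patients) == 0L) stop("subset_cohort: empty selection")
  cohort
}

#' Flatten a cohort to a long event table
#'
#' @param cohort An `ehr_cohort`.
#' @return A data.frame with columns `patient_id`, `visit_index`,
#'   `timestamp`, `event_type`, `value`, one row per clinical event.
#' @export
cohort_events <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    per_visit <- lapply(p$visits, function(v)
      data.frame(patient_id = p$patient_id, visit_index = v$index,
                 timestamp = v$timestamp, event_type = names(v$events),
                 value = unname(v$events), stringsAsFactors = FALSE))
    do.call(rbind, per_visit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Strict structural validation used by readers and the simulator.
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  for (p in cohort$patients) {
    ts <- vapply(p$visits, function(v) v$timestamp, numeric(1))
    if (any(ts < 0))
      stop("validate_cohort: negative timestamp for patient ", p$patient_id)
    if (any(diff(ts) <= 0))
      stop("validate_cohort: non-monotone visit timestamps for patient ",
           p$patient_id)
    for (v in p$visits) {
      if (anyDuplicated(names(v$events)))
        stop("validate_cohort: duplicate event type in a visit of patient ",
             p$patient_id)
      if (any(!is.finite(v$events)))
        stop("validate_cohort: non-finite event value for patient ",
             p$patient_id)
    }
  }
  invisible(cohort)
}
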