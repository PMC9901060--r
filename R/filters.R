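#' Heart-failure ICD codes bundled with the package
#'
#' The 25 ICD-9 and 27 ICD-10 diagnosis codes defining the heart-failure
#' cohort, shipped as a plain-text table.
#'
#' @return A data.frame with columns `system` and `code`.
#' @export
hf_icd_codes <- function() {
  utils::read.delim(system.file("extdata", "hf_icd_codes.tsv",
                                package = "graphDBP"),
                    colClasses = "character")
}

#' Heart-failure drug category map bundled with the package
#'
#' Medication name to drug-category table for the five categories:
#' ACEI (angiotensin-converting-enzyme inhibitors), BB (beta blockers),
#' ARB (angiotensin II receptor blockers), Statin and LD (loop diuretics).
#'
#' @return A data.frame with columns `category` and `medication`.
#' @export
hf_drug_map <- function() {
  utils::read.delim(system.file("extdata", "hf_drug_categories.tsv",
                                package = "graphDBP"),
                    colClasses = "character")
}

#' Diabetes-mellitus medications (curated list)
#'
#' A small curated list of common diabetes medications used for the
#' polypharmacy stratification (heart-failure plus diabetes drugs).
#'
#' @return Character vector of medication names.
#' @export
dm_medications <- function() {
  utils::read.delim(system.file("extdata", "dm_medications.tsv",
                                package = "graphDBP"),
                    colClasses = "character")$medication
}

#' Retain patients with a heart-failure diagnosis code
#'
#' A patient is retained when at least one of their diagnosis events (event
#' types matching an ICD code) is in `icd_codes`.  Idempotent; the output is
#' always a sub-cohort of the input.
#'
#' @param cohort An `ehr_cohort` whose diagnosis events are coded as event
#'   types (e.g. `"I50.9"` with an indicator value).
#' @param icd_codes Character vector of diagnosis codes; defaults to the
#'   bundled heart-failure table ([hf_icd_codes()]).
#' @return The filtered `ehr_cohort`.
#' @export
filter_hf_by_icd <- function(cohort, icd_codes = hf_icd_codes()$code) {
  if (length(icd_codes) == 0L)
    stop("filter_hf_by_icd: empty diagnosis code set")
  keep <- vapply(cohort$patients, function(p)
    any(vapply(p$visits, function(v)
      any(names(v$events) %in% icd_codes & v$events != 0), logical(1))),
    logical(1))
  if (!any(keep)) stop("filter_hf_by_icd: no patient matches the code set")
  subset_cohort(cohort, keep)
}

#' Assign drug categories from medication names
#'
#' Sets `drug_categories` to the union of categories of the record's
#' medications under `category_map` (case-insensitive match on medication
#' name).  Unmapped drugs are ignored with a warning.
#'
#' @param record A `patient_record` with a `drugs` field.
#' @param category_map data.frame with columns `category`, `medication`;
#'   defaults to the bundled table ([hf_drug_map()]).
#' @return The record with `drug_categories` filled in.
#' @export
assign_drug_category <- function(record, category_map = hf_drug_map()) {
  idx <- match(tolower(record$drugs), tolower(category_map$medication))
  if (anyNA(idx) && length(record$drugs))
    warning("assign_drug_category: unmapped drugs for patient ",
            record$patient_id, ": ",
            paste(record$drugs[is.na(idx)], collapse = ", "))
  record$drug_categories <- sort(unique(category_map$category[idx[!is.na(idx)]]))
  record
}

## category of a single medication name, NA when unmapped
drug_category_of <- function(drug, category_map = hf_drug_map()) {
  category_map$category[match(tolower(drug), tolower(category_map$medication))]
}
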