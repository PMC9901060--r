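#' Read a cohort from disk
#'
#' Two plain-text layouts are supported.  `"long"` is a delimited table with
#' header `patient_id, visit_index, timestamp, event_type, value`, one row
#' per clinical event; patient-level metadata (drugs, subtype), if any, lives
#' in a JSON sidecar `<path>.meta.json` written by [write_cohort()].
#' `"jsonl"` holds one JSON patient object per line with all fields inline.
#'
#' @param path File path.
#' @param format `"long"` or `"jsonl"`; guessed from the extension
#'   (`.jsonl` vs anything else) when missing.
#' @return An `ehr_cohort`, visits sorted by timestamp within each patient.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, format = c("guess", "long", "jsonl")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "long"
  if (!file.exists(path)) stop("read_cohort: no such file: ", path)
  if (format == "long") read_cohort_long(path) else read_cohort_jsonl(path)
}

read_cohort_long <- function(path) {
  tab <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "auto",
                      colClasses = list(character = c("patient_id", "event_type"))),
    error = function(e) stop("read_cohort: parse error in ", path, ": ",
                             conditionMessage(e)))
  need <- c("patient_id", "visit_index", "timestamp", "event_type", "value")
  if (!all(need %in% names(tab)))
    stop("read_cohort: header must contain ", paste(need, collapse = ", "))
  bad <- which(!is.finite(tab$value) | !is.finite(tab$timestamp) |
                 is.na(tab$visit_index))
  if (length(bad))
    stop("read_cohort: malformed row at data line ", bad[1])
  if (any(tab$timestamp < 0))
    stop("read_cohort: negative timestamp at data line ",
         which(tab$timestamp < 0)[1])

  meta <- list()
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta_list <- jsonlite::fromJSON(meta_path, simplifyVector = FALSE)
    meta <- setNames(meta_list, vapply(meta_list, `[[`, "", "patient_id"))
  }

  split_pat <- split(tab, by = "patient_id", sorted = FALSE)
  patients <- lapply(split_pat, function(df) {
    df <- df[order(df$visit_index), ]
    visits <- lapply(split(df, df$visit_index), function(vd) {
      if (length(unique(vd$timestamp)) != 1L)
        stop("read_cohort: unequal timestamps within visit ",
             vd$visit_index[1], " of patient ", vd$patient_id[1])
      visit(vd$visit_index[1], vd$timestamp[1],
            setNames(vd$value, vd$event_type))
    })
    ts <- vapply(visits, `[[`, numeric(1), "timestamp")
    if (any(diff(ts[order(vapply(visits, `[[`, integer(1), "index"))]) <= 0))
      stop("read_cohort: non-monotone timestamps for patient ",
           df$patient_id[1])
    m <- meta[[df$patient_id[1]]]
    patient_record(df$patient_id[1], unname(visits[order(ts)]),
                   drugs = as.character(unlist(m$drugs)),
                   drug_categories = as.character(unlist(m$drug_categories)),
                   subtype = scalar_or_na(m$subtype))
  })
  cohort(unname(patients))
}

read_cohort_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  patients <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("read_cohort: malformed JSON at line ", i))
    visits <- lapply(obj$visits, function(v)
      visit(v$index, v$timestamp,
            setNames(vapply(v$events, function(e) as.numeric(e$value), 0),
                     vapply(v$events, function(e) e$event_type, ""))))
    patient_record(obj$patient_id, visits,
                   drugs = as.character(unlist(obj$drugs)),
                   drug_categories = as.character(unlist(obj$drug_categories)),
                   subtype = scalar_or_na(obj$subtype))
  })
  cohort(patients)
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(co, path))` is the
#' identity on valid cohorts.  In `"long"` mode a JSON metadata sidecar
#' `<path>.meta.json` is written whenever any patient carries drugs, drug
#' categories or a subtype label.
#'
#' @param cohort An `ehr_cohort`.
#' @param path Output file path.
#' @param format `"long"` or `"jsonl"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("guess", "long", "jsonl")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "long"
  validate_cohort(cohort)
  if (format == "long") {
    data.table::fwrite(cohort_events(cohort), path, sep = ",")
    has_meta <- vapply(cohort$patients, function(p)
      length(p$drugs) > 0 || length(p$drug_categories) > 0 || !is.na(p$subtype),
      logical(1))
    meta_path <- paste0(path, ".meta.json")
    if (any(has_meta)) {
      meta <- lapply(unname(cohort$patients), function(p) {
        m <- list(patient_id = p$patient_id, drugs = p$drugs,
                  drug_categories = p$drug_categories)
        if (!is.na(p$subtype)) m$subtype <- p$subtype
        m
      })
      jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
    } else if (file.exists(meta_path)) {
      unlink(meta_path)
    }
  } else {
    lines <- vapply(unname(cohort$patients), function(p) {
      obj <- list(
        patient_id = p$patient_id,
        drugs = p$drugs, drug_categories = p$drug_categories)
      if (!is.na(p$subtype)) obj$subtype <- p$subtype
      obj$visits <- lapply(p$visits, function(v)
        list(index = v$index, timestamp = v$timestamp,
             events = lapply(seq_along(v$events), function(j)
               list(event_type = names(v$events)[j],
                    value = unname(v$events[j])))))
      as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

scalar_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x)
}
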