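#' Build a patient knowledge graph
#'
#' Transforms one patient's longitudinal record into the temporal knowledge
#' graph `G = (V, E, A, X)`.  One node is introduced per observed
#' (event type, visit) pair within the selected data source; missing events
#' simply have no node.  Within each event type's chronological chain every
#' node is connected (undirected) to all later nodes of that chain, so the
#' one-hop neighborhood carries long-term dependencies; the adjacency `A`
#' stores this explicit temporal structure.  The node feature matrix
#' `X` (|V| x 1) is the normalized event value plus the patient's min-max
#' normalized timestamp, infusing positional information.
#'
#' The final `horizon` visits are withheld; the target is the DBP value of
#' the first withheld visit (`horizon = 1` forecasts the last visit,
#' `horizon = 2` the second-to-last).
#'
#' @param record A `patient_record`.
#' @param source_mode `"ALL"`, `"Demographics"`, `"Lab"` or `"Comorbidity"`.
#'   Single sources also keep the past DBP chain, since DBP is the outcome
#'   of interest.
#' @param horizon Number of trailing visits withheld (>= 1).
#' @param scaler Optional [fit_value_scaler()] from the training fold; when
#'   `NULL`, lab/demographic values are min-max normalized within the
#'   patient's own observed window.
#' @param tfidf Optional `tfidf_model` from [tfidf_fit()]; comorbidity node
#'   values are then scaled tf-idf weights, otherwise the raw indicator.
#' @return A `patient_graph` (fields `nodes`, `A`, `X`, `target`,
#'   `source_mode`, `patient_id`, `horizon`), or a `patient_skip` marker
#'   carrying the reason when the patient cannot be forecast (no DBP in the
#'   withheld visit, or no observed visits left).
#' @export
build_patient_graph <- function(record,
                                source_mode = c("ALL", "Demographics", "Lab",
                                                "Comorbidity"),
                                horizon = 1, scaler = NULL, tfidf = NULL) {
  source_mode <- match.arg(source_mode)
  stopifnot(horizon >= 1)
  T_vis <- length(record$visits)
  n_obs <- T_vis - horizon
  if (n_obs < 1L)
    return(skip_reason("no observed visits left after withholding"))
  target_visit <- record$visits[[n_obs + 1L]]
  if (!"DBP" %in% names(target_visit$events))
    return(skip_reason("no DBP in withheld visit"))
  target <- unname(target_visit$events[["DBP"]])

  scope <- switch(source_mode,
    ALL = c(DEMOGRAPHIC_EVENTS, LAB_EVENTS, COMORBIDITY_EVENTS),
    Demographics = unique(c(DEMOGRAPHIC_EVENTS, "DBP")),
    Lab = LAB_EVENTS,
    Comorbidity = unique(c(COMORBIDITY_EVENTS, "DBP")))

  obs <- record$visits[seq_len(n_obs)]
  ets <- character(); viss <- integer(); tss <- numeric(); vals <- numeric()
  for (v in obs) {
    keep <- intersect(names(v$events), scope)
    if (!length(keep)) next
    keep <- keep[order(match(keep, scope))]
    ets <- c(ets, keep)
    viss <- c(viss, rep.int(v$index, length(keep)))
    tss <- c(tss, rep.int(v$timestamp, length(keep)))
    vals <- c(vals, unname(v$events[keep]))
  }
  if (length(ets) == 0L)
    return(skip_reason("no in-scope events observed"))
  nodes <- data.frame(event_type = ets, visit = viss, timestamp = tss,
                      value = vals, stringsAsFactors = FALSE)

  ## node values: labs/demographics min-max normalized (training-fold
  ## scaler if given, else within-patient); comorbidities tf-idf weighted
  vnorm <- numeric(nrow(nodes))
  for (et in unique(nodes$event_type)) {
    idx <- which(nodes$event_type == et)
    if (et %in% COMORBIDITY_EVENTS) {
      vnorm[idx] <- if (is.null(tfidf)) pmin(1, abs(nodes$value[idx]))
                    else tfidf_node_value(tfidf, record, et)
    } else if (is.null(scaler)) {
      vnorm[idx] <- minmax_normalize(nodes$value[idx])
    } else {
      vnorm[idx] <- apply_value_scaler(scaler, et, nodes$value[idx])
    }
  }
  tnorm <- if (length(unique(nodes$timestamp)) == 1L) rep(0, nrow(nodes))
           else minmax_normalize(nodes$timestamp)
  X <- matrix(vnorm + tnorm, ncol = 1)

  n <- nrow(nodes)
  A <- matrix(0, n, n)
  for (et in unique(nodes$event_type)) {
    chain <- which(nodes$event_type == et)          # already visit-ordered
    if (length(chain) > 1)
      for (a in seq_len(length(chain) - 1))
        for (b in (a + 1):length(chain)) {
          A[chain[a], chain[b]] <- 1
          A[chain[b], chain[a]] <- 1
        }
  }
  node_names <- paste0(nodes$event_type, "_", nodes$visit)
  dimnames(A) <- list(node_names, node_names)
  rownames(X) <- node_names

  structure(list(nodes = nodes, A = A, X = X, target = target,
                 source_mode = source_mode, horizon = horizon,
                 patient_id = record$patient_id),
            class = "patient_graph")
}

skip_reason <- function(reason) {
  structure(list(reason = reason), class = "patient_skip")
}

#' Was a patient skipped by graph construction?
#'
#' @param x Result of [build_patient_graph()].
#' @return `TRUE` for a skip marker (its `$reason` says why).
#' @export
is_skipped <- function(x) inherits(x, "patient_skip")

#' @export
print.patient_graph <- function(x, ...) {
  cat("patient graph ", x$patient_id, " [", x$source_mode, ", horizon ",
      x$horizon, "]: ", nrow(x$nodes), " nodes, ", sum(x$A) / 2,
      " edges, target DBP ", format(x$target), "\n", sep = "")
  invisible(x)
}

#' Build the graphs of a whole cohort
#'
#' Applies [build_patient_graph()] to every patient, dropping those that
#' cannot be forecast and logging the reasons.
#'
#' @inheritParams build_patient_graph
#' @param cohort An `ehr_cohort`.
#' @param quiet Suppress the skip log message.
#' @return Named list of `patient_graph`s; skipped patients are reported in
#'   attribute `"skipped"` (named character vector of reasons).
#' @export
build_cohort_graphs <- function(cohort, source_mode = "ALL", horizon = 1,
                                scaler = NULL, tfidf = NULL, quiet = TRUE) {
  graphs <- lapply(cohort$patients, build_patient_graph,
                   source_mode = source_mode, horizon = horizon,
                   scaler = scaler, tfidf = tfidf)
  skipped <- vapply(graphs, function(g)
    if (is_skipped(g)) g$reason else NA_character_, character(1))
  skipped <- skipped[!is.na(skipped)]
  graphs <- Filter(Negate(is_skipped), graphs)
  if (length(skipped) && !quiet)
    message("build_cohort_graphs: skipped ", length(skipped), " patients (",
            paste(unique(skipped), collapse = "; "), ")")
  attr(graphs, "skipped") <- skipped
  graphs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort-wide event co-occurrence attention mask
#'
#' Builds the binary event-type co-occurrence matrix `M` over the cohort
#' vocabulary: `M[i, j] = 1` iff event types `i` and `j` appear together in
#' at least one record.  A record is a single visit by default (each
#' patient record corresponds to one visit in the source data),
#' configurable to whole-patient co-occurrence.  The diagonal is forced to
#' 1 so attention to a node's own event type is never masked out.  Build
#' the mask from training-fold patients only to keep held-out co-occurrence
#' structure out of the model.
#'
#' @param cohort An `ehr_cohort` (training fold).
#' @param level `"visit"` (default) or `"patient"`.
#' @param vocabulary Event-type order of the matrix; defaults to the cohort
#'   vocabulary.
#' @return A `cooccurrence_mask` with fields `M` (named binary matrix) and
#'   `vocabulary`.
#' @export
build_cooccurrence_mask <- function(cohort, level = c("visit", "patient"),
                                    vocabulary = cohort$vocabulary) {
  level <- match.arg(level)
  k <- length(vocabulary)
  M <- matrix(0, k, k, dimnames = list(vocabulary, vocabulary))
  for (p in cohort$patients) {
    groups <- if (level == "visit")
      lapply(p$visits, function(v) names(v$events))
    else
      list(unique(unlist(lapply(p$visits, function(v) names(v$events)))))
    for (g in groups) {
      g <- intersect(g, vocabulary)
      if (length(g) > 1) M[g, g] <- 1
    }
  }
  diag(M) <- 1
  structure(list(M = M, vocabulary = vocabulary),
            class = "cooccurrence_mask")
}

#' Expand the event-type mask to node level
#'
#' Node pair (p, q) may attend iff their event types co-occur:
#' `node_mask[p, q] = M[type(p), type(q)]`.  Timesteps are ignored, so two
#' nodes of the same event type are always mutually visible (diagonal of
#' `M` is 1).
#'
#' @param mask A [build_cooccurrence_mask()] result.
#' @param graph A `patient_graph`.
#' @return Binary |V| x |V| matrix with unit diagonal.
#' @export
expand_mask_to_nodes <- function(mask, graph) {
  types <- graph$nodes$event_type
  unknown <- setdiff(types, mask$vocabulary)
  if (length(unknown))
    stop("expand_mask_to_nodes: event types not in mask vocabulary: ",
         paste(unique(unknown), collapse = ", "))
  out <- mask$M[types, types, drop = FALSE]
  dimnames(out) <- dimnames(graph$A)
  out
}

#' Serialize a patient graph to plain text
#'
#' Writes a node table `(node_id, event_type, timestep, feature)` and an
#' edge list to a single readable file for inspection.
#'
#' @param graph A `patient_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_graph <- function(graph, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# nodes: node_id\tevent_type\ttimestep\tfeature", con)
  for (i in seq_len(nrow(graph$nodes)))
    writeLines(sprintf("%s\t%s\t%d\t%.10g", rownames(graph$X)[i],
                       graph$nodes$event_type[i], graph$nodes$visit[i],
                       graph$X[i, 1]), con)
  writeLines("# edges: from\tto", con)
  idx <- which(upper.tri(graph$A) & graph$A == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(idx)))
    writeLines(paste(rownames(graph$A)[idx[r, 1]],
                     colnames(graph$A)[idx[r, 2]], sep = "\t"), con)
  invisible(path)
}
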