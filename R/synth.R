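#' Configuration of the synthetic EHR cohort simulator
#'
#' The simulator emulates the structure of a longitudinal heart-failure
#' cohort — ordered visits with hemodynamic labs (DBP, SBP, SVR),
#' demographics, sparse comorbidities, medication categories and a
#' last-visit DBP target — on top of a linear-Gaussian latent health state,
#' so the irreducible forecasting error is known in closed form.
#'
#' Per patient with subtype regime `(a_d, ar, b_d)`:
#' \deqn{h_t = ar \cdot h_{t-1} + \eta_t, \qquad
#'       DBP_t = a_d h_t + b_d + s \cdot t + \epsilon_t,}
#' with `s` the summed per-visit drug effect of the patient's categories,
#' and SBP/SVR linear in the same latent state.  The innovation variance is
#' chosen so the latent state is stationary with standard deviation
#' `latent_sd` in both regimes.
#'
#' @param n_patients Number of patients (> 0).
#' @param visit_rate Mean of the Poisson visit count, truncated to >= 2.
#' @param noise_sd Observation noise SD on every lab value (mmHg for BP).
#' @param ar_coef Latent-state autoregression of the HFrEF regime, in
#'   (-1, 1); the HFpEF regime uses `hfpef_ar`.
#' @param hfpef_ar Autoregression of the HFpEF regime.
#' @param drug_effects Named per-visit DBP shift (mmHg/visit) per drug
#'   category; a patient's trend slope is the sum over their categories.
#' @param subtype_fraction Fraction of HFpEF patients in \[0, 1\].
#' @param subtype_gap Difference in baseline DBP level (mmHg) between the
#'   HFpEF and HFrEF regimes (HFrEF baseline stays at 68).
#' @param missing_prob Independent per-event dropout probability in
#'   \[0, 1); DBP is always measured (it is the variable of interest).
#' @param latent_sd Stationary SD of the latent health state.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 800, visit_rate = 5, noise_sd = 5,
                       ar_coef = 0.9, hfpef_ar = 0.8,
                       drug_effects = c(ACEI = -0.8, BB = -1.0, ARB = -0.8,
                                        Statin = -0.1, LD = -1.2),
                       subtype_fraction = 0.5, subtype_gap = 10,
                       missing_prob = 0.1, latent_sd = 2, seed = 1) {
  stopifnot(n_patients > 0, visit_rate > 0, noise_sd >= 0,
            abs(ar_coef) < 1, abs(hfpef_ar) < 1,
            subtype_fraction >= 0, subtype_fraction <= 1,
            missing_prob >= 0, missing_prob < 1, latent_sd > 0)
  stopifnot(all(names(drug_effects) %in% HF_DRUG_CATEGORIES))
  structure(list(n_patients = as.integer(n_patients), visit_rate = visit_rate,
                 noise_sd = noise_sd, ar_coef = ar_coef, hfpef_ar = hfpef_ar,
                 drug_effects = drug_effects,
                 subtype_fraction = subtype_fraction,
                 subtype_gap = subtype_gap,
                 missing_prob = missing_prob, latent_sd = latent_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Fixed generative coefficients shared by both regimes (recorded in the
## output metadata).  BP in mmHg, SVR in dyn.s.cm^-5, ages in years.
synth_coefficients <- function(config) {
  list(
    regimes = list(
      HFrEF = list(a_d = 4.0, ar = config$ar_coef, b_d = 68),
      HFpEF = list(a_d = 3.0, ar = config$hfpef_ar,
                   b_d = 68 + config$subtype_gap)),
    a_s = 6, b_s = 125, a_v = 4, b_v = 1100,
    latent_sd = config$latent_sd, gap_mean_days = 30,
    age_mean = 74, age_sd = 8,
    comorbidity_base = c(hypertension = 0.6, hyperlipidemia = 0.4,
                         shortness_of_breath = 0.35, atrial_fibrillation = 0.3,
                         cancer = 0.12, diabetes_mellitus = 0.3,
                         dyslipidemia = 0.25),
    comorbidity_slope = 0.5,
    dm_drug_prob = 0.3)
}

#' Generate a synthetic EHR cohort
#'
#' Draws a cohort under [sim_config()]; see that page for the generative
#' model.  The true coefficients, the latent trajectories and each
#' patient's trend slope are attached as attribute `"sim_meta"` (and can be
#' persisted with [write_sim_meta()]), so the irreducible noise floor can
#' be estimated with [oracle_predictor()].
#'
#' @param config A [sim_config()].
#' @return An `ehr_cohort` with per-patient drugs, drug categories and
#'   subtype labels; attribute `"sim_meta"` carries the generative truth.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- synth_coefficients(config)
  drug_map <- hf_drug_map()
  dm_drugs <- dm_medications()

  patients <- vector("list", config$n_patients)
  meta_pat <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    subtype <- if (runif(1) < config$subtype_fraction) "HFpEF" else "HFrEF"
    rg <- cf$regimes[[subtype]]
    sd_eta <- config$latent_sd * sqrt(1 - rg$ar^2)

    T_vis <- 0L
    while (T_vis < 2L) T_vis <- rpois(1, config$visit_rate)
    ts <- cumsum(c(0, rexp(T_vis - 1, rate = 1 / cf$gap_mean_days)))

    h <- numeric(T_vis)
    h[1] <- rnorm(1, 0, config$latent_sd)
    if (T_vis > 1)
      for (t in 2:T_vis) h[t] <- rg$ar * h[t - 1] + rnorm(1, 0, sd_eta)

    n_cat <- sample(1:2, 1)
    cats <- sample(HF_DRUG_CATEGORIES, n_cat)
    drugs <- vapply(cats, function(cc)
      sample(drug_map$medication[drug_map$category == cc], 1), character(1))
    if (runif(1) < cf$dm_drug_prob) drugs <- c(drugs, sample(dm_drugs, 1))
    slope <- sum(config$drug_effects[cats], na.rm = TRUE)

    com_p <- plogis(qlogis(cf$comorbidity_base) + cf$comorbidity_slope * h[1])
    coms <- names(com_p)[runif(length(com_p)) < com_p]
    age0 <- rnorm(1, cf$age_mean, cf$age_sd)
    gender <- rbinom(1, 1, 0.5)

    visits <- vector("list", T_vis)
    for (t in seq_len(T_vis)) {
      eps <- rnorm(3, 0, config$noise_sd)
      ev <- c(DBP = rg$a_d * h[t] + rg$b_d + slope * t + eps[1],
              SBP = cf$a_s * h[t] + cf$b_s + eps[2],
              SVR = cf$a_v * h[t] + cf$b_v + eps[3],
              age = age0 + ts[t] / 365, gender = gender)
      if (length(coms)) ev <- c(ev, setNames(rep(1, length(coms)), coms))
      if (config$missing_prob > 0) {
        drop <- runif(length(ev)) < config$missing_prob
        drop[names(ev) == "DBP"] <- FALSE
        ev <- ev[!drop]
      }
      visits[[t]] <- visit(t, ts[t], ev)
    }
    patients[[i]] <- patient_record(pid, visits, drugs = unname(drugs),
                                    drug_categories = cats, subtype = subtype)
    meta_pat[[i]] <- list(patient_id = pid, subtype = subtype, slope = slope,
                          n_visits = T_vis, h = h)
  }
  co <- cohort(patients,
               vocabulary = c(DEMOGRAPHIC_EVENTS, LAB_EVENTS,
                              COMORBIDITY_EVENTS))
  validate_cohort(co)
  attr(co, "sim_meta") <- list(config = config, coefficients = cf,
                               patients = setNames(meta_pat,
                                                   vapply(meta_pat, `[[`, "",
                                                          "patient_id")))
  co
}

#' Oracle DBP predictor from the generative truth
#'
#' Predicts each patient's target DBP by its conditional mean given the
#' latent health state, `a_d h_T + b_d + s T`.  Its RMSE against the
#' realized targets estimates the irreducible noise floor, approximately
#' `noise_sd`.
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @param metadata The `"sim_meta"` attribute of that cohort (default).
#' @return data.frame `(patient_id, target, oracle)`, with the oracle RMSE
#'   as attribute `"rmse"`.
#' @export
oracle_predictor <- function(cohort, metadata = attr(cohort, "sim_meta")) {
  if (is.null(metadata))
    stop("oracle_predictor: generative metadata missing")
  rows <- lapply(cohort$patients, function(p) {
    m <- metadata$patients[[p$patient_id]]
    if (is.null(m)) stop("oracle_predictor: no metadata for ", p$patient_id)
    rg <- metadata$coefficients$regimes[[m$subtype]]
    T_vis <- m$n_visits
    data.frame(patient_id = p$patient_id, target = p$target_dbp,
               oracle = rg$a_d * m$h[T_vis] + rg$b_d + m$slope * T_vis)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rmse") <- sqrt(mean((out$target - out$oracle)^2))
  out
}

#' Persist the generative truth of a synthetic cohort
#'
#' Sidecar JSON with the configuration, coefficients and latent
#' trajectories, so a written cohort file plus its sidecar reproduce the
#' oracle.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_meta <- function(cohort, path) {
  meta <- attr(cohort, "sim_meta")
  if (is.null(meta)) stop("write_sim_meta: cohort has no generative metadata")
  meta$config <- unclass(meta$config)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a generative-truth sidecar
#'
#' @param path JSON path written by [write_sim_meta()].
#' @return The metadata list, usable as the `metadata` argument of
#'   [oracle_predictor()].
#' @export
read_sim_meta <- function(path) {
  meta <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  meta$patients <- lapply(meta$patients, function(m) {
    m$h <- as.numeric(unlist(m$h)); m
  })
  meta$coefficients$regimes <- lapply(meta$coefficients$regimes, as.list)
  meta
}

## Mean of a Poisson(lambda) truncated to >= 2; closed form used by tests.
truncated_poisson_mean <- function(lambda) {
  p0 <- stats::dpois(0, lambda); p1 <- stats::dpois(1, lambda)
  (lambda - p1) / (1 - p0 - p1)
}
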