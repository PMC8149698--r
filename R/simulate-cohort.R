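# Synthetic clinical cohort generator: stage-dependent miRNA expression,
# miRNA-mRNA dependence via a Gaussian copula, and exponential survival with
# proportional hazards and independent censoring.

#' Configuration for a synthetic clinical cohort
#'
#' @param n_patients cohort size.
#' @param n_mirnas,n_mrnas numbers of miRNA and mRNA features.
#' @param stage_probs probabilities of tumour stages 0-4 (must sum to 1).
#'   The default puts few patients in stages 0 and 4, mirroring real HER2+
#'   cohorts where the extreme stages are too small to test.
#' @param corr_structure data.frame (mirna, mrna, rho) of target Spearman
#'   correlations; all other pairs are independent. Achieved via a Gaussian
#'   copula with Pearson correlation `2*sin(pi*rho/6)`, which is exact for
#'   bivariate normal margins.
#' @param stage_effects named per-miRNA additive shift per stage unit
#'   (monotone in stage).
#' @param hazard_log_hr named per-miRNA log hazard ratio per unit expression.
#' @param baseline_hazard events per month for a patient at expression 0.
#' @param censor_rate expected censored fraction under the null, in [0, 1);
#'   censoring times are independent exponentials.
#' @param disease_death_prob probability a death is disease-specific (drives
#'   the BCSS vs OS endpoints).
#' @param seed integer seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 300L,
                              n_mirnas = 8L,
                              n_mrnas = 100L,
                              stage_probs = c("0" = 0.02, "1" = 0.30,
                                              "2" = 0.40, "3" = 0.25,
                                              "4" = 0.03),
                              corr_structure = NULL,
                              stage_effects = NULL,
                              hazard_log_hr = NULL,
                              baseline_hazard = 0.01,
                              censor_rate = 0.3,
                              disease_death_prob = 0.7,
                              seed = 1L) {
  if (abs(sum(stage_probs) - 1) > 1e-8)
    config_error("stage_probs must sum to 1")
  if (censor_rate < 0 || censor_rate >= 1)
    config_error("censor_rate must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 n_mirnas = as.integer(n_mirnas),
                 n_mrnas = as.integer(n_mrnas),
                 stage_probs = stage_probs,
                 corr_structure = corr_structure,
                 stage_effects = stage_effects,
                 hazard_log_hr = hazard_log_hr,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 disease_death_prob = disease_death_prob,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Generate a synthetic clinical cohort with ground truth
#'
#' Patients carry tumour stage, miRNA and mRNA expression (standard-normal
#' margins before stage shifts), and exponential survival times with hazard
#' `baseline_hazard * exp(sum(log_hr * expression))`, censored independently.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (list: `patients` data.frame with stage, time
#'   in months, event indicator and cause; `mirna` and `mrna` patient x
#'   feature matrices) and `ground_truth` (true correlated pairs, true
#'   stage-shifted miRNAs, true prognostic miRNAs).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config"))
    config_error("config must be a cohort_sim_config")
  set.seed(config$seed)
  n <- config$n_patients
  mirna_ids <- sprintf("hsa-miR-sim-%03d", seq_len(config$n_mirnas))
  mrna_ids <- sprintf("GENE%04d", seq_len(config$n_mrnas))
  p <- config$n_mirnas + config$n_mrnas

  R <- diag(p)
  dimnames(R) <- list(c(mirna_ids, mrna_ids), c(mirna_ids, mrna_ids))
  cs <- config$corr_structure
  if (!is.null(cs) && nrow(cs) > 0L) {
    stopifnot_columns(cs, c("mirna", "mrna", "rho"), "corr_structure")
    bad <- !(cs$mirna %in% mirna_ids) | !(cs$mrna %in% mrna_ids)
    if (any(bad))
      config_error("corr_structure refers to unknown miRNA/mRNA ids")
    r_pearson <- 2 * sin(pi * cs$rho / 6)
    for (i in seq_len(nrow(cs))) {
      R[cs$mirna[i], cs$mrna[i]] <- r_pearson[i]
      R[cs$mrna[i], cs$mirna[i]] <- r_pearson[i]
    }
  }
  L <- tryCatch(chol(R), error = function(e)
    config_error("requested correlation structure is not positive definite"))
  Z <- matrix(rnorm(n * p), nrow = n) %*% L
  colnames(Z) <- colnames(R)
  mirna <- Z[, mirna_ids, drop = FALSE]
  mrna <- Z[, mrna_ids, drop = FALSE]

  stages <- sample(as.integer(names(config$stage_probs)), n, replace = TRUE,
                   prob = config$stage_probs)
  if (!is.null(config$stage_effects)) {
    for (id in names(config$stage_effects)) {
      mirna[, id] <- mirna[, id] + config$stage_effects[[id]] * stages
    }
  }

  log_hr <- setNames(numeric(config$n_mirnas), mirna_ids)
  if (!is.null(config$hazard_log_hr)) {
    log_hr[names(config$hazard_log_hr)] <- config$hazard_log_hr
  }
  rate <- config$baseline_hazard * exp(as.vector(mirna %*% log_hr))
  t_event <- rexp(n, rate)
  if (config$censor_rate > 0) {
    c_rate <- config$baseline_hazard * config$censor_rate /
      (1 - config$censor_rate)
    t_cens <- rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  cause <- ifelse(event == 1L,
                  ifelse(runif(n) < config$disease_death_prob,
                         "disease", "other"),
                  NA_character_)

  patients <- data.frame(
    patient_id = sprintf("PT%04d", seq_len(n)),
    stage = stages, time = time, event = event, cause = cause,
    stringsAsFactors = FALSE)
  rownames(mirna) <- patients$patient_id
  rownames(mrna) <- patients$patient_id

  list(cohort = list(patients = patients, mirna = mirna, mrna = mrna),
       ground_truth = list(
         correlated_pairs = cs,
         stage_mirnas = names(config$stage_effects %||% numeric(0)),
         prognostic_mirnas = names(which(log_hr != 0))))
}
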