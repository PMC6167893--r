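#' Scenario configuration for the synthetic cohort generator
#'
#' Defines the generative model for [simulate_cohort()]: a two-stage
#' stratified PSU sample with oversampling of persons aged 45 and over, an
#' additively coded biallelic risk genotype in Hardy-Weinberg proportions,
#' and a recursive life-course system over BMI at ages 21/45/65 and
#' period-specific type-2-diabetes (T2D) first-diagnosis indicators.
#'
#' The structural defaults are the package's reference scenario for a large
#' US Hispanic/Latino community cohort: risk-allele frequency 0.255; direct
#' per-allele effects on BMI of -0.20, -0.18 and +0.01 kg/m2 at ages 21, 45
#' and 65; per-allele log-odds of first T2D diagnosis of log(1.32) in each
#' age period; BMI tracking (carryover) of 0.8 kg/m2 per kg/m2; and a
#' +2.8 kg/m2 shift in the next BMI after a diagnosis. Diagnosis is a
#' two-period discrete hazard: a first diagnosis in 22-45 removes the person
#' from the risk set for a new diagnosis in 46-65, so `theta_D1_D2` (default
#' 0) only matters under non-standard persistent-status reinterpretations of
#' the period indicators.
#'
#' @param n_strata number of sampled strata.
#' @param psus_per_stratum primary sampling units sampled per stratum.
#' @param persons_per_psu persons sampled per PSU.
#' @param risk_allele_freq population risk-allele frequency in (0, 1).
#' @param beta_G_bmi21,beta_G_bmi45,beta_G_bmi65 direct per-allele effects on
#'   BMI at each age (kg/m2 per allele).
#' @param beta_G_bmi_exam total per-allele effect on BMI at the baseline
#'   examination (kg/m2 per allele); the examination BMI node shares the
#'   life-course residual trajectory but carries its own genetic effect.
#' @param beta_bmi_carryover kg/m2 of later BMI per kg/m2 of the previous BMI.
#' @param theta_G_D1,theta_G_D2 per-allele log-odds of first T2D diagnosis in
#'   ages 22-45 and (among the still-undiagnosed) 46-65.
#' @param theta_bmi_D log-odds of next-period diagnosis per kg/m2 of the
#'   preceding BMI.
#' @param theta_D1_D2 log-odds term for an earlier diagnosis in the later
#'   period equation; inert under the first-diagnosis hazard (see Details).
#' @param beta_D_bmi kg/m2 added to the next BMI after a period diagnosis.
#' @param alpha_D1,alpha_D2 logistic intercepts of the two period hazards.
#' @param intercept_bmi21,intercept_bmi45,intercept_bmi65,intercept_bmi_exam
#'   linear intercepts of the BMI nodes (kg/m2), calibrated so the default
#'   scenario reproduces population means near 23.8, 27.5, 29.0 and 29.6.
#' @param sd_bmi21,sd_bmi45,sd_bmi65,sd_bmi_exam residual SDs of the BMI
#'   nodes (kg/m2), sized so that well under 1% of generated BMIs fall
#'   outside the quality-control plausibility bounds of 16-70 kg/m2.
#' @param recall_sd SD of recall noise added to self-reported weights (kg).
#' @param psu_re_sd SD of a shared PSU-level random intercept on all BMI
#'   nodes (kg/m2); creates the within-cluster correlation the sandwich
#'   variance must absorb.
#' @param covar_effects_bmi,covar_effects_d named numeric vectors
#'   `c(age, female, education)` of covariate effects on BMI nodes (kg/m2)
#'   and diagnosis logits (log-odds).
#' @param oversample_age45 proportion of the sample aged 45+, above its
#'   population share `pop_age45`; drives the age-group inclusion
#'   probabilities and hence the sampling weights.
#' @param pop_age45 population proportion aged 45+.
#' @param g_missing_rate proportion of genotypes set missing.
#' @param equal_weights if `TRUE` all sampling weights are 1 (a
#'   self-weighting design), used for parameter-recovery studies.
#' @param seed master integer seed; stages draw from named substreams via
#'   [substream_seed()].
#' @return an object of class `scenario_config` (a validated list).
#' @seealso [simulate_cohort()], [apply_age_censoring()], [inject_artifacts()]
#' @export
scenario_config <- function(n_strata = 10,
                            psus_per_stratum = 4,
                            persons_per_psu = 226,
                            risk_allele_freq = 0.255,
                            beta_G_bmi21 = -0.20,
                            beta_G_bmi45 = -0.18,
                            beta_G_bmi65 = 0.01,
                            beta_G_bmi_exam = -0.37,
                            beta_bmi_carryover = 0.8,
                            theta_G_D1 = log(1.32),
                            theta_G_D2 = log(1.32),
                            theta_bmi_D = 0.10,
                            theta_D1_D2 = 0,
                            beta_D_bmi = 2.8,
                            alpha_D1 = -5.16,
                            alpha_D2 = -4.0,
                            intercept_bmi21 = 23.4,
                            intercept_bmi45 = 7.9,
                            intercept_bmi65 = 5.9,
                            intercept_bmi_exam = 29.3,
                            sd_bmi21 = 3.0,
                            sd_bmi45 = 3.0,
                            sd_bmi65 = 3.0,
                            sd_bmi_exam = 1.0,
                            recall_sd = 2.0,
                            psu_re_sd = 0.5,
                            covar_effects_bmi = c(age = 0.02, female = -0.3,
                                                  education = -0.4),
                            covar_effects_d = c(age = 0, female = -0.2,
                                                education = -0.3),
                            oversample_age45 = 0.62,
                            pop_age45 = 0.40,
                            g_missing_rate = 0,
                            equal_weights = FALSE,
                            seed = 1L) {
  cfg <- list(
    n_strata = n_strata, psus_per_stratum = psus_per_stratum,
    persons_per_psu = persons_per_psu,
    risk_allele_freq = risk_allele_freq,
    beta_G_bmi21 = beta_G_bmi21, beta_G_bmi45 = beta_G_bmi45,
    beta_G_bmi65 = beta_G_bmi65, beta_G_bmi_exam = beta_G_bmi_exam,
    beta_bmi_carryover = beta_bmi_carryover,
    theta_G_D1 = theta_G_D1, theta_G_D2 = theta_G_D2,
    theta_bmi_D = theta_bmi_D, theta_D1_D2 = theta_D1_D2,
    beta_D_bmi = beta_D_bmi,
    alpha_D1 = alpha_D1, alpha_D2 = alpha_D2,
    intercept_bmi21 = intercept_bmi21, intercept_bmi45 = intercept_bmi45,
    intercept_bmi65 = intercept_bmi65,
    intercept_bmi_exam = intercept_bmi_exam,
    sd_bmi21 = sd_bmi21, sd_bmi45 = sd_bmi45, sd_bmi65 = sd_bmi65,
    sd_bmi_exam = sd_bmi_exam,
    recall_sd = recall_sd, psu_re_sd = psu_re_sd,
    covar_effects_bmi = covar_effects_bmi,
    covar_effects_d = covar_effects_d,
    oversample_age45 = oversample_age45, pop_age45 = pop_age45,
    g_missing_rate = g_missing_rate,
    equal_weights = isTRUE(equal_weights),
    seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_svypath(msg, "svypath_config_error")
  counts <- c(cfg$n_strata, cfg$psus_per_stratum, cfg$persons_per_psu)
  chk(all(is.finite(counts)) && all(counts >= 1) &&
        all(counts == round(counts)),
      "design counts (strata, PSUs, persons) must be integers >= 1")
  chk(cfg$psus_per_stratum >= 2,
      "at least 2 PSUs per stratum are required for variance estimation")
  chk(is.finite(cfg$risk_allele_freq) && cfg$risk_allele_freq > 0 &&
        cfg$risk_allele_freq < 1,
      "risk_allele_freq must lie strictly in (0, 1)")
  sds <- c(cfg$sd_bmi21, cfg$sd_bmi45, cfg$sd_bmi65, cfg$sd_bmi_exam)
  chk(all(is.finite(sds)) && all(sds > 0),
      "all BMI residual SDs must be > 0")
  chk(is.finite(cfg$recall_sd) && cfg$recall_sd >= 0,
      "recall_sd must be >= 0")
  chk(is.finite(cfg$psu_re_sd) && cfg$psu_re_sd >= 0,
      "psu_re_sd must be >= 0")
  for (prop in c("oversample_age45", "pop_age45")) {
    chk(is.finite(cfg[[prop]]) && cfg[[prop]] > 0 && cfg[[prop]] < 1,
        sprintf("%s must lie strictly in (0, 1)", prop))
  }
  chk(cfg$g_missing_rate >= 0 && cfg$g_missing_rate < 1,
      "g_missing_rate must lie in [0, 1)")
  for (cv in c("covar_effects_bmi", "covar_effects_d")) {
    v <- cfg[[cv]]
    chk(is.numeric(v) && all(is.finite(v)) &&
          setequal(names(v), c("age", "female", "education")),
        sprintf("%s must be a finite named vector c(age, female, education)",
                cv))
  }
  struct <- unlist(cfg[c("beta_G_bmi21", "beta_G_bmi45", "beta_G_bmi65",
                         "beta_G_bmi_exam", "beta_bmi_carryover",
                         "theta_G_D1", "theta_G_D2", "theta_bmi_D",
                         "theta_D1_D2", "beta_D_bmi", "alpha_D1", "alpha_D2",
                         "intercept_bmi21", "intercept_bmi45",
                         "intercept_bmi65", "intercept_bmi_exam")])
  chk(all(is.finite(struct)), "all structural coefficients must be finite")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  n <- x$n_strata * x$psus_per_stratum * x$persons_per_psu
  cat("<scenario_config>\n")
  cat(sprintf("  design: %d strata x %d PSUs x %d persons (n = %d)%s\n",
              x$n_strata, x$psus_per_stratum, x$persons_per_psu, n,
              if (x$equal_weights) ", equal weights" else ""))
  cat(sprintf("  risk allele freq %.3f; G->BMI (21/45/65/exam): %.2f %.2f %.2f %.2f\n",
              x$risk_allele_freq, x$beta_G_bmi21, x$beta_G_bmi45,
              x$beta_G_bmi65, x$beta_G_bmi_exam))
  cat(sprintf("  G->T2D odds ratios: %.2f (22-45), %.2f (46-65); BMI->T2D %.2f/kgm2\n",
              exp(x$theta_G_D1), exp(x$theta_G_D2), exp(x$theta_bmi_D)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Read or write a scenario configuration as JSON
#'
#' @param path file path.
#' @param config a [scenario_config()] object.
#' @return `read_scenario_config()` returns a validated `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (cv in c("covar_effects_bmi", "covar_effects_d")) {
    if (!is.null(raw[[cv]])) raw[[cv]] <- unlist(raw[[cv]])
  }
  do.call(scenario_config, raw)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- unclass(config)
  for (cv in c("covar_effects_bmi", "covar_effects_d")) {
    out[[cv]] <- as.list(out[[cv]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
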