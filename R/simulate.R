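#' Simulate a life-course cohort under a two-stage survey design
#'
#' Generates one synthetic cohort from a [scenario_config()]: strata with
#' unequal PSU inclusion fractions, person-level oversampling of ages 45+,
#' Hardy-Weinberg genotypes, the recursive BMI/T2D system, self-reported
#' weight histories with recall noise, glycemic laboratory values, and
#' sampling weights equal to the product of inverse stratum-PSU and person
#' inclusion probabilities.
#'
#' The full latent trajectory (BMI at 21/45/65 regardless of attained age,
#' true period diagnosis indicators) is retained in `attr(cohort, "truth")`
#' so downstream stages can be scored against ground truth. A small set of
#' background (unrelated, pi-hat < 0.2) kinship pairs is attached as
#' `attr(cohort, "kinship")`; [inject_artifacts()] adds flagged pairs.
#'
#' @param config a [scenario_config()].
#' @param censor apply [apply_age_censoring()] before returning (default
#'   `TRUE`). `censor = FALSE` returns the complete-data cohort in which all
#'   weight-history and period-diagnosis fields are observed for everyone;
#'   used for factorization-identity checks and as generative ground truth.
#' @return a `data.frame` with one row per sampled participant (see package
#'   vignette for the column dictionary), with attributes `truth`,
#'   `kinship` and `config`.
#' @export
simulate_cohort <- function(config, censor = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  set.seed(substream_seed(cfg$seed, "simulate"))

  n_psu_tot <- cfg$n_strata * cfg$psus_per_stratum
  n <- n_psu_tot * cfg$persons_per_psu
  stratum <- rep(seq_len(cfg$n_strata), each = cfg$psus_per_stratum *
                   cfg$persons_per_psu)
  psu_within <- rep(rep(seq_len(cfg$psus_per_stratum),
                        each = cfg$persons_per_psu), cfg$n_strata)
  psu <- sprintf("s%02d_p%02d", stratum, psu_within)

  # First stage: stratum s contains psus_per_stratum * (2 + (s-1) mod 4)
  # PSUs of which psus_per_stratum are sampled -> PSU inclusion fraction
  # 1 / (2 + (s-1) mod 4). Second stage: persons sampled with an age-group
  # probability that oversamples ages 45+ relative to their population share.
  f_psu <- 1 / (2 + (stratum - 1) %% 4)
  old <- stats::runif(n) < cfg$oversample_age45
  odds_ratio <- (cfg$oversample_age45 / (1 - cfg$oversample_age45)) /
    (cfg$pop_age45 / (1 - cfg$pop_age45))
  p_base <- 0.25
  p_person <- ifelse(old, pmin(p_base * odds_ratio, 0.95), p_base)
  sampling_weight <- if (cfg$equal_weights) rep(1, n) else
    1 / (f_psu * p_person)

  # age: 45+ follows a decreasing triangular-type density on [45, 76]
  # (Beta(1,2) shape) so roughly 13% of the 45+ group is 65 or older; under
  # 45 is uniform on [21, 45)
  age_exam <- ifelse(old,
                     45 + 31 * (1 - sqrt(stats::runif(n))),
                     21 + 24 * stats::runif(n))
  age_exam <- round(age_exam, 1)

  female <- stats::rbinom(n, 1, 0.52)
  education <- stats::rbinom(n, 1, 0.69)
  groups <- c("SouthAmerican", "CentralAmerican", "Cuban", "Dominican",
              "Mexican", "PuertoRican")
  analysis_group <- sample(groups, n, replace = TRUE,
                           prob = c(0.075, 0.118, 0.195, 0.088, 0.351, 0.172))
  # four-way continental ancestry proportions: Dirichlet with group-specific
  # concentration (European, African, Northern and Caribbean/Southern
  # Native American components)
  alpha_by_group <- rbind(
    SouthAmerican   = c(5, 0.6, 1.5, 3.0),
    CentralAmerican = c(4, 0.8, 3.0, 1.5),
    Cuban           = c(7, 1.5, 0.4, 0.6),
    Dominican       = c(4, 4.0, 0.3, 1.2),
    Mexican         = c(4, 0.5, 5.0, 0.6),
    PuertoRican     = c(6, 2.0, 0.4, 1.6))
  anc <- matrix(stats::rgamma(n * 4, shape = alpha_by_group[analysis_group, ]),
                nrow = n)
  anc <- anc / rowSums(anc)
  colnames(anc) <- c("anc_eur", "anc_afr", "anc_nam_north", "anc_nam_south")

  height_cm <- round(pmin(pmax(
    stats::rnorm(n, ifelse(female == 1, 158, 170),
                 ifelse(female == 1, 6, 7)), 130), 205))

  G <- stats::rbinom(n, 2, cfg$risk_allele_freq)
  if (cfg$g_missing_rate > 0) {
    G[stats::runif(n) < cfg$g_missing_rate] <- NA_integer_
  }
  # structural equations use dosage 0 for the few missing genotypes; those
  # records are excluded from genetic analyses downstream anyway
  Gz <- ifelse(is.na(G), 0, G)

  # independent PSU-level intercepts per BMI node: real within-cluster
  # correlation for the variance estimator without making one node's
  # random effect part of another equation's residual
  psu_idx <- match(psu, unique(psu))
  u_draw <- function() stats::rnorm(n_psu_tot, 0, cfg$psu_re_sd)[psu_idx]
  u21 <- u_draw(); u45 <- u_draw(); u65 <- u_draw(); u_exam <- u_draw()
  cv_bmi <- cfg$covar_effects_bmi["age"] * age_exam +
    cfg$covar_effects_bmi["female"] * female +
    cfg$covar_effects_bmi["education"] * education
  cv_d <- cfg$covar_effects_d["age"] * age_exam +
    cfg$covar_effects_d["female"] * female +
    cfg$covar_effects_d["education"] * education

  eps21 <- stats::rnorm(n, 0, cfg$sd_bmi21)
  eps45 <- stats::rnorm(n, 0, cfg$sd_bmi45)
  eps65 <- stats::rnorm(n, 0, cfg$sd_bmi65)

  bmi21 <- cfg$intercept_bmi21 + cfg$beta_G_bmi21 * Gz + cv_bmi + u21 + eps21

  eta1 <- cfg$alpha_D1 + cfg$theta_G_D1 * Gz + cfg$theta_bmi_D * bmi21 + cv_d
  d1_true <- stats::rbinom(n, 1, plogis_(eta1))
  dx_age <- ifelse(d1_true == 1, floor(stats::runif(n, 22, 45)), NA_real_)

  bmi45 <- cfg$intercept_bmi45 + cfg$beta_bmi_carryover * bmi21 +
    cfg$beta_G_bmi45 * Gz + cfg$beta_D_bmi * d1_true + cv_bmi + u45 + eps45

  # second-period hazard among the still-undiagnosed (first diagnosis in
  # 22-45 removes a person from the 46-65 risk set); theta_D1_D2 is kept in
  # the predictor for persistent-status reinterpretations but is inert here
  eta2 <- cfg$alpha_D2 + cfg$theta_G_D2 * Gz + cfg$theta_bmi_D * bmi45 +
    cfg$theta_D1_D2 * d1_true + cv_d
  d2_true <- ifelse(d1_true == 1, 0L, stats::rbinom(n, 1, plogis_(eta2)))
  dx_age <- ifelse(d2_true == 1, floor(stats::runif(n, 46, 65)), dx_age)

  bmi65 <- cfg$intercept_bmi65 + cfg$beta_bmi_carryover * bmi45 +
    cfg$beta_G_bmi65 * Gz + cfg$beta_D_bmi * d2_true + cv_bmi + u65 + eps65

  # late-life (post-65) diagnoses so examination-time diabetic strata are
  # populated among the oldest participants
  undiag <- d1_true == 0 & d2_true == 0 & age_exam > 65
  eta3 <- cfg$alpha_D2 + cfg$theta_G_D2 * Gz + cfg$theta_bmi_D * bmi65 + cv_d
  d3 <- undiag & stats::rbinom(n, 1, plogis_(eta3)) == 1
  dx_age <- ifelse(d3, floor(stats::runif(n, 66, pmax(age_exam, 66.01))), dx_age)

  # a diagnosis is reportable at examination only if already received
  diabetes_diagnosis_age <- ifelse(!is.na(dx_age) & dx_age <= age_exam,
                                   dx_age, NA_real_)

  # examination BMI: own genetic effect plus the shared life-course residual
  # trajectory (linearly interpolated between ages), keeping the marginal
  # per-allele effect exactly beta_G_bmi_exam
  r21 <- eps21
  r45 <- cfg$beta_bmi_carryover * eps21 + eps45
  r65 <- cfg$beta_bmi_carryover * r45 + eps65
  w45 <- pmin(pmax((age_exam - 21) / 24, 0), 1)
  w65 <- pmin(pmax((age_exam - 45) / 20, 0), 1)
  r_exam <- (1 - w45) * r21 + w45 * ((1 - w65) * r45 + w65 * r65)
  bmi_exam <- cfg$intercept_bmi_exam + cfg$beta_G_bmi_exam * Gz + cv_bmi +
    u_exam + r_exam + stats::rnorm(n, 0, cfg$sd_bmi_exam)
  bmi_exam <- pmax(bmi_exam, 15)

  hm2 <- (height_cm / 100)^2
  measured_weight_kg <- round(bmi_exam * hm2, 1)
  self_weight_exam <- round_half_away(bmi_exam * hm2 + stats::rnorm(n, 0, 0.8))

  set.seed(substream_seed(cfg$seed, "recall"))
  recall <- function(bmi) round_half_away(bmi * hm2 +
                                            stats::rnorm(n, 0, cfg$recall_sd))
  weight_at_21 <- recall(bmi21)
  weight_at_45 <- recall(bmi45)
  weight_at_65 <- recall(bmi65)

  set.seed(substream_seed(cfg$seed, "labs"))
  prior_dx <- !is.na(diabetes_diagnosis_age)
  rtrunc <- function(mu, sd, lo, hi) pmin(pmax(stats::rnorm(n, mu, sd), lo), hi)
  fasting_glucose <- round(ifelse(prior_dx, rtrunc(150, 35, 80, 400),
                                  rtrunc(94, 12, 60, 300)))
  fasting_insulin <- round(ifelse(prior_dx, rtrunc(14, 6, 2, 80),
                                  rtrunc(12, 6, 2, 80)), 1)
  ogtt_glucose <- ifelse(prior_dx, NA_real_, round(rtrunc(112, 28, 60, 350)))
  hba1c_pct <- round(ifelse(prior_dx, rtrunc(7.4, 1.2, 4.8, 14),
                            rtrunc(5.42, 0.45, 4, 9)), 1)
  on_diabetes_meds <- ifelse(prior_dx, stats::rbinom(n, 1, 0.6), 0L)

  cohort <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    stratum = stratum, psu = psu, sampling_weight = sampling_weight,
    female = female, age_exam = age_exam, education = education,
    anc, analysis_group = analysis_group, G = G,
    height_cm = height_cm, measured_weight_kg = measured_weight_kg,
    self_weight_exam = self_weight_exam,
    weight_at_21 = weight_at_21, weight_at_45 = weight_at_45,
    weight_at_65 = weight_at_65,
    diabetes_diagnosis_age = diabetes_diagnosis_age,
    fasting_glucose = fasting_glucose, fasting_insulin = fasting_insulin,
    ogtt_glucose = ogtt_glucose, hba1c_pct = hba1c_pct,
    on_diabetes_meds = on_diabetes_meds,
    pregnant = 0L, amputation = 0L,
    D1 = as.integer(d1_true), D2 = as.integer(d2_true),
    stringsAsFactors = FALSE
  )

  attr(cohort, "truth") <- data.frame(
    id = cohort$id, bmi21 = bmi21, bmi45 = bmi45, bmi65 = bmi65,
    bmi_exam = bmi_exam, d1_true = d1_true, d2_true = d2_true,
    stringsAsFactors = FALSE)
  set.seed(substream_seed(cfg$seed, "kinship"))
  n_bg <- max(1L, round(n * 0.005))
  bg1 <- sample(cohort$id, n_bg)
  bg2 <- sample(setdiff(cohort$id, bg1), n_bg)
  attr(cohort, "kinship") <- data.frame(
    id1 = pmin(bg1, bg2), id2 = pmax(bg1, bg2),
    pi_hat = round(stats::runif(n_bg, 0, 0.2), 4), stringsAsFactors = FALSE)
  attr(cohort, "config") <- cfg

  if (censor) apply_age_censoring(cohort) else cohort
}

#' Apply design-based age censoring of period outcomes
#'
#' A period-specific T2D indicator is defined only for participants old
#' enough to have completed the period: `D1` (first diagnosis in ages 22-45)
#' requires examination age >= 45 and `D2` (first diagnosis in 46-65)
#' requires age >= 65; otherwise the indicator is missing. Self-reported
#' weights at ages not yet attained are likewise set missing. A 50-year-old
#' diagnosed at 40 therefore has `D1 = 1` and `D2 = NA`.
#'
#' Records whose reported diagnosis age exceeds the examination age are
#' flagged in a logical column `inconsistent_diagnosis` and their period
#' indicators are set missing.
#'
#' @param cohort a cohort `data.frame` with `age_exam` and
#'   `diabetes_diagnosis_age` columns.
#' @return the cohort with `D1`, `D2`, `weight_at_45`, `weight_at_65` and
#'   `inconsistent_diagnosis` set per the censoring rules (idempotent).
#' @export
apply_age_censoring <- function(cohort) {
  stopifnot(all(c("age_exam", "diabetes_diagnosis_age") %in% names(cohort)))
  age <- cohort$age_exam
  dx <- cohort$diabetes_diagnosis_age
  bad <- !is.na(dx) & dx > age
  cohort$inconsistent_diagnosis <- bad
  dx[bad] <- NA_real_

  d1 <- ifelse(age >= 45, as.integer(!is.na(dx) & dx >= 22 & dx <= 45),
               NA_integer_)
  d2 <- ifelse(age >= 65, as.integer(!is.na(dx) & dx >= 46 & dx <= 65),
               NA_integer_)
  d1[bad] <- NA_integer_
  d2[bad] <- NA_integer_
  cohort$D1 <- d1
  cohort$D2 <- d2
  censor_col <- function(cohort, col, min_age) {
    if (col %in% names(cohort)) cohort[[col]][age < min_age] <- NA_real_
    cohort
  }
  cohort <- censor_col(cohort, "weight_at_21", 21)
  cohort <- censor_col(cohort, "weight_at_45", 45)
  cohort <- censor_col(cohort, "weight_at_65", 65)
  cohort <- censor_col(cohort, "bmi21", 21)
  cohort <- censor_col(cohort, "bmi45", 45)
  cohort <- censor_col(cohort, "bmi65", 65)
  cohort
}

#' Inject quality-control artifacts into a clean cohort
#'
#' Stress input for the QC stage: re-expresses a fraction of self-reported
#' weights in pounds (lb/kg unit confusion), flags a fraction of women as
#' pregnant at examination, corrupts weights so the implied BMI falls
#' outside [16, 70], sets diagnosis ages before 22, and appends close-kin
#' pairs (pi-hat in (0.35, 0.98)) to the kinship table. Every injection is
#' recorded with its hidden truth in `attr(cohort, "artifact_truth")` so
#' recovery can be scored. Rates of 0 are exact no-ops.
#'
#' @param cohort a cohort `data.frame` (typically from [simulate_cohort()]).
#' @param rates named list of injection rates in `[0, 1]`:
#'   `unit_confusion` (per examination self-reported weight, where a
#'   concurrent measured reference exists), `unit_confusion_recall` (per
#'   non-missing recalled weight cell; these lack a concurrent reference
#'   and stress the detector), `pregnancy`, `bmi_out_of_range`,
#'   `early_diagnosis`, `related_pairs` (per record). Omitted entries
#'   default to 0.
#' @param seed integer seed for the injection substream.
#' @return the corrupted cohort; attributes `artifact_truth` (data frame of
#'   id, field, kind, true value, injected value) and `kinship` updated.
#' @export
inject_artifacts <- function(cohort, rates = list(), seed = 1L) {
  defaults <- list(unit_confusion = 0, unit_confusion_recall = 0,
                   pregnancy = 0, bmi_out_of_range = 0,
                   early_diagnosis = 0, related_pairs = 0)
  unknown <- setdiff(names(rates), names(defaults))
  if (length(unknown) > 0) {
    stop_svypath(paste("unknown artifact rate(s):",
                       paste(unknown, collapse = ", ")),
                 "svypath_config_error")
  }
  rates <- utils::modifyList(defaults, rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop_svypath("artifact rates must lie in [0, 1]", "svypath_config_error")
  }
  set.seed(substream_seed(seed, "artifacts"))
  n <- nrow(cohort)
  truth <- list()
  wcols <- c("weight_at_21", "weight_at_45", "weight_at_65")
  lb_per_kg <- 2.2046

  corrupt_lb <- function(cohort, wc, rate, truth) {
    avail <- which(!is.na(cohort[[wc]]))
    pick <- avail[stats::runif(length(avail)) < rate]
    if (length(pick) > 0) {
      true_val <- cohort[[wc]][pick]
      inj <- round_half_away(true_val * lb_per_kg)
      cohort[[wc]][pick] <- inj
      truth[[length(truth) + 1L]] <- data.frame(
        id = cohort$id[pick], field = wc, kind = "unit_confusion",
        true_value = true_val, injected_value = inj,
        stringsAsFactors = FALSE)
    }
    list(cohort = cohort, truth = truth)
  }
  if (rates$unit_confusion > 0) {
    res <- corrupt_lb(cohort, "self_weight_exam", rates$unit_confusion, truth)
    cohort <- res$cohort; truth <- res$truth
  }
  if (rates$unit_confusion_recall > 0) {
    for (wc in wcols) {
      res <- corrupt_lb(cohort, wc, rates$unit_confusion_recall, truth)
      cohort <- res$cohort; truth <- res$truth
    }
  }
  if (rates$pregnancy > 0) {
    cand <- which(cohort$female == 1 & cohort$age_exam < 50)
    pick <- cand[stats::runif(length(cand)) < rates$pregnancy]
    if (length(pick) > 0) {
      truth[[length(truth) + 1L]] <- data.frame(
        id = cohort$id[pick], field = "pregnant", kind = "pregnancy",
        true_value = 0, injected_value = 1, stringsAsFactors = FALSE)
      cohort$pregnant[pick] <- 1L
    }
  }
  if (rates$bmi_out_of_range > 0) {
    pick <- which(stats::runif(n) < rates$bmi_out_of_range &
                    !is.na(cohort$weight_at_21))
    if (length(pick) > 0) {
      hm2 <- (cohort$height_cm[pick] / 100)^2
      target_bmi <- ifelse(stats::runif(length(pick)) < 0.5, 12, 80)
      inj <- round_half_away(target_bmi * hm2)
      truth[[length(truth) + 1L]] <- data.frame(
        id = cohort$id[pick], field = "weight_at_21", kind = "bmi_out_of_range",
        true_value = cohort$weight_at_21[pick], injected_value = inj,
        stringsAsFactors = FALSE)
      cohort$weight_at_21[pick] <- inj
    }
  }
  if (rates$early_diagnosis > 0) {
    pick <- which(stats::runif(n) < rates$early_diagnosis)
    if (length(pick) > 0) {
      inj <- sample(10:20, length(pick), replace = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        id = cohort$id[pick], field = "diabetes_diagnosis_age",
        kind = "early_diagnosis",
        true_value = cohort$diabetes_diagnosis_age[pick],
        injected_value = inj, stringsAsFactors = FALSE)
      cohort$diabetes_diagnosis_age[pick] <- inj
    }
  }
  if (rates$related_pairs > 0) {
    n_pairs <- stats::rbinom(1, n, rates$related_pairs)
    if (n_pairs > 0) {
      id1 <- sample(cohort$id, n_pairs)
      id2 <- sample(setdiff(cohort$id, id1), n_pairs)
      newp <- data.frame(id1 = pmin(id1, id2), id2 = pmax(id1, id2),
                         pi_hat = round(stats::runif(n_pairs, 0.40, 0.60), 4),
                         stringsAsFactors = FALSE)
      kin <- attr(cohort, "kinship")
      attr(cohort, "kinship") <- rbind(
        kin %||% newp[0, ], newp)
      truth[[length(truth) + 1L]] <- data.frame(
        id = newp$id1, field = "kinship", kind = "related_pair",
        true_value = NA_real_, injected_value = newp$pi_hat,
        stringsAsFactors = FALSE)
    }
  }
  attr(cohort, "artifact_truth") <- if (length(truth) > 0) {
    do.call(rbind, truth)
  } else {
    data.frame(id = character(), field = character(), kind = character(),
               true_value = numeric(), injected_value = numeric(),
               stringsAsFactors = FALSE)
  }
  cohort
}

#' Replace QC-derived BMI columns with the generator's latent values
#'
#' Parameter-recovery studies score the estimator against the generative
#' coefficients, which govern the latent BMI trajectory. Self-report
#' instruments (whole-kg weights, whole-cm heights, plausibility-bound
#' rejections) add measurement error that attenuates regressor
#' coefficients by up to about one percent -- a property of the data, not
#' of the estimator -- so recovery runs swap in the latent node values
#' while keeping the sampling design and the age censoring of the observed
#' cohort.
#'
#' @param cohort a [simulate_cohort()] output (its `truth` attribute must
#'   be present).
#' @return the cohort with `bmi21`, `bmi45`, `bmi65` set to the latent
#'   values, censored at the same ages as the observed columns.
#' @export
latent_bmi_cohort <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) {
    stop_svypath("cohort carries no latent truth attribute",
                 "svypath_config_error")
  }
  idx <- match(cohort$id, tr$id)
  cohort$bmi21 <- tr$bmi21[idx]
  cohort$bmi45 <- ifelse(cohort$age_exam >= 45, tr$bmi45[idx], NA_real_)
  cohort$bmi65 <- ifelse(cohort$age_exam >= 65, tr$bmi65[idx], NA_real_)
  cohort
}

#' Cohort and kinship file input/output
#'
#' The cohort travels as a UTF-8 CSV with a header row and empty fields for
#' missing values; kinship pairs as a 3-column TSV (`id1`, `id2`, `pi_hat`).
#'
#' @param cohort,pairs data frames to write.
#' @param path file path.
#' @return readers return the data frame; writers return `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  na.strings = "")
}

#' @rdname write_cohort
#' @export
write_kinship <- function(pairs, path) {
  stopifnot(all(c("id1", "id2", "pi_hat") %in% names(pairs)))
  utils::write.table(pairs[, c("id1", "id2", "pi_hat")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_kinship <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
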