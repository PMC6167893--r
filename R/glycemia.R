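#' American Diabetes Association glycemic classification
#'
#' Classifies each record's glycemic state at examination: T2D if any ADA
#' criterion is met (fasting glucose >= 126 mg/dL, 2-h post-load OGTT
#' glucose >= 200 mg/dL, HbA1c >= 6.5%, or current diabetes medication);
#' impaired fasting glucose (IFG) among non-diabetics as fasting glucose
#' 100-125 mg/dL or post-load glucose 140-199 mg/dL; controlled diabetes,
#' defined only among diabetics, as HbA1c < 7%. Homeostatic model indices
#' use the standard Matthews forms, HOMA-IR = glucose x insulin / 405 and
#' HOMA-B = 360 x insulin / (glucose - 63) (glucose in mg/dL, insulin in
#' mU/L); HOMA-B is undefined at fasting glucose <= 63 mg/dL.
#'
#' @param cohort data frame with columns `fasting_glucose`,
#'   `fasting_insulin`, `ogtt_glucose`, `hba1c_pct`, `on_diabetes_meds`.
#' @param homa_ir_denom,homa_b_num,homa_b_offset overridable constants of
#'   the HOMA formulas.
#' @return the cohort with columns `t2d_at_exam`, `impaired_fasting_glucose`
#'   (`NA` among diabetics), `controlled` (`NA` among non-diabetics),
#'   `homa_ir`, `homa_b` appended.
#' @export
#' @examples
#' classify_glycemia(data.frame(fasting_glucose = 130, fasting_insulin = 10,
#'                              ogtt_glucose = NA, hba1c_pct = 5.5,
#'                              on_diabetes_meds = 0))$t2d_at_exam  # 1
classify_glycemia <- function(cohort, homa_ir_denom = 405,
                              homa_b_num = 360, homa_b_offset = 63) {
  need <- c("fasting_glucose", "fasting_insulin", "ogtt_glucose",
            "hba1c_pct", "on_diabetes_meds")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop_svypath(paste("missing glycemic column(s):",
                       paste(missing_cols, collapse = ", ")),
                 "svypath_config_error")
  }
  fg <- cohort$fasting_glucose
  og <- cohort$ogtt_glucose
  a1c <- cohort$hba1c_pct
  meds <- cohort$on_diabetes_meds %in% 1
  any_measure <- !is.na(fg) | !is.na(og) | !is.na(a1c) |
    !is.na(cohort$on_diabetes_meds)
  if (!all(any_measure)) {
    stop_svypath("records without any glycemic measurement cannot be classified",
                 "svypath_config_error")
  }
  ge <- function(x, cut) !is.na(x) & x >= cut
  t2d <- ge(fg, 126) | ge(og, 200) | ge(a1c, 6.5) | meds

  ifg <- ifelse(t2d, NA,
                as.integer((!is.na(fg) & fg >= 100 & fg <= 125) |
                             (!is.na(og) & og >= 140 & og <= 199)))
  controlled <- ifelse(t2d, as.integer(!is.na(a1c) & a1c < 7), NA)

  ins <- cohort$fasting_insulin
  homa_ir <- fg * ins / homa_ir_denom
  homa_b <- ifelse(!is.na(fg) & fg > homa_b_offset,
                   homa_b_num * ins / (fg - homa_b_offset), NA_real_)
  n_undef <- sum(!is.na(fg) & fg <= homa_b_offset & !is.na(ins))
  if (n_undef > 0) {
    message(sprintf(
      "HOMA-B undefined for %d record(s) with fasting glucose <= %g mg/dL",
      n_undef, homa_b_offset))
  }
  cohort$t2d_at_exam <- as.integer(t2d)
  cohort$impaired_fasting_glucose <- ifg
  cohort$controlled <- controlled
  cohort$homa_ir <- homa_ir
  cohort$homa_b <- homa_b
  cohort
}

#' Mutually exclusive glycemic strata for stratified BMI models
#'
#' Partitions the analytic sample into examination-time strata used for
#' stratified genotype-BMI models: previously diagnosed (self-reported
#' diagnosis before examination), undiagnosed T2D (no prior diagnosis but
#' ADA-positive at examination), impaired fasting glucose, and
#' normoglycemic; plus an overlay flag for current diabetes medication.
#'
#' @param cohort a [classify_glycemia()]-annotated cohort with a
#'   `diabetes_diagnosis_age` column.
#' @return the cohort with a factor column `glycemic_stratum` and logical
#'   `on_meds_stratum`.
#' @export
glycemic_strata <- function(cohort) {
  stopifnot(all(c("t2d_at_exam", "impaired_fasting_glucose",
                  "diabetes_diagnosis_age") %in% names(cohort)))
  prior <- !is.na(cohort$diabetes_diagnosis_age)
  undiag_t2d <- !prior & cohort$t2d_at_exam == 1
  ifg <- !prior & cohort$t2d_at_exam == 0 &
    cohort$impaired_fasting_glucose %in% 1
  stratum <- ifelse(prior, "prior_diagnosis",
                    ifelse(undiag_t2d, "undiagnosed_t2d",
                           ifelse(ifg, "impaired_fasting_glucose",
                                  "normoglycemic")))
  cohort$glycemic_stratum <- factor(
    stratum, levels = c("normoglycemic", "impaired_fasting_glucose",
                        "undiagnosed_t2d", "prior_diagnosis"))
  cohort$on_meds_stratum <- cohort$on_diabetes_meds %in% 1
  cohort
}
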