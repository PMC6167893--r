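#' Quality-control rule parameters for weight histories
#'
#' Bundles the constants of the weight-history cleaning stage: plausibility
#' bounds for BMI (values below 16 or above 70 kg/m2 are rejected outright),
#' the minimum believable age of a type-2 diagnosis (22 years, below which a
#' diagnosis is more plausibly type 1), the lb-per-kg conversion factor, and
#' the relative tolerance around that factor within which a self-reported /
#' reference weight ratio is read as lb/kg unit confusion.
#'
#' The default `unit_confusion_rel_tol` of 0.05 separates the conversion
#' ratio (2.2046) from plausible true weight change between adjacent ages:
#' a flagged ratio must lie in roughly (2.09, 2.31), i.e. the person would
#' have had to more than double their weight.
#'
#' @param bmi_lower,bmi_upper BMI plausibility bounds (kg/m2).
#' @param min_diagnosis_age youngest credible T2D diagnosis age (years).
#' @param lb_per_kg pounds per kilogram.
#' @param unit_confusion_rel_tol relative tolerance around `lb_per_kg` for
#'   the unit-confusion detector, in (0, 1).
#' @param height_range plausible standing height range (cm).
#' @return an object of class `qc_ruleset`.
#' @export
qc_ruleset <- function(bmi_lower = 16, bmi_upper = 70,
                       min_diagnosis_age = 22, lb_per_kg = 2.2046,
                       unit_confusion_rel_tol = 0.05,
                       height_range = c(100, 220)) {
  if (!(bmi_lower < bmi_upper)) {
    stop_svypath("bmi_lower must be below bmi_upper", "svypath_config_error")
  }
  if (!(unit_confusion_rel_tol > 0 && unit_confusion_rel_tol < 1)) {
    stop_svypath("unit_confusion_rel_tol must lie in (0, 1)",
                 "svypath_config_error")
  }
  structure(list(bmi_lower = bmi_lower, bmi_upper = bmi_upper,
                 min_diagnosis_age = min_diagnosis_age,
                 lb_per_kg = lb_per_kg,
                 unit_confusion_rel_tol = unit_confusion_rel_tol,
                 height_range = height_range),
            class = "qc_ruleset")
}

#' Standardize a body weight to whole kilograms
#'
#' Weights reported in pounds are divided by the lb-per-kg factor; all
#' weights are then rounded to the whole kilogram with halves away from
#' zero, eliminating measurement error by unit of report.
#'
#' @param value positive numeric weight(s).
#' @param unit `"lb"` or `"kg"`, recycled along `value`.
#' @param ruleset a [qc_ruleset()].
#' @return numeric vector of whole-kg weights. Missing values propagate;
#'   non-positive or non-numeric input raises an error tagged
#'   `svypath_qc_error`.
#' @export
#' @examples
#' standardize_weight(154, "lb")  # 70
standardize_weight <- function(value, unit, ruleset = qc_ruleset()) {
  if (!is.numeric(value)) {
    stop_svypath("weight must be numeric [rule: weight_standardization]",
                 "svypath_qc_error")
  }
  unit <- rep_len(unit, length(value))
  if (!all(unit %in% c("lb", "kg"))) {
    stop_svypath("unit must be 'lb' or 'kg' [rule: weight_standardization]",
                 "svypath_qc_error")
  }
  if (any(!is.na(value) & value <= 0)) {
    stop_svypath("weights must be positive [rule: weight_standardization]",
                 "svypath_qc_error")
  }
  kg <- ifelse(unit == "lb", value / ruleset$lb_per_kg, value)
  round_half_away(kg)
}

#' Detect lb/kg unit confusion in a self-reported weight
#'
#' If the ratio of a self-reported weight to a concurrent reference weight
#' (the measured weight, or the median of the person's other weights) is
#' within `unit_confusion_rel_tol` of the lb-per-kg factor, the self-report
#' is recoded as having been given in pounds and flagged. A missing
#' reference passes the value through unflagged: without a reference there
#' is no evidence of confusion.
#'
#' @param self_weight positive numeric vector of self-reported weights.
#' @param reference_weight numeric vector of reference weights (may be NA).
#' @param ruleset a [qc_ruleset()].
#' @return data frame with columns `corrected_kg` and `flagged`.
#' @export
#' @examples
#' detect_unit_confusion(154, 70)  # corrected to 70, flagged
detect_unit_confusion <- function(self_weight, reference_weight,
                                  ruleset = qc_ruleset()) {
  stopifnot(length(self_weight) == length(reference_weight))
  if (any(!is.na(self_weight) & self_weight <= 0) ||
      any(!is.na(reference_weight) & reference_weight <= 0)) {
    stop_svypath("weights must be positive [rule: unit_confusion]",
                 "svypath_qc_error")
  }
  ratio <- self_weight / reference_weight
  flagged <- !is.na(ratio) &
    abs(ratio / ruleset$lb_per_kg - 1) <= ruleset$unit_confusion_rel_tol
  corrected <- ifelse(flagged,
                      round_half_away(self_weight / ruleset$lb_per_kg),
                      self_weight)
  data.frame(corrected_kg = corrected, flagged = flagged)
}

#' Body mass index with plausibility bounds
#'
#' Computes weight / height^2 (kg/m2) and rejects -- does not clip --
#' values below `bmi_lower` or above `bmi_upper`, or computed from a height
#' outside the plausible standing range. Rejected and missing-operand
#' results are `NA`; the reason is available via `attr(, "status")`.
#'
#' @param weight_kg numeric weight in kg.
#' @param height_cm numeric height in cm.
#' @param ruleset a [qc_ruleset()].
#' @return numeric BMI vector with a `status` attribute taking values
#'   `"ok"`, `"missing"`, `"rejected_low"`, `"rejected_high"`,
#'   `"height_out_of_range"`.
#' @export
#' @examples
#' compute_bmi(70, 170)  # 24.22
compute_bmi <- function(weight_kg, height_cm, ruleset = qc_ruleset()) {
  n <- max(length(weight_kg), length(height_cm))
  weight_kg <- rep_len(weight_kg, n)
  height_cm <- rep_len(height_cm, n)
  bmi <- weight_kg / (height_cm / 100)^2
  status <- rep("ok", n)
  status[is.na(weight_kg) | is.na(height_cm)] <- "missing"
  bad_h <- !is.na(height_cm) & (height_cm < ruleset$height_range[1] |
                                  height_cm > ruleset$height_range[2])
  status[bad_h] <- "height_out_of_range"
  status[status == "ok" & bmi < ruleset$bmi_lower] <- "rejected_low"
  status[status == "ok" & bmi > ruleset$bmi_upper] <- "rejected_high"
  bmi[status != "ok"] <- NA_real_
  structure(bmi, status = status)
}

#' Clean a cohort's weight history and derive BMI columns
#'
#' Applies the full weight-history cleaning to a cohort: baseline (measured
#' and self-reported examination) weights of currently pregnant women and of
#' participants with limb amputations are dropped, recalled weights are
#' screened for lb/kg unit confusion against the person's reference weight
#' (measured weight if available, else the median of the other weights),
#' and BMI columns `bmi_measured`, `bmi_self_exam`, `bmi21`, `bmi45`,
#' `bmi65` are derived with the plausibility bounds of the ruleset. A bound
#' violation drops the BMI value, not the person.
#'
#' @param cohort cohort data frame.
#' @param ruleset a [qc_ruleset()].
#' @return the cohort with BMI columns added; unit-confusion recodes are
#'   logged in `attr(, "unit_confusion_log")` (id, field, original,
#'   corrected).
#' @export
clean_weight_history <- function(cohort, ruleset = qc_ruleset()) {
  drop_baseline <- cohort$pregnant %in% 1 | cohort$amputation %in% 1
  cohort$measured_weight_kg[drop_baseline] <- NA_real_
  cohort$self_weight_exam[drop_baseline] <- NA_real_

  logs <- list()
  # examination self-report screened against its concurrent measured weight
  res <- detect_unit_confusion(cohort$self_weight_exam,
                               cohort$measured_weight_kg, ruleset)
  hit <- which(res$flagged)
  if (length(hit) > 0) {
    logs[[length(logs) + 1L]] <- data.frame(
      id = cohort$id[hit], field = "self_weight_exam",
      original = cohort$self_weight_exam[hit],
      corrected = res$corrected_kg[hit], stringsAsFactors = FALSE)
    cohort$self_weight_exam[hit] <- res$corrected_kg[hit]
  }

  # recalled weights screened against the median of the person's other
  # self-reports (no concurrent reference exists at a recalled age)
  wcols <- c("weight_at_21", "weight_at_45", "weight_at_65")
  wmat <- as.matrix(cohort[, wcols])
  for (wc in wcols) {
    others <- cbind(wmat[, setdiff(wcols, wc), drop = FALSE],
                    cohort$self_weight_exam)
    ref <- apply(others, 1, stats::median, na.rm = TRUE)
    ref[is.nan(ref)] <- NA_real_
    res <- detect_unit_confusion(cohort[[wc]], ref, ruleset)
    hit <- which(res$flagged)
    if (length(hit) > 0) {
      logs[[length(logs) + 1L]] <- data.frame(
        id = cohort$id[hit], field = wc, original = cohort[[wc]][hit],
        corrected = res$corrected_kg[hit], stringsAsFactors = FALSE)
      cohort[[wc]][hit] <- res$corrected_kg[hit]
    }
  }

  cohort$bmi_measured <- as.numeric(compute_bmi(cohort$measured_weight_kg,
                                                cohort$height_cm, ruleset))
  cohort$bmi_self_exam <- as.numeric(compute_bmi(cohort$self_weight_exam,
                                                 cohort$height_cm, ruleset))
  cohort$bmi21 <- as.numeric(compute_bmi(cohort$weight_at_21,
                                         cohort$height_cm, ruleset))
  cohort$bmi45 <- as.numeric(compute_bmi(cohort$weight_at_45,
                                         cohort$height_cm, ruleset))
  cohort$bmi65 <- as.numeric(compute_bmi(cohort$weight_at_65,
                                         cohort$height_cm, ruleset))
  attr(cohort, "unit_confusion_log") <- if (length(logs) > 0) {
    do.call(rbind, logs)
  } else {
    data.frame(id = character(), field = character(), original = numeric(),
               corrected = numeric(), stringsAsFactors = FALSE)
  }
  cohort
}

new_flow_ledger <- function(steps, excluded_ids, n_start) {
  stopifnot(is.data.frame(steps),
            all(c("rule", "n_before", "n_excluded", "n_after") %in%
                  names(steps)))
  if (nrow(steps) > 0) {
    if (any(steps$n_after != steps$n_before - steps$n_excluded)) {
      stop_svypath("ledger arithmetic violated: n_after != n_before - n_excluded",
                   "svypath_ledger_error")
    }
    if (steps$n_before[1] != n_start ||
        (nrow(steps) > 1 &&
         any(steps$n_before[-1] != steps$n_after[-nrow(steps)]))) {
      stop_svypath("ledger chaining violated: step k n_before != step k-1 n_after",
                   "svypath_ledger_error")
    }
  }
  structure(list(steps = steps, excluded_ids = excluded_ids,
                 n_start = n_start,
                 final_n = if (nrow(steps) > 0) steps$n_after[nrow(steps)]
                           else n_start),
            class = "flow_ledger")
}

#' Exclusion-flow ledger from printed per-rule counts
#'
#' Builds a [build_flow_ledger()]-style ledger purely from a starting count
#' and ordered per-rule exclusion counts, verifying the conservation
#' arithmetic (each step's output is its input minus its exclusions, and
#' steps chain). Used to audit a published exclusion flowchart.
#'
#' @param n_start count entering the first rule.
#' @param counts named integer vector of exclusions per rule, in order.
#' @return a `flow_ledger`; `$final_n` is the analytic sample size.
#' @export
#' @examples
#' ledger_from_counts(12073, c(early_diagnosis = 87, no_usable_weight = 1054,
#'                             missing_group = 122, missing_education = 14,
#'                             relatedness = 1765))$final_n  # 9031
ledger_from_counts <- function(n_start, counts) {
  stopifnot(length(counts) > 0, !is.null(names(counts)))
  n_before <- n_start - c(0, cumsum(counts)[-length(counts)])
  steps <- data.frame(rule = names(counts), n_before = n_before,
                      n_excluded = as.integer(counts),
                      n_after = n_before - as.integer(counts),
                      stringsAsFactors = FALSE)
  new_flow_ledger(steps, stats::setNames(vector("list", length(counts)),
                                         names(counts)), n_start)
}

default_exclusion_rules <- function() {
  has_any_bmi <- function(ch) {
    bm <- ch[, c("bmi_measured", "bmi_self_exam", "bmi21", "bmi45", "bmi65")]
    rowSums(!is.na(bm)) > 0
  }
  list(
    pregnancy_amputation = function(ch, rs, kin) {
      # baseline measures are already dropped by clean_weight_history; the
      # person is excluded only when nothing usable remains
      (ch$pregnant %in% 1 | ch$amputation %in% 1) & !has_any_bmi(ch)
    },
    early_diagnosis = function(ch, rs, kin) {
      !is.na(ch$diabetes_diagnosis_age) &
        ch$diabetes_diagnosis_age < rs$min_diagnosis_age
    },
    no_usable_height_weight = function(ch, rs, kin) {
      is.na(ch$height_cm) | !has_any_bmi(ch)
    },
    missing_analysis_group = function(ch, rs, kin) {
      is.na(ch$analysis_group) | ch$analysis_group == ""
    },
    missing_education = function(ch, rs, kin) is.na(ch$education),
    relatedness = function(ch, rs, kin) {
      if (is.null(kin) || nrow(kin) == 0) return(rep(FALSE, nrow(ch)))
      kin <- kin[kin$id1 %in% ch$id & kin$id2 %in% ch$id, , drop = FALSE]
      if (nrow(kin) == 0) return(rep(FALSE, nrow(ch)))
      wmat <- ch[, c("weight_at_21", "weight_at_45", "weight_at_65",
                     "measured_weight_kg")]
      n_weights <- stats::setNames(rowSums(!is.na(wmat)), ch$id)
      keep <- prune_relatives(kin, n_weights)
      !(ch$id %in% keep)
    }
  )
}

#' Ordered exclusion flow with conservation accounting
#'
#' Applies the ordered person-level exclusion rules (pregnancy/amputation
#' leaving no usable measure, diabetes diagnosis before the minimum age, no
#' usable height or weight, missing genetic analysis group, missing
#' education, close relatedness) and returns a ledger in which every step
#' records counts before, excluded and after. A person who trips several
#' rules is counted once, under the earliest rule (first-rule-wins). The
#' excluded ids of every rule are retrievable from `$excluded_ids`.
#'
#' @param cohort a cohort cleaned by [clean_weight_history()] (the BMI
#'   columns must exist; they are derived on the fly otherwise).
#' @param ruleset a [qc_ruleset()].
#' @param kinship optional kinship pair data frame (`id1`, `id2`,
#'   `pi_hat`); defaults to `attr(cohort, "kinship")`.
#' @param rules optional named list of rule functions
#'   `function(cohort, ruleset, kinship) -> logical`; the default set above.
#'   An empty list yields a ledger with `final_n` equal to the input count.
#' @return a `flow_ledger`; the retained cohort is in `attr(, "cohort")`.
#' @export
build_flow_ledger <- function(cohort, ruleset = qc_ruleset(),
                              kinship = attr(cohort, "kinship"),
                              rules = default_exclusion_rules()) {
  if (!all(c("bmi_measured", "bmi21") %in% names(cohort))) {
    cohort <- clean_weight_history(cohort, ruleset)
  }
  n_start <- nrow(cohort)
  current <- cohort
  steps <- list()
  excluded_ids <- list()
  for (rn in names(rules)) {
    flag <- rules[[rn]](current, ruleset, kinship)
    flag[is.na(flag)] <- FALSE
    n_before <- nrow(current)
    excluded_ids[[rn]] <- current$id[flag]
    steps[[rn]] <- data.frame(rule = rn, n_before = n_before,
                              n_excluded = sum(flag),
                              n_after = n_before - sum(flag),
                              stringsAsFactors = FALSE)
    current <- current[!flag, , drop = FALSE]
  }
  steps <- if (length(steps) > 0) do.call(rbind, steps) else
    data.frame(rule = character(), n_before = integer(),
               n_excluded = integer(), n_after = integer(),
               stringsAsFactors = FALSE)
  rownames(steps) <- NULL
  ledger <- new_flow_ledger(steps, excluded_ids, n_start)
  attr(ledger, "cohort") <- current
  ledger
}

#' @export
print.flow_ledger <- function(x, ...) {
  cat(sprintf("<flow_ledger> %d -> %d\n", x$n_start, x$final_n))
  if (nrow(x$steps) > 0) {
    print(x$steps, row.names = FALSE)
  } else {
    cat("  (no exclusion rules applied)\n")
  }
  invisible(x)
}

#' Write an exclusion-flow ledger to JSON or a text table
#'
#' @param ledger a `flow_ledger`.
#' @param path output file path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_flow_ledger <- function(ledger, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(n_start = ledger$n_start, final_n = ledger$final_n,
           steps = ledger$steps, excluded_ids = ledger$excluded_ids),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(utils::capture.output(print(ledger)), con)
  }
  invisible(path)
}
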