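#' Pipeline configuration
#'
#' Describes one end-to-end run: either a simulation scenario or an input
#' cohort file (exactly one of the two), optional kinship/VCF inputs, QC
#' rule overrides, model settings and an output directory.
#'
#' @param scenario a [scenario_config()], or `NULL` when reading a cohort.
#' @param cohort_path path to a cohort CSV, or `NULL` when simulating.
#' @param kinship_path optional kinship TSV (`id1`, `id2`, `pi_hat`).
#' @param vcf_path,variant_id optional single-variant VCF supplying the
#'   genotype column (ALT allele treated as the risk allele).
#' @param ruleset a [qc_ruleset()].
#' @param artifact_rates rates passed to [inject_artifacts()] after
#'   simulation (ignored for file input).
#' @param d1_d2 include the D1 -> D2 edge in the fitted path model;
#'   default `FALSE` (see [default_path_spec()]).
#' @param covariates adjustment set for regression and path models.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, cohort_path = NULL,
                            kinship_path = NULL, vcf_path = NULL,
                            variant_id = NULL, ruleset = qc_ruleset(),
                            artifact_rates = list(), d1_d2 = FALSE,
                            covariates = c("age_exam", "female", "education",
                                           "anc_eur", "anc_afr",
                                           "anc_nam_north", "analysis_group"),
                            out_dir = NULL, seed = 1L) {
  if (is.null(scenario) == is.null(cohort_path)) {
    stop_svypath("exactly one of 'scenario' and 'cohort_path' must be given",
                 "svypath_config_error")
  }
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_config"))
  structure(list(scenario = scenario, cohort_path = cohort_path,
                 kinship_path = kinship_path, vcf_path = vcf_path,
                 variant_id = variant_id, ruleset = ruleset,
                 artifact_rates = artifact_rates, d1_d2 = d1_d2,
                 covariates = covariates, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> weight-history QC and exclusion flow
#' -> genetics (genotype merge, Hardy-Weinberg) -> survey-weighted
#' descriptive and regression tables -> path model with effect
#' decomposition. The run is deterministic given the seed. Outputs, when
#' `out_dir` is set, comprise the flow ledger, per-genotype adjusted-means
#' table, the per-outcome genotype regression table, the
#' glycemic-stratified regression table, path-model coefficient and
#' effect-decomposition tables, and a manifest (package version, seed,
#' MD5 hashes of file inputs, timestamp).
#'
#' @param config a [pipeline_config()].
#' @return a result bundle (list); see the names of the returned list.
#'   A stage failure raises an error naming the stage; when `out_dir` is
#'   set, a manifest flagged `"invalid"` is persisted before rethrowing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(
    package = "svypath",
    version = as.character(utils::packageVersion("svypath")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    inputs = list(), status = "running")
  bundle <- list(manifest = manifest)
  persist_invalid <- function(stage) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      manifest$status <- "invalid"
      manifest$failed_stage <- stage
      jsonlite::write_json(manifest, file.path(config$out_dir,
                                               "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  run_guarded <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      persist_invalid(stage)
      stop_svypath(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e)), "svypath_stage_error")
    })
  }

  ## acquire cohort
  cohort <- run_guarded("input", {
    if (!is.null(config$scenario)) {
      cfg <- config$scenario
      ch <- simulate_cohort(cfg)
      if (length(config$artifact_rates) > 0) {
        ch <- inject_artifacts(ch, config$artifact_rates,
                               seed = config$seed)
      }
      ch
    } else {
      manifest$inputs$cohort <- unname(tools::md5sum(config$cohort_path))
      ch <- read_cohort(config$cohort_path)
      if (!is.null(config$kinship_path)) {
        manifest$inputs$kinship <- unname(tools::md5sum(config$kinship_path))
        attr(ch, "kinship") <- read_kinship(config$kinship_path)
      }
      ch
    }
  })

  ## genetics: optional VCF genotype merge, HWE
  genetics <- run_guarded("genetics", {
    if (!is.null(config$vcf_path)) {
      manifest$inputs$vcf <- unname(tools::md5sum(config$vcf_path))
      gt <- read_variant_vcf(config$vcf_path, config$variant_id)
      dos <- additive_code(gt, risk_allele = attr(gt, "alt"),
                           ref_allele = attr(gt, "ref"),
                           variant_id = config$variant_id)
      cohort$G <- dos[match(cohort$id, names(dos))]
    }
    counts <- genotype_counts_from_dosage(cohort$G)
    list(counts = counts, hwe = hwe_test(counts))
  })

  ## weight-history QC and exclusion flow
  qc <- run_guarded("qc", {
    # censor first so BMI columns are derived from the censored weights
    cleaned <- clean_weight_history(apply_age_censoring(cohort),
                                    config$ruleset)
    ledger <- build_flow_ledger(cleaned, config$ruleset)
    list(ledger = ledger, cohort = attr(ledger, "cohort"),
         unit_confusion_log = attr(cleaned, "unit_confusion_log"))
  })
  analytic <- run_guarded("glycemia", {
    glycemic_strata(classify_glycemia(qc$cohort))
  })

  design <- run_guarded("design", survey_design(analytic))
  covs <- config$covariates

  descriptives <- run_guarded("descriptives", {
    rows <- list()
    add <- function(label, variable, subpop = NULL) {
      m <- estimate_mean_prop(design, variable, subpop = subpop)
      rows[[length(rows) + 1L]] <<- data.frame(
        measure = label, n = m$n, estimate = m$estimate, se = m$se,
        ci_low = m$ci[1], ci_high = m$ci[2], stringsAsFactors = FALSE)
    }
    add("female_pct", "female")
    add("age_at_exam", "age_exam")
    add("education_pct", "education")
    add("bmi_at_21", "bmi21")
    add("bmi_at_45", "bmi45")
    add("bmi_at_65", "bmi65")
    add("t2d_22_45_pct", "D1")
    add("t2d_46_65_pct", "D2")
    do.call(rbind, rows)
  })

  genotype_means <- run_guarded("genotype_means", {
    out <- list()
    for (oc in c("bmi_measured", "bmi_self_exam")) {
      gm <- adjusted_genotype_means(design, oc,
                                    c("age_exam", "female", "anc_eur",
                                      "anc_afr", "anc_nam_north"))
      df <- gm$means
      df$outcome <- oc
      df$joint_p <- gm$joint_p
      out[[oc]] <- df
    }
    do.call(rbind, out)
  })

  regression <- run_guarded("regression", {
    outcomes <- c(measured_bmi_exam = "bmi_measured",
                  self_report_bmi_exam = "bmi_self_exam",
                  bmi_at_21 = "bmi21", bmi_at_45 = "bmi45",
                  bmi_at_65 = "bmi65")
    rows <- lapply(names(outcomes), function(lbl) {
      f <- fit_weighted_glm(design, outcomes[[lbl]], c("G", covs),
                            family = "linear")
      g <- f$summary[f$summary$term == "G", ]
      data.frame(outcome = lbl, n = f$n_used, estimate = g$estimate,
                 se = g$se, ci_low = g$ci_low, ci_high = g$ci_high,
                 p_value = g$p_value, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  stratified <- run_guarded("stratified", {
    rows <- list()
    for (st in levels(analytic$glycemic_stratum)) {
      sub <- analytic$glycemic_stratum == st
      for (oc in c("bmi_measured", "bmi_self_exam")) {
        f <- tryCatch(fit_weighted_glm(design, oc, c("G", covs),
                                       family = "linear", subpop = sub),
                      svypath_error = function(e) NULL)
        if (is.null(f)) next
        g <- f$summary[f$summary$term == "G", ]
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, outcome = oc, n = f$n_used, estimate = g$estimate,
          se = g$se, ci_low = g$ci_low, ci_high = g$ci_high,
          p_value = g$p_value, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  path <- run_guarded("path_model", {
    spec <- default_path_spec(d1_d2 = config$d1_d2, covariates = covs)
    fit <- fit_path_model(analytic, spec, design)
    eff <- list()
    for (tgt in c("D1", "bmi45", "D2", "bmi65")) {
      e <- as.data.frame(effect_decomposition(fit, "G", tgt))
      for (cl in c("exp_estimate", "exp_ci_low", "exp_ci_high")) {
        if (!cl %in% names(e)) e[[cl]] <- NA_real_
      }
      if (nrow(e) > 0) e$target <- tgt
      eff[[tgt]] <- e
    }
    eff <- do.call(rbind, lapply(eff, as.data.frame))
    rownames(eff) <- NULL
    coefs <- do.call(rbind, lapply(names(fit$node_fits), function(nd) {
      s <- fit$node_fits[[nd]]$summary
      for (cl in c("odds_ratio", "or_ci_low", "or_ci_high")) {
        if (!cl %in% names(s)) s[[cl]] <- NA_real_
      }
      s$equation <- nd
      s
    }))
    list(fit = fit, coefficients = coefs, effects = eff,
         odds_ratios = rbind(edge_odds_ratio(fit, "G", "D1"),
                             edge_odds_ratio(fit, "G", "D2")))
  })

  manifest$status <- "ok"
  manifest$final_n <- qc$ledger$final_n
  bundle <- list(
    manifest = manifest,
    hwe = list(chi2 = genetics$hwe$chi2, p_value = genetics$hwe$p_value,
               counts = unname(genetics$counts$counts),
               allele_freq = genetics$counts$p),
    flow_ledger = qc$ledger,
    descriptives = descriptives,
    genotype_means = genotype_means,
    regression = regression,
    stratified = stratified,
    path_coefficients = path$coefficients,
    path_effects = path$effects,
    path_odds_ratios = path$odds_ratios,
    analytic_cohort = analytic,
    path_fit = path$fit)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_flow_ledger(qc$ledger, file.path(config$out_dir,
                                           "flow_ledger.json"), "json")
    write_flow_ledger(qc$ledger, file.path(config$out_dir,
                                           "flow_ledger.txt"), "text")
    render_tables(bundle[c("descriptives", "genotype_means", "regression",
                           "stratified", "path_coefficients",
                           "path_effects", "path_odds_ratios")],
                  format = "csv", dir = config$out_dir)
    render_tables(bundle[c("regression", "path_effects")],
                  format = "json", dir = config$out_dir)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Render result tables to files
#'
#' Writes each data frame in `results` to `<dir>/<name>.<ext>` with a
#' stable column order. Missing values render as empty fields in CSV,
#' `null` in JSON; the text format is a fixed-width table at most 120
#' characters wide.
#'
#' @param results named list of data frames.
#' @param format `"csv"`, `"json"` or `"text"`.
#' @param dir output directory (created if needed).
#' @return character vector of the file paths written.
#' @export
render_tables <- function(results, format = c("csv", "json", "text"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- c(csv = "csv", json = "json", text = "txt")[[format]]
  paths <- character()
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    path <- file.path(dir, paste0(nm, ".", ext))
    if (format == "csv") {
      utils::write.csv(df, path, row.names = FALSE, na = "")
    } else if (format == "json") {
      jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
    } else {
      txt <- utils::capture.output(print(df, row.names = FALSE, digits = 4))
      txt <- vapply(txt, function(l) {
        if (nchar(l) > 120) paste0(substr(l, 1, 117), "...") else l
      }, character(1), USE.NAMES = FALSE)
      writeLines(txt, path)
    }
    paths <- c(paths, path)
  }
  paths
}
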