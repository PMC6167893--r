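test_that("scenario configuration rejects degenerate settings", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(risk_allele_freq = 0),
               class = "svypath_config_error")
  expect_error(scenario_config(risk_allele_freq = 1.2),
               class = "svypath_config_error")
  expect_error(scenario_config(sd_bmi21 = -1), class = "svypath_config_error")
  expect_error(scenario_config(n_strata = 0), class = "svypath_config_error")
  expect_error(scenario_config(psus_per_stratum = 1),
               class = "svypath_config_error")
  expect_error(scenario_config(oversample_age45 = 1),
               class = "svypath_config_error")
  expect_error(scenario_config(covar_effects_bmi = c(age = 1)),
               class = "svypath_config_error")
  expect_error(scenario_config(beta_G_bmi21 = Inf),
               class = "svypath_config_error")
})

test_that("scenario configuration round-trips through JSON", {
  cfg <- small_scenario(seed = 5, beta_G_bmi21 = -0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_config(cfg, path)
  cfg2 <- read_scenario_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  # at allele frequency 0.255 the expected class proportions are
  # 0.745^2 = 0.555, 2*0.255*0.745 = 0.380, 0.255^2 = 0.065
  cfg <- scenario_config(n_strata = 10, psus_per_stratum = 3,
                         persons_per_psu = 301, seed = 3)  # n = 9030
  ch <- simulate_cohort(cfg)
  n <- nrow(ch)
  props <- table(factor(ch$G, levels = 0:2)) / n
  expected <- c(0.745^2, 2 * 0.255 * 0.745, 0.255^2)
  for (k in 1:3) {
    tol <- 4 * sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(props[[k]] - expected[k]), tol)
  }
})

test_that("null scenario has no genotype-BMI association and equal node means", {
  cfg <- scenario_config(
    n_strata = 8, psus_per_stratum = 4, persons_per_psu = 300,
    beta_G_bmi21 = 0, beta_G_bmi45 = 0, beta_G_bmi65 = 0,
    beta_G_bmi_exam = 0, beta_bmi_carryover = 0, theta_G_D1 = 0,
    theta_G_D2 = 0, theta_bmi_D = 0, beta_D_bmi = 0, recall_sd = 0,
    intercept_bmi45 = 23.4, intercept_bmi65 = 23.4,
    covar_effects_bmi = c(age = 0, female = 0, education = 0),
    equal_weights = TRUE, seed = 21)
  ch <- simulate_cohort(cfg, censor = FALSE)
  tr <- attr(ch, "truth")
  n <- nrow(ch)
  expect_lt(abs(stats::cor(ch$G, tr$bmi21)), 3.5 / sqrt(n))
  expect_lt(abs(stats::cor(ch$G, tr$bmi45)), 3.5 / sqrt(n))
  # identical conditional (here unconditional) means across ages
  expect_lt(abs(mean(tr$bmi45) - mean(tr$bmi21)), 0.25)
  expect_lt(abs(mean(tr$bmi65) - mean(tr$bmi21)), 0.25)
})

test_that("sampling design oversamples ages 45+ and yields positive inverse-probability weights", {
  cfg <- scenario_config(n_strata = 10, psus_per_stratum = 4,
                         persons_per_psu = 250, seed = 13)
  ch <- simulate_cohort(cfg)
  expect_true(all(ch$sampling_weight > 0))
  expect_lt(abs(mean(ch$age_exam >= 45) - 0.62), 0.02)
  expect_lt(abs(mean(ch$age_exam >= 65) - 0.08), 0.02)
  # oversampled old records carry smaller weights (higher inclusion prob)
  expect_lt(mean(ch$sampling_weight[ch$age_exam >= 45]),
            mean(ch$sampling_weight[ch$age_exam < 45]))
  # ancestry proportions sum to one
  anc <- ch$anc_eur + ch$anc_afr + ch$anc_nam_north + ch$anc_nam_south
  expect_equal(anc, rep(1, nrow(ch)), tolerance = 1e-9)
  # equal-weight variant
  chw <- simulate_cohort(small_scenario(equal_weights = TRUE))
  expect_true(all(chw$sampling_weight == 1))
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(small_scenario(seed = 99))
  b <- simulate_cohort(small_scenario(seed = 99))
  expect_identical(a, b)
  c2 <- simulate_cohort(small_scenario(seed = 100))
  expect_false(identical(a$G, c2$G))
})

test_that("age censoring enforces the period-indicator invariants exhaustively", {
  grid <- expand.grid(age = c(21, 30, 44.9, 45, 50, 64.9, 65, 70, 76),
                      dx = c(NA, 15, 25, 40, 45, 46, 60, 65, 68))
  ch <- data.frame(id = seq_len(nrow(grid)), age_exam = grid$age,
                   diabetes_diagnosis_age = grid$dx,
                   weight_at_21 = 60, weight_at_45 = 70, weight_at_65 = 75)
  out <- apply_age_censoring(ch)
  bad <- !is.na(out$diabetes_diagnosis_age) &
    out$diabetes_diagnosis_age > out$age_exam
  expect_true(all(out$inconsistent_diagnosis ==
                    (!is.na(grid$dx) & grid$dx > grid$age)))
  ok <- !out$inconsistent_diagnosis
  expect_true(all(is.na(out$D1[out$age_exam < 45])))
  expect_true(all(!is.na(out$D1[ok & out$age_exam >= 45])))
  expect_true(all(is.na(out$D2[out$age_exam < 65])))
  expect_true(all(!is.na(out$D2[ok & out$age_exam >= 65])))
  expect_true(all(is.na(out$weight_at_45[out$age_exam < 45])))
  expect_true(all(is.na(out$weight_at_65[out$age_exam < 65])))

  # the worked examples: 50-year-old diagnosed at 40; 70-year-old never
  # diagnosed; 30-year-old
  ex <- apply_age_censoring(data.frame(
    id = 1:3, age_exam = c(50, 70, 30),
    diabetes_diagnosis_age = c(40, NA, NA),
    weight_at_45 = c(70, 70, 70), weight_at_65 = c(75, 75, 75)))
  expect_equal(ex$D1, c(1L, 0L, NA))
  expect_equal(ex$D2, c(NA, 0L, NA))
  expect_true(is.na(ex$weight_at_45[3]) && is.na(ex$weight_at_65[3]))

  # idempotent
  chs <- simulate_cohort(small_scenario(seed = 2))
  expect_identical(apply_age_censoring(chs)$D1, chs$D1)
})

test_that("artifact injection is a no-op at rate zero and records hidden truth", {
  ch <- simulate_cohort(small_scenario(seed = 4))
  out <- inject_artifacts(ch, list(), seed = 4)
  expect_identical(out[, names(ch)], ch[, names(ch)])
  expect_equal(nrow(attr(out, "artifact_truth")), 0)

  out2 <- inject_artifacts(ch, list(unit_confusion = 0.2,
                                    related_pairs = 0.05,
                                    early_diagnosis = 0.05,
                                    bmi_out_of_range = 0.05), seed = 4)
  tru <- attr(out2, "artifact_truth")
  expect_gt(nrow(tru), 0)
  uc <- tru[tru$kind == "unit_confusion", ][1, ]
  expect_equal(uc$injected_value, round(uc$true_value * 2.2046))
  stored <- out2[[uc$field]][out2$id == uc$id]
  expect_equal(stored, uc$injected_value)
  # injected kin pairs appear in the kinship table in the flagged window
  kin <- attr(out2, "kinship")
  inj <- kin$pi_hat > 0.35 & kin$pi_hat < 0.98
  expect_gt(sum(inj), 0)
  expect_error(inject_artifacts(ch, list(bogus = 0.1)),
               class = "svypath_config_error")
  expect_error(inject_artifacts(ch, list(pregnancy = 2)),
               class = "svypath_config_error")
})

test_that("simulated genotype HWE chi-square p-values are null-distributed across cohorts", {
  pvals <- vapply(1:300, function(r) {
    cfg <- scenario_config(n_strata = 2, psus_per_stratum = 2,
                           persons_per_psu = 250, seed = 5000 + r)
    ch <- simulate_cohort(cfg)
    hwe_test(genotype_counts_from_dosage(ch$G))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("cohort and kinship files round-trip through CSV/TSV", {
  ch <- simulate_cohort(small_scenario(seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(ch))
  expect_equal(back$weight_at_65, ch$weight_at_65)
  expect_equal(back$G, ch$G)
  kin <- attr(ch, "kinship")
  kpath <- withr::local_tempfile(fileext = ".tsv")
  write_kinship(kin, kpath)
  expect_equal(read_kinship(kpath), kin)
})
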