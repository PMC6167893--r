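test_that("default specification has the declared edge set and guards its structure", {
  # enumerating the listed edges: 5 genotype edges, BMI21->{D1, BMI45},
  # D1->BMI45, BMI45->{D2, BMI65}, D2->BMI65, plus the optional D1->D2
  sp <- default_path_spec(d1_d2 = TRUE)
  expect_equal(nrow(sp$edges), 12)
  expect_equal(nrow(default_path_spec(d1_d2 = FALSE)$edges), 11)
  # acyclic by construction: every edge points forward
  pos <- stats::setNames(seq_len(nrow(sp$nodes)), sp$nodes$name)
  expect_true(all(pos[sp$edges$from] < pos[sp$edges$to]))

  # removing a chain node breaks the temporal chain
  nodes <- sp$nodes[sp$nodes$name != "bmi45", ]
  edges <- sp$edges[sp$edges$from != "bmi45" & sp$edges$to != "bmi45", ]
  expect_error(path_spec(nodes, edges), regexp = "chain",
               class = "svypath_spec_error")
  # backward edges are rejected
  expect_error(path_spec(sp$nodes, data.frame(from = "bmi45", to = "bmi21")),
               class = "svypath_spec_error")
  # edges into exogenous nodes are rejected
  expect_error(path_spec(sp$nodes, rbind(sp$edges,
                                         data.frame(from = "bmi21", to = "G"))),
               class = "svypath_spec_error")
})

test_that("complete-data factorized fit equals per-equation weighted GLMs exactly", {
  ch <- complete_cohort(seed = 23)
  d <- survey_design(ch)
  sp <- default_path_spec(d1_d2 = FALSE,
                          covariates = c("age_exam", "female", "education"))
  fit <- fit_path_model(ch, sp, d)
  g_ok <- !is.na(ch$G)
  for (nd in c("bmi21", "D1", "bmi45", "D2", "bmi65")) {
    pars <- sp$edges$from[sp$edges$to == nd]
    fam <- if (nd %in% c("D1", "D2")) "logit" else "linear"
    sub <- g_ok
    if (nd == "D2") sub <- sub & ch$D1 == 0  # hazard risk set
    single <- fit_weighted_glm(d, nd, c(pars, sp$covariates), family = fam,
                               subpop = sub)
    idx <- grep(paste0("^", nd, "~"), names(fit$coefficients))
    expect_equal(unname(fit$coefficients[idx]),
                 unname(single$coefficients), tolerance = 1e-10)
    # the joint covariance's diagonal block is the single-equation sandwich
    expect_equal(unname(fit$vcov[idx, idx]), unname(single$vcov),
                 tolerance = 1e-10)
  }
})

test_that("factorized estimates are unbiased under design-induced age censoring", {
  # missingness created solely by apply_age_censoring is monotone in age,
  # so available-case equation fits are full-information ML
  reps <- 120
  edge_names <- c("bmi21~G", "D1~G", "D1~bmi21", "bmi45~G", "bmi45~bmi21",
                  "bmi45~D1", "D2~G", "D2~bmi45", "bmi65~G", "bmi65~bmi45",
                  "bmi65~D2")
  truth <- c(-0.20, log(1.32), 0.10, -0.18, 0.8, 2.8,
             log(1.32), 0.10, 0.01, 0.8, 2.8)
  sp <- default_path_spec(d1_d2 = FALSE,
                          covariates = c("age_exam", "female", "education"))
  ests <- t(vapply(seq_len(reps), function(r) {
    cfg <- scenario_config(n_strata = 5, psus_per_stratum = 4,
                           persons_per_psu = 200, equal_weights = TRUE,
                           recall_sd = 0, seed = 40000 + r)
    ch <- latent_bmi_cohort(simulate_cohort(cfg))
    fit <- fit_path_model(ch, sp, survey_design(ch))
    fit$coefficients[edge_names]
  }, numeric(length(edge_names))))
  bias <- colMeans(ests) - truth
  mcse <- apply(ests, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(bias) < 3.2 * mcse),
              info = paste(names(bias), round(bias / mcse, 2),
                           collapse = "; "))
})

test_that("records with missing genotype are excluded globally with a logged count", {
  ch <- complete_cohort(seed = 24)
  ch$G[1:25] <- NA
  d <- survey_design(ch)
  sp <- default_path_spec(d1_d2 = FALSE,
                          covariates = c("age_exam", "female"))
  fit <- fit_path_model(ch, sp, d)
  expect_equal(fit$n_missing_G, 25)
  manual <- fit_weighted_glm(d, "bmi21", c("G", "age_exam", "female"),
                             family = "linear", subpop = !is.na(ch$G))
  idx <- grep("^bmi21~", names(fit$coefficients))
  expect_equal(unname(fit$coefficients[idx]), unname(manual$coefficients))
})

test_that("fitting the D1->D2 edge on first-diagnosis indicators hits structural separation", {
  ch <- complete_cohort(seed = 25, n_per_psu = 400)
  d <- survey_design(ch)
  sp <- default_path_spec(d1_d2 = TRUE,
                          covariates = c("age_exam", "female"))
  # a first diagnosis in 22-45 leaves no one to be newly diagnosed in
  # 46-65: D1 = 1 implies D2 = 0, so the D1 coefficient diverges
  expect_error(fit_path_model(ch, sp, d),
               regexp = "D1|separation|converge")
})

test_that("Monte-Carlo EM beats available-case fitting when mediators are missing off-pattern", {
  # 25% of the BMI-45 mediator deleted completely at random while D2 and
  # BMI-65 stay observed; the EM recovers the information in those rows
  sp <- default_path_spec(d1_d2 = FALSE,
                          covariates = c("age_exam", "female"))
  reps <- 40
  res <- t(vapply(seq_len(reps), function(r) {
    cfg <- scenario_config(n_strata = 4, psus_per_stratum = 3,
                           persons_per_psu = 100, equal_weights = TRUE,
                           recall_sd = 0, seed = 60000 + r)
    ch <- latent_bmi_cohort(simulate_cohort(cfg, censor = FALSE))
    set.seed(70000 + r)
    ch$bmi45[stats::runif(nrow(ch)) < 0.25] <- NA
    d <- survey_design(ch)
    f_fact <- fit_path_model(ch, sp, d, method = "factorized")
    f_fiml <- fit_path_model(ch, sp, d, method = "fiml_mc",
                             mc_draws = 32L, mc_iter = 15L, seed = r)
    keys <- c("D2~bmi45", "bmi65~bmi45")
    c(f_fact$coefficients[keys], f_fiml$coefficients[keys])
  }, numeric(4)))
  truth <- c(0.10, 0.8)
  rmse <- function(cols) sqrt(mean((res[, cols] -
                                      rep(truth, each = reps))^2))
  expect_lt(rmse(3:4), rmse(1:2))
})

test_that("convergence metadata is recorded", {
  ch <- complete_cohort(seed = 26)
  fit <- fit_path_model(ch, default_path_spec(
    d1_d2 = FALSE, covariates = c("age_exam", "female")))
  expect_true(fit$converged)
  expect_true(all(vapply(fit$node_fits, function(f) f$grad_norm < 1e-6,
                         logical(1))))
})
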