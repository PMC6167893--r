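test_that("design validation catches bad weights and PSU-stratum nesting", {
  d <- data.frame(stratum = c(1, 1, 2, 2), psu = c("a", "b", "c", "d"),
                  sampling_weight = c(1, 2, 3, 4), y = 1:4)
  expect_s3_class(survey_design(d), "survey_design")
  d$sampling_weight[1] <- -1
  expect_error(survey_design(d), class = "svypath_design_error")
  d$sampling_weight[1] <- 1
  d$stratum <- c(1, 2, 1, 2)  # psu "a" would sit in stratum 1 only: ok
  d2 <- d
  d2$psu <- c("a", "a", "c", "d")  # psu "a" in two strata
  expect_error(survey_design(d2), class = "svypath_design_error")
})

test_that("weighted mean reduces to the plain mean under equal weights", {
  d <- toy_design()
  d$data$sampling_weight <- 2.5
  dd <- survey_design(d$data)
  m <- estimate_mean_prop(dd, "y")
  expect_equal(m$estimate, mean(d$data$y))
  # subpopulation of everyone equals the unrestricted estimate
  m2 <- estimate_mean_prop(dd, "y", subpop = rep(TRUE, 8))
  expect_equal(m2$estimate, m$estimate)
  expect_equal(m2$se, m$se)
})

test_that("toy two-stratum SE matches hand-enumerated PSU-total linearization", {
  d <- toy_design()
  dat <- d$data
  W <- sum(dat$sampling_weight)
  est <- sum(dat$sampling_weight * dat$y) / W
  z <- dat$sampling_weight * (dat$y - est) / W
  # PSU totals; with 2 PSUs per stratum the stratum contribution
  # (n_h/(n_h-1)) * sum of squared deviations collapses to (t1 - t2)^2
  t_psu <- tapply(z, dat$psu, sum)
  v_hand <- (t_psu[["p1"]] - t_psu[["p2"]])^2 +
    (t_psu[["p3"]] - t_psu[["p4"]])^2
  m <- estimate_mean_prop(d, "y")
  expect_equal(m$estimate, est)
  expect_equal(m$se, sqrt(v_hand))
})

test_that("unit-weight fits equal ordinary least squares and ML logit", {
  ch <- complete_cohort(seed = 6)
  ch$sampling_weight <- 1
  d <- survey_design(ch)
  f <- fit_weighted_glm(d, "bmi21", c("G", "age_exam", "female"),
                        family = "linear")
  ols <- stats::lm(bmi21 ~ G + age_exam + female, data = ch)
  expect_equal(unname(f$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-10)
  fl <- fit_weighted_glm(d, "D1", c("G", "bmi21"), family = "logit")
  ml <- stats::glm(D1 ~ G + bmi21, data = ch, family = stats::binomial())
  expect_equal(unname(fl$coefficients), unname(stats::coef(ml)),
               tolerance = 1e-7)
})

test_that("weighted 2x2 logit equals the hand-computed log odds ratio", {
  dat <- expand.grid(x = c(0, 1), y = c(0, 1), psu = 1:4)
  dat$stratum <- ifelse(dat$psu <= 2, "A", "B")
  set.seed(12)
  dat$sampling_weight <- stats::runif(nrow(dat), 0.5, 3)
  d <- survey_design(dat)
  f <- fit_weighted_glm(d, "y", "x", family = "logit")
  w <- function(xx, yy) sum(dat$sampling_weight[dat$x == xx & dat$y == yy])
  log_or <- log((w(1, 1) * w(0, 0)) / (w(1, 0) * w(0, 1)))
  expect_equal(unname(f$coefficients["x"]), log_or, tolerance = 1e-7)
  expect_equal(f$summary$odds_ratio[f$summary$term == "x"], exp(log_or),
               tolerance = 1e-7)
})

test_that("linear fits are invariant to rescaling all weights", {
  ch <- complete_cohort(seed = 14)
  d1 <- survey_design(ch)
  ch2 <- ch
  ch2$sampling_weight <- ch2$sampling_weight * 3.7
  d2 <- survey_design(ch2)
  f1 <- fit_weighted_glm(d1, "bmi45", c("G", "bmi21", "D1", "age_exam"),
                         family = "linear")
  f2 <- fit_weighted_glm(d2, "bmi45", c("G", "bmi21", "D1", "age_exam"),
                         family = "linear")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$summary$se, f2$summary$se, tolerance = 1e-8)
})

test_that("degenerate designs and model matrices raise targeted errors", {
  ch <- complete_cohort(seed = 15)
  # single-PSU stratum: hard error by default, centered policy runs
  one <- ch[ch$psu != "s01_p01" | ch$stratum != 1, ]
  one$psu[one$stratum == 1] <- "s01_p02"
  d_bad <- survey_design(one)
  expect_error(fit_weighted_glm(d_bad, "bmi21", "G", family = "linear"),
               regexp = "single PSU", class = "svypath_design_error")
  d_ctr <- survey_design(one, single_psu = "centered")
  expect_s3_class(fit_weighted_glm(d_ctr, "bmi21", "G", family = "linear"),
                  "svy_fit")

  # rank deficiency names the aliased column
  ch$G2 <- ch$G
  ch$sep <- as.numeric(ch$D1 == 1)
  d <- survey_design(ch)
  expect_error(fit_weighted_glm(d, "bmi21", c("G", "G2"), family = "linear"),
               regexp = "G2", class = "svypath_design_error")

  # complete separation names an offending covariate
  expect_error(fit_weighted_glm(d, "D1", c("sep", "G"), family = "logit"),
               regexp = "sep", class = "svypath_design_error")
})

test_that("domain variance from score-zeroing is no smaller than naive row-dropping", {
  ch <- complete_cohort(seed = 16, n_per_psu = 150)
  d <- survey_design(ch)
  set.seed(33)
  wins <- vapply(1:30, function(r) {
    sub <- stats::runif(nrow(ch)) < 0.6
    full <- estimate_mean_prop(d, "bmi21", subpop = sub)
    dropped <- survey_design(ch[sub, , drop = FALSE])
    naive <- estimate_mean_prop(dropped, "bmi21")
    full$se >= naive$se - 1e-12
  }, logical(1))
  expect_gte(mean(wins), 0.90)
})

test_that("adjusted genotype means reduce to weighted raw means without covariates", {
  ch <- complete_cohort(seed = 17)
  d <- survey_design(ch)
  gm <- adjusted_genotype_means(d, "bmi21", character(0))
  for (cls in 0:2) {
    sel <- ch$G == cls & !is.na(ch$bmi21)
    raw <- sum(ch$sampling_weight[sel] * ch$bmi21[sel]) /
      sum(ch$sampling_weight[sel])
    expect_equal(gm$means$estimate[gm$means$genotype == cls], raw,
                 tolerance = 1e-8)
  }
  expect_true(gm$joint_p >= 0 && gm$joint_p <= 1)
  ch$G[ch$G == 2] <- 1
  expect_error(adjusted_genotype_means(survey_design(ch), "bmi21",
                                       character(0)),
               class = "svypath_design_error")
})

test_that("dis-joint genotype coding recovers a dominant effect the additive slope attenuates", {
  # dominant truth: CT and TT both shifted by delta; under HWE at p=0.255
  # the additive projection of (0, d, d) has slope d * 0.283/0.380 = 0.745 d
  delta <- 1.0
  set.seed(55)
  res <- t(sapply(1:40, function(r) {
    n <- 3000
    dat <- data.frame(
      stratum = rep(1:5, each = 600),
      psu = rep(sprintf("q%02d", 1:15), each = 200),
      sampling_weight = 1,
      G = stats::rbinom(n, 2, 0.255))
    dat$y <- 25 + delta * (dat$G >= 1) + stats::rnorm(n, 0, 3)
    d <- survey_design(dat)
    gm <- adjusted_genotype_means(d, "y", character(0))
    add <- fit_weighted_glm(d, "y", "G", family = "linear")
    c(ct_effect = gm$means$estimate[2] - gm$means$estimate[1],
      slope = unname(add$coefficients["G"]))
  }))
  mcse <- apply(res, 2, stats::sd) / sqrt(nrow(res))
  expect_lt(abs(mean(res[, "ct_effect"]) - delta), 3 * mcse["ct_effect"])
  expect_lt(mean(res[, "slope"]), 0.85 * delta)  # attenuated per-allele slope
})
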