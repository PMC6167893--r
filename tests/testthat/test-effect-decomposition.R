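# hand-built minimal fit: exogenous x -> linear m -> linear y
chain_fit <- function(a = 0.5, b = -1.2, sa = 0.1, sb = 0.2,
                      direct = NULL, sd_direct = 0.15) {
  nodes <- data.frame(name = c("x", "m", "y"),
                      family = c("exogenous", "linear", "linear"))
  edges <- data.frame(from = c("x", "m"), to = c("m", "y"))
  cf <- c("m~x" = a, "y~m" = b)
  vc <- diag(c(sa^2, sb^2))
  if (!is.null(direct)) {
    edges <- rbind(edges, data.frame(from = "x", to = "y"))
    cf <- c(cf, "y~x" = direct)
    vc <- diag(c(sa^2, sb^2, sd_direct^2))
  }
  dimnames(vc) <- list(names(cf), names(cf))
  spec <- path_spec(nodes, edges)
  structure(list(spec = spec, coefficients = cf, vcov = vc),
            class = "path_fit")
}

test_that("three-node chain indirect effect matches the closed-form delta method", {
  a <- 0.5; b <- -1.2; sa <- 0.1; sb <- 0.2
  eff <- effect_decomposition(chain_fit(a, b, sa, sb), "x", "y")
  ind <- eff[eff$kind == "indirect", ]
  expect_equal(ind$estimate, a * b)
  expect_equal(ind$se, sqrt(a^2 * sb^2 + b^2 * sa^2), tolerance = 1e-12)
  # no direct edge: direct effect is exactly zero, total equals indirect
  expect_equal(eff$estimate[eff$kind == "direct"], 0)
  expect_equal(eff$estimate[eff$kind == "total"], a * b)
})

test_that("delta-method SE agrees with a parametric bootstrap within ten percent", {
  fit <- chain_fit(0.5, -1.2, 0.1, 0.2, direct = 0.3)
  eff <- effect_decomposition(fit, "x", "y")
  set.seed(91)
  draws <- matrix(stats::rnorm(1000 * 3), ncol = 3) %*%
    chol(fit$vcov) + matrix(fit$coefficients, 1000, 3, byrow = TRUE)
  boot_ind <- draws[, 1] * draws[, 2]
  boot_tot <- boot_ind + draws[, 3]
  se_ind <- eff$se[eff$kind == "indirect"]
  se_tot <- eff$se[eff$kind == "total"]
  expect_lt(abs(stats::sd(boot_ind) - se_ind) / se_ind, 0.10)
  expect_lt(abs(stats::sd(boot_tot) - se_tot) / se_tot, 0.10)
})

test_that("path enumeration matches an independent adjacency-power count", {
  sp <- default_path_spec(d1_d2 = TRUE)
  nms <- sp$nodes$name
  A <- matrix(0, 6, 6, dimnames = list(nms, nms))
  for (k in seq_len(nrow(sp$edges))) A[sp$edges$from[k], sp$edges$to[k]] <- 1
  # number of directed paths = sum over k >= 1 of (A^k)[source, target]
  count_paths <- function(src, tgt) {
    tot <- 0; P <- A
    for (k in 1:5) { tot <- tot + P[src, tgt]; P <- P %*% A }
    tot
  }
  for (tgt in c("D1", "bmi45", "D2", "bmi65")) {
    expect_equal(length(enumerate_paths(sp, "G", tgt)),
                 count_paths("G", tgt))
  }
  expect_equal(length(enumerate_paths(sp, "bmi65", "bmi65")), 1)
})

test_that("decomposition on a fitted model is additive to machine precision", {
  ch <- complete_cohort(seed = 27)
  fit <- fit_path_model(ch, default_path_spec(
    d1_d2 = FALSE, covariates = c("age_exam", "female")))
  for (tgt in c("bmi45", "D2", "bmi65")) {
    eff <- effect_decomposition(fit, "G", tgt)
    tot <- eff$estimate[eff$kind == "total"]
    parts <- sum(eff$estimate[eff$kind != "total"])
    expect_equal(tot - parts, 0, tolerance = 1e-12)
  }
  # zeroing one edge coefficient nullifies every path through it
  fit0 <- fit
  fit0$coefficients[["bmi45~bmi21"]] <- 0
  eff <- effect_decomposition(fit0, "G", "bmi65")
  through <- grepl("bmi21->bmi45", eff$path)
  expect_true(all(eff$estimate[through & eff$kind == "indirect"] == 0))
  # effects into a logit node carry exponentiated columns
  effd <- effect_decomposition(fit, "G", "D2")
  expect_true(all(c("exp_estimate", "exp_ci_low") %in% names(effd)))
  expect_equal(effd$exp_estimate, exp(effd$estimate))
})

test_that("source after target or outside the model is rejected; no path yields empty", {
  fit <- chain_fit()
  expect_error(effect_decomposition(fit, "y", "x"),
               class = "svypath_spec_error")
  expect_error(effect_decomposition(fit, "q", "y"),
               class = "svypath_spec_error")
  # two disconnected halves: no path, empty table
  nodes <- data.frame(name = c("x", "m", "y"),
                      family = c("exogenous", "linear", "linear"))
  edges <- data.frame(from = "x", to = "m")
  fit2 <- structure(list(spec = path_spec(nodes, edges),
                         coefficients = c("m~x" = 0.5),
                         vcov = matrix(0.01, 1, 1,
                                       dimnames = list("m~x", "m~x"))),
                    class = "path_fit")
  eff <- effect_decomposition(fit2, "x", "y")
  expect_equal(nrow(eff), 0)
})

test_that("edge odds ratios exponentiate correctly and refuse linear targets", {
  nodes <- data.frame(name = c("x", "d"), family = c("exogenous", "logit"))
  edges <- data.frame(from = "x", to = "d")
  fit <- structure(list(spec = path_spec(nodes, edges),
                        coefficients = c("d~x" = log(1.32)),
                        vcov = matrix(0.1183759^2, 1, 1,
                                      dimnames = list("d~x", "d~x"))),
                   class = "path_fit")
  or <- edge_odds_ratio(fit, "x", "d")
  expect_equal(or$odds_ratio, 1.32)
  expect_equal(or$or_ci_low, 1.05, tolerance = 0.005)
  expect_equal(or$or_ci_high, 1.67, tolerance = 0.005)

  fit$coefficients[["d~x"]] <- 0
  expect_equal(edge_odds_ratio(fit, "x", "d")$odds_ratio, 1)

  ch <- complete_cohort(seed = 28)
  pf <- fit_path_model(ch, default_path_spec(
    d1_d2 = FALSE, covariates = c("age_exam", "female")))
  expect_error(edge_odds_ratio(pf, "G", "bmi45"),
               class = "svypath_fit_error")
  expect_error(edge_odds_ratio(pf, "bmi65", "D2"),
               class = "svypath_fit_error")
})
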