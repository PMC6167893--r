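#' Complex survey design specification
#'
#' Binds a cohort data frame to its two-stage design structure: stratum and
#' primary sampling unit (PSU) identifiers and positive sampling weights.
#' All variance estimation in the package is Taylor linearization over
#' between-PSU variation within strata, and subpopulation (domain) analyses
#' zero out score contributions rather than dropping records, so the full
#' design information always enters the variance.
#'
#' @param data cohort data frame.
#' @param strata,psu,weights column names of the stratum id, PSU id and
#'   sampling weight.
#' @param single_psu policy for strata containing a single sampled PSU:
#'   `"error"` (default; a lone PSU hides design defects) or `"centered"`
#'   (center that PSU's score at the grand mean across all PSUs).
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(data, strata = "stratum", psu = "psu",
                          weights = "sampling_weight",
                          single_psu = c("error", "centered")) {
  single_psu <- match.arg(single_psu)
  stopifnot(is.data.frame(data))
  for (col in c(strata, psu, weights)) {
    if (!col %in% names(data)) {
      stop_svypath(sprintf("design column '%s' not found in data", col),
                   "svypath_design_error")
    }
  }
  w <- data[[weights]]
  if (any(is.na(w)) || any(w <= 0)) {
    stop_svypath("sampling weights must be positive and non-missing",
                 "svypath_design_error")
  }
  tab <- unique(data.frame(s = data[[strata]], p = data[[psu]]))
  if (anyDuplicated(tab$p)) {
    stop_svypath("each PSU must belong to exactly one stratum",
                 "svypath_design_error")
  }
  structure(list(data = data, strata_col = strata, psu_col = psu,
                 weights_col = weights, single_psu = single_psu),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  s <- x$data[[x$strata_col]]
  p <- x$data[[x$psu_col]]
  cat(sprintf("<survey_design> %d records, %d strata, %d PSUs\n",
              nrow(x$data), length(unique(s)), length(unique(p))))
  invisible(x)
}

# Stratified between-PSU covariance of score totals. `scores` is an
# n x p matrix of per-record linearized contributions (zero outside the
# estimation domain); returns the p x p design-based covariance.
psu_score_covariance <- function(design, scores) {
  scores <- as.matrix(scores)
  s <- as.character(design$data[[design$strata_col]])
  p <- as.character(design$data[[design$psu_col]])
  key <- paste(s, p, sep = "\r")
  totals <- rowsum(scores, key, reorder = FALSE)
  stratum_of <- sub("\r.*$", "", rownames(totals))
  V <- matrix(0, ncol(scores), ncol(scores))
  grand_mean <- colMeans(totals)
  for (h in unique(stratum_of)) {
    rows <- which(stratum_of == h)
    nh <- length(rows)
    if (nh < 2) {
      if (design$single_psu == "error") {
        stop_svypath(sprintf(
          "stratum '%s' has a single PSU; variance is undefined (set single_psu = 'centered' to center at the grand mean)",
          h), "svypath_design_error")
      }
      dev <- sweep(totals[rows, , drop = FALSE], 2, grand_mean)
      V <- V + crossprod(dev)
    } else {
      dev <- sweep(totals[rows, , drop = FALSE], 2,
                   colMeans(totals[rows, , drop = FALSE]))
      V <- V + nh / (nh - 1) * crossprod(dev)
    }
  }
  V
}

resolve_subpop <- function(design, subpop) {
  n <- nrow(design$data)
  if (is.null(subpop)) return(rep(TRUE, n))
  if (is.character(subpop) && length(subpop) == 1) {
    subpop <- design$data[[subpop]]
  }
  subpop <- as.logical(subpop)
  stopifnot(length(subpop) == n)
  subpop[is.na(subpop)] <- FALSE
  subpop
}

#' Design-based mean or proportion
#'
#' Horvitz-Thompson ratio mean of a numeric or binary variable with
#' Taylor-linearized SE from between-PSU variation within strata.
#' Subpopulation estimates keep every record in the variance computation,
#' zeroing the score contributions of records outside the domain.
#'
#' @param design a [survey_design()].
#' @param variable column name of the analysis variable.
#' @param subpop optional domain: a logical vector over the design rows or
#'   the name of a logical/0-1 column.
#' @param level confidence level.
#' @return list with `estimate`, `se`, `ci`, `n` (records contributing).
#' @export
estimate_mean_prop <- function(design, variable, subpop = NULL,
                               level = 0.95) {
  stopifnot(inherits(design, "survey_design"))
  y <- design$data[[variable]]
  if (is.null(y)) {
    stop_svypath(sprintf("variable '%s' not found", variable),
                 "svypath_design_error")
  }
  y <- as.numeric(y)
  w <- design$data[[design$weights_col]]
  dom <- resolve_subpop(design, subpop) & !is.na(y)
  if (!any(dom)) {
    stop_svypath("no non-missing records in the requested domain",
                 "svypath_design_error")
  }
  W <- sum(w[dom])
  est <- sum(w[dom] * y[dom]) / W
  z <- numeric(nrow(design$data))
  z[dom] <- w[dom] * (y[dom] - est) / W
  V <- psu_score_covariance(design, matrix(z, ncol = 1))
  se <- sqrt(V[1, 1])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se, ci = c(est - zq * se, est + zq * se),
       n = sum(dom))
}

#' Survey-weighted generalized linear model with sandwich variance
#'
#' Weighted pseudo-maximum-likelihood point estimates (identity-link
#' Gaussian for `family = "linear"`, logit link for `family = "logit"`)
#' with design-based Taylor-linearization covariance: per-record score
#' contributions are aggregated to PSU totals and their between-PSU,
#' within-stratum covariance is sandwiched between the inverse expected
#' information. Records with missing response or covariates are excluded
#' from estimation (complete case within the equation) but retained, with
#' zero scores, in the variance aggregation; subpopulations are handled
#' the same way.
#'
#' Confidence intervals use the normal reference (`estimate +/- z * SE`);
#' set `df` to a finite value (conventionally PSUs minus strata) for a t
#' reference.
#'
#' @param design a [survey_design()].
#' @param response response column name (0/1 for `"logit"`).
#' @param covariates character vector of model terms (column names or
#'   formula pieces such as interactions).
#' @param family `"linear"` or `"logit"`.
#' @param subpop optional domain, as in [estimate_mean_prop()].
#' @param level confidence level.
#' @param df degrees of freedom for the interval reference; `Inf` = normal.
#' @return object of class `svy_fit`: `coefficients`, `vcov`, a `summary`
#'   data frame (term, estimate, se, ci, p, and odds ratios for logit),
#'   `n_used`, `family`, `converged`.
#' @export
fit_weighted_glm <- function(design, response, covariates,
                             family = c("linear", "logit"), subpop = NULL,
                             level = 0.95, df = Inf) {
  family <- match.arg(family)
  stopifnot(inherits(design, "survey_design"))
  data <- design$data
  fml <- stats::as.formula(paste(
    response, "~", if (length(covariates) > 0)
      paste(covariates, collapse = " + ") else "1"))
  mf_all <- stats::model.frame(fml, data = data, na.action = stats::na.pass)
  est_rows <- stats::complete.cases(mf_all) & resolve_subpop(design, subpop)
  if (sum(est_rows) < length(covariates) + 2) {
    stop_svypath("too few complete records to fit the model",
                 "svypath_design_error")
  }
  mf <- mf_all[est_rows, , drop = FALSE]
  X <- stats::model.matrix(fml, mf)
  y <- as.numeric(stats::model.response(mf))
  w <- data[[design$weights_col]][est_rows]

  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_svypath(paste("design matrix is rank deficient; aliased column(s):",
                       paste(aliased, collapse = ", ")),
                 "svypath_design_error")
  }

  if (family == "linear") {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    mu <- drop(X %*% beta)
    info_w <- w
    converged <- TRUE
  } else {
    if (!all(y %in% 0:1)) {
      stop_svypath("logit response must be 0/1", "svypath_design_error")
    }
    fit <- suppressWarnings(
      stats::glm.fit(X, y, weights = w, family = stats::quasibinomial()))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    converged <- fit$converged
    big <- which(abs(beta) > 15)
    big <- big[colnames(X)[big] != "(Intercept)"]
    if (length(big) > 0 && (any(mu > 1 - 1e-8) || any(mu < 1e-8))) {
      stop_svypath(paste("(quasi-)complete separation detected; offending covariate(s):",
                         paste(colnames(X)[big], collapse = ", ")),
                   "svypath_design_error")
    }
    info_w <- w * mu * (1 - mu)
  }

  scores_est <- X * (w * (y - mu))
  grad_norm <- max(abs(colSums(scores_est))) / sum(w)
  scores <- matrix(0, nrow(data), ncol(X),
                   dimnames = list(NULL, colnames(X)))
  scores[est_rows, ] <- scores_est
  bread <- crossprod(X, X * info_w)
  Vs <- psu_score_covariance(design, scores)
  Binv <- solve(bread)
  vc <- Binv %*% Vs %*% Binv
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))

  se <- sqrt(diag(vc))
  q <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df) else
    stats::qnorm(1 - (1 - level) / 2)
  zstat <- beta / se
  pval <- if (is.finite(df)) 2 * stats::pt(-abs(zstat), df) else
    2 * stats::pnorm(-abs(zstat))
  smry <- data.frame(term = colnames(X), estimate = unname(beta),
                     se = unname(se),
                     ci_low = unname(beta - q * se),
                     ci_high = unname(beta + q * se),
                     p_value = unname(pval), stringsAsFactors = FALSE)
  if (family == "logit") {
    smry$odds_ratio <- exp(smry$estimate)
    smry$or_ci_low <- exp(smry$ci_low)
    smry$or_ci_high <- exp(smry$ci_high)
  }
  structure(list(coefficients = beta, vcov = vc, summary = smry,
                 n_used = sum(est_rows), family = family,
                 converged = converged, grad_norm = grad_norm,
                 response = response,
                 formula = fml,
                 scores = scores, bread = bread, est_rows = est_rows,
                 X_names = colnames(X)),
            class = "svy_fit")
}

#' @export
print.svy_fit <- function(x, ...) {
  cat(sprintf("<svy_fit> %s, n = %d%s\n", x$family, x$n_used,
              if (!x$converged) " (NOT converged)" else ""))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Covariate-adjusted outcome means by genotype class
#'
#' Models the outcome on two genotype indicator contrasts (no additive
#' assumption) plus covariates, and reports the model-based mean for each
#' genotype class at the weighted covariate means, with a joint 2-df Wald
#' test of any genotype effect.
#'
#' @param design a [survey_design()].
#' @param outcome outcome column name.
#' @param covariates character vector of adjustment terms (may be empty,
#'   in which case the adjusted means equal the weighted raw means per
#'   class).
#' @param genotype dosage column name (values 0/1/2).
#' @param subpop optional domain.
#' @return list with `means` (data frame: genotype, estimate, se, ci) and
#'   `joint_p` (2-df Wald p-value), plus the underlying `fit`.
#' @export
adjusted_genotype_means <- function(design, outcome, covariates,
                                    genotype = "G", subpop = NULL) {
  data <- design$data
  gvals <- data[[genotype]]
  if (!all(stats::na.omit(gvals) %in% 0:2)) {
    stop_svypath("genotype column must hold dosages 0/1/2",
                 "svypath_design_error")
  }
  for (cls in 0:2) {
    if (!any(gvals %in% cls)) {
      stop_svypath(sprintf("empty genotype class %d", cls),
                   "svypath_design_error")
    }
  }
  data$.g1 <- as.numeric(gvals == 1)
  data$.g2 <- as.numeric(gvals == 2)
  data$.g1[is.na(gvals)] <- NA
  data$.g2[is.na(gvals)] <- NA
  d2 <- survey_design(data, design$strata_col, design$psu_col,
                      design$weights_col, design$single_psu)
  fit <- fit_weighted_glm(d2, outcome, c(".g1", ".g2", covariates),
                          family = "linear", subpop = subpop)

  # weighted covariate means over the estimation sample
  mf <- stats::model.frame(fit$formula, data = data,
                           na.action = stats::na.pass)
  X <- stats::model.matrix(fit$formula, mf[fit$est_rows, , drop = FALSE])
  w <- data[[design$weights_col]][fit$est_rows]
  xbar <- colSums(X * w) / sum(w)

  rows <- lapply(0:2, function(cls) {
    cvec <- xbar
    cvec[".g1"] <- as.numeric(cls == 1)
    cvec[".g2"] <- as.numeric(cls == 2)
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    data.frame(genotype = cls, estimate = est, se = se,
               ci_low = est - 1.96 * se, ci_high = est + 1.96 * se)
  })
  gi <- match(c(".g1", ".g2"), names(fit$coefficients))
  bg <- fit$coefficients[gi]
  wald <- drop(t(bg) %*% solve(fit$vcov[gi, gi]) %*% bg)
  list(means = do.call(rbind, rows),
       joint_p = stats::pchisq(wald, df = 2, lower.tail = FALSE),
       joint_wald = wald, fit = fit)
}
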