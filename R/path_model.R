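#' Specify a recursive life-course path model
#'
#' A path model is a system of regressions over an acyclic, temporally
#' ordered set of nodes: each endogenous node is modelled on its parent
#' nodes plus a common covariate set, with a linear family for continuous
#' (BMI) nodes and a logit family for binary (period-diagnosis) nodes.
#' Node order in `nodes` is the temporal order; every edge must point
#' forward.
#'
#' @param nodes data frame with columns `name` and `family`
#'   (`"exogenous"`, `"linear"` or `"logit"`).
#' @param edges data frame with columns `from`, `to`.
#' @param covariates character vector of adjustment terms entering every
#'   endogenous node's equation.
#' @param method `"factorized"` (default) or `"fiml_mc"`; see
#'   [fit_path_model()].
#' @return object of class `path_spec`.
#' @export
path_spec <- function(nodes, edges, covariates = character(),
                      method = c("factorized", "fiml_mc")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(nodes), all(c("name", "family") %in% names(nodes)),
            is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (anyDuplicated(nodes$name)) {
    stop_svypath("duplicate node names", "svypath_spec_error")
  }
  if (!all(nodes$family %in% c("exogenous", "linear", "logit"))) {
    stop_svypath("node family must be exogenous, linear or logit",
                 "svypath_spec_error")
  }
  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$name)
  bad <- !(edges$from %in% nodes$name) | !(edges$to %in% nodes$name)
  if (any(bad)) {
    stop_svypath("edge endpoints must be declared nodes",
                 "svypath_spec_error")
  }
  if (any(pos[edges$from] >= pos[edges$to])) {
    stop_svypath(
      "every edge must point forward in the temporal node order (the graph must be a recursive DAG)",
      "svypath_spec_error")
  }
  if (any(nodes$family[match(edges$to, nodes$name)] == "exogenous")) {
    stop_svypath("exogenous nodes cannot receive edges", "svypath_spec_error")
  }
  canon <- c("G", "bmi21", "D1", "bmi45", "D2", "bmi65")
  if (any(canon %in% nodes$name) && !all(canon %in% nodes$name)) {
    stop_svypath(
      paste("broken temporal chain: the life-course model requires all of",
            paste(canon, collapse = ", ")), "svypath_spec_error")
  }
  structure(list(nodes = nodes, edges = edges,
                 covariates = covariates, method = method),
            class = "path_spec")
}

#' Default life-course path specification
#'
#' The a priori structural model: genotype dosage `G` sends direct edges to
#' BMI at ages 21/45/65 and to both period T2D indicators; each BMI feeds
#' the diagnosis indicator of the immediately following period; each
#' period diagnosis feeds the BMI at the period's end; and BMI tracks from
#' each age to the next. Examination age (age at recall), sex, education,
#' ancestry proportions and genetic analysis group enter every equation.
#'
#' The `d1_d2` edge (earlier diagnosis entering the later period's
#' equation) is configurable and defaults on; note that when the period
#' indicators encode a single first-diagnosis age, no new diagnosis can
#' occur in 46-65 after one in 22-45, so fitting with this edge meets
#' structural (quasi-complete) separation. Analyses in this package fit
#' with `d1_d2 = FALSE` for that reason.
#'
#' @param d1_d2 include the D1 -> D2 edge (default `TRUE`; 11 edges with
#'   it, 10 without).
#' @param covariates adjustment terms for every equation.
#' @param method estimation method, as in [path_spec()].
#' @return a `path_spec`.
#' @export
default_path_spec <- function(d1_d2 = TRUE,
                              covariates = c("age_exam", "female",
                                             "education", "anc_eur",
                                             "anc_afr", "anc_nam_north",
                                             "analysis_group"),
                              method = c("factorized", "fiml_mc")) {
  nodes <- data.frame(
    name = c("G", "bmi21", "D1", "bmi45", "D2", "bmi65"),
    family = c("exogenous", "linear", "logit", "linear", "logit", "linear"),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = "G", to = c("bmi21", "D1", "bmi45", "D2", "bmi65")),
    data.frame(from = "bmi21", to = c("D1", "bmi45")),
    data.frame(from = "D1", to = "bmi45"),
    if (d1_d2) data.frame(from = "D1", to = "D2"),
    data.frame(from = "bmi45", to = c("D2", "bmi65")),
    data.frame(from = "D2", to = "bmi65"))
  path_spec(nodes, edges, covariates, match.arg(method))
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("<path_spec> %d nodes, %d edges, method = %s\n",
              nrow(x$nodes), nrow(x$edges), x$method))
  for (nd in x$nodes$name[x$nodes$family != "exogenous"]) {
    pars <- x$edges$from[x$edges$to == nd]
    cat(sprintf("  %s (%s) ~ %s + covariates\n", nd,
                x$nodes$family[x$nodes$name == nd],
                paste(pars, collapse = " + ")))
  }
  invisible(x)
}

parents_of <- function(spec, node) spec$edges$from[spec$edges$to == node]
endo_nodes <- function(spec) spec$nodes$name[spec$nodes$family != "exogenous"]
node_family <- function(spec, node) {
  spec$nodes$family[spec$nodes$name == node]
}

#' Fit a recursive path model with design-based variance
#'
#' Estimates every node-given-parents equation by survey-weighted
#' pseudo-maximum likelihood and assembles the joint sandwich covariance of
#' all coefficients by stacking the per-equation score contributions before
#' PSU aggregation, so cross-equation covariances (needed for indirect
#' effects) are design-consistent.
#'
#' With no latent variables the joint likelihood of a recursive DAG
#' factorizes node-wise, so on complete data the `"factorized"` fit equals
#' the per-equation fits exactly. Under the age-monotone missingness
#' created by [apply_age_censoring()] -- a node is missing only when all
#' later nodes are missing too -- the missing factors integrate to one and
#' the factorized fit is full-information maximum likelihood for
#' missing-at-random data. The `"fiml_mc"` method additionally recovers
#' information from non-monotone patterns (a BMI mediator missing while a
#' descendant is observed) by Monte-Carlo EM: the missing mediator is
#' integrated over `mc_draws` importance draws from its conditional given
#' its parents, weighted by the likelihood of the observed descendants.
#'
#' Records with missing genotype are excluded from estimation globally
#' (the genotype is exogenous to every equation) with the count reported
#' in `$n_missing_G`; they still contribute zero scores to the variance.
#'
#' @param cohort cohort data frame carrying the node columns (`G`,
#'   `bmi21`, `D1`, `bmi45`, `D2`, `bmi65`; see [clean_weight_history()])
#'   and the covariates.
#' @param spec a [path_spec()].
#' @param design a [survey_design()] over `cohort`; built from the default
#'   design columns when `NULL`.
#' @param method overrides `spec$method` when given.
#' @param mc_draws Monte-Carlo draws per missing mediator (fiml_mc).
#' @param mc_iter maximum EM iterations (fiml_mc).
#' @param mc_tol EM convergence tolerance on the largest coefficient
#'   change (fiml_mc).
#' @param seed substream seed for the Monte-Carlo draws (fiml_mc).
#' @param hazard_risk_sets when `TRUE` (default), a logit node whose
#'   equation omits an earlier logit node as a parent is fit on that
#'   earlier indicator's risk set (records with the earlier indicator 0):
#'   period indicators encode a single first diagnosis, so the later
#'   period's model is a discrete-time hazard among the still-undiagnosed.
#'   Fitting the marginal equation instead (`FALSE`) attenuates the later
#'   period's coefficients.
#' @return object of class `path_fit`: per-node fits (`$node_fits`),
#'   stacked `$coefficients` named `"node~term"`, joint `$vcov`,
#'   `$n_per_node`, `$n_missing_G`, `$method`, `$spec`, `$converged`.
#'   A per-node failure to converge raises an error naming the node and
#'   its final gradient norm.
#' @export
fit_path_model <- function(cohort, spec, design = NULL,
                           method = NULL, mc_draws = 64L, mc_iter = 30L,
                           mc_tol = 1e-6, seed = 1L,
                           hazard_risk_sets = TRUE) {
  stopifnot(inherits(spec, "path_spec"))
  method <- method %||% spec$method
  method <- match.arg(method, c("factorized", "fiml_mc"))
  if (is.null(design)) design <- survey_design(cohort)
  data <- design$data

  g_ok <- !is.na(data$G)
  n_missing_G <- sum(!g_ok)

  pos <- stats::setNames(seq_len(nrow(spec$nodes)), spec$nodes$name)
  logit_nodes <- spec$nodes$name[spec$nodes$family == "logit"]
  fits <- list()
  for (nd in endo_nodes(spec)) {
    fam <- if (node_family(spec, nd) == "logit") "logit" else "linear"
    sub <- g_ok
    if (hazard_risk_sets && fam == "logit") {
      earlier <- logit_nodes[pos[logit_nodes] < pos[nd]]
      for (L in setdiff(earlier, parents_of(spec, nd))) {
        sub <- sub & !is.na(data[[L]]) & data[[L]] == 0
      }
    }
    fit <- fit_weighted_glm(design, nd,
                            c(parents_of(spec, nd), spec$covariates),
                            family = fam, subpop = sub)
    if (!fit$converged) {
      stop_svypath(sprintf(
        "equation for node '%s' did not converge (gradient norm %.3g)",
        nd, fit$grad_norm), "svypath_fit_error")
    }
    fits[[nd]] <- fit
  }

  if (method == "fiml_mc") {
    fits <- fiml_mc_refit(data, spec, design, fits, g_ok, mc_draws,
                          mc_iter, mc_tol, seed, hazard_risk_sets)
  }

  # stack per-record scores across equations and sandwich once, so the
  # joint covariance carries design-based cross-equation terms
  score_list <- lapply(fits, function(f) f$scores)
  stacked <- do.call(cbind, score_list)
  p_per <- vapply(fits, function(f) length(f$coefficients), integer(1))
  coef_names <- unlist(lapply(names(fits), function(nd) {
    paste0(nd, "~", names(fits[[nd]]$coefficients))
  }), use.names = FALSE)
  colnames(stacked) <- coef_names
  V <- psu_score_covariance(design, stacked)
  B <- matrix(0, sum(p_per), sum(p_per))
  off <- 0
  for (f in fits) {
    idx <- off + seq_along(f$coefficients)
    B[idx, idx] <- f$bread
    off <- off + length(f$coefficients)
  }
  Binv <- solve(B)
  joint_vcov <- Binv %*% V %*% Binv
  joint_vcov <- (joint_vcov + t(joint_vcov)) / 2
  dimnames(joint_vcov) <- list(coef_names, coef_names)

  coefs <- stats::setNames(
    unlist(lapply(fits, function(f) unname(f$coefficients))), coef_names)

  structure(list(node_fits = fits, coefficients = coefs,
                 vcov = joint_vcov,
                 n_per_node = vapply(fits, function(f) f$n_used, integer(1)),
                 n_missing_G = n_missing_G, method = method, spec = spec,
                 converged = TRUE),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("<path_fit> method = %s; %d records missing genotype excluded\n",
              x$method, x$n_missing_G))
  for (nd in names(x$node_fits)) {
    cat(sprintf("-- %s (n = %d) --\n", nd, x$n_per_node[[nd]]))
    print(x$node_fits[[nd]]$summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

# residual SD of a fitted linear node (weighted)
node_sigma <- function(fit, design) {
  if (fit$family != "linear") return(NA_real_)
  data <- design$data
  mf <- stats::model.frame(fit$formula, data = data,
                           na.action = stats::na.pass)
  rows <- fit$est_rows
  X <- stats::model.matrix(fit$formula, mf[rows, , drop = FALSE])
  y <- as.numeric(stats::model.response(mf[rows, , drop = FALSE]))
  w <- data[[design$weights_col]][rows]
  mu <- drop(X %*% fit$coefficients)
  sqrt(sum(w * (y - mu)^2) / sum(w))
}

# Monte-Carlo EM over missing continuous mediators. Rows where a linear
# (BMI) node is missing but some endogenous descendant is observed are
# expanded into mc_draws importance copies; the missing value is drawn from
# its conditional given parents at current parameters and re-weighted by
# the likelihood of the row's observed endogenous nodes. M-steps refit
# every equation on the weighted augmented data.
fiml_mc_refit <- function(data, spec, design, fits, g_ok, mc_draws,
                          mc_iter, mc_tol, seed, hazard_risk_sets = TRUE) {
  endo <- endo_nodes(spec)
  logit_nodes <- spec$nodes$name[spec$nodes$family == "logit"]
  risk_sub <- function(nd, dat, base) {
    pos_ <- stats::setNames(seq_len(nrow(spec$nodes)), spec$nodes$name)
    sub <- base
    if (hazard_risk_sets && node_family(spec, nd) == "logit") {
      earlier <- logit_nodes[pos_[logit_nodes] < pos_[nd]]
      for (L in setdiff(earlier, parents_of(spec, nd))) {
        sub <- sub & !is.na(dat[[L]]) & dat[[L]] == 0
      }
    }
    sub
  }
  linear_nodes <- endo[vapply(endo, function(nd)
    node_family(spec, nd) == "linear", logical(1))]

  desc_observed <- rep(FALSE, nrow(data))
  aug_missing <- matrix(FALSE, nrow(data), length(linear_nodes),
                        dimnames = list(NULL, linear_nodes))
  pos <- stats::setNames(seq_len(nrow(spec$nodes)), spec$nodes$name)
  for (ln in linear_nodes) {
    later <- endo[pos[endo] > pos[ln]]
    if (length(later) == 0) next
    obs_later <- Reduce(`|`, lapply(later, function(x) !is.na(data[[x]])))
    # the mediator's own parents must be observed (or imputable earlier
    # linear nodes) for the conditional proposal to be evaluable
    pars_ok <- rep(TRUE, nrow(data))
    for (pp in parents_of(spec, ln)) {
      ok_pp <- !is.na(data[[pp]])
      if (pp %in% linear_nodes) ok_pp <- ok_pp | aug_missing[, pp]
      pars_ok <- pars_ok & ok_pp
    }
    aug_missing[, ln] <- is.na(data[[ln]]) & obs_later & g_ok & pars_ok
  }
  aug_rows <- which(rowSums(aug_missing) > 0)
  if (length(aug_rows) == 0) return(fits)

  S <- mc_draws
  set.seed(substream_seed(seed, "fiml_mc"))
  # fixed uniform/normal draws (common random numbers across EM iterations)
  z_draws <- matrix(stats::rnorm(length(aug_rows) * S * length(linear_nodes)),
                    nrow = length(aug_rows) * S)
  colnames(z_draws) <- linear_nodes

  long_idx <- rep(aug_rows, each = S)
  w_col <- design$weights_col
  base_w <- data[[w_col]][long_idx]

  coef_of <- function(fits) unlist(lapply(fits, function(f)
    unname(f$coefficients)))
  sigmas <- vapply(fits, node_sigma, numeric(1), design = design)

  predict_node <- function(fit, newdata) {
    mf <- stats::model.frame(fit$formula[-2], data = newdata,
                             na.action = stats::na.pass)
    X <- stats::model.matrix(fit$formula[-2], mf)
    drop(X %*% fit$coefficients)
  }

  prev <- coef_of(fits)
  for (it in seq_len(mc_iter)) {
    aug <- data[long_idx, , drop = FALSE]
    logw <- numeric(nrow(aug))
    # draw missing mediators in temporal order from node | parents
    for (ln in linear_nodes) {
      rows_ln <- aug_missing[long_idx, ln]
      if (!any(rows_ln)) next
      mu <- predict_node(fits[[ln]], aug[rows_ln, , drop = FALSE])
      aug[[ln]][rows_ln] <- mu + sigmas[[ln]] * z_draws[rows_ln, ln]
    }
    # importance weight: likelihood of observed endogenous nodes whose
    # parent set includes an imputed mediator
    for (nd in endo) {
      pars <- parents_of(spec, nd)
      imp_par <- intersect(pars, linear_nodes)
      if (length(imp_par) == 0) next
      uses_imp <- Reduce(`|`, lapply(imp_par, function(x)
        aug_missing[long_idx, x]))
      pars_ok <- Reduce(`&`, lapply(pars, function(x) !is.na(aug[[x]])))
      rows_nd <- uses_imp & pars_ok & !is.na(data[[nd]][long_idx])
      if (!any(rows_nd)) next
      eta <- predict_node(fits[[nd]], aug[rows_nd, , drop = FALSE])
      yv <- data[[nd]][long_idx][rows_nd]
      if (node_family(spec, nd) == "logit") {
        pr <- plogis_(eta)
        logw[rows_nd] <- logw[rows_nd] +
          ifelse(yv == 1, log(pr), log1p(-pr))
      } else {
        logw[rows_nd] <- logw[rows_nd] +
          stats::dnorm(yv, eta, sigmas[[nd]], log = TRUE)
      }
    }
    # self-normalize within each original record
    grp <- rep(seq_along(aug_rows), each = S)
    mx <- tapply(logw, grp, max)[grp]
    pw <- exp(logw - mx)
    tot <- tapply(pw, grp, sum)[grp]
    frac <- pw / tot
    aug[[w_col]] <- base_w * frac

    # M-step: refit on original-complete rows plus augmented copies
    aug_all <- rbind(data[-aug_rows, , drop = FALSE], aug)
    d_aug <- survey_design(aug_all, design$strata_col, design$psu_col,
                           w_col, single_psu = design$single_psu)
    g_ok_aug <- !is.na(aug_all$G)
    affected <- union(linear_nodes[colSums(aug_missing) > 0],
                      endo[vapply(endo, function(nd)
                        length(intersect(parents_of(spec, nd),
                                         linear_nodes[colSums(aug_missing) > 0])) > 0,
                        logical(1))])
    new_fits <- fits
    for (nd in intersect(endo, affected)) {
      new_fits[[nd]] <- fit_weighted_glm(
        d_aug, nd, c(parents_of(spec, nd), spec$covariates),
        family = if (node_family(spec, nd) == "logit") "logit" else "linear",
        subpop = risk_sub(nd, aug_all, g_ok_aug))
    }
    sigmas <- vapply(new_fits, function(f)
      if (f$family == "linear" && nrow(f$scores) == nrow(aug_all))
        node_sigma(f, d_aug) else
          if (f$family == "linear") node_sigma(f, design) else NA_real_,
      numeric(1))
    cur <- coef_of(new_fits)
    delta <- max(abs(cur - prev))
    fits <- new_fits
    prev <- cur
    if (delta < mc_tol) break
  }

  # map augmented scores back to original records for the PSU sandwich:
  # expected (Fisher-identity) scores are the importance-weighted sums of
  # complete-data scores over each record's copies
  for (nd in endo) {
    f <- fits[[nd]]
    sc_aug <- f$scores  # rows: (n - n_aug) originals then n_aug * S copies
    if (nrow(sc_aug) == nrow(data)) next  # equation untouched by imputation
    n_keep <- nrow(data) - length(aug_rows)
    sc <- matrix(0, nrow(data), ncol(sc_aug),
                 dimnames = list(NULL, colnames(sc_aug)))
    sc[-aug_rows, ] <- sc_aug[seq_len(n_keep), , drop = FALSE]
    tail_sc <- sc_aug[-seq_len(n_keep), , drop = FALSE]
    sc[aug_rows, ] <- rowsum(tail_sc, rep(seq_along(aug_rows), each = S),
                             reorder = FALSE)
    f$scores <- sc
    fits[[nd]] <- f
  }
  fits
}
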