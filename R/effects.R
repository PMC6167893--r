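#' Enumerate directed paths between two nodes of a path specification
#'
#' Depth-first enumeration over the edge list; because the graph is a
#' recursive DAG the search terminates and every path is visited once.
#'
#' @param spec a [path_spec()].
#' @param source,target node names.
#' @return list of character vectors, each a node sequence from `source`
#'   to `target`.
#' @export
enumerate_paths <- function(spec, source, target) {
  out <- list()
  walk <- function(node, trail) {
    if (node == target) {
      out[[length(out) + 1L]] <<- trail
      return()
    }
    for (nxt in spec$edges$to[spec$edges$from == node]) {
      walk(nxt, c(trail, nxt))
    }
  }
  walk(source, source)
  out
}

edge_coef_name <- function(from, to) paste0(to, "~", from)

#' Direct, indirect and total effects between two nodes
#'
#' Decomposes the association of `source` on `target` on the
#' linear-predictor scale: the direct effect is the edge coefficient of
#' `source` in `target`'s equation (zero if no direct edge exists); each
#' indirect effect is the product of edge coefficients along one directed
#' multi-edge path; the total effect is their sum. Standard errors come
#' from the multivariate delta method using the joint (cross-equation)
#' sandwich covariance of the path fit. Effects into a logit node are also
#' reported exponentiated (odds-ratio scale).
#'
#' Products of coefficients through logit nodes live on the
#' linear-predictor scale by convention; odds ratios do not collapse over
#' mediators, and risk-scale mediation effects are out of scope.
#'
#' @param fit a [fit_path_model()] result.
#' @param source,target node names with `source` temporally before
#'   `target`.
#' @return data frame of class `effect_table` with columns `kind`
#'   (`direct`, `indirect`, `total`), `path`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, and exponentiated columns when `target` is a
#'   logit node. No connecting path yields an empty table, not an error.
#' @export
effect_decomposition <- function(fit, source, target) {
  stopifnot(inherits(fit, "path_fit"))
  spec <- fit$spec
  pos <- stats::setNames(seq_len(nrow(spec$nodes)), spec$nodes$name)
  if (!(source %in% names(pos)) || !(target %in% names(pos))) {
    stop_svypath("source and target must be nodes of the fitted model",
                 "svypath_spec_error")
  }
  if (pos[source] >= pos[target]) {
    stop_svypath("source must precede target in the temporal order",
                 "svypath_spec_error")
  }
  paths <- enumerate_paths(spec, source, target)
  cf <- fit$coefficients
  V <- fit$vcov
  p <- length(cf)

  eff_rows <- list()
  grad_total <- numeric(p)
  est_total <- 0
  add_row <- function(kind, path_str, est, grad) {
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    data.frame(kind = kind, path = path_str, estimate = est, se = se,
               ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
               p_value = if (se > 0) 2 * stats::pnorm(-abs(est / se))
                         else NA_real_,
               stringsAsFactors = FALSE)
  }

  direct_idx <- match(edge_coef_name(source, target), names(cf))
  grad_direct <- numeric(p)
  est_direct <- 0
  if (!is.na(direct_idx)) {
    est_direct <- cf[[direct_idx]]
    grad_direct[direct_idx] <- 1
  }
  if (length(paths) == 0) {
    out <- data.frame(kind = character(), path = character(),
                      estimate = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("effect_table", class(out))
    return(out)
  }
  eff_rows[["direct"]] <- add_row("direct",
                                  paste(c(source, target), collapse = "->"),
                                  est_direct, grad_direct)
  est_total <- est_direct
  grad_total <- grad_direct

  for (pa in paths) {
    if (length(pa) == 2) next  # the direct edge, already reported
    idx <- vapply(seq_len(length(pa) - 1), function(k) {
      nm <- edge_coef_name(pa[k], pa[k + 1])
      i <- match(nm, names(cf))
      if (is.na(i)) {
        stop_svypath(sprintf("coefficient '%s' absent from fit", nm),
                     "svypath_spec_error")
      }
      i
    }, integer(1))
    vals <- cf[idx]
    est <- prod(vals)
    grad <- numeric(p)
    for (k in seq_along(idx)) {
      grad[idx[k]] <- grad[idx[k]] + prod(vals[-k])
    }
    eff_rows[[paste(pa, collapse = "->")]] <-
      add_row("indirect", paste(pa, collapse = "->"), est, grad)
    est_total <- est_total + est
    grad_total <- grad_total + grad
  }
  eff_rows[["total"]] <- add_row("total",
                                 paste(c(source, "...", target),
                                       collapse = "->"),
                                 est_total, grad_total)
  out <- do.call(rbind, eff_rows)
  rownames(out) <- NULL
  if (node_family(spec, target) == "logit") {
    out$exp_estimate <- exp(out$estimate)
    out$exp_ci_low <- exp(out$ci_low)
    out$exp_ci_high <- exp(out$ci_high)
  }
  class(out) <- c("effect_table", class(out))
  out
}

#' Odds ratio for one edge into a logit node
#'
#' Exponentiates the edge coefficient with a normal-reference confidence
#' interval: `OR = exp(b)`, `CI = exp(b +/- 1.96 SE)`.
#'
#' @param fit a [fit_path_model()] result.
#' @param from,to edge endpoints; `to` must be a logit-family node.
#' @return one-row data frame with `estimate` (log-odds), `se`,
#'   `odds_ratio`, `or_ci_low`, `or_ci_high`, `p_value`.
#' @export
edge_odds_ratio <- function(fit, from, to) {
  stopifnot(inherits(fit, "path_fit"))
  if (node_family(fit$spec, to) != "logit") {
    stop_svypath(sprintf("node '%s' is not a logit node; odds ratios are undefined",
                         to), "svypath_fit_error")
  }
  nm <- edge_coef_name(from, to)
  i <- match(nm, names(fit$coefficients))
  if (is.na(i)) {
    stop_svypath(sprintf("no fitted edge %s -> %s", from, to),
                 "svypath_fit_error")
  }
  b <- fit$coefficients[[i]]
  se <- sqrt(fit$vcov[i, i])
  data.frame(edge = paste(from, to, sep = "->"), estimate = b, se = se,
             odds_ratio = exp(b),
             or_ci_low = exp(b - 1.96 * se),
             or_ci_high = exp(b + 1.96 * se),
             p_value = 2 * stats::pnorm(-abs(b / se)),
             stringsAsFactors = FALSE)
}
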