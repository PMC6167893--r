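#' Genotype counts for a biallelic variant
#'
#' Container for the three genotype counts of a biallelic SNP, ordered as
#' (homozygous reference, heterozygous, homozygous risk). The risk-allele
#' frequency is derived as `p = (n_het + 2 n_hom_risk) / (2 N)`.
#'
#' @param n_ref_ref,n_het,n_risk_risk non-negative genotype counts.
#' @return an object of class `genotype_counts` with elements `counts`,
#'   `n`, `p`.
#' @export
#' @examples
#' genotype_counts(5040, 3373, 618)$p  # 0.255
genotype_counts <- function(n_ref_ref, n_het, n_risk_risk) {
  counts <- c(n_ref_ref = n_ref_ref, n_het = n_het,
              n_risk_risk = n_risk_risk)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_svypath("genotype counts must be non-negative integers",
                 "svypath_genetics_error")
  }
  n <- sum(counts)
  if (n <= 0) {
    stop_svypath("total genotype count must be positive",
                 "svypath_genetics_error")
  }
  structure(list(counts = counts, n = n,
                 p = (counts[[2]] + 2 * counts[[3]]) / (2 * n)),
            class = "genotype_counts")
}

#' Count genotype classes from a dosage vector
#'
#' @param dosage integer vector of risk-allele dosages in `{0, 1, 2}`
#'   (missing dropped).
#' @return a [genotype_counts()] object.
#' @export
genotype_counts_from_dosage <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  if (!all(dosage %in% 0:2)) {
    stop_svypath("dosages must be 0, 1 or 2", "svypath_genetics_error")
  }
  genotype_counts(sum(dosage == 0), sum(dosage == 1), sum(dosage == 2))
}

#' Additive risk-allele dosage coding
#'
#' Codes an unordered allele pair as the count of risk alleles (e.g. with
#' risk allele T at a C/T SNP: CC = 0, CT = 1, TT = 2). The coding is
#' invariant to the order of the two alleles, and missing genotypes
#' propagate.
#'
#' @param genotype character vector of allele pairs, as two characters
#'   (`"CT"`) or separated by `/` or `|` (`"C/T"`); `NA`, `""`, `"./."`
#'   are missing.
#' @param risk_allele,ref_allele single-character alleles.
#' @param variant_id label used in error messages.
#' @return integer dosage vector in `{0, 1, 2, NA}`. Any allele outside
#'   `{ref_allele, risk_allele}` raises an error naming the variant.
#' @export
additive_code <- function(genotype, risk_allele = "T", ref_allele = "C",
                          variant_id = "variant") {
  stopifnot(nchar(risk_allele) == 1, nchar(ref_allele) == 1)
  g <- gsub("[/|]", "", as.character(genotype))
  g[g %in% c("", "..", ".")] <- NA_character_
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  if (any(nchar(g[ok]) != 2)) {
    stop_svypath(sprintf("malformed genotype for %s: expected an allele pair",
                         variant_id), "svypath_genetics_error")
  }
  a1 <- substr(g, 1, 1)
  a2 <- substr(g, 2, 2)
  alleles <- c(a1[ok], a2[ok])
  bad <- setdiff(unique(alleles), c(risk_allele, ref_allele))
  if (length(bad) > 0) {
    stop_svypath(sprintf("allele(s) %s not in {%s, %s} for %s",
                         paste(bad, collapse = ","), ref_allele,
                         risk_allele, variant_id),
                 "svypath_genetics_error")
  }
  out[ok] <- (a1[ok] == risk_allele) + (a2[ok] == risk_allele)
  names(out) <- names(genotype)
  out
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square test (no continuity correction)
#' comparing observed genotype counts to the expectations
#' `N * ((1-p)^2, 2p(1-p), p^2)` at the estimated allele frequency `p`.
#' The conditional exact test (summing the probabilities of heterozygote
#' counts no more probable than the observed one, given the allele counts)
#' is available as `method = "exact"`.
#'
#' @param counts a [genotype_counts()] object or numeric vector of the
#'   three counts.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return list of class `hwe_test` with `chi2` (`NA` for the exact
#'   method), `p_value`, `expected`, `method`.
#' @export
#' @examples
#' hwe_test(genotype_counts(5040, 3373, 618))  # p = 0.097, rounds to 0.10
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (!inherits(counts, "genotype_counts")) {
    stopifnot(is.numeric(counts), length(counts) == 3)
    counts <- genotype_counts(counts[1], counts[2], counts[3])
  }
  p <- counts$p
  expected <- counts$n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(expected == 0)) {
    stop_svypath("monomorphic variant: an expected genotype count is zero",
                 "svypath_genetics_error")
  }
  if (method == "chisq") {
    chi2 <- sum((counts$counts - expected)^2 / expected)
    p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p_value <- hwe_exact_p(counts$counts)
  }
  structure(list(chi2 = chi2, p_value = p_value, expected = expected,
                 observed = counts$counts, method = method),
            class = "hwe_test")
}

# conditional exact test: distribution of the heterozygote count given the
# minor-allele count under random mating, in log space for large N
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_rare <- min(counts[[2]] + 2 * counts[[3]], counts[[2]] + 2 * counts[[1]])
  obs_het <- counts[[2]]
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  log_prob <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_rare + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(obs_het, hets)] * (1 + 1e-12)])
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("<hwe_test> method = %s\n", x$method))
  cat(sprintf("  observed %s, expected %s\n",
              paste(x$observed, collapse = "/"),
              paste(round(x$expected, 1), collapse = "/")))
  if (!is.na(x$chi2)) cat(sprintf("  chi2 = %.4f (1 df), ", x$chi2))
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}

#' Prune close relatives from a cohort by kinship
#'
#' Pairs with estimated genome sharing `lower < pi_hat < upper` (strict;
#' defaults 0.35 and 0.98) are close relatives, of which only one member
#' may remain. Pairs at or above `upper` are near-duplicates, routed to
#' `attr(, "duplicates")` for separate handling and not pruned here.
#'
#' The default `"optimal"` method removes, within each connected component
#' of the flagged-pair graph, an exact minimum-size set of individuals such
#' that no flagged pair survives, choosing among the minimum-size sets the
#' one that drops the members with the fewest non-missing weight
#' measurements (ties drop the lexicographically larger id). For a single
#' flagged pair this reduces to dropping the member with fewer weight
#' measurements. `method = "greedy"` instead resolves flagged pairs one at
#' a time in order of descending `pi_hat` with the same within-pair rule;
#' it can remove more individuals than necessary on star-shaped components.
#'
#' @param pairs data frame with columns `id1`, `id2`, `pi_hat`.
#' @param n_weights named integer vector mapping every id appearing in
#'   flagged pairs to its count of non-missing weight measurements.
#' @param lower,upper open-interval bounds on `pi_hat` defining a flagged
#'   pair.
#' @param method `"optimal"` (default) or `"greedy"`.
#' @param max_exact largest component size solved exactly; larger
#'   components fall back to greedy with a warning.
#' @return character vector of retained ids (all ids in `n_weights` never
#'   flagged, plus the kept members of flagged components), with attributes
#'   `dropped` and `duplicates`.
#' @export
prune_relatives <- function(pairs, n_weights, lower = 0.35, upper = 0.98,
                            method = c("optimal", "greedy"),
                            max_exact = 24L) {
  method <- match.arg(method)
  stopifnot(all(c("id1", "id2", "pi_hat") %in% names(pairs)))
  ids_in_pairs <- unique(c(pairs$id1, pairs$id2))
  missing_ids <- setdiff(ids_in_pairs, names(n_weights))
  if (length(missing_ids) > 0) {
    stop_svypath(sprintf("kinship pair id(s) absent from cohort: %s",
                         paste(utils::head(missing_ids, 5), collapse = ", ")),
                 "svypath_genetics_error")
  }
  if (any(pairs$id1 == pairs$id2)) {
    stop_svypath("kinship pairs must link two distinct ids",
                 "svypath_genetics_error")
  }
  dup <- pairs[pairs$pi_hat >= upper, , drop = FALSE]
  flagged <- pairs[pairs$pi_hat > lower & pairs$pi_hat < upper, , drop = FALSE]
  all_ids <- names(n_weights)
  if (nrow(flagged) == 0) {
    return(structure(all_ids, dropped = character(), duplicates = dup))
  }

  if (method == "greedy") {
    dropped <- character()
    ord <- order(-flagged$pi_hat, flagged$id1, flagged$id2)
    for (k in ord) {
      a <- flagged$id1[k]; b <- flagged$id2[k]
      if (a %in% dropped || b %in% dropped) next
      dropped <- c(dropped, pick_member_to_drop(a, b, n_weights))
    }
  } else {
    comp <- graph_components(flagged$id1, flagged$id2)
    dropped <- character()
    for (nodes in comp) {
      sub <- flagged[flagged$id1 %in% nodes & flagged$id2 %in% nodes, ,
                     drop = FALSE]
      if (length(nodes) > max_exact) {
        warning(sprintf(
          "relatedness component of %d individuals exceeds max_exact; using greedy resolution",
          length(nodes)))
        sub_keep <- prune_relatives(sub, n_weights[nodes], lower, upper,
                                    method = "greedy")
        dropped <- c(dropped, attr(sub_keep, "dropped"))
      } else {
        dropped <- c(dropped, min_removal_set(nodes, sub, n_weights))
      }
    }
  }
  keep <- setdiff(all_ids, dropped)
  structure(keep, dropped = dropped, duplicates = dup)
}

pick_member_to_drop <- function(a, b, n_weights) {
  wa <- n_weights[[a]]; wb <- n_weights[[b]]
  if (wa < wb) a
  else if (wb < wa) b
  else max(a, b)  # tie: lexicographically larger id dropped
}

graph_components <- function(id1, id2) {
  nodes <- unique(c(id1, id2))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(id1)) {
    ra <- find(id1[k]); rb <- find(id2[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

# exact minimum vertex cover of one flagged component by branch and bound;
# among minimum covers prefers removing lower total weight-measurement
# counts, then the cover whose sorted id string is lexicographically
# largest (so ties drop later ids)
min_removal_set <- function(nodes, sub, n_weights) {
  edges <- cbind(match(sub$id1, nodes), match(sub$id2, nodes))
  nw <- n_weights[nodes]
  best <- list(size = Inf, wsum = Inf, key = "", set = integer())
  score_key <- function(set) {
    paste(sort(nodes[set], decreasing = TRUE), collapse = "|")
  }
  consider <- function(set) {
    size <- length(set)
    wsum <- sum(nw[set])
    key <- score_key(set)
    if (size < best$size ||
        (size == best$size && (wsum < best$wsum ||
          (wsum == best$wsum && key > best$key)))) {
      best <<- list(size = size, wsum = wsum, key = key, set = set)
    }
  }
  recurse <- function(removed, edge_alive) {
    if (length(removed) > best$size) return()
    alive <- which(edge_alive)
    if (length(alive) == 0) {
      consider(removed)
      return()
    }
    if (length(removed) == best$size) return()  # can only get worse
    e <- alive[1]
    for (v in edges[e, ]) {
      covered <- edge_alive & !(edges[, 1] == v | edges[, 2] == v)
      recurse(c(removed, v), covered)
    }
  }
  recurse(integer(), rep(TRUE, nrow(sub)))
  nodes[best$set]
}

#' Read the genotype column of a single biallelic variant from a VCF
#'
#' Extracts per-sample allele pairs for one variant from a VCF v4.x file,
#' keyed by sample name, with `"./."` read as missing. The result feeds
#' [additive_code()] with the ALT allele as the risk allele.
#'
#' @param path VCF file path (plain text).
#' @param variant_id the `ID` field of the wanted row.
#' @return named character vector of allele pairs (e.g. `"CT"`), with
#'   attributes `ref` and `alt`. Errors if the variant is absent,
#'   multiallelic, or has malformed genotype calls.
#' @export
read_variant_vcf <- function(path, variant_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  row <- which(ids == variant_id)
  if (length(row) == 0) {
    stop_svypath(sprintf("variant '%s' not found in %s", variant_id, path),
                 "svypath_genetics_error")
  }
  if (length(row) > 1) {
    stop_svypath(sprintf("variant '%s' appears %d times in %s", variant_id,
                         length(row), path), "svypath_genetics_error")
  }
  ref <- vcfR::getREF(v)[row]
  alt <- vcfR::getALT(v)[row]
  if (grepl(",", alt) || nchar(ref) != 1 || nchar(alt) != 1) {
    stop_svypath(sprintf("variant '%s' is not a biallelic SNP (REF=%s ALT=%s)",
                         variant_id, ref, alt), "svypath_genetics_error")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[row, ]
  parse_one <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_character_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2 || !all(parts %in% c("0", "1"))) {
      stop_svypath(sprintf("malformed GT '%s' for variant '%s'", g,
                           variant_id), "svypath_genetics_error")
    }
    paste0(ifelse(parts == "0", ref, alt), collapse = "")
  }
  out <- vapply(gt, parse_one, character(1))
  structure(out, ref = ref, alt = alt)
}
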