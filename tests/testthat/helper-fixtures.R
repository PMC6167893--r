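# shared fixtures, all generated in code

small_scenario <- function(seed = 42, ...) {
  scenario_config(n_strata = 4, psus_per_stratum = 3, persons_per_psu = 100,
                  seed = seed, ...)
}

# complete-data cohort (no age censoring) with QC-derived BMI columns
complete_cohort <- function(seed = 42, n_per_psu = 200, ...) {
  cfg <- scenario_config(n_strata = 4, psus_per_stratum = 3,
                         persons_per_psu = n_per_psu, seed = seed, ...)
  clean_weight_history(simulate_cohort(cfg, censor = FALSE))
}

# tiny hand-enumerable two-stratum design: 2 strata x 2 PSUs, weights 1..8
toy_design <- function() {
  d <- data.frame(
    id = letters[1:8],
    stratum = rep(c("A", "B"), each = 4),
    psu = c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p4"),
    sampling_weight = 1:8,
    y = c(2, 4, 3, 7, 6, 1, 8, 5),
    x = c(0, 1, 0, 1, 1, 0, 1, 0))
  survey_design(d)
}

# plain-text single-variant VCF written on the fly
write_toy_vcf <- function(path, gts = c(S1 = "0/0", S2 = "0/1", S3 = "1/1"),
                          id = "rs7903146", ref = "C", alt = "T") {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(gts)), collapse = "\t"),
    paste(c("10", "114758349", id, ref, alt, ".", "PASS", ".", "GT",
            unname(gts)), collapse = "\t"))
  writeLines(lines, path)
  path
}

# brute-force minimum removal over all subsets: smallest sets covering all
# flagged pairs (ties enumerated)
brute_min_removal <- function(ids, pairs) {
  flagged <- pairs[pairs$pi_hat > 0.35 & pairs$pi_hat < 0.98, , drop = FALSE]
  if (nrow(flagged) == 0) return(list(size = 0, sets = list(character())))
  best_size <- length(ids)
  sets <- list()
  for (k in 0:length(ids)) {
    if (k > best_size) break
    for (comb in utils::combn(ids, k, simplify = FALSE)) {
      ok <- !any(!(flagged$id1 %in% comb) & !(flagged$id2 %in% comb))
      if (ok) {
        best_size <- k
        sets[[length(sets) + 1L]] <- comb
      }
    }
    if (length(sets) > 0) break
  }
  list(size = best_size, sets = sets)
}

expect_no_flagged_pair <- function(keep, pairs) {
  flagged <- pairs[pairs$pi_hat > 0.35 & pairs$pi_hat < 0.98, , drop = FALSE]
  bad <- flagged$id1 %in% keep & flagged$id2 %in% keep
  expect_false(any(bad))
}
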