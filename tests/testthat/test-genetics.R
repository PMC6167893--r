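test_that("additive coding counts risk alleles and is order-invariant", {
  expect_equal(additive_code(c("CC", "CT", "TT")), c(0L, 1L, 2L))
  expect_equal(additive_code("TC"), additive_code("CT"))
  expect_equal(additive_code("C/T"), 1L)
  expect_equal(additive_code("T|T"), 2L)
  expect_true(is.na(additive_code(NA_character_)))
  expect_true(is.na(additive_code("./.")))
  expect_error(additive_code("AG", variant_id = "rs0001"),
               regexp = "rs0001", class = "svypath_genetics_error")
})

test_that("HWE chi-square matches the closed form on published-style counts", {
  # brute-force expectation: p = (3373 + 2*618)/(2*9031) = 0.25518,
  # chi2 = sum (obs - exp)^2 / exp = 2.7488, p = 0.0973
  h <- hwe_test(genotype_counts(5040, 3373, 618))
  expect_equal(h$chi2, 2.748772, tolerance = 1e-5)
  expect_equal(h$p_value, 0.0973291, tolerance = 1e-5)
  expect_equal(round(h$p_value, 2), 0.10)

  # perfect equilibrium at p = 0.5
  h0 <- hwe_test(c(2500, 5000, 2500))
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p_value, 1)

  # gross departure: all homozygotes
  hx <- hwe_test(c(10, 0, 10))
  expect_gt(hx$chi2, 15)
  expect_lt(hx$p_value, 1e-4)

  expect_error(hwe_test(c(50, 0, 0)), class = "svypath_genetics_error")
})

test_that("exact HWE test is a valid option and agrees with chi-square at scale", {
  he <- hwe_test(genotype_counts(5040, 3373, 618), method = "exact")
  expect_true(he$p_value > 0 && he$p_value <= 1)
  expect_equal(he$p_value, 0.0973, tolerance = 0.02)
  # tiny table against direct enumeration of the conditional distribution
  he2 <- hwe_test(c(4, 2, 4), method = "exact")
  expect_true(he2$p_value <= 1)
})

test_that("HWE p-values are uniform under the null (KS over replicates)", {
  set.seed(77)
  pvals <- replicate(1000, {
    g <- stats::rbinom(500, 2, 0.3)
    hwe_test(genotype_counts_from_dosage(g))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("relative pruning drops the fewest-weights member and leaves no flagged pair", {
  nw <- c(A = 4, B = 2, C = 4, D = 4)
  pairs <- data.frame(id1 = "A", id2 = "B", pi_hat = 0.5)
  keep <- prune_relatives(pairs, nw)
  expect_true("A" %in% keep)   # B has fewer weight measurements
  expect_false("B" %in% keep)

  # pi-hat window is open: 0.99 is duplicate territory, 0.35 not flagged
  keep <- prune_relatives(data.frame(id1 = "A", id2 = "B", pi_hat = 0.99), nw)
  expect_setequal(keep, names(nw))
  expect_equal(nrow(attr(keep, "duplicates")), 1)
  keep <- prune_relatives(data.frame(id1 = "A", id2 = "B", pi_hat = 0.35), nw)
  expect_setequal(keep, names(nw))

  # triangle with equal counts: exactly one member remains, none flagged
  tri <- data.frame(id1 = c("A", "B", "A"), id2 = c("B", "C", "C"),
                    pi_hat = c(0.5, 0.5, 0.5))
  keep <- prune_relatives(tri, nw)
  expect_equal(length(attr(keep, "dropped")), 2)
  expect_no_flagged_pair(keep, tri)

  expect_error(prune_relatives(data.frame(id1 = "A", id2 = "Z",
                                          pi_hat = 0.5), nw),
               regexp = "Z", class = "svypath_genetics_error")
})

test_that("pruning matches exhaustive minimal-removal search on small graphs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    ids <- LETTERS[seq_len(n)]
    n_edges <- sample(1:min(10, n * (n - 1) / 2), 1)
    all_pairs <- t(utils::combn(ids, 2))
    pick <- sample(nrow(all_pairs), n_edges)
    pairs <- data.frame(id1 = all_pairs[pick, 1], id2 = all_pairs[pick, 2],
                        pi_hat = round(stats::runif(n_edges, 0.4, 0.9), 3))
    nw <- stats::setNames(sample(0:4, n, replace = TRUE), ids)
    keep <- prune_relatives(pairs, nw)
    expect_no_flagged_pair(keep, pairs)
    brute <- brute_min_removal(ids, pairs)
    expect_equal(length(attr(keep, "dropped")), brute$size)
  }
})

test_that("pruning output never retains a flagged pair on larger random graphs", {
  set.seed(202)
  for (rep in 1:10) {
    n <- 50
    ids <- sprintf("P%02d", 1:n)
    m <- 60
    i1 <- sample(ids, m, replace = TRUE)
    i2 <- sample(ids, m, replace = TRUE)
    okp <- i1 != i2
    pairs <- data.frame(id1 = i1[okp], id2 = i2[okp],
                        pi_hat = stats::runif(sum(okp), 0.2, 0.99))
    nw <- stats::setNames(sample(0:4, n, replace = TRUE), ids)
    for (meth in c("optimal", "greedy")) {
      keep <- suppressWarnings(prune_relatives(pairs, nw, method = meth))
      expect_no_flagged_pair(keep, pairs)
    }
  }
})

test_that("single-variant VCF ingestion yields allele pairs and catches malformed input", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, gts = c(S1 = "0/0", S2 = "0/1", S3 = "1/1",
                              S4 = "./."))
  gt <- read_variant_vcf(path, "rs7903146")
  expect_equal(unname(gt[1:3]), c("CC", "CT", "TT"))
  expect_true(is.na(gt[["S4"]]))
  dos <- additive_code(gt, risk_allele = attr(gt, "alt"),
                       ref_allele = attr(gt, "ref"))
  cnt <- genotype_counts_from_dosage(dos)
  expect_equal(unname(cnt$counts), c(1, 1, 1))

  expect_error(read_variant_vcf(path, "rs999"),
               class = "svypath_genetics_error")
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path2, alt = "T,G")
  expect_error(read_variant_vcf(path2, "rs7903146"),
               regexp = "biallelic", class = "svypath_genetics_error")
  path3 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path3, gts = c(S1 = "0/2", S2 = "0/1", S3 = "1/1"))
  expect_error(read_variant_vcf(path3, "rs7903146"),
               class = "svypath_genetics_error")
})
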