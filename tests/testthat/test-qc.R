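test_that("HWE chi-square p-value matches expectation and edge cases", {
  expect_equal(hwe_chisq_pvalue(25, 50, 25), 1)
  expect_equal(hwe_chisq_pvalue(50, 0, 0), 1)
  # (10, 80, 10): expected (25, 50, 25) -> chi2 = 9 + 18 + 9 = 36
  expect_equal(hwe_chisq_pvalue(10, 80, 10),
               pchisq(36, 1, lower.tail = FALSE))
  expect_error(hwe_chisq_pvalue(-1, 2, 3), "negative")
  for (case in list(c(12, 5, 3), c(0, 10, 0), c(7, 7, 7), c(1, 0, 99))) {
    expect_equal(hwe_chisq_pvalue(case[1], case[2], case[3]),
                 oracle_hwe(case[1], case[2], case[3]))
  }
})

test_that("panel filters remove what they should and tally removals", {
  # 10 samples, constructed frequencies; SNP2 has low MAF
  freqs <- c(0.5, 0.02, 0.5, 0.5)
  set.seed(7)
  H <- sapply(freqs, function(f) rbinom(20, 1, f))
  H[, 2] <- c(rep(1L, 1), rep(0L, 19))      # MAF = 0.05 - eps
  p <- panel_from_H(H)
  out <- filter_panel(p, qc_thresholds(maf = 0.06))
  expect_equal(out$report$maf_removed, 1)
  expect_equal(n_snps(out$panel), 3)

  # duplicate id: second copy dropped
  p2 <- p
  p2$variants$id[2] <- p2$variants$id[1]
  out2 <- filter_panel(p2, qc_thresholds(maf = 0, hwe_p = 0))
  expect_equal(out2$report$duplicate_removed, 1)

  # sex chromosome removal
  p3 <- p
  p3$variants$chrom <- c("1", "X", "1", "1")
  out3 <- filter_panel(p3, qc_thresholds(maf = 0, hwe_p = 0),
                       sex_chroms = "X")
  expect_equal(out3$report$sex_unplaced_removed, 1)

  # a clean panel passes identically and filtering is idempotent
  clean <- random_panel(n_snps = 15, n_per_pop = 10, pops = "p1", seed = 2)
  r1 <- filter_panel(clean, qc_thresholds(maf = 0.01, hwe_p = 1e-12))
  r2 <- filter_panel(r1$panel, qc_thresholds(maf = 0.01, hwe_p = 1e-12))
  expect_equal(r2$panel$H, r1$panel$H)
  expect_equal(r2$report$snps_retained, r1$report$snps_retained)

  # removal counts are additive
  rep3 <- out3$report
  expect_equal(rep3$input_snps - rep3$sex_unplaced_removed -
                 rep3$duplicate_removed - rep3$snp_callrate_removed -
                 rep3$maf_removed - rep3$hwe_removed,
               rep3$snps_retained)

  expect_error(filter_panel(p, qc_thresholds(maf = 1)), "empty panel")
})

test_that("sample call-rate filter removes sparse samples", {
  p <- random_panel(n_snps = 10, n_per_pop = 5, pops = "p1", seed = 4)
  p$H[1, 1:6] <- NA_integer_   # sample 1 call rate 0.4
  out <- filter_panel(p, qc_thresholds(sample_call_rate = 0.8, maf = 0,
                                       hwe_p = 0, snp_call_rate = 0))
  expect_equal(out$report$sample_callrate_removed, 1)
  expect_equal(n_samples(out$panel), 4)
})

test_that("merge keeps mutual SNPs and checks alleles strand-safely", {
  a <- random_panel(n_snps = 4, n_per_pop = 3, pops = "pa", seed = 1)
  b <- random_panel(n_snps = 4, n_per_pop = 3, pops = "pb", seed = 2)
  b$variants$pos[4] <- b$variants$pos[4] + 5L   # s4 no longer shared
  m <- merge_panels(a, b)
  expect_equal(n_snps(m), 3)
  expect_equal(n_samples(m), 6)
  expect_equal(m$H[1:6, ], a$H[, 1:3])

  # complemented alleles still match (strand flip)
  b2 <- random_panel(n_snps = 4, n_per_pop = 3, pops = "pb", seed = 2)
  b2$variants$ref <- "T"; b2$variants$alt <- "G"
  expect_equal(n_snps(merge_panels(a, b2)), 4)

  # true allele mismatch errors with the SNP named
  b3 <- random_panel(n_snps = 4, n_per_pop = 3, pops = "pb", seed = 2)
  b3$variants$alt[2] <- "G"
  expect_error(merge_panels(a, b3), "s2")

  expect_error(merge_panels(a, a), "disjoint")
})

test_that("IBS matrix matches shared-allele counting", {
  # identical samples -> 1; opposite homozygotes -> 0; het vs hom -> 0.5
  H <- rbind(c(0L, 1L), c(0L, 1L),   # sample 1: genotypes 0, 2
             c(0L, 1L), c(0L, 1L),   # sample 2: identical
             c(1L, 0L), c(1L, 0L),   # sample 3: opposite
             c(0L, 0L), c(1L, 1L))   # sample 4: het at both
  p <- panel_from_H(H)
  M <- ibs_matrix(p)
  expect_equal(unname(M[1, 2]), 1)
  expect_equal(unname(M[1, 3]), 0)
  expect_equal(unname(M[1, 4]), 0.5)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 4))

  # invariant to sample permutation (up to the same permutation)
  p2 <- subset_panel(p, samples = c(3, 1, 4, 2))
  M2 <- ibs_matrix(p2)
  expect_equal(unname(M2), unname(M[c(3, 1, 4, 2), c(3, 1, 4, 2)]))
})

test_that("PCA of a two-block IBS matrix separates the blocks", {
  n <- 8
  M <- matrix(0.5, n, n)
  M[1:4, 1:4] <- 1
  M[5:8, 5:8] <- 1
  res <- pca_from_ibs(M)
  pc1 <- res$coords[, 1]
  expect_true(all(sign(pc1[1:4]) == sign(pc1[1])))
  expect_true(all(sign(pc1[5:8]) == -sign(pc1[1])))
  # centering property: adding a constant changes nothing
  res2 <- pca_from_ibs(M + 0.17)
  expect_equal(abs(res2$coords), abs(res$coords), tolerance = 1e-8)
  # degenerate: identical samples collapse to the origin
  res3 <- pca_from_ibs(matrix(1, 5, 5))
  expect_equal(max(abs(res3$coords)), 0, tolerance = 1e-8)
  expect_error(pca_from_ibs(matrix(c(1, 0.2, 0.4, 1), 2, 2)), "symmetric")
})

test_that("a sample far from its breed cluster is flagged as outlier", {
  set.seed(11)
  # two tight clusters plus one displaced sample labelled with breed A
  xy <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
              matrix(rnorm(20, 5, 0.05), 10, 2),
              c(5, 5))
  D <- as.matrix(dist(xy))
  ibs <- 1 - D / max(D)
  breeds <- c(rep("A", 10), rep("B", 10), "A")
  res <- pca_from_ibs(ibs, breeds = breeds, outlier_z = 3)
  expect_true(res$outlier[21])
  expect_false(any(res$outlier[1:20]))
})
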