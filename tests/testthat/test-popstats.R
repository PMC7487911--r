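test_that("running median reproduces window medians with constant ends", {
  expect_equal(running_median(c(5, 1, 7), 1), c(5, 1, 7))
  expect_equal(running_median(rep(3, 6), 5), rep(3, 6))
  expect_equal(running_median(c(1, 9, 2, 3), 3), c(2, 2, 3, 3))
  # window wider than the vector collapses to the global median
  expect_equal(running_median(c(1, 2, 9), 5), rep(2, 3))
  expect_error(running_median(1:4, 2), "odd")
  set.seed(5)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    k <- sample(c(3, 5, 7, 9), 1)
    x <- rnorm(n)
    expect_equal(running_median(x, k), oracle_runmed(x, k))
  }
})

test_that("smoothing stays within input range and fixes constants", {
  set.seed(8)
  x <- rnorm(100)
  sm <- running_median(x, 31)
  expect_true(all(sm >= min(x) & sm <= max(x)))
  expect_equal(running_median(rep(1.5, 40), 31), rep(1.5, 40))
})

test_that("Weir-Cockerham FST handles fixed differences and clipping", {
  # fixed difference, no heterozygotes -> theta = 1
  freqs <- list(p1 = rep(1, 5), p2 = rep(0, 5))
  H <- rbind(matrix(1L, 10, 5), matrix(0L, 10, 5))
  samples <- rbind(toy_samples(5, "p1"), toy_samples(5, "p2"))
  p <- haplotype_panel(toy_variants(5), samples, H)
  fst <- wc_fst_per_snp(p, "p1", smooth_k = NA)
  expect_equal(fst$values, rep(1, 5))

  # identical groups -> raw theta <= 0 -> clipped to 0
  Hsame <- rbind(matrix(rep(c(0L, 1L), 5 * 5), 10, 5),
                 matrix(rep(c(0L, 1L), 5 * 5), 10, 5))
  p2 <- haplotype_panel(toy_variants(5), samples, Hsame)
  expect_equal(wc_fst_per_snp(p2, "p1", smooth_k = NA)$values, rep(0, 5))

  expect_error(wc_fst_per_snp(p, "nope"), "focal population")
})

test_that("per-SNP FST equals the independent variance-component oracle", {
  set.seed(21)
  for (i in 1:200) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    g1 <- sample(0:2, n1, replace = TRUE)
    g2 <- sample(0:2, n2, replace = TRUE)
    if (length(unique(c(g1, g2))) == 1) next
    # build a panel realizing exactly these genotypes at one SNP;
    # haplotype layout is hapA then hapB per sample
    expand <- function(g) unlist(lapply(g, function(x)
      if (x == 0) c(0L, 0L) else if (x == 1) c(0L, 1L) else c(1L, 1L)))
    hcol <- c(expand(g1), expand(g2))
    H <- cbind(hcol, hcol)   # two identical SNPs so the panel is non-trivial
    samples <- rbind(toy_samples(n1, "a"), toy_samples(n2, "b"))
    p <- haplotype_panel(toy_variants(2), samples, H)
    got <- wc_fst_per_snp(p, "a", smooth_k = NA)$values[1]
    want <- oracle_wc_fst(c(n1, n2), c(mean(g1) / 2, mean(g2) / 2),
                          c(mean(g1 == 1), mean(g2 == 1)))
    if (!is.finite(want)) want <- 0
    expect_equal(got, max(0, want), tolerance = 1e-12)
  }
})

test_that("FST is invariant to sample order and bounded in [0,1]", {
  p <- random_panel(n_snps = 30, n_per_pop = 8, seed = 31)
  f1 <- wc_fst_per_snp(p, "p1")$values
  perm <- sample(seq_len(n_samples(p)))
  f2 <- wc_fst_per_snp(subset_panel(p, samples = perm), "p1")$values
  expect_equal(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
})

test_that("site pi matches pairwise-difference enumeration", {
  # n = 2 chromosomes, one of each allele -> pi = 1
  p <- panel_from_H(rbind(c(0L, 0L), c(1L, 0L)))
  expect_equal(site_pi(p, "p1", smooth_k = NA)$values, c(1, 0))
  # n = 4, single alt -> 2*3*1/12 = 0.5
  p2 <- panel_from_H(rbind(c(1L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L)))
  expect_equal(site_pi(p2, "p1", smooth_k = NA)$values[1], 0.5)
  set.seed(13)
  for (i in 1:200) {
    nh <- 2 * sample(2:8, 1)
    alleles <- rbinom(nh, 1, runif(1, 0.1, 0.9))
    H <- cbind(as.integer(alleles), 0L)
    p3 <- panel_from_H(H)
    expect_equal(site_pi(p3, "p1", smooth_k = NA)$values[1],
                 oracle_site_pi(alleles))
  }
})

test_that("pi is zero exactly at sites monomorphic in the population", {
  p <- random_panel(n_snps = 40, n_per_pop = 6, seed = 17)
  raw <- site_pi(p, "p1", smooth_k = NA)$values
  mono <- apply(dcmscan:::pop_hap_matrix(p, "p1"), 2,
                function(x) length(unique(x)) == 1)
  expect_equal(raw == 0, mono)
  expect_true(all(raw >= 0 & raw <= 1))
})

test_that("binned Tajima's D matches the textbook-constants oracle", {
  # n = 10 chromosomes, 5 segregating sites with alt counts (1,1,2,5,9)
  counts <- c(1, 1, 2, 5, 9)
  H <- sapply(counts, function(k) c(rep(1L, k), rep(0L, 10 - k)))
  p <- panel_from_H(H)
  d <- tajimas_d_per_snp(p, "p1", bin_bp = 1e6)
  expect_equal(d$values, rep(oracle_tajimas_d(H), 5))

  set.seed(29)
  for (i in 1:60) {
    nh <- 2 * sample(3:10, 1)
    ns <- sample(3:12, 1)
    H <- matrix(rbinom(nh * ns, 1, runif(1, 0.2, 0.8)), nh, ns)
    p <- panel_from_H(H)
    expect_equal(tajimas_d_per_snp(p, "p1", bin_bp = 1e9)$values,
                 rep(oracle_tajimas_d(H), ns))
  }
})

test_that("Tajima's D bin edge cases give zero and respect bin geometry", {
  # monomorphic bin -> 0
  p <- panel_from_H(matrix(0L, 6, 4))
  expect_equal(tajimas_d_per_snp(p, "p1")$values, rep(0, 4))
  # SNPs falling in different bins get their own bin's D
  H <- cbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L),
             c(1L, 1L, 1L, 0L), c(0L, 1L, 1L, 1L))
  v <- toy_variants(4)
  v$pos <- c(100L, 200L, 1000100L, 1000200L)
  p2 <- haplotype_panel(v, toy_samples(2), H)
  d <- tajimas_d_per_snp(p2, "p1", bin_bp = 1e6)$values
  expect_equal(d[1], d[2])
  expect_equal(d[3], d[4])
  expect_equal(d[1], oracle_tajimas_d(H[, 1:2]))
  expect_equal(d[3], oracle_tajimas_d(H[, 3:4]))
  # position scaling that preserves bin membership leaves D unchanged
  v3 <- v; v3$pos <- v$pos * 2L
  p3 <- haplotype_panel(v3, toy_samples(2), H)
  expect_equal(tajimas_d_per_snp(p3, "p1", bin_bp = 2e6)$values, d)
})
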