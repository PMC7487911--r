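test_that("fractional-rank p-values follow the (N+1) convention", {
  expect_equal(rank_pvalues(5, "left"), 0.5)
  expect_equal(rank_pvalues(5, "right"), 0.5)
  expect_equal(rank_pvalues(c(1, 2, 3), "right"), c(0.75, 0.5, 0.25))
  expect_equal(rank_pvalues(c(1, 2, 3), "left"), c(0.25, 0.5, 0.75))
  expect_error(rank_pvalues(numeric(0)), "empty")
  set.seed(51)
  for (i in 1:200) {
    x <- sample(round(rnorm(sample(3:30, 1)), 1))  # generates ties
    for (tail in c("left", "right")) {
      p <- rank_pvalues(x, tail)
      expect_equal(p, oracle_rank_p(x, tail))
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("DCMS limit cases: identity R sums, all-ones R averages", {
  P <- matrix(0.1, 1, 3)
  expect_equal(dcms_scores(P, diag(3)), 3 * log(9))
  expect_equal(dcms_scores(P, matrix(1, 3, 3)), log(9))
  expect_equal(dcms_scores(matrix(0.5, 1, 3), diag(3)), 0)
  expect_error(dcms_scores(matrix(c(0, 0.5, 0.5), 1), diag(3)),
               "strictly")
})

test_that("DCMS weight factor is bounded and scores decrease in each p", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    A <- matrix(rnorm(n * 40), 40, n)
    R <- cov2cor(crossprod(A))
    w <- colSums(abs(R))
    expect_true(all(1 / w >= 1 / n - 1e-12 & 1 / w <= 1 + 1e-12))
    p <- matrix(runif(n, 0.2, 0.8), 1, n)
    base <- dcms_scores(p, R)
    for (t in seq_len(n)) {
      p2 <- p
      p2[t] <- p[t] + 0.1
      expect_lt(dcms_scores(p2, R), base)
    }
  }
})

test_that("MCD correlation recovers structure and degenerates loudly", {
  set.seed(71)
  x <- rnorm(300)
  S <- cbind(a = x, b = x + rnorm(300, sd = 1e-3), c = rnorm(300))
  R <- mcd_correlation(S, nsamp = 200, seed = 1)
  expect_equal(unname(R["a", "b"]), 1, tolerance = 1e-4)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_equal(R, t(R))

  # exactly collinear columns make every subset scatter singular
  expect_error(mcd_correlation(cbind(x, x, rnorm(300)), nsamp = 50,
                               seed = 3), "degenerate")

  # independent columns: off-diagonals near zero
  S2 <- matrix(rnorm(5000 * 3), 5000, 3)
  R2 <- mcd_correlation(S2, nsamp = 300, seed = 2)
  expect_lt(max(abs(R2[upper.tri(R2)])), 0.1)

  expect_error(mcd_correlation(cbind(rep(1, 50), rnorm(50)), nsamp = 10,
                               seed = 1), "degenerate")
  expect_error(mcd_correlation(S, nsamp = 10), "seed")
})

test_that("subset-sampled MCD equals exhaustive enumeration on tiny N", {
  set.seed(81)
  for (i in 1:20) {
    S <- matrix(rnorm(24), 12, 2)
    got <- mcd_correlation(S, alpha = 0.75, nsamp = 10000, seed = i)
    want <- oracle_mcd_exhaustive(S, alpha = 0.75)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("Huber fit tracks the mean on clean data, resists contamination", {
  set.seed(91)
  # a symmetric sample fully inside the Huber threshold (bimodal, so the
  # MAD scale exceeds max|x - mu|/k): every weight is 1 and the
  # M-estimate coincides with the arithmetic mean
  x <- sample(c(-1, 1), 2000, replace = TRUE) + runif(2000, -0.1, 0.1)
  fit <- huber_normal_fit(x)
  expect_equal(fit$mu, mean(x), tolerance = 1e-6)
  # 5% gross positive outliers
  xc <- c(rnorm(950), rep(50, 50))
  fitc <- huber_normal_fit(xc)
  expect_lt(abs(fitc$mu - median(xc[1:950])), abs(mean(xc) - median(xc[1:950])))
  expect_error(huber_normal_fit(rep(1, 100)), "degenerate")
  expect_error(huber_normal_fit(1:5), "at least 10")
})

test_that("Huber fit agrees with the reference robust fitter", {
  skip_if_not_installed("MASS")
  set.seed(93)
  x <- c(rnorm(400, mean = 3), rexp(40) + 8)
  fit <- huber_normal_fit(x)
  ref <- MASS::rlm(x ~ 1)
  expect_equal(fit$mu, unname(coef(ref)[1]), tolerance = 0.02)
  expect_equal(fit$sd, ref$s, tolerance = 0.05)
})

test_that("normal upper-tail p-values are calibrated and monotone", {
  expect_equal(normal_pvalues(2, 2, 1), 0.5)
  expect_equal(normal_pvalues(2 + 1.959964, 2, 1), 0.025, tolerance = 1e-6)
  x <- c(0, 1, 2, 5)
  p <- normal_pvalues(x, 1, 2)
  expect_true(all(diff(p) < 0))
  expect_error(normal_pvalues(1, 0, 0), "positive")
})

test_that("BH q-values match the step-up oracle", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_qvalues(c(0.5, 1.2)), "outside")
  set.seed(101)
  for (i in 1:200) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_qvalues(p), oracle_bh(p))
  }
})

test_that("pipeline p-values are invariant to monotone track transforms", {
  set.seed(111)
  x <- rnorm(200)
  for (tail in c("left", "right")) {
    p1 <- rank_pvalues(x, tail)
    p2 <- rank_pvalues(exp(2 * x) + 5, tail)   # strictly increasing map
    expect_equal(p1, p2)
  }
})

test_that("dcms_from_tracks is reproducible and internally consistent", {
  set.seed(121)
  n <- 400
  tracks <- list(FST = pmax(0, rnorm(n, 0.2, 0.1)),
                 PI = runif(n, 0, 0.5),
                 TAJD = rnorm(n),
                 H1 = runif(n, 0.2, 0.9))
  tracks$H12 <- tracks$H1 + runif(n, 0, 0.1)
  r1 <- dcms_from_tracks(tracks, nsamp = 100, seed = 5)
  r2 <- dcms_from_tracks(tracks, nsamp = 100, seed = 5)
  expect_equal(r1$dcms, r2$dcms)
  expect_equal(r1$q, r2$q)
  expect_equal(r1$q, bh_qvalues(r1$p))
  expect_equal(r1$p, normal_pvalues(r1$dcms, r1$mu, r1$sd))
  expect_true(all(r1$q >= 0 & r1$q <= 1))
  # q is monotone non-decreasing in p after sorting
  o <- order(r1$p)
  expect_true(all(diff(r1$q[o]) >= -1e-12))
})

test_that("pure-noise tracks yield essentially no q < 0.05 calls", {
  set.seed(131)
  frac <- replicate(5, {
    n <- 500
    tracks <- list(FST = rnorm(n), PI = rnorm(n), TAJD = rnorm(n),
                   H1 = rnorm(n), H12 = rnorm(n))
    r <- dcms_from_tracks(tracks, nsamp = 100, seed = sample.int(1e6, 1))
    mean(r$q < 0.05)
  })
  expect_equal(median(frac), 0)
})
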