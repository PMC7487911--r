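# independent brute-force oracles; each re-derives its quantity from first
# principles, never through the package's own code path

# HWE chi-square by explicit expected counts
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * n)
  if (p %in% c(0, 1)) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  pchisq(sum((c(nAA, nAa, naa) - e)^2 / e), 1, lower.tail = FALSE)
}

# Weir & Cockerham (1984) theta-hat transcribed independently, r groups
oracle_wc_fst <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  CV2 <- sum((n - nbar)^2) / (r - 1) / nbar^2   # squared CV of sizes
  nc <- nbar * (1 - CV2 / r)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# per-site pi by enumerating all chromosome pairs
oracle_site_pi <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(0)
  pairs <- combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Tajima's D from a haplotype matrix (rows = chromosomes), textbook constants
oracle_tajimas_d <- function(M) {
  n <- nrow(M)
  seg <- apply(M, 2, function(x) length(unique(x)) > 1)
  S <- sum(seg)
  if (S == 0) return(0)
  khat <- sum(apply(M, 2, oracle_site_pi))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(0)
  (khat - S / a1) / sqrt(v)
}

# H1/H12 by direct string counting
oracle_h1_h12 <- function(M) {
  keys <- apply(M, 1, paste, collapse = "")
  p <- sort(table(keys) / length(keys), decreasing = TRUE)
  p <- as.numeric(p)
  h1 <- sum(p^2)
  h12 <- if (length(p) >= 2) {
    (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
  } else {
    p[1]^2
  }
  c(h1 = h1, h12 = h12)
}

# fractional ranks by explicit pairwise counting
oracle_rank_p <- function(x, tail) {
  n <- length(x)
  r <- vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, 0)
  if (tail == "left") r / (n + 1) else (n + 1 - r) / (n + 1)
}

# BH step-up by scanning all thresholds
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# running median by explicit window enumeration with constant ends
oracle_runmed <- function(x, k) {
  n <- length(x)
  half <- (k - 1) / 2
  if (k >= n) return(rep(median(x), n))
  out <- numeric(n)
  for (i in (half + 1):(n - half)) out[i] <- median(x[(i - half):(i + half)])
  out[seq_len(half)] <- out[half + 1]
  out[(n - half + 1):n] <- out[n - half]
  out
}

# exhaustive MCD over all (p+1)-subsets with independently coded C-steps
oracle_mcd_exhaustive <- function(S, alpha = 0.75) {
  N <- nrow(S); p <- ncol(S)
  h <- ceiling(alpha * N)
  subs <- combn(N, p + 1)
  best_det <- Inf; best <- NULL
  for (j in seq_len(ncol(subs))) {
    pts <- S[subs[, j], , drop = FALSE]
    mu <- colMeans(pts); sig <- cov(pts)
    if (!is.finite(det(sig)) || det(sig) <= 0) next
    repeat {
      d2 <- mahalanobis(S, mu, sig)
      sel <- sort(order(d2)[1:h])
      mu2 <- colMeans(S[sel, , drop = FALSE])
      sig2 <- cov(S[sel, , drop = FALSE])
      if (!is.finite(det(sig2)) || det(sig2) <= 0) { sig <- NULL; break }
      if (isTRUE(all.equal(mu, mu2)) &&
          isTRUE(all.equal(sig, sig2))) break
      mu <- mu2; sig <- sig2
    }
    if (is.null(sig)) next
    if (det(sig) < best_det) {
      best_det <- det(sig); best <- list(mu = mu, sigma = sig)
    }
  }
  d2 <- mahalanobis(S, best$mu, best$sigma)
  sig_c <- best$sigma * median(d2) / qchisq(0.5, p)
  keep <- mahalanobis(S, best$mu, sig_c) <= qchisq(0.975, p)
  cov2cor(cov(S[keep, , drop = FALSE]))
}
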