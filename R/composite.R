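# default one-tailed direction per statistic: extreme differentiation and
# haplotype homozygosity are high under a sweep (right tail), diversity and
# Tajima's D are depressed (left tail)
default_tails <- c(FST = "right", PI = "left", TAJD = "left",
                   H1 = "right", H12 = "right")

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Fractional-rank one-tailed p-values for a statistic track
#'
#' With ascending fractional ranks r (ties averaged) over N values, the
#' left-tailed p-value is r / (N + 1) and the right-tailed p-value is
#' (N + 1 - r) / (N + 1); the N + 1 denominator keeps every p strictly
#' inside (0, 1), which the logit transform of the composite requires.
#'
#' @param track a `StatTrack` or numeric vector.
#' @param tail `"left"` (small values extreme) or `"right"` (large values
#'   extreme).
#' @return numeric vector of p-values in (0, 1).
#' @export
rank_pvalues <- function(track, tail = c("left", "right")) {
  tail <- match.arg(tail)
  x <- if (inherits(track, "StatTrack")) track$values else track
  if (length(x) == 0) stop("empty track")
  if (any(!is.finite(x))) stop("track contains non-finite values")
  r <- rank(x, ties.method = "average")
  n <- length(x)
  if (tail == "left") r / (n + 1) else (n + 1 - r) / (n + 1)
}

mcd_cstep <- function(S, mu, sigma, h, max_iter = 100) {
  old <- integer(0)
  det_val <- NA_real_
  for (it in seq_len(max_iter)) {
    d2 <- tryCatch(stats::mahalanobis(S, mu, sigma),
                   error = function(e) NULL)
    if (is.null(d2)) return(NULL)
    sel <- sort(order(d2)[seq_len(h)])
    if (identical(sel, old)) break
    old <- sel
    mu <- colMeans(S[sel, , drop = FALSE])
    sigma <- stats::cov(S[sel, , drop = FALSE])
    det_val <- det(sigma)
    if (!is.finite(det_val) || det_val <= 0) return(NULL)
  }
  list(mu = mu, sigma = sigma, det = det_val, subset = old)
}

#' Robust correlation matrix by FAST-MCD
#'
#' Estimates the minimum covariance determinant location/scatter of the
#' N x n statistic matrix from `nsamp` random (n+1)-point starting subsets,
#' each concentrated by C-steps to convergence on the h = ceiling(alpha N)
#' points with smallest Mahalanobis distance. The minimum-determinant
#' solution is consistency-corrected (median distance against the
#' chi-square(n) median) and reweighted at the chi-square(n) 0.975 cutoff;
#' the reweighted covariance is returned as a correlation matrix. When
#' `nsamp` is at least the number of possible subsets, all subsets are
#' enumerated, making the estimate deterministic.
#'
#' @param S numeric matrix, rows = loci, columns = statistics; rows with
#'   non-finite entries are dropped.
#' @param alpha subset fraction (default 0.75).
#' @param nsamp number of starting subsets (paper-scale default 50000;
#'   use smaller values for quick runs).
#' @param seed integer seed making subset sampling reproducible (required).
#' @return n x n correlation matrix (symmetric, unit diagonal).
#' @export
mcd_correlation <- function(S, alpha = 0.75, nsamp = 50000, seed) {
  if (missing(seed)) stop("seed is required for reproducible MCD")
  S <- as.matrix(S)
  S <- S[stats::complete.cases(S) & rowSums(!is.finite(S)) == 0, ,
         drop = FALSE]
  N <- nrow(S); p <- ncol(S)
  if (N <= p) stop("need more rows than statistics")
  spread <- apply(S, 2, function(x) diff(range(x)))
  if (any(spread == 0)) {
    stop("degenerate statistics: zero-spread column(s) ",
         paste(which(spread == 0), collapse = ", "))
  }
  h <- ceiling(alpha * N)
  n_all <- choose(N, p + 1)
  subsets <- if (is.finite(n_all) && n_all <= nsamp) {
    asplit(utils::combn(N, p + 1), 2)
  } else {
    with_seed(seed, replicate(nsamp, sample.int(N, p + 1), simplify = FALSE))
  }
  best <- NULL
  for (sub in subsets) {
    sub <- as.integer(sub)
    mu <- colMeans(S[sub, , drop = FALSE])
    sigma <- stats::cov(S[sub, , drop = FALSE])
    if (!is.finite(det(sigma)) || det(sigma) <= 0) next
    sol <- mcd_cstep(S, mu, sigma, h)
    if (is.null(sol) || !is.finite(sol$det)) next
    if (is.null(best) || sol$det < best$det) best <- sol
  }
  if (is.null(best)) stop("degenerate statistics: no non-singular subset")
  d2 <- stats::mahalanobis(S, best$mu, best$sigma)
  sigma_c <- best$sigma * stats::median(d2) / stats::qchisq(0.5, p)
  w <- stats::mahalanobis(S, best$mu, sigma_c) <= stats::qchisq(0.975, p)
  sigma_rw <- stats::cov(S[w, , drop = FALSE])
  R <- stats::cov2cor(sigma_rw)
  dimnames(R) <- dimnames(S)[c(2, 2)]
  R
}

#' De-correlated composite of multiple signals
#'
#' For locus l with one-tailed p-values p_lt across the n statistics and
#' robust correlation matrix R, the composite is
#' DCMS_l = sum_t log((1 - p_lt) / p_lt) / w_t with w_t = sum_i |r_it|
#' (natural log). The per-statistic weight factor 1/w_t lies in
#' `[1/n, 1]`: uncorrelated statistics contribute their full logit term
#' (the composite is the plain sum), fully correlated statistics are
#' down-weighted to 1/n each (the composite is the average).
#'
#' @param P N x n matrix of p-values strictly in (0, 1).
#' @param R n x n correlation matrix.
#' @return numeric vector of composite scores, one per locus.
#' @export
dcms_scores <- function(P, R) {
  P <- as.matrix(P); R <- as.matrix(R)
  if (ncol(P) != ncol(R) || nrow(R) != ncol(R)) {
    stop("P columns and R dimensions must agree")
  }
  if (any(P <= 0 | P >= 1)) stop("p-values must lie strictly in (0, 1)")
  if (any(abs(R) > 1 + 1e-8) || any(abs(diag(R) - 1) > 1e-8)) {
    stop("R must be a correlation matrix")
  }
  w <- colSums(abs(R))
  n <- ncol(R)
  if (any(1 / w < 1 / n - 1e-12) || any(1 / w > 1 + 1e-12)) {
    stop("weight factor outside [1/n, 1]")
  }
  as.vector(log((1 - P) / P) %*% (1 / w))
}

#' Per-statistic weight factors of the composite
#'
#' The weight factor of statistic t is 1 / sum_i |r_it|; with n mutually
#' uncorrelated statistics it equals 1 (the composite is the plain sum of
#' logit terms) and with n fully correlated statistics it equals 1/n (the
#' composite is their average). It always lies in `[1/n, 1]`.
#'
#' @param R n x n correlation matrix.
#' @return numeric vector of n weight factors.
#' @export
dcms_weight_factors <- function(R) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R), all(abs(diag(R) - 1) < 1e-8))
  1 / colSums(abs(R))
}

#' Intercept-only Huber fit of the composite score distribution
#'
#' Robust normal calibration of the genome-wide score vector: location by
#' Huber M-estimation (tuning constant k = 1.345), scale re-estimated each
#' iteration as 1.4826 x median absolute deviation about the current
#' location, iterated to convergence.
#'
#' @param x numeric vector (at least 10 finite values with nonzero spread).
#' @param k Huber tuning constant.
#' @param tol relative convergence tolerance on the location step.
#' @param max_iter iteration cap.
#' @return list with `mu` and `sd`.
#' @export
huber_normal_fit <- function(x, k = 1.345, tol = 1e-8, max_iter = 200) {
  x <- x[is.finite(x)]
  if (length(x) < 10) stop("need at least 10 finite values")
  mu <- stats::median(x)
  s <- stats::mad(x, center = mu)
  if (s == 0) stop("degenerate scores: zero spread")
  for (it in seq_len(max_iter)) {
    u <- (x - mu) / s
    w <- ifelse(u == 0, 1, pmin(1, k / abs(u)))
    mu_new <- sum(w * x) / sum(w)
    s <- stats::mad(x, center = mu_new)
    if (s == 0) stop("degenerate scores: zero spread")
    done <- abs(mu_new - mu) < tol * s
    mu <- mu_new
    if (done) break
  }
  list(mu = mu, sd = s)
}

#' Upper-tail normal p-values for composite scores
#'
#' @param x numeric vector of scores.
#' @param mu,sd fitted normal location and scale (`sd > 0`).
#' @return vector of upper-tail p-values.
#' @export
normal_pvalues <- function(x, mu, sd) {
  if (sd <= 0) stop("sd must be positive")
  stats::pnorm(x, mean = mu, sd = sd, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m p_(j) / j, capped
#' at 1 and mapped back to input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full composite on a set of statistic tracks
#'
#' Converts each track to fractional-rank one-tailed p-values (left tail
#' for diversity and Tajima's D, right tail for FST, H1, H12), estimates
#' the robust correlation among the raw tracks by FAST-MCD, computes the
#' composite score, calibrates it with the Huber normal fit, and attaches
#' upper-tail p-values and BH q-values.
#'
#' @param tracks named list of `StatTrack`s (names in
#'   `c("FST","PI","TAJD","H1","H12")`, all same length).
#' @param alpha,nsamp,seed passed to [mcd_correlation()].
#' @param tails named character vector of tail directions per statistic.
#' @return object of class `DcmsResult`: list with `dcms`, `mu`, `sd`,
#'   `p`, `q`, the p-value matrix `P`, and correlation matrix `R`.
#' @export
dcms_from_tracks <- function(tracks, alpha = 0.75, nsamp = 50000, seed,
                             tails = default_tails) {
  stopifnot(length(tracks) >= 2, !is.null(names(tracks)))
  vals <- lapply(tracks, function(t)
    if (inherits(t, "StatTrack")) t$values else t)
  lens <- vapply(vals, length, 1L)
  if (length(unique(lens)) != 1) stop("tracks must share one length")
  S <- do.call(cbind, vals)
  colnames(S) <- names(tracks)
  P <- vapply(names(tracks), function(nm) {
    rank_pvalues(vals[[nm]], tails[[nm]])
  }, numeric(nrow(S)))
  R <- mcd_correlation(S, alpha = alpha, nsamp = nsamp, seed = seed)
  dcms <- dcms_scores(P, R)
  fit <- huber_normal_fit(dcms)
  pv <- normal_pvalues(dcms, fit$mu, fit$sd)
  structure(list(dcms = dcms, mu = fit$mu, sd = fit$sd, p = pv,
                 q = bh_qvalues(pv), P = P, R = R),
            class = "DcmsResult")
}

#' @export
print.DcmsResult <- function(x, ...) {
  cat("DcmsResult:", length(x$dcms), "SNPs; mu =", signif(x$mu, 4),
      ", sd =", signif(x$sd, 4), ";", sum(x$q < 0.05), "SNPs at q < 0.05\n")
  invisible(x)
}
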