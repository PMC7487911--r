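#' Per-SNP statistic track
#'
#' A named numeric vector aligned to the variant order of the panel it was
#' computed from, plus the population it belongs to.
#'
#' @param stat_name one of `"FST"`, `"PI"`, `"TAJD"`, `"H1"`, `"H12"`.
#' @param values numeric vector, one value per SNP, no missing values.
#' @param breed population label.
#' @return object of class `StatTrack`.
#' @export
stat_track <- function(stat_name, values, breed) {
  stopifnot(stat_name %in% c("FST", "PI", "TAJD", "H1", "H12"),
            is.numeric(values))
  if (anyNA(values)) stop("StatTrack values must be complete")
  structure(list(stat_name = stat_name, values = as.numeric(values),
                 breed = breed),
            class = "StatTrack")
}

#' @export
print.StatTrack <- function(x, ...) {
  cat("StatTrack", x$stat_name, "for", x$breed, "-", length(x$values),
      "SNPs, range [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "]\n")
  invisible(x)
}

#' Running median with constant end rule
#'
#' Centered window median of odd width `k`; the first and last `(k-1)/2`
#' positions repeat the first and last computed median. A window wider
#' than the vector collapses to the whole-vector median everywhere.
#'
#' @param values numeric vector.
#' @param k odd window width.
#' @return smoothed vector, same length.
#' @export
running_median <- function(values, k) {
  if (k %% 2 == 0) stop("window width k must be odd")
  n <- length(values)
  if (n == 0) return(values)
  if (k >= n) return(rep(stats::median(values), n))
  as.numeric(stats::runmed(values, k, endrule = "constant"))
}

smooth_by_chrom <- function(values, chrom, k) {
  out <- numeric(length(values))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    out[idx] <- running_median(values[idx], k)
  }
  out
}

# per-group allele frequency, sample size and observed het share at one SNP
wc_components <- function(n, p, h, r = 2) {
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Per-SNP Weir-Cockerham FST, one breed against the rest
#'
#' Computes the two-group (focal breed vs all remaining samples pooled)
#' variance-components estimator theta-hat = a / (a + b + c) at every SNP,
#' sets negative estimates to zero, and smooths per chromosome with a
#' running median.
#'
#' @param panel a `HaplotypePanel`.
#' @param focal_pop population label of the focal breed.
#' @param smooth_k running-median width (odd; 31 by default). `NA` skips
#'   smoothing (used by tests against the raw estimator).
#' @return a `StatTrack` with `stat_name = "FST"`.
#' @export
wc_fst_per_snp <- function(panel, focal_pop, smooth_k = 31) {
  if (!focal_pop %in% panel$samples$pop) {
    stop("focal population not in panel: ", focal_pop)
  }
  G <- genotype_matrix(panel)
  in_focal <- panel$samples$pop == focal_pop
  grp <- list(G[in_focal, , drop = FALSE], G[!in_focal, , drop = FALSE])
  nsnp <- ncol(G)
  raw <- numeric(nsnp)
  for (j in seq_len(nsnp)) {
    n <- p <- h <- numeric(2)
    for (g in 1:2) {
      x <- grp[[g]][, j]
      x <- x[!is.na(x)]
      n[g] <- length(x)
      if (n[g] > 0) {
        p[g] <- mean(x) / 2
        h[g] <- mean(x == 1)
      }
    }
    if (any(n < 2)) { raw[j] <- 0; next }
    comp <- wc_components(n, p, h)
    denom <- sum(comp)
    raw[j] <- if (denom == 0) 0 else comp["a"] / denom
  }
  raw[raw < 0] <- 0
  vals <- if (is.na(smooth_k)) raw else
    smooth_by_chrom(raw, panel$variants$chrom, smooth_k)
  stat_track("FST", vals, focal_pop)
}

# ref/alt/total non-missing chromosome counts per site in one population
pop_site_counts <- function(panel, pop) {
  Hp <- pop_hap_matrix(panel, pop)
  n1 <- colSums(Hp == 1L, na.rm = TRUE)
  n <- colSums(!is.na(Hp))
  list(n = n, c0 = n - n1, c1 = n1)
}

#' Per-site nucleotide diversity within a population
#'
#' For a biallelic site with `c0` ref and `c1` alt alleles among `n`
#' called chromosomes, pi = 2 c0 c1 / (n (n - 1)); sites with fewer than
#' two called chromosomes score 0. Smoothed per chromosome by running
#' median.
#'
#' @inheritParams wc_fst_per_snp
#' @param pop population label.
#' @return a `StatTrack` with `stat_name = "PI"`.
#' @export
site_pi <- function(panel, pop, smooth_k = 31) {
  cnt <- pop_site_counts(panel, pop)
  raw <- ifelse(cnt$n >= 2,
                2 * cnt$c0 * cnt$c1 / (cnt$n * (cnt$n - 1)), 0)
  vals <- if (is.na(smooth_k)) raw else
    smooth_by_chrom(raw, panel$variants$chrom, smooth_k)
  stat_track("PI", vals, pop)
}

#' Tajima's D standardization constants for n chromosomes
#' @noRd
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Binned Tajima's D assigned back to SNPs
#'
#' Each chromosome is cut into non-overlapping bins of `bin_bp` base pairs
#' (`[0, bin_bp)`, `[bin_bp, 2 bin_bp)`, ...). Within a bin, D is the
#' standardized difference between the mean pairwise diversity and the
#' segregating-sites estimate of theta; bins with no segregating sites or
#' an undefined variance score 0, and every SNP inherits its bin's value.
#'
#' @inheritParams site_pi
#' @param bin_bp bin width in base pairs (default 300000).
#' @return a `StatTrack` with `stat_name = "TAJD"`.
#' @export
tajimas_d_per_snp <- function(panel, pop, bin_bp = 300000) {
  if (bin_bp <= 0) stop("bin_bp must be positive")
  cnt <- pop_site_counts(panel, pop)
  v <- panel$variants
  bin <- paste(v$chrom, v$pos %/% bin_bp, sep = "\r")
  vals <- numeric(nrow(v))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    n_site <- cnt$n[idx]
    usable <- n_site >= 2
    if (!any(usable)) { vals[idx] <- 0; next }
    n_modal <- as.integer(names(sort(table(n_site[usable]),
                                     decreasing = TRUE))[1])
    seg <- usable & cnt$c0[idx] > 0 & cnt$c1[idx] > 0
    S <- sum(seg)
    if (S == 0 || n_modal < 2) { vals[idx] <- 0; next }
    khat <- sum(2 * cnt$c0[idx][usable] * cnt$c1[idx][usable] /
                  (n_site[usable] * (n_site[usable] - 1)))
    cst <- tajima_constants(n_modal)
    varD <- cst$e1 * S + cst$e2 * S * (S - 1)
    vals[idx] <- if (varD <= 0) 0 else (khat - S / cst$a1) / sqrt(varD)
  }
  stat_track("TAJD", vals, pop)
}
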