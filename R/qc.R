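#' QC threshold set
#'
#' Defaults follow the usual SNP-array practice for selection scans: SNP
#' call rate >= 0.95, MAF >= 0.05, Hardy-Weinberg chi-square p >= 1e-6,
#' sample call rate >= 0.95.
#'
#' @param snp_call_rate minimum fraction of called genotypes per SNP.
#' @param maf minimum minor allele frequency.
#' @param hwe_p minimum HWE chi-square p-value.
#' @param sample_call_rate minimum fraction of called genotypes per sample.
#' @return list of class `QcThresholds`.
#' @export
qc_thresholds <- function(snp_call_rate = 0.95, maf = 0.05, hwe_p = 1e-6,
                          sample_call_rate = 0.95) {
  thr <- list(snp_call_rate = snp_call_rate, maf = maf, hwe_p = hwe_p,
              sample_call_rate = sample_call_rate)
  if (any(unlist(thr) < 0 | unlist(thr) > 1)) {
    stop("all thresholds must lie in [0, 1]")
  }
  structure(thr, class = "QcThresholds")
}

#' Hardy-Weinberg chi-square goodness-of-fit p-value
#'
#' 1-df chi-square test of the observed genotype counts against the
#' expectation at the sample allele frequency. Monomorphic input is in
#' perfect equilibrium by construction and returns 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return the p-value.
#' @export
hwe_chisq_pvalue <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expd <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Apply the SNP/sample quality-control filters
#'
#' Filters run in a fixed order — duplicate ids and sex/unplaced
#' chromosomes, then sample call rate, SNP call rate, MAF, and HWE — and
#' the report tallies removals per step so that counts are additive. MAF
#' and HWE use non-missing alleles/genotypes only.
#'
#' @param panel a `HaplotypePanel`.
#' @param thr a [qc_thresholds()] object.
#' @param sex_chroms character vector of chromosome labels to drop
#'   (sex chromosomes, unplaced scaffolds).
#' @return list with the filtered `panel` and a `report` (class `QcReport`).
#' @export
filter_panel <- function(panel, thr = qc_thresholds(),
                         sex_chroms = character()) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  report <- list(input_snps = n_snps(panel), input_samples = n_samples(panel),
                 filter_order = c("duplicate", "sex_unplaced",
                                  "sample_call_rate", "snp_call_rate",
                                  "maf", "hwe"))

  dup <- duplicated(panel$variants$id)
  sexy <- panel$variants$chrom %in% sex_chroms
  report$duplicate_removed <- sum(dup)
  report$sex_unplaced_removed <- sum(sexy & !dup)
  keep <- !(dup | sexy)
  if (!all(keep)) panel <- subset_panel(panel, snps = keep)

  G <- genotype_matrix(panel)
  s_rate <- rowMeans(!is.na(G))
  keep_s <- s_rate >= thr$sample_call_rate
  report$sample_callrate_removed <- sum(!keep_s)
  if (!all(keep_s)) {
    if (!any(keep_s)) stop("all samples removed by call-rate filter")
    panel <- subset_panel(panel, samples = keep_s)
    G <- genotype_matrix(panel)
  }

  callrate <- colMeans(!is.na(G))
  keep_v <- callrate >= thr$snp_call_rate
  report$snp_callrate_removed <- sum(!keep_v)

  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- keep_v & (is.nan(maf) | maf < thr$maf)
  report$maf_removed <- sum(fail_maf)
  keep_v <- keep_v & !fail_maf

  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(1)
    hwe_chisq_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
  }, 0)
  fail_hwe <- keep_v & hwe_p < thr$hwe_p
  report$hwe_removed <- sum(fail_hwe)
  keep_v <- keep_v & !fail_hwe

  if (!any(keep_v)) stop("empty panel: all SNPs removed by QC")
  panel <- subset_panel(panel, snps = keep_v)
  report$snps_retained <- n_snps(panel)
  report$samples_retained <- n_samples(panel)
  class(report) <- "QcReport"
  list(panel = panel, report = report)
}

#' @export
print.QcReport <- function(x, ...) {
  cat("QC report:", x$input_snps, "SNPs /", x$input_samples,
      "samples in;", x$snps_retained, "SNPs /", x$samples_retained,
      "samples retained\n")
  for (f in c("duplicate_removed", "sex_unplaced_removed",
              "sample_callrate_removed", "snp_callrate_removed",
              "maf_removed", "hwe_removed")) {
    cat(sprintf("  %-24s %d\n", f, x[[f]]))
  }
  invisible(x)
}

complement_allele <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

#' Merge two panels on their mutual SNPs
#'
#' Variants are intersected by (chrom, pos, id); shared SNPs must carry the
#' same ref/alt alleles, either directly or after complementing both (a
#' strand-safe check). Samples are concatenated; variant order follows the
#' first panel.
#'
#' @param a,b `HaplotypePanel`s with disjoint sample sets.
#' @return the merged `HaplotypePanel`.
#' @export
merge_panels <- function(a, b) {
  if (length(intersect(a$samples$sample, b$samples$sample)) > 0) {
    stop("sample sets must be disjoint")
  }
  key <- function(v) paste(v$chrom, v$pos, v$id, sep = "\r")
  ka <- key(a$variants); kb <- key(b$variants)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) stop("empty panel: no mutual SNPs")
  ia <- match(shared, ka)
  ia <- ia[order(ia)]
  ib <- match(key(a$variants[ia, ]), kb)
  va <- a$variants[ia, ]; vb <- b$variants[ib, ]
  same <- (va$ref == vb$ref & va$alt == vb$alt) |
    (complement_allele(va$ref) == vb$ref & complement_allele(va$alt) == vb$alt)
  if (!all(same)) {
    stop("allele mismatch at shared SNP(s): ",
         paste(va$id[!same], collapse = ", "))
  }
  haplotype_panel(
    va,
    rbind(a$samples, b$samples),
    rbind(a$H[, ia, drop = FALSE], b$H[, ib, drop = FALSE]),
    phased = a$phased && b$phased
  )
}

#' Identity-by-state matrix between samples
#'
#' Entry (i, j) is the average over jointly called SNPs of the number of
#' shared alleles between the two diploid genotypes divided by two, so
#' identical genotype vectors score 1 and opposite homozygotes score 0.
#'
#' @param panel a `HaplotypePanel` with at least two samples.
#' @return symmetric matrix in `[0, 1]` with unit diagonal, sample ids as
#'   dimnames.
#' @export
ibs_matrix <- function(panel) {
  G <- genotype_matrix(panel)
  ns <- nrow(G)
  if (ns < 2) stop("need at least two samples")
  M <- diag(1, ns)
  for (i in seq_len(ns - 1L)) {
    gi <- G[i, ]
    for (j in seq(i + 1L, ns)) {
      d <- abs(gi - G[j, ])
      ok <- !is.na(d)
      if (!any(ok)) stop("samples ", rownames(G)[i], " and ", rownames(G)[j],
                         " share no called SNPs")
      M[i, j] <- M[j, i] <- 1 - sum(d[ok]) / (2 * sum(ok))
    }
  }
  dimnames(M) <- list(rownames(G), rownames(G))
  M
}

#' Principal components of an IBS matrix with breed-outlier flags
#'
#' Double-centers the similarity matrix (which removes any additive
#' constant) and eigen-decomposes it; coordinates are eigenvectors scaled
#' by the square root of their (non-negative) eigenvalues. A sample is
#' flagged as an outlier when its robust z-distance from its breed centroid
#' in the PC1-PC2 plane exceeds `outlier_z` (centroid = per-axis median,
#' scale = 1.4826 x MAD).
#'
#' @param ibs symmetric IBS matrix.
#' @param n_components number of leading components to return.
#' @param breeds optional character vector of breed labels per sample; when
#'   supplied, outlier flags are computed per breed.
#' @param outlier_z robust-SD threshold (default 3).
#' @return list with `coords` (n x k matrix), `eigenvalues`, `breed`, and
#'   logical `outlier`.
#' @export
pca_from_ibs <- function(ibs, n_components = 2, breeds = NULL,
                         outlier_z = 3) {
  ibs <- as.matrix(ibs)
  if (nrow(ibs) != ncol(ibs) || !isTRUE(all.equal(ibs, t(ibs),
                                                  tolerance = 1e-8))) {
    stop("IBS matrix must be symmetric")
  }
  n <- nrow(ibs)
  J <- diag(n) - matrix(1 / n, n, n)
  C <- J %*% ibs %*% J
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  k <- min(n_components, n)
  lam <- pmax(e$values[seq_len(k)], 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  rownames(coords) <- rownames(ibs)
  colnames(coords) <- paste0("PC", seq_len(k))
  outlier <- rep(FALSE, n)
  if (!is.null(breeds)) {
    stopifnot(length(breeds) == n)
    xy <- coords[, seq_len(min(2L, k)), drop = FALSE]
    for (b in unique(breeds)) {
      idx <- which(breeds == b)
      ctr <- apply(xy[idx, , drop = FALSE], 2, stats::median)
      sc <- apply(xy[idx, , drop = FALSE], 2, stats::mad)
      sc <- pmax(sc, 1e-12)
      z2 <- rowSums(sweep(sweep(xy[idx, , drop = FALSE], 2, ctr), 2, sc,
                          "/")^2)
      outlier[idx] <- sqrt(z2) > outlier_z
    }
  }
  list(coords = coords, eigenvalues = e$values, breed = breeds,
       outlier = outlier)
}
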