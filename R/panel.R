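#' Construct a phased haplotype panel
#'
#' The central container of the scan: an ordered variant table, a sample
#' table with population labels, and a haplotype allele matrix with two rows
#' per sample (hapA then hapB, in sample order) and one column per variant.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt`; one row per biallelic SNP, strictly increasing
#'   `pos` within each chromosome.
#' @param samples data.frame with columns `sample` and `pop`.
#' @param H integer matrix of allele codes in \{0, 1, NA\};
#'   `2 * nrow(samples)` rows and `nrow(variants)` columns.
#' @param phased logical; `TRUE` when rows are resolved parental haplotypes.
#'
#' @return An object of class `HaplotypePanel`.
#' @export
haplotype_panel <- function(variants, samples, H, phased = TRUE) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need_v %in% names(variants))) {
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  }
  if (!all(c("sample", "pop") %in% names(samples))) {
    stop("samples must have columns: sample, pop")
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$id <- as.character(variants$id)
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  obj <- structure(
    list(variants = variants, samples = samples, H = H,
         phased = isTRUE(phased)),
    class = "HaplotypePanel"
  )
  validate_panel(obj)
  obj
}

#' Validate a HaplotypePanel's invariants
#'
#' Checks dimensions, allele codes, position ordering and monotonicity.
#' Called by the constructor; exported so readers and the simulator can
#' re-assert after surgery.
#'
#' @param panel a `HaplotypePanel`.
#' @return `panel`, invisibly; errors describe the first violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  v <- panel$variants
  if (nrow(panel$H) != 2L * nrow(panel$samples)) {
    stop("haplotype rows (", nrow(panel$H), ") must equal 2 x samples (",
         2L * nrow(panel$samples), ")")
  }
  if (ncol(panel$H) != nrow(v)) {
    stop("haplotype columns (", ncol(panel$H), ") must equal variants (",
         nrow(v), ")")
  }
  bad <- !(panel$H %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("allele codes must be 0, 1 or NA")
  if (nrow(v) > 0) {
    if (any(v$pos < 1L)) stop("positions must be >= 1")
    for (chr in unique(v$chrom)) {
      p <- v$pos[v$chrom == chr]
      if (any(diff(p) <= 0)) {
        i <- which(diff(p) <= 0)[1]
        stop("non-monotonic positions on chromosome ", chr,
             " at record ", v$id[v$chrom == chr][i + 1L])
      }
    }
  }
  invisible(panel)
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat("HaplotypePanel:", nrow(x$variants), "SNPs x", nrow(x$samples),
      "samples (", nrow(x$H), "haplotypes ),",
      if (x$phased) "phased" else "unphased", "\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  populations:", paste(sort(unique(x$samples$pop)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of SNPs in a panel
#' @param panel a `HaplotypePanel`.
#' @return integer count.
#' @export
n_snps <- function(panel) nrow(panel$variants)

#' Number of samples in a panel
#' @param panel a `HaplotypePanel`.
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' Haplotype row indices for a set of samples
#' @noRd
hap_rows <- function(sample_idx) {
  as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
}

#' Subset a panel by SNPs and/or samples
#'
#' @param panel a `HaplotypePanel`.
#' @param snps integer or logical index into variants (default all).
#' @param samples integer or logical index into samples (default all).
#' @return the subset `HaplotypePanel`, variant order preserved.
#' @export
subset_panel <- function(panel, snps = NULL, samples = NULL) {
  v <- panel$variants
  s <- panel$samples
  H <- panel$H
  if (!is.null(snps)) {
    if (is.logical(snps)) snps <- which(snps)
    v <- v[snps, , drop = FALSE]
    H <- H[, snps, drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.logical(samples)) samples <- which(samples)
    s <- s[samples, , drop = FALSE]
    H <- H[hap_rows(samples), , drop = FALSE]
  }
  rownames(v) <- NULL
  rownames(s) <- NULL
  haplotype_panel(v, s, H, phased = panel$phased)
}

#' Diploid genotype dosage matrix (samples x SNPs)
#'
#' Sums the two haplotype rows of each sample; NA if either allele is
#' missing.
#'
#' @param panel a `HaplotypePanel`.
#' @return integer matrix, `n_samples x n_snps`, entries 0/1/2/NA.
#' @export
genotype_matrix <- function(panel) {
  ns <- n_samples(panel)
  a <- panel$H[seq(1L, by = 2L, length.out = ns), , drop = FALSE]
  b <- panel$H[seq(2L, by = 2L, length.out = ns), , drop = FALSE]
  G <- a + b
  rownames(G) <- panel$samples$sample
  G
}

#' Haplotype rows belonging to one population
#' @noRd
pop_hap_matrix <- function(panel, pop) {
  idx <- which(panel$samples$pop == pop)
  if (length(idx) == 0) stop("unknown population label: ", pop)
  panel$H[hap_rows(idx), , drop = FALSE]
}
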