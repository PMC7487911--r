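#' Haplotype spectrum of a window
#'
#' Counts the distinct allele strings among a set of haplotypes; rows
#' containing a missing allele are excluded and frequencies renormalized
#' over the remainder.
#'
#' @param M haplotype matrix (rows = haplotypes, columns = the window's
#'   SNPs), allele codes 0/1/NA.
#' @return sorted (decreasing) numeric vector of haplotype frequencies.
#' @export
haplotype_spectrum <- function(M) {
  ok <- rowSums(is.na(M)) == 0
  M <- M[ok, , drop = FALSE]
  if (nrow(M) == 0) return(numeric(0))
  key <- do.call(paste0, lapply(seq_len(ncol(M)), function(j) M[, j]))
  sort(as.numeric(table(key)) / length(key), decreasing = TRUE)
}

h_stats_from_spectrum <- function(p) {
  if (length(p) == 0) return(c(h1 = NA_real_, h12 = NA_real_))
  h1 <- sum(p^2)
  p2 <- if (length(p) >= 2) p[2] else 0
  c(h1 = h1, h12 = h1 + 2 * p[1] * p2)
}

#' Garud's H1 and H12 over sliding SNP windows
#'
#' Slides a window of `window` consecutive SNPs (step `step`) along each
#' chromosome within one population's phased haplotypes. With the window's
#' distinct-haplotype frequencies p1 >= p2 >= ...: H1 = sum(p_i^2) and
#' H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2 = H1 + 2 p1 p2. Each window's
#' value is anchored to the SNP at ordinal `ceiling(window / 2)` within
#' the window; SNPs without an anchored window (chromosome ends, or gaps
#' when `step > 1`) take the value of the nearest anchored SNP.
#'
#' @param panel a phased `HaplotypePanel`.
#' @param pop population label.
#' @param window window size in SNPs (default 14).
#' @param step step size in SNPs (default 1).
#' @return list with `h1` and `h12` `StatTrack`s.
#' @export
window_h_stats <- function(panel, pop, window = 14, step = 1) {
  if (!panel$phased) stop("H1/H12 require a phased panel")
  Hp <- pop_hap_matrix(panel, pop)
  chrom <- panel$variants$chrom
  h1 <- h12 <- numeric(ncol(Hp))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    n <- length(idx)
    if (n < window) {
      stop("chromosome ", ch, " shorter than window (", n, " < ", window, ")")
    }
    starts <- seq(1L, n - window + 1L, by = step)
    anchors <- starts + ceiling(window / 2) - 1L
    w1 <- w12 <- numeric(length(starts))
    for (s in seq_along(starts)) {
      cols <- idx[starts[s]:(starts[s] + window - 1L)]
      hs <- h_stats_from_spectrum(haplotype_spectrum(Hp[, cols, drop = FALSE]))
      w1[s] <- hs["h1"]; w12[s] <- hs["h12"]
    }
    if (anyNA(w1)) stop("window with no complete haplotype on chromosome ", ch)
    # nearest anchored window per SNP (constant extension at the ends)
    pos <- seq_len(n)
    left <- findInterval(pos, anchors)
    lo <- pmax(left, 1L)
    hi <- pmin(left + 1L, length(anchors))
    pick_hi <- left == 0L |
      (left < length(anchors) &
         abs(anchors[hi] - pos) < abs(anchors[lo] - pos))
    nearest <- ifelse(pick_hi, hi, lo)
    h1[idx] <- w1[nearest]
    h12[idx] <- w12[nearest]
  }
  list(h1 = stat_track("H1", h1, pop),
       h12 = stat_track("H12", h12, pop))
}
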