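#' Call significant regions from per-SNP q-values
#'
#' A maximal run of at least `min_seed` consecutive SNPs with q < `sig`
#' seeds a region. Each region is then extended outward over flanking SNPs
#' with q <= `ext` and stops just before the first flanking SNP with
#' q > `ext`; by default the boundary is the last included SNP's position
#' (`include_boundary_snp = TRUE` selects the alternative reading that
#' includes the first q > ext SNP). Regions whose extensions touch or
#' overlap are merged, the peak being the overall minimum-q SNP.
#'
#' @param snps data.frame with columns `chrom`, `pos` (sorted within
#'   chromosome) and `q`.
#' @param sig significance threshold on q (default 0.05).
#' @param ext extension threshold on q (default 0.1).
#' @param min_seed minimum run length of significant SNPs (default 2).
#' @param breed label stored on the output regions.
#' @param include_boundary_snp boundary convention flag (see above).
#' @return data.frame with columns `breed`, `region_id`, `chrom`, `start`,
#'   `end`, `n_sig_snps`, `peak_pos`, `peak_q`.
#' @export
call_regions <- function(snps, sig = 0.05, ext = 0.1, min_seed = 2,
                         breed = "pop", include_boundary_snp = FALSE) {
  stopifnot(all(c("chrom", "pos", "q") %in% names(snps)))
  if (any(snps$q < 0 | snps$q > 1)) stop("q-values outside [0, 1]")
  out <- list()
  for (ch in unique(snps$chrom)) {
    d <- snps[snps$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$pos, strictly = TRUE)) {
      stop("positions not sorted on chromosome ", ch)
    }
    n <- nrow(d)
    sig_mask <- d$q < sig
    r <- rle(sig_mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed_runs <- which(r$values & r$lengths >= min_seed)
    if (length(seed_runs) == 0) next
    spans <- lapply(seed_runs, function(k) {
      i <- starts[k]; j <- ends[k]
      while (i > 1L && d$q[i - 1L] <= ext) i <- i - 1L
      while (j < n && d$q[j + 1L] <= ext) j <- j + 1L
      if (include_boundary_snp) {
        i <- max(1L, i - 1L)
        j <- min(n, j + 1L)
      }
      c(i, j)
    })
    # merge index spans that touch or overlap
    spans <- spans[order(vapply(spans, `[`, 1L, 1L))]
    merged <- list(spans[[1]])
    for (s in spans[-1]) {
      last <- merged[[length(merged)]]
      if (s[1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], s[2]))
      } else {
        merged[[length(merged) + 1L]] <- s
      }
    }
    for (s in merged) {
      idx <- s[1]:s[2]
      qi <- d$q[idx]
      peak <- idx[which.min(qi)]
      out[[length(out) + 1L]] <- data.frame(
        breed = breed, chrom = ch, start = d$pos[s[1]], end = d$pos[s[2]],
        n_sig_snps = sum(qi < sig), peak_pos = d$pos[peak],
        peak_q = d$q[peak], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(breed = character(), region_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), n_sig_snps = integer(),
                      peak_pos = integer(), peak_q = numeric(),
                      stringsAsFactors = FALSE))
  }
  regions <- do.call(rbind, out)
  regions$region_id <- paste(breed, seq_len(nrow(regions)), sep = "_")
  rownames(regions) <- NULL
  regions[, c("breed", "region_id", "chrom", "start", "end", "n_sig_snps",
              "peak_pos", "peak_q")]
}

#' Annotate regions with overlapping genes, ranked by distance to the peak
#'
#' A gene is a hit when its interval overlaps the region at all; hits are
#' ranked by base-pair distance from the region's peak SNP to the nearest
#' gene edge (0 when the peak lies inside the gene), ties broken by
#' genomic start. Rank 1 is the closest gene to the most significant SNP.
#'
#' @param regions data.frame from [call_regions()].
#' @param genes data.frame from [read_gene_models()].
#' @return data.frame with columns `region_id`, `gene_id`, `distance_bp`,
#'   `rank`.
#' @export
annotate_regions <- function(regions, genes) {
  empty <- data.frame(region_id = character(), gene_id = character(),
                      distance_bp = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0) return(empty)
  unmatched <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(unmatched) > 0) {
    stop("chromosome label(s) absent from gene set: ",
         paste(unmatched, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    g <- genes[genes$chrom == r$chrom & genes$end >= r$start &
                 genes$start <= r$end, , drop = FALSE]
    if (nrow(g) == 0) next
    dist <- ifelse(r$peak_pos >= g$start & r$peak_pos <= g$end, 0L,
                   pmin(abs(r$peak_pos - g$start), abs(r$peak_pos - g$end)))
    ord <- order(dist, g$start)
    out[[length(out) + 1L]] <- data.frame(
      region_id = r$region_id, gene_id = g$gene_id[ord],
      distance_bp = as.integer(dist[ord]), rank = seq_along(ord),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Descriptive summary of called regions per breed
#'
#' @param regions data.frame from [call_regions()] (possibly several
#'   breeds concatenated).
#' @return data.frame with one row per breed: region count, mean and SD of
#'   region length in kb, total length in Mb, and total significant SNPs.
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0) {
    return(data.frame(breed = character(), n_regions = integer(),
                      mean_kb = numeric(), sd_kb = numeric(),
                      total_mb = numeric(), n_snps = integer(),
                      stringsAsFactors = FALSE))
  }
  len_bp <- regions$end - regions$start + 1
  agg <- lapply(split(seq_len(nrow(regions)), regions$breed), function(idx) {
    data.frame(breed = regions$breed[idx[1]], n_regions = length(idx),
               mean_kb = mean(len_bp[idx]) / 1e3,
               sd_kb = if (length(idx) > 1) stats::sd(len_bp[idx]) / 1e3
                       else NA_real_,
               total_mb = sum(len_bp[idx]) / 1e6,
               n_snps = sum(regions$n_sig_snps[idx]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res
}
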