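#' Read a phased VCF into a HaplotypePanel
#'
#' Parses a VCF 4.x file with a GT FORMAT field into the two-rows-per-sample
#' haplotype matrix used by all downstream statistics. Only biallelic SNP
#' records are accepted; multi-allelic records are rejected rather than
#' split, because every statistic in the scan assumes biallelic markers.
#'
#' @param path path to an uncompressed or gzipped VCF.
#' @param pop_labels named character vector mapping sample id to population
#'   label. Every sample in the file must be covered; `NULL` assigns all
#'   samples the label `"pop"`.
#' @param allow_unphased if `TRUE`, genotypes separated by `/` are accepted
#'   and their alleles taken in input order; otherwise an unphased genotype
#'   is an error.
#' @return a [haplotype_panel()] with haplotype rows in sample order
#'   (hapA then hapB per sample).
#' @export
read_phased_vcf <- function(path, pop_labels = NULL, allow_unphased = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records")
  if (ncol(vcf@gt) < 2) stop("VCF contains no sample genotype columns")
  if (!all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop("missing GT field in FORMAT")
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    bad <- fix$ID[grepl(",", fix$ALT, fixed = TRUE)][1]
    stop("multi-allelic record not supported: ", bad)
  }
  if (anyDuplicated(fix$ID)) {
    stop("duplicated variant id: ", fix$ID[duplicated(fix$ID)][1])
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samp <- colnames(gt)
  if (is.null(pop_labels)) {
    pop <- rep("pop", length(samp))
  } else {
    if (!all(samp %in% names(pop_labels))) {
      stop("samples without a population label: ",
           paste(setdiff(samp, names(pop_labels)), collapse = ", "))
    }
    pop <- unname(pop_labels[samp])
  }
  unph <- grepl("/", gt, fixed = TRUE)
  if (any(unph, na.rm = TRUE) && !allow_unphased) {
    i <- which(unph)[1]
    stop("unphased genotype at record ", fix$ID[(i - 1) %% nrow(gt) + 1],
         " (use allow_unphased to accept)")
  }
  # gt is variants x samples; build haplotypes as 2*samples x variants
  code <- function(a) {
    out <- suppressWarnings(as.integer(a))
    if (any(!is.na(out) & !(out %in% c(0L, 1L)))) {
      stop("allele code outside {0,1} in GT")
    }
    out
  }
  split_gt <- strsplit(ifelse(is.na(gt), ".|.", gt), "[|/]")
  lens <- lengths(split_gt)
  if (any(lens != 2L)) stop("non-diploid GT encountered")
  allele1 <- code(vapply(split_gt, `[`, "", 1L))
  allele2 <- code(vapply(split_gt, `[`, "", 2L))
  nv <- nrow(gt); ns <- length(samp)
  H <- matrix(NA_integer_, nrow = 2L * ns, ncol = nv)
  # split_gt ran column-major over gt (variant fastest)
  for (j in seq_len(ns)) {
    idx <- (j - 1L) * nv + seq_len(nv)
    H[2L * j - 1L, ] <- allele1[idx]
    H[2L * j, ] <- allele2[idx]
  }
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  haplotype_panel(variants,
                 data.frame(sample = samp, pop = pop,
                            stringsAsFactors = FALSE),
                 H, phased = TRUE)
}

#' Write a HaplotypePanel as a phased VCF
#'
#' Emits a minimal uncompressed VCF 4.2 with phased GT, the exact inverse
#' of [read_phased_vcf()] on valid panels.
#'
#' @param panel a `HaplotypePanel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  v <- panel$variants
  ns <- n_samples(panel)
  sep <- if (panel$phased) "|" else "/"
  a <- panel$H[seq(1L, by = 2L, length.out = ns), , drop = FALSE]
  b <- panel$H[seq(2L, by = 2L, length.out = ns), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix(paste0(fmt(t(a)), sep, fmt(t(b))), nrow = nrow(v))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dcmscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, if (nrow(v)) body), path)
  invisible(path)
}

#' Read gene models from BED4+ or GFF3
#'
#' Internal coordinates are 1-based inclusive (VCF convention): BED's
#' 0-based half-open intervals are converted at this boundary, GFF3 is
#' taken as-is.
#'
#' @param path input file.
#' @param format `"BED"` or `"GFF3"`.
#' @param protein_coding_only if `TRUE` and a biotype is present, keep only
#'   `protein_coding` genes.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `biotype` (NA when the format carries none).
#' @export
read_gene_models <- function(path, format = c("BED", "GFF3"),
                             protein_coding_only = FALSE) {
  format <- match.arg(format)
  if (format == "BED") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    genes <- lapply(which(keep), function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 4) stop("malformed BED line ", i, ": expected >= 4 fields")
      s0 <- suppressWarnings(as.integer(f[2]))
      e0 <- suppressWarnings(as.integer(f[3]))
      if (is.na(s0) || is.na(e0)) stop("malformed BED line ", i,
                                       ": non-integer coordinates")
      if (s0 >= e0) stop("malformed BED line ", i, ": start >= end")
      data.frame(gene_id = f[4], chrom = f[1], start = s0 + 1L, end = e0,
                 biotype = if (length(f) >= 7) f[7] else NA_character_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, genes)
    if (is.null(out)) {
      out <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        biotype = character(), stringsAsFactors = FALSE)
    }
  } else {
    g <- ape::read.gff(path, GFF3 = TRUE)
    g <- g[g$type == "gene", , drop = FALSE]
    ids <- vapply(as.character(g$attributes), function(a) {
      m <- regmatches(a, regexpr("(^|;)(ID|gene_id)=[^;]+", a))
      if (length(m)) sub("^;?(ID|gene_id)=", "", m) else NA_character_
    }, "", USE.NAMES = FALSE)
    bt <- vapply(as.character(g$attributes), function(a) {
      m <- regmatches(a, regexpr("(gene_biotype|biotype)=[^;]+", a))
      if (length(m)) sub("^(gene_biotype|biotype)=", "", m) else NA_character_
    }, "", USE.NAMES = FALSE)
    out <- data.frame(gene_id = ids, chrom = as.character(g$seqid),
                      start = as.integer(g$start), end = as.integer(g$end),
                      biotype = bt, stringsAsFactors = FALSE)
    if (any(out$start > out$end)) stop("gene with start > end in GFF3")
  }
  if (protein_coding_only && any(!is.na(out$biotype))) {
    out <- out[!is.na(out$biotype) & out$biotype == "protein_coding", ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

region_table_cols <- c("breed", "region_id", "chrom", "start", "end",
                       "n_snps", "peak_pos", "peak_q", "gene_id",
                       "distance_bp", "rank")

#' Write regions and gene hits to one TSV
#'
#' One row per region (gene fields empty) followed by one row per gene hit
#' carrying its rank; an empty region list yields a header-only file. The
#' format round-trips through [read_region_table()].
#'
#' @param regions data.frame as returned by [call_regions()] (columns
#'   `breed`, `region_id`, `chrom`, `start`, `end`, `n_sig_snps`,
#'   `peak_pos`, `peak_q`).
#' @param hits data.frame as returned by [annotate_regions()] (columns
#'   `region_id`, `gene_id`, `distance_bp`, `rank`), or `NULL`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, hits = NULL, path) {
  rows <- list()
  if (!is.null(regions) && nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        breed = r$breed, region_id = r$region_id, chrom = r$chrom,
        start = r$start, end = r$end, n_snps = r$n_sig_snps,
        peak_pos = r$peak_pos, peak_q = r$peak_q,
        gene_id = NA_character_, distance_bp = NA_integer_,
        rank = NA_integer_, stringsAsFactors = FALSE)
      if (!is.null(hits) && nrow(hits) > 0) {
        h <- hits[hits$region_id == r$region_id, , drop = FALSE]
        if (nrow(h) > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            breed = r$breed, region_id = r$region_id, chrom = r$chrom,
            start = r$start, end = r$end, n_snps = r$n_sig_snps,
            peak_pos = r$peak_pos, peak_q = r$peak_q,
            gene_id = h$gene_id, distance_bp = h$distance_bp,
            rank = h$rank, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(region_table_cols)),
                           region_table_cols))
  utils::write.table(tab[region_table_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a region/gene-hit TSV
#'
#' @param path file written by [write_region_table()].
#' @return list with `regions` and `hits` data.frames.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                           stringsAsFactors = FALSE,
                           colClasses = c(breed = "character",
                                          region_id = "character",
                                          chrom = "character",
                                          start = "integer", end = "integer",
                                          n_snps = "integer",
                                          peak_pos = "integer",
                                          peak_q = "numeric",
                                          gene_id = "character",
                                          distance_bp = "integer",
                                          rank = "integer"))
  is_region <- is.na(tab$gene_id)
  regions <- tab[is_region, c("breed", "region_id", "chrom", "start", "end",
                              "n_snps", "peak_pos", "peak_q")]
  names(regions)[names(regions) == "n_snps"] <- "n_sig_snps"
  hits <- tab[!is_region, c("region_id", "gene_id", "distance_bp", "rank")]
  rownames(regions) <- NULL
  rownames(hits) <- NULL
  list(regions = regions, hits = hits)
}

#' Write per-SNP statistic tracks as TSV
#'
#' @param variants variant table of the panel the tracks align to.
#' @param tracks named list of numeric vectors (one value per SNP).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(variants, tracks, path) {
  stopifnot(all(vapply(tracks, length, 1L) == nrow(variants)))
  tab <- cbind(variants[, c("chrom", "pos", "id")],
               as.data.frame(tracks, optional = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
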