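#' Assemble a run configuration for the scan
#'
#' Collects every tunable of the pipeline in one validated list. Input is
#' either a `simulate` block (a [sim_config()]) or one or more VCF paths
#' with population labels; `groups` maps each breed to a QC group so that
#' quality control runs per group before the mutual-SNP merge.
#'
#' @param vcf character vector of phased VCF paths (one per QC group), or
#'   `NULL` when simulating.
#' @param pop_labels named character vector sample -> breed (VCF input).
#' @param simulate a `SimConfig`, or `NULL` when reading VCFs.
#' @param genes optional gene-model file path.
#' @param genes_format `"BED"` or `"GFF3"`.
#' @param groups named character vector breed -> group; `NULL` puts every
#'   breed in one group.
#' @param thresholds a [qc_thresholds()].
#' @param sex_chroms chromosome labels removed during QC.
#' @param pca_outlier_z robust-SD threshold for PCA outlier removal;
#'   `NA` disables the outlier step.
#' @param h_window,h_step haplotype-homozygosity window and step (SNPs).
#' @param smooth_k running-median width for FST and pi.
#' @param tajd_bin Tajima's D bin width in bp.
#' @param alpha,nsamp MCD subset fraction and starting-subset count.
#' @param sig,ext,min_seed region-calling thresholds.
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(vcf = NULL, pop_labels = NULL, simulate = NULL,
                       genes = NULL, genes_format = "BED", groups = NULL,
                       thresholds = qc_thresholds(),
                       sex_chroms = character(), pca_outlier_z = 3,
                       h_window = 14, h_step = 1, smooth_k = 31,
                       tajd_bin = 300000, alpha = 0.75, nsamp = 500,
                       sig = 0.05, ext = 0.1, min_seed = 2, seed = 1,
                       out_dir = NULL) {
  if (is.null(vcf) == is.null(simulate)) {
    stop("provide exactly one of vcf or simulate")
  }
  stopifnot(h_window >= 2, h_step >= 1, smooth_k %% 2 == 1, tajd_bin > 0,
            alpha > 0.5, alpha <= 1, nsamp >= 1, sig > 0, sig < 1,
            ext >= sig, ext < 1, min_seed >= 1)
  structure(list(vcf = vcf, pop_labels = pop_labels, simulate = simulate,
                 genes = genes, genes_format = genes_format,
                 groups = groups, thresholds = thresholds,
                 sex_chroms = sex_chroms, pca_outlier_z = pca_outlier_z,
                 h_window = h_window, h_step = h_step, smooth_k = smooth_k,
                 tajd_bin = tajd_bin, alpha = alpha, nsamp = nsamp,
                 sig = sig, ext = ext, min_seed = min_seed,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `thresholds` and
#' `simulate` may be nested maps, `pop_labels` and `groups` plain maps.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(qc_thresholds,
                                                      y$thresholds)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$sweeps)) {
      y$simulate$sweeps <- as.data.frame(do.call(rbind,
                                                 lapply(y$simulate$sweeps,
                                                        as.data.frame)))
    }
    y$simulate <- do.call(sim_config, y$simulate)
  }
  for (k in c("pop_labels", "groups")) {
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  }
  do.call(run_config, y)
}

# stable child seed per stage/breed, kept within 32-bit range
child_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1009 + 7919 * stage_index) %% 2147483647)
}

qc_and_merge <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- simulate_scan_dataset(cfg$simulate)
    panel0 <- sim$panel
    truth <- sim$truth
  } else {
    panels <- lapply(cfg$vcf, read_phased_vcf, pop_labels = cfg$pop_labels)
    panel0 <- if (length(panels) == 1) panels[[1]] else
      Reduce(merge_panels, panels)
    truth <- NULL
  }
  groups <- cfg$groups
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(unique(panel0$samples$pop))),
                              unique(panel0$samples$pop))
  }
  missing_breeds <- setdiff(unique(panel0$samples$pop), names(groups))
  if (length(missing_breeds) > 0) {
    stop("breeds without a QC group: ", paste(missing_breeds, collapse = ", "))
  }
  grp_of_sample <- unname(groups[panel0$samples$pop])
  reports <- list()
  filtered <- list()
  for (g in unique(grp_of_sample)) {
    sub <- subset_panel(panel0, samples = grp_of_sample == g)
    fr <- filter_panel(sub, cfg$thresholds, cfg$sex_chroms)
    filtered[[g]] <- fr$panel
    reports[[g]] <- fr$report
  }
  panel <- Reduce(merge_panels, filtered)
  pca <- NULL
  if (!is.na(cfg$pca_outlier_z) && n_samples(panel) >= 3) {
    pca <- pca_from_ibs(ibs_matrix(panel), n_components = 2,
                        breeds = panel$samples$pop,
                        outlier_z = cfg$pca_outlier_z)
    if (any(pca$outlier)) {
      panel <- subset_panel(panel, samples = !pca$outlier)
    }
  }
  list(panel = panel, qc_reports = reports, pca = pca, truth = truth)
}

#' Run the full selection-signature scan
#'
#' Per-group QC, mutual-SNP merge and PCA outlier removal, then for every
#' breed: the five statistic tracks on the merged panel (FST contrasting
#' the breed against all remaining samples pooled; pi, Tajima's D, H1 and
#' H12 within the breed), the DCMS composite with its robust-normal
#' calibration and BH q-values, region calling, and (when gene models are
#' supplied) distance-ranked gene annotation. When `cfg$out_dir` is set,
#' tracks, per-SNP composite tables, region/gene tables, the summary and a
#' JSON run-report are written there.
#'
#' @param cfg a `RunConfig`.
#' @return list of class `ScanResult`: `panel`, `qc_reports`, `truth`
#'   (simulated input only), per-breed `breeds` (tracks, `DcmsResult`,
#'   regions, hits), pooled `regions`, `hits`, `summary`, and `report`.
#' @export
run_scan <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  prep <- qc_and_merge(cfg)
  panel <- prep$panel
  genes <- if (!is.null(cfg$genes)) {
    read_gene_models(cfg$genes, cfg$genes_format, protein_coding_only = TRUE)
  } else NULL
  breeds <- unique(panel$samples$pop)
  multi <- length(breeds) > 1
  res <- list()
  all_regions <- list(); all_hits <- list()
  for (bi in seq_along(breeds)) {
    b <- breeds[bi]
    tracks <- list(
      FST = if (multi) wc_fst_per_snp(panel, b, cfg$smooth_k) else NULL,
      PI = site_pi(panel, b, cfg$smooth_k),
      TAJD = tajimas_d_per_snp(panel, b, cfg$tajd_bin)
    )
    hh <- window_h_stats(panel, b, cfg$h_window, cfg$h_step)
    tracks$H1 <- hh$h1
    tracks$H12 <- hh$h12
    tracks <- tracks[!vapply(tracks, is.null, TRUE)]
    dc <- dcms_from_tracks(tracks, alpha = cfg$alpha, nsamp = cfg$nsamp,
                           seed = child_seed(cfg$seed, bi))
    snps <- data.frame(chrom = panel$variants$chrom,
                       pos = panel$variants$pos, q = dc$q,
                       stringsAsFactors = FALSE)
    regions <- call_regions(snps, sig = cfg$sig, ext = cfg$ext,
                            min_seed = cfg$min_seed, breed = b)
    hits <- if (!is.null(genes) && nrow(regions) > 0) {
      annotate_regions(regions, genes)
    } else {
      annotate_regions(regions[0, , drop = FALSE],
                       data.frame(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  biotype = character()))
    }
    res[[b]] <- list(tracks = tracks, dcms = dc, regions = regions,
                     hits = hits)
    all_regions[[b]] <- regions
    all_hits[[b]] <- hits
  }
  regions <- do.call(rbind, c(all_regions, list(make.row.names = FALSE)))
  hits <- do.call(rbind, c(all_hits, list(make.row.names = FALSE)))
  summary <- summarize_regions(regions)
  report <- list(
    package = "dcmscan",
    version = as.character(utils::packageVersion("dcmscan")),
    seed = cfg$seed,
    parameters = cfg[c("h_window", "h_step", "smooth_k", "tajd_bin",
                       "alpha", "nsamp", "sig", "ext", "min_seed")],
    qc = lapply(prep$qc_reports, unclass),
    pca_outliers_removed = if (is.null(prep$pca)) 0L else
      sum(prep$pca$outlier),
    calibration = lapply(res, function(r) list(mu = r$dcms$mu,
                                               sd = r$dcms$sd)),
    correlation = lapply(res, function(r) r$dcms$R)
  )
  out <- structure(list(panel = panel, qc_reports = prep$qc_reports,
                        truth = prep$truth, breeds = res, regions = regions,
                        hits = hits, summary = summary, report = report),
                   class = "ScanResult")
  if (!is.null(cfg$out_dir)) write_scan_outputs(out, cfg)
  out
}

#' @export
print.ScanResult <- function(x, ...) {
  cat("ScanResult:", n_snps(x$panel), "SNPs,", n_samples(x$panel),
      "samples,", length(x$breeds), "breeds;", nrow(x$regions),
      "regions called\n")
  invisible(x)
}

write_scan_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- res$panel$variants
  for (b in names(res$breeds)) {
    r <- res$breeds[[b]]
    tab <- lapply(r$tracks, function(t) t$values)
    names(tab) <- tolower(names(tab))
    pcols <- as.data.frame(r$dcms$P)
    names(pcols) <- paste0("p_", tolower(colnames(r$dcms$P)))
    full <- cbind(v[, c("chrom", "pos", "id")], as.data.frame(tab), pcols,
                  dcms = r$dcms$dcms, p = r$dcms$p, q = r$dcms$q)
    utils::write.table(full, file.path(cfg$out_dir,
                                       paste0(b, "_dcms.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_region_table(r$regions, r$hits,
                       file.path(cfg$out_dir, paste0(b, "_regions.tsv")))
  }
  utils::write.table(res$summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$report,
                       file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  invisible(NULL)
}
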