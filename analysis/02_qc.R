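#!/usr/bin/env Rscript

# Step 2 — quality control and population structure.
#
# Reads the simulated phased panel, applies the SNP/sample filters per
# breed group (call rate >= 0.95, MAF >= 0.05, HWE p >= 1e-6), merges the
# groups on mutual SNPs, and checks the IBS-PCA for breed-cluster
# outliers. Writes the merged panel, QC report and PCA coordinates.

suppressPackageStartupMessages(library(dcmscan))
suppressPackageStartupMessages(library(jsonlite))

out <- "results"
vcf_samples <- function(path) {
  hdr <- grep("^#CHROM", readLines(path, n = 100), value = TRUE)
  strsplit(hdr, "\t", fixed = TRUE)[[1]][-(1:9)]
}
sample_ids <- vcf_samples("results/sim/panel.vcf")
pop_labels <- setNames(sub("_s[0-9]+$", "", sample_ids), sample_ids)

panel0 <- read_phased_vcf("results/sim/panel.vcf", pop_labels = pop_labels)
cat("Input:", n_snps(panel0), "SNPs,", n_samples(panel0), "samples\n")

# the simulated panel is one jointly-typed dataset, so QC runs as a
# single group (per-group QC applies when separately genotyped breed
# groups are merged)
groups <- c(pop1 = "all", pop2 = "all")
reports <- list()
filtered <- list()
for (g in unique(groups)) {
  keep <- panel0$samples$pop %in% names(groups)[groups == g]
  fr <- filter_panel(subset_panel(panel0, samples = keep))
  filtered[[g]] <- fr$panel
  reports[[g]] <- unclass(fr$report)
  cat("Group", g, ":", fr$report$snps_retained, "of",
      fr$report$input_snps, "SNPs retained\n")
}
panel <- Reduce(merge_panels, filtered)
cat("Merged mutual-SNP panel:", n_snps(panel), "SNPs\n")

pca <- pca_from_ibs(ibs_matrix(panel), breeds = panel$samples$pop)
cat("PCA outliers flagged:", sum(pca$outlier), "\n")
if (any(pca$outlier)) panel <- subset_panel(panel, samples = !pca$outlier)

dir.create(out, showWarnings = FALSE)
write_phased_vcf(panel, file.path(out, "panel_qc.vcf"))
write_json(reports, file.path(out, "qc_report.json"), auto_unbox = TRUE,
           digits = NA, pretty = TRUE)
write.table(data.frame(sample = panel$samples$sample,
                       pop = panel$samples$pop,
                       round(pca$coords[!pca$outlier, , drop = FALSE], 6)),
            file.path(out, "pca_coords.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("QC-passed panel written to", file.path(out, "panel_qc.vcf"), "\n")
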