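#!/usr/bin/env Rscript

# Step 3 — the five per-SNP statistics.
#
# On the merged post-QC panel, for each breed: Weir-Cockerham FST (breed
# vs the rest, negatives clipped, running-median k = 31), per-site
# nucleotide diversity (same smoothing), binned Tajima's D (300 kb bins,
# empty bins -> 0), and Garud's H1/H12 (14-SNP windows, step 1). One TSV
# per breed under results/tracks/.

suppressPackageStartupMessages(library(dcmscan))

out <- "results/tracks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

hdr <- grep("^#CHROM", readLines("results/panel_qc.vcf", n = 100),
            value = TRUE)
ids <- strsplit(hdr, "\t", fixed = TRUE)[[1]][-(1:9)]
panel <- read_phased_vcf("results/panel_qc.vcf",
                         pop_labels = setNames(sub("_s[0-9]+$", "", ids), ids))

for (b in unique(panel$samples$pop)) {
  hh <- window_h_stats(panel, b, window = 14, step = 1)
  tracks <- list(
    fst = wc_fst_per_snp(panel, b, smooth_k = 31)$values,
    pi = site_pi(panel, b, smooth_k = 31)$values,
    tajd = tajimas_d_per_snp(panel, b, bin_bp = 300000)$values,
    h1 = hh$h1$values, h12 = hh$h12$values
  )
  write_track_table(panel$variants, tracks,
                    file.path(out, paste0(b, "_tracks.tsv")))
  cat(sprintf(
    "%s: mean FST %.3f | mean pi %.3f | mean D %+.2f | median H12 %.3f\n",
    b, mean(tracks$fst), mean(tracks$pi), mean(tracks$tajd),
    median(tracks$h12)))
}
cat("Tracks written under", out, "\n")
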