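#!/usr/bin/env Rscript

# Step 1 — simulate the study panel.
#
# Two populations of diploid effective size 500 diverge for 200
# generations after a 100-generation ancestral burn-in; population pop1
# carries one hard sweep (s = 0.1, de-novo origin, survival-conditioned).
# 3000 biallelic SNPs on a 30 Mb chromosome, 25 diploids sampled per
# population. This moderate-drift regime keeps the genome-wide background
# below the saturation plateau discussed in the methods vignette, so the
# sweep footprint is typically recoverable. Writes the phased VCF, the
# sweep truth (BED) and the realized configuration under results/sim/.

suppressPackageStartupMessages(library(dcmscan))
suppressPackageStartupMessages(library(jsonlite))

seed <- 20260926L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_pops = 2, ne = 500, split_generations = 200,
  n_snps = 3000, chrom_length_bp = 30e6, rec_rate = 1e-8,
  burn_in_generations = 100, samples_per_pop = 25, seed = seed,
  sweeps = data.frame(pop = 1, snp_index = 1500, s = 0.1, mode = "de_novo"),
  condition_on_sweep_survival = TRUE
)
sim <- simulate_scan_dataset(cfg)

write_phased_vcf(sim$panel, file.path(out, "panel.vcf"))
# truth as BED (0-based half-open at the boundary)
with(sim$truth, writeLines(
  sprintf("%s\t%d\t%d\tsweep_%s_s%.2g", chrom, focal_pos - 1L, focal_pos,
          pop, s),
  file.path(out, "truth.bed")))
write_json(unclass(cfg), file.path(out, "sim_config.json"),
           auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Simulated", n_snps(sim$panel), "SNPs x", n_samples(sim$panel),
    "samples into", out, "\n")
cat("Sweep at", sim$truth$focal_pos, "bp reached frequency",
    round(sim$truth$final_freq, 3), "in", sim$truth$pop, "\n")
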