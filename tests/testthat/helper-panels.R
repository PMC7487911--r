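# small panel constructors used across the suite

toy_variants <- function(n, chrom = "1", step = 100L) {
  data.frame(chrom = chrom, pos = seq(step, by = step, length.out = n),
             id = paste0("s", seq_len(n)), ref = "A", alt = "C",
             stringsAsFactors = FALSE)
}

toy_samples <- function(n, pop = "p1") {
  data.frame(sample = paste0(pop, "_", seq_len(n)), pop = pop,
             stringsAsFactors = FALSE)
}

# panel from an explicit haplotype matrix (rows = haplotypes)
panel_from_H <- function(H, pop = "p1", chrom = "1") {
  H <- as.matrix(H)
  haplotype_panel(toy_variants(ncol(H), chrom = chrom),
                  toy_samples(nrow(H) / 2, pop = pop), H)
}

# random complete panel, optionally two populations
random_panel <- function(n_snps = 20, n_per_pop = 6, pops = c("p1", "p2"),
                         seed = 1) {
  set.seed(seed)
  samples <- do.call(rbind, lapply(pops, function(p) toy_samples(n_per_pop, p)))
  H <- matrix(rbinom(2 * nrow(samples) * n_snps, 1, 0.5),
              nrow = 2 * nrow(samples))
  haplotype_panel(toy_variants(n_snps), samples, H)
}

# panel built from per-population allele frequencies (one chromosome)
panel_from_freqs <- function(freq_by_pop, n_per_pop, seed = 1) {
  set.seed(seed)
  pops <- names(freq_by_pop)
  n_snps <- length(freq_by_pop[[1]])
  H <- NULL
  samples <- NULL
  for (p in pops) {
    Hp <- sapply(freq_by_pop[[p]], function(f)
      rbinom(2 * n_per_pop, 1, f))
    H <- rbind(H, Hp)
    samples <- rbind(samples, toy_samples(n_per_pop, p))
  }
  haplotype_panel(toy_variants(n_snps), samples, H)
}

write_toy_vcf <- function(path, gt_rows, samples = c("A", "B"),
                          chrom = "1", pos = NULL, ids = NULL) {
  n <- length(gt_rows)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n)
  if (is.null(ids)) ids <- paste0("v", seq_len(n))
  head <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(n), function(i)
    paste(c(chrom, pos[i], ids[i], "A", "C", ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t"), "")
  writeLines(c(head, body), path)
  path
}
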