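#' Configuration for the forward Wright-Fisher simulator
#'
#' Defines a set of populations diverged from a common ancestor: the
#' ancestral pool is initialized site-wise from a neutral-like frequency
#' law (density proportional to 1/f, truncated to
#' `[1/(2 Ne), 1 - 1/(2 Ne)]`), evolved `burn_in_generations` to build
#' linkage disequilibrium through recombination and drift, then split into
#' `n_pops` populations that drift (and optionally sweep) independently
#' for `split_generations`. There is no recurrent mutation: variation
#' enters only through the initial frequencies, which is sufficient for
#' sweep footprints over the short horizons simulated here.
#'
#' @param n_pops number of populations.
#' @param ne diploid effective size per population (recycled).
#' @param split_generations generations of independent evolution after the
#'   split.
#' @param n_snps number of biallelic SNPs on the single chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param rec_rate per-bp per-generation recombination rate (1e-8 is
#'   about 1 cM/Mb).
#' @param burn_in_generations ancestral generations before the split.
#' @param sweeps data.frame of hard sweeps, columns `pop` (1-based
#'   population index), `snp_index` (focal SNP ordinal), `s` (selection
#'   coefficient), `h` (dominance, default 0.5), `start_gen` (generation
#'   after the split at which selection starts, default 0), and `p0`
#'   (initial ancestral frequency of the focal allele, default 0.1; `NA`
#'   draws it from the neutral law like any other site); or `NULL`.
#'   An optional `mode` column selects `"standing"` (default: selection
#'   acts post-split on the standing focal variant, which drifts through
#'   the burn-in and may be lost) or `"de_novo"` (a single copy of the
#'   selected allele is introduced on one random haplotype of the swept
#'   population at the split — the classic hard-sweep origin).
#' @param condition_on_sweep_survival if `TRUE`, the post-split evolution
#'   of a swept population is re-drawn (up to `max_retries` times) until
#'   the selected allele survives to the final generation; off by default
#'   so that neutral-behaviour checks are unbiased. Losses under the
#'   default are recorded in the truth table, never an error.
#' @param max_retries retry cap under survival conditioning.
#' @param samples_per_pop diploid samples drawn per population at the end.
#' @param seed integer seed; every random draw derives from it.
#' @param chrom chromosome label on the output panel.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_pops = 2, ne = 200, split_generations = 150,
                       n_snps = 3000, chrom_length_bp = 30e6,
                       rec_rate = 1e-8, burn_in_generations = 100,
                       sweeps = NULL, samples_per_pop = 25, seed = 1,
                       chrom = "1", condition_on_sweep_survival = FALSE,
                       max_retries = 200) {
  ne <- rep_len(as.integer(ne), n_pops)
  stopifnot(n_pops >= 1, all(ne > 1), n_snps >= 1, chrom_length_bp >= n_snps,
            split_generations >= 0, burn_in_generations >= 0,
            all(samples_per_pop <= ne))
  if (!is.null(sweeps)) {
    sweeps <- as.data.frame(sweeps)
    if (is.null(sweeps$h)) sweeps$h <- 0.5
    if (is.null(sweeps$start_gen)) sweeps$start_gen <- 0
    if (is.null(sweeps$p0)) sweeps$p0 <- 0.1
    if (is.null(sweeps$mode)) sweeps$mode <- "standing"
    stopifnot(all(sweeps$mode %in% c("standing", "de_novo")))
    stopifnot(all(sweeps$pop %in% seq_len(n_pops)),
              all(sweeps$snp_index >= 1 & sweeps$snp_index <= n_snps),
              all(sweeps$s >= 0))
  }
  structure(list(n_pops = n_pops, ne = ne,
                 split_generations = split_generations, n_snps = n_snps,
                 chrom_length_bp = chrom_length_bp, rec_rate = rec_rate,
                 burn_in_generations = burn_in_generations, sweeps = sweeps,
                 samples_per_pop = rep_len(samples_per_pop, n_pops),
                 seed = as.integer(seed), chrom = chrom,
                 condition_on_sweep_survival =
                   isTRUE(condition_on_sweep_survival),
                 max_retries = max_retries),
            class = "SimConfig")
}

# one Wright-Fisher generation: 2N gametes, each a recombinant of the two
# haplotypes of a fitness-weighted parent
wf_generation <- function(H, pos, chrom_len, rec_rate, w = NULL) {
  n_ind <- nrow(H) / 2L
  n_gam <- nrow(H)
  parents <- if (is.null(w)) {
    sample.int(n_ind, n_gam, replace = TRUE)
  } else {
    sample.int(n_ind, n_gam, replace = TRUE, prob = w)
  }
  start_hap <- sample.int(2L, n_gam, replace = TRUE)
  n_cross <- stats::rpois(n_gam, rec_rate * chrom_len)
  plain <- n_cross == 0L
  Hnew <- H[2L * parents - 2L + start_hap, , drop = FALSE]
  for (g in which(!plain)) {
    xs <- sort(stats::runif(n_cross[g], 0, chrom_len))
    use_second <- (start_hap[g] - 1L + findInterval(pos, xs)) %% 2L == 1L
    h1 <- H[2L * parents[g] - 1L, ]
    h2 <- H[2L * parents[g], ]
    Hnew[g, ] <- ifelse(use_second, h2, h1)
  }
  Hnew
}

sweep_fitness <- function(H, snp_index, s, h) {
  n_ind <- nrow(H) / 2L
  g <- H[seq(1L, by = 2L, length.out = n_ind), snp_index] +
    H[seq(2L, by = 2L, length.out = n_ind), snp_index]
  c(1, 1 + h * s, 1 + s)[g + 1L]
}

#' Simulate a multi-population phased panel with known sweep truth
#'
#' Runs the Wright-Fisher model of [sim_config()] and draws
#' `samples_per_pop` diploids per population without replacement. The
#' returned truth table records, for every configured sweep, the focal
#' position and the final population frequency of the selected allele
#' (0 when the allele was lost; loss is recorded, never an error).
#'
#' @param cfg a `SimConfig`.
#' @return list with `panel` (a phased `HaplotypePanel`, populations
#'   labelled `pop1..popK`) and `truth` (data.frame `pop`, `chrom`,
#'   `focal_pos`, `snp_index`, `s`, `final_freq`).
#' @export
simulate_scan_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$n_snps))
    lo <- 1 / (2 * cfg$ne[1]); hi <- 1 - lo
    u <- stats::runif(cfg$n_snps)
    freq <- lo * (hi / lo)^u          # inverse CDF of density ~ 1/f
    if (!is.null(cfg$sweeps)) {
      pin <- !is.na(cfg$sweeps$p0) & cfg$sweeps$mode == "standing"
      freq[cfg$sweeps$snp_index[pin]] <- cfg$sweeps$p0[pin]
    }
    if (!is.null(cfg$sweeps)) {
      # a de-novo selected allele does not exist before its introduction
      freq[cfg$sweeps$snp_index[cfg$sweeps$mode == "de_novo"]] <- 0
    }
    n_anc <- 2L * cfg$ne[1]
    H <- matrix(stats::rbinom(n_anc * cfg$n_snps, 1L,
                              rep(freq, each = n_anc)),
                nrow = n_anc)
    for (g in seq_len(cfg$burn_in_generations)) {
      H <- wf_generation(H, pos, cfg$chrom_length_bp, cfg$rec_rate)
    }
    pops <- vector("list", cfg$n_pops)
    for (k in seq_len(cfg$n_pops)) {
      # found population k by drawing its first generation from the
      # ancestral pool
      Hk <- H
      if (cfg$ne[k] != cfg$ne[1]) {
        rows <- sample.int(nrow(H), 2L * cfg$ne[k], replace = TRUE)
        Hk <- H[rows, , drop = FALSE]
      }
      sw <- if (!is.null(cfg$sweeps)) {
        cfg$sweeps[cfg$sweeps$pop == k, , drop = FALSE]
      } else {
        data.frame()
      }
      if (nrow(sw) > 0 && any(sw$mode == "de_novo")) {
        for (i in which(sw$mode == "de_novo")) {
          Hk[, sw$snp_index[i]] <- 0L
          Hk[sample.int(nrow(Hk), 1L), sw$snp_index[i]] <- 1L
        }
      }
      # conditioning is only possible when the allele exists at the split
      condition <- cfg$condition_on_sweep_survival && nrow(sw) > 0 &&
        all(colSums(Hk[, sw$snp_index, drop = FALSE]) > 0)
      attempts <- if (condition) cfg$max_retries else 1L
      Hk0 <- Hk
      for (a in seq_len(attempts)) {
        Hk <- Hk0
        lost <- FALSE
        for (g in seq_len(cfg$split_generations)) {
          w <- NULL
          if (nrow(sw) > 0) {
            w <- rep(1, cfg$ne[k])
            for (i in seq_len(nrow(sw))) {
              if (g > sw$start_gen[i]) {
                w <- w * sweep_fitness(Hk, sw$snp_index[i], sw$s[i], sw$h[i])
              }
            }
          }
          Hk <- wf_generation(Hk, pos, cfg$chrom_length_bp, cfg$rec_rate, w)
          if (condition &&
              any(colSums(Hk[, sw$snp_index, drop = FALSE]) == 0L)) {
            lost <- TRUE
            break
          }
        }
        if (!lost) break
      }
      pops[[k]] <- Hk
    }
    truth <- NULL
    if (!is.null(cfg$sweeps) && nrow(cfg$sweeps) > 0) {
      truth <- data.frame(
        pop = paste0("pop", cfg$sweeps$pop), chrom = cfg$chrom,
        focal_pos = pos[cfg$sweeps$snp_index],
        snp_index = cfg$sweeps$snp_index, s = cfg$sweeps$s,
        final_freq = vapply(seq_len(nrow(cfg$sweeps)), function(i) {
          mean(pops[[cfg$sweeps$pop[i]]][, cfg$sweeps$snp_index[i]])
        }, 0), stringsAsFactors = FALSE)
    } else {
      truth <- data.frame(pop = character(), chrom = character(),
                          focal_pos = integer(), snp_index = integer(),
                          s = numeric(), final_freq = numeric(),
                          stringsAsFactors = FALSE)
    }
    Hs <- vector("list", cfg$n_pops)
    samples <- NULL
    for (k in seq_len(cfg$n_pops)) {
      ind <- sort(sample.int(cfg$ne[k], cfg$samples_per_pop[k]))
      Hs[[k]] <- pops[[k]][hap_rows(ind), , drop = FALSE]
      samples <- rbind(samples, data.frame(
        sample = sprintf("pop%d_s%02d", k, seq_along(ind)),
        pop = paste0("pop", k), stringsAsFactors = FALSE))
    }
    variants <- data.frame(chrom = cfg$chrom, pos = pos,
                           id = paste0("snp", seq_len(cfg$n_snps)),
                           ref = "A", alt = "C", stringsAsFactors = FALSE)
    panel <- haplotype_panel(variants, samples, do.call(rbind, Hs),
                             phased = TRUE)
    list(panel = panel, truth = truth)
  })
}
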