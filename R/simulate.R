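#' Simulation configuration
#'
#' Defines a seeded multi-population scenario on one chromosome: ancestral
#' allele frequencies with per-population Balding-Nichols drift, optional
#' two-source admixture, phased haplotypes built as founder mosaics with
#' recombination-driven LD decay, and an optional localized hard sweep.
#' The defaults are the package's reference scenario: four populations
#' (fat-rump-like E1, two long-fat-tail-like E2/E3, thin-tail-like S) with
#' drift F = 0.05, 20 diploid samples each, 20,000 SNPs on a 50-Mb
#' chromosome and a sweep in E1 at 25 Mb with a 300-kb half-width.
#'
#' @param n_pops Number of populations.
#' @param samples_per_pop Diploid samples per population.
#' @param n_snps SNPs (evenly spaced on the chromosome).
#' @param chrom_length Chromosome length in bp.
#' @param fst_drift Per-population Balding-Nichols F (recycled).
#' @param admixture `NULL` or `list(target =, sources = c(,), theta =)`;
#'   the target's frequencies become
#'   `theta * p_source1 + (1 - theta) * p_source2`.
#' @param sweep `NULL` or `list(pop =, center =, half_width =,
#'   founder_fraction =)`.
#' @param recomb_switch_rate Per-bp founder-switch probability of the
#'   haplotype-copying model.
#' @param n_founders Founder haplotypes per population pool.
#' @param pop_names Population labels; defaults to E1/E2/E3/S for four
#'   populations.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 4, samples_per_pop = 20, n_snps = 20000,
                       chrom_length = 5e7, fst_drift = 0.05,
                       admixture = NULL,
                       sweep = list(pop = "E1", center = 2.5e7,
                                    half_width = 3e5,
                                    founder_fraction = 0.05),
                       recomb_switch_rate = 1e-5, n_founders = 20,
                       pop_names = NULL, seed = 20190109) {
  if (is.null(pop_names)) {
    pop_names <- if (n_pops == 4) c("E1", "E2", "E3", "S")
                 else paste0("P", seq_len(n_pops))
  }
  if (length(pop_names) != n_pops) abort("pop_names length must equal n_pops")
  fst_drift <- rep_len(fst_drift, n_pops)
  if (any(fst_drift <= 0 | fst_drift >= 1)) abort("fst_drift must lie in (0, 1)")
  if (!is.null(admixture)) {
    if (admixture$theta < 0 || admixture$theta > 1) abort("theta must lie in [0, 1]")
    if (!all(c(admixture$target, admixture$sources) %in% pop_names)) {
      abort("admixture populations must be among pop_names")
    }
  }
  if (!is.null(sweep)) {
    if (!sweep$pop %in% pop_names) abort("sweep population must be among pop_names")
    if (sweep$center - sweep$half_width < 1 ||
        sweep$center + sweep$half_width > chrom_length) {
      abort("sweep interval must lie within the chromosome")
    }
    if (sweep$founder_fraction <= 0 || sweep$founder_fraction > 1) {
      abort("founder_fraction must lie in (0, 1]")
    }
  }
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 n_snps = n_snps, chrom_length = chrom_length,
                 fst_drift = setNames(fst_drift, pop_names),
                 admixture = admixture, sweep = sweep,
                 recomb_switch_rate = recomb_switch_rate,
                 n_founders = n_founders, pop_names = pop_names,
                 seed = seed),
            class = "sim_config")
}

sim_variants <- function(cfg) {
  pos <- pmax(1, round((seq_len(cfg$n_snps) - 0.5) *
                         cfg$chrom_length / cfg$n_snps))
  tibble(chrom = "1", pos = pos,
         variant_id = paste0("snp", seq_len(cfg$n_snps)),
         ref = "A", alt = "G")
}

#' Simulate true population allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95) per SNP; each population
#' drifts via the Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with its own F.  An admixed target's
#' frequencies are the theta-mixture of its sources' drifted frequencies.
#' Fully deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `freq_table` of true frequencies (counts filled with
#'   `2 * samples_per_pop`, the allele total a matching genotype sample
#'   would have).
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  m <- cfg$n_snps
  anc <- runif(m, 0.05, 0.95)
  freqs <- matrix(NA_real_, cfg$n_pops, m,
                  dimnames = list(cfg$pop_names, NULL))
  for (i in seq_len(cfg$n_pops)) {
    F <- cfg$fst_drift[i]
    freqs[i, ] <- rbeta(m, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
  }
  if (!is.null(cfg$admixture)) {
    adm <- cfg$admixture
    freqs[adm$target, ] <- adm$theta * freqs[adm$sources[1], ] +
      (1 - adm$theta) * freqs[adm$sources[2], ]
  }
  ft <- freq_table(cfg$pop_names, freqs, 2 * cfg$samples_per_pop,
                   sim_variants(cfg))
  attr(ft, "ancestral") <- anc
  ft
}

#' Simulate phased haplotypes from population frequencies
#'
#' Per population, a founder pool of `n_founders` haplotypes is drawn
#' Bernoulli from the population frequencies, and each sample haplotype is
#' a Li-Stephens-style founder mosaic with per-gap switch probability
#' `1 - (1 - rate)^gap`, giving geometric-decay LD.  In the sweep
#' population, each haplotype is "swept" with probability
#' `1 - founder_fraction`; a swept haplotype carries the founder-1 tract
#' from the sweep center outward to a per-side escape distance drawn
#' uniformly between half and the full `half_width` (a recombination-escape
#' taper, so homozygosity and differentiation peak at the center and are
#' guaranteed over the inner half of the interval).
#'
#' @param cfg A [sim_config()].
#' @param freqs A `freq_table` from [simulate_frequencies()] (same config).
#' @return A list with `haplotypes` (a `hap_set` over all samples) and
#'   `samples` (sample table with population labels).
#' @export
simulate_haplotypes <- function(cfg, freqs) {
  set.seed(cfg$seed + 1)
  m <- cfg$n_snps
  variants <- freqs$variants
  gaps <- c(0, diff(variants$pos))
  switch_prob <- 1 - (1 - cfg$recomb_switch_rate)^gaps
  n_hap <- 2 * cfg$samples_per_pop
  hap_list <- vector("list", cfg$n_pops)
  ids_list <- vector("list", cfg$n_pops)
  for (i in seq_len(cfg$n_pops)) {
    pop <- cfg$pop_names[i]
    founders <- matrix(rbinom(cfg$n_founders * m, 1,
                              rep(freqs$freqs[i, ], each = cfg$n_founders)),
                       nrow = cfg$n_founders)
    H <- .mosaic_cpp(founders, n_hap, switch_prob)
    if (!is.null(cfg$sweep) && pop == cfg$sweep$pop) {
      sw <- cfg$sweep
      swept <- runif(n_hap) < (1 - sw$founder_fraction)
      e_left <- sw$half_width * (0.5 + 0.5 * runif(n_hap))
      e_right <- sw$half_width * (0.5 + 0.5 * runif(n_hap))
      for (h in which(swept)) {
        cols <- variants$pos >= sw$center - e_left[h] &
          variants$pos <= sw$center + e_right[h]
        H[h, cols] <- founders[1, cols]
      }
    }
    hap_list[[i]] <- H
    ids_list[[i]] <- rep(paste0(pop, "_", seq_len(cfg$samples_per_pop)),
                         each = 2)
  }
  sample_id <- unlist(ids_list)
  h <- haplotype_set(do.call(rbind, hap_list), sample_id, variants)
  samples <- tibble(sample_id = unique(sample_id),
                    population = rep(cfg$pop_names,
                                     each = cfg$samples_per_pop))
  list(haplotypes = h, samples = samples)
}

#' Simulate a complete dataset (frequencies, haplotypes, genotypes, truth)
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (`geno_dataset`), `haplotypes`
#'   (`hap_set`), `freqs` (true `freq_table`), `truth` (sweep/admixture
#'   spec and seed) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  freqs <- simulate_frequencies(cfg)
  hs <- simulate_haplotypes(cfg, freqs)
  geno <- collapse_haplotypes(hs$haplotypes, hs$samples)
  list(genotypes = geno, haplotypes = hs$haplotypes, freqs = freqs,
       truth = list(sweep = cfg$sweep, admixture = cfg$admixture,
                    seed = cfg$seed),
       config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits the PLINK trio, a phased plain-text VCF, a sample-to-population
#' TSV and `truth.json` (sweep interval, admixture spec, seed); reading the
#' files back reproduces the in-memory data.
#'
#' @param sim Output of [simulate_dataset()].
#' @param out_prefix Path prefix for all files.
#' @return `out_prefix`, invisibly.
#' @export
write_dataset <- function(sim, out_prefix) {
  write_plink(sim$genotypes, out_prefix)
  write_vcf(sim$genotypes, paste0(out_prefix, ".vcf"),
            haplotypes = sim$haplotypes)
  readr::write_tsv(sim$genotypes$samples[, c("sample_id", "population")],
                   paste0(out_prefix, ".pops.tsv"))
  jsonlite::write_json(sim$truth, paste0(out_prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_prefix)
}
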