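pop_mask <- function(d, pop) {
  labels <- pop_labels(d)
  mask <- labels == pop
  if (!any(mask)) abort(paste("population not present:", pop))
  mask
}

pop_freq_stats <- function(d, pop) {
  calls <- d$calls[pop_mask(d, pop), , drop = FALSE]
  nm <- colSums(!is.na(calls))
  p <- ifelse(nm > 0, colMeans(calls, na.rm = TRUE) / 2, NA_real_)
  list(calls = calls, n_nonmiss = nm, p = p, usable = nm > 0)
}

#' Proportion of polymorphic SNPs in a population
#'
#' Fraction of variants segregating (0 < alt frequency < 1) within the
#' population, among variants with at least one non-missing call there.
#'
#' @param d A `geno_dataset`.
#' @param pop Population label.
#' @return A fraction in `[0, 1]`.
#' @export
prop_polymorphic <- function(d, pop) {
  st <- pop_freq_stats(d, pop)
  p <- st$p[st$usable]
  mean(p > 0 & p < 1)
}

#' Mean expected heterozygosity in a population
#'
#' Per SNP `2 p (1 - p)` from the within-population alt frequency, averaged
#' over SNPs with at least one non-missing call in the population.  With
#' `unbiased = TRUE` the Nei small-sample correction `2n/(2n - 1)` is
#' applied per SNP.
#'
#' @inheritParams prop_polymorphic
#' @param unbiased Apply the allele-count small-sample correction.
#'   Default `FALSE` (plain 2pq mean).
#' @return Mean expected heterozygosity.
#' @export
expected_het <- function(d, pop, unbiased = FALSE) {
  st <- pop_freq_stats(d, pop)
  p <- st$p[st$usable]
  he <- 2 * p * (1 - p)
  if (unbiased) {
    c_al <- 2 * st$n_nonmiss[st$usable]
    he <- he * c_al / (c_al - 1)
  }
  mean(he)
}

#' Mean observed heterozygosity in a population
#'
#' Per SNP, the fraction of heterozygous calls among non-missing calls,
#' averaged over SNPs with at least one non-missing call.
#'
#' @inheritParams prop_polymorphic
#' @return Mean observed heterozygosity.
#' @export
observed_het <- function(d, pop) {
  st <- pop_freq_stats(d, pop)
  het <- colSums(st$calls == 1L, na.rm = TRUE)[st$usable] /
    st$n_nonmiss[st$usable]
  mean(het)
}

#' Mean method-of-moments inbreeding coefficient in a population
#'
#' Per individual, `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the
#' observed homozygous count over that individual's non-missing SNPs, `L`
#' the number of such SNPs, and `E_hom` sums `1 - 2p(1-p) * c/(c-1)` with
#' `p` the within-population alt frequency and `c` the population's
#' non-missing allele count at the SNP.  The population value is the mean
#' over individuals.
#'
#' @inheritParams prop_polymorphic
#' @return Mean inbreeding coefficient.
#' @export
inbreeding_f <- function(d, pop) {
  st <- pop_freq_stats(d, pop)
  if (nrow(st$calls) < 2) {
    abort("inbreeding F needs at least 2 individuals (sample-size correction)")
  }
  c_al <- 2 * st$n_nonmiss
  ehet <- ifelse(c_al > 1, 2 * st$p * (1 - st$p) * c_al / (c_al - 1), NA_real_)
  f_ind <- apply(st$calls, 1, function(g) {
    nm <- !is.na(g) & !is.na(ehet)
    L <- sum(nm)
    if (L == 0) return(NA_real_)
    o_hom <- sum(g[nm] != 1L)
    e_hom <- sum(1 - ehet[nm])
    if (abs(L - e_hom) < .Machine$double.eps) return(NA_real_)
    (o_hom - e_hom) / (L - e_hom)
  })
  mean(f_ind, na.rm = TRUE)
}

#' Per-population diversity table
#'
#' One row per population: sample size, proportion of polymorphic SNPs
#' (`pn`), mean expected (`he`) and observed (`ho`) heterozygosity, and the
#' mean inbreeding coefficient (`f`).
#'
#' @param d A `geno_dataset` with population labels.
#' @param unbiased_he Passed to [expected_het()].
#' @return A tibble with columns `population`, `n`, `pn`, `he`, `ho`, `f`.
#' @export
diversity_table <- function(d, unbiased_he = FALSE) {
  pops <- unique(pop_labels(d))
  purrr::map_dfr(pops, function(pop) {
    tibble(population = pop,
           n = sum(d$samples$population == pop),
           pn = prop_polymorphic(d, pop),
           he = expected_het(d, pop, unbiased = unbiased_he),
           ho = observed_het(d, pop),
           f = if (sum(d$samples$population == pop) > 1)
             inbreeding_f(d, pop) else NA_real_)
  })
}
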