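#' Per-SNP two-group FST
#'
#' The estimator `1 - (p1 q1 + p2 q2) / (2 pr qr)` with `pr = (p1 + p2)/2`
#' and `qr = 1 - pr`: the fraction of heterozygosity lost relative to the
#' pooled (mean) frequency.  SNPs monomorphic across both groups
#' (`pr qr = 0`) are undefined and return `NA` (excluded, not zero).
#'
#' @param p1,p2 Alt-allele frequencies in groups 1 and 2 (vectorized).
#' @return Per-SNP FST values in `[0, 1]`, `NA` where undefined.
#' @export
fst_snp <- function(p1, p2) {
  q1 <- 1 - p1
  q2 <- 1 - p2
  pr <- (p1 + p2) / 2
  qr <- 1 - pr
  ifelse(pr * qr > 0, 1 - (p1 * q1 + p2 * q2) / (2 * pr * qr), NA_real_)
}

#' Windowed FST scan with Z-score standardization
#'
#' Per-SNP FST between two groups is averaged within each window of the
#' grid; window means are standardized to Z-scores (ZFST) using the mean
#' and population SD over all emitted windows of the comparison.
#'
#' @param f A `freq_table` whose rows include the two groups (pool
#'   populations first with [pool_freqs()] if needed).
#' @param groups Length-2 character vector of group labels.
#' @param grid Window grid from [window_grid()].
#' @param min_snps Minimum usable SNPs for a window to be emitted.
#'   Default 1.
#' @return Tibble of window statistics: `chrom`, `start`, `end`,
#'   `method = "fst"`, `raw`, `standardized`, `p` (always 1; this arm uses
#'   the Z threshold), `n_snps`.
#' @export
fst_windows <- function(f, groups, grid, min_snps = 1) {
  if (length(groups) != 2) abort("fst_windows needs exactly 2 groups")
  idx <- match(groups, f$pops)
  if (anyNA(idx)) abort("group label not present in freq_table")
  fst <- fst_snp(f$freqs[idx[1], ], f$freqs[idx[2], ])
  ok <- !is.na(fst)
  snps <- tibble(chrom = f$variants$chrom[ok], pos = f$variants$pos[ok],
                 value = fst[ok])
  w <- grid_window_stats(snps, grid)
  w <- w[w$n_snps >= max(min_snps, 1), , drop = FALSE]
  if (nrow(w) == 0) abort("no windows with usable SNPs")
  w$method <- "fst"
  w$standardized <- standardize(w$raw)
  w$p <- 1
  select(w, "chrom", "start", "end", "method", "raw", "standardized", "p",
         "n_snps")
}
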