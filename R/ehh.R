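#' Site-EHH curve from a focal SNP
#'
#' Extended haplotype homozygosity (allele-agnostic site version): at each
#' SNP out to distance d, the probability that two haplotypes drawn without
#' replacement are identical over all SNPs from the focal out to d (the
#' focal allele included).  The curve starts at 1 at the focal SNP by
#' convention and is truncated at the first point where EHH drops below
#' `cutoff` (excluded), an inter-SNP gap exceeds `max_gap`, or the
#' chromosome ends.
#'
#' @param h A `hap_set` restricted to one population/group (single
#'   chromosome).
#' @param focal Focal variant index (1-based column of `h`).
#' @param side `"left"` or `"right"`.
#' @param cutoff EHH truncation threshold.  Default 0.05.
#' @param max_gap Maximum tolerated inter-SNP gap in bp.  Default 200,000.
#' @return Tibble with `pos` and `ehh`, focal point first.
#' @export
ehh <- function(h, focal, side = c("right", "left"), cutoff = 0.05,
                max_gap = 200000) {
  side <- match.arg(side)
  if (length(unique(h$variants$chrom)) != 1) {
    abort("EHH runs on a single chromosome")
  }
  as_tibble(.ehh_side_cpp(h$haplotypes, h$variants$pos, as.integer(focal),
                          if (side == "right") 1L else -1L, cutoff, max_gap))
}

#' Integrated site-EHH (iES) at a focal SNP
#'
#' The trapezoidal integral of the site-EHH curve over physical position,
#' both sides of the focal SNP summed; units bp.
#'
#' @inheritParams ehh
#' @return A single non-negative number.
#' @export
ies <- function(h, focal, cutoff = 0.05, max_gap = 200000) {
  left <- ehh(h, focal, "left", cutoff, max_gap)
  right <- ehh(h, focal, "right", cutoff, max_gap)
  trap <- function(tb) {
    if (nrow(tb) < 2) return(0)
    sum(0.5 * (tb$ehh[-1] + tb$ehh[-nrow(tb)]) * abs(diff(tb$pos)))
  }
  trap(left) + trap(right)
}

# iES at every SNP, per chromosome, via the compiled kernel
ies_all <- function(h, cutoff = 0.05, max_gap = 200000) {
  out <- numeric(ncol(h$haplotypes))
  for (chr in unique(h$variants$chrom)) {
    idx <- which(h$variants$chrom == chr)
    out[idx] <- .ies_batch_cpp(h$haplotypes[, idx, drop = FALSE],
                               h$variants$pos[idx], cutoff, max_gap)
  }
  out
}

#' Two-sided significance transform for standardized Rsb
#'
#' `P_Rsb = -log10(1 - 2 (Phi(|Rsb|) - 0.5))` with `Phi` the Gaussian CDF:
#' the `-log10` of the two-sided normal p-value of a standardized Rsb
#' score.  A score of 3.29 (the two-sided 0.001 quantile) maps to 3.
#'
#' @param rsb_std Standardized Rsb values.
#' @return `P_Rsb` values (capped at the smallest representable p).
#' @export
prsb <- function(rsb_std) {
  -log10(pmax(2 * pnorm(abs(rsb_std), lower.tail = FALSE),
              .Machine$double.xmin))
}

#' Cross-population Rsb scan
#'
#' For every SNP shared by the two groups, computes `ln(iES1 / iES2)`,
#' standardizes by median-centring and (population-)SD scaling across SNPs,
#' and transforms to the two-sided significance scale
#' `P_Rsb = -log10(1 - 2(Phi(|Rsb|) - 0.5))`.  Each window of the grid
#' carries the maximum `P_Rsb` of its SNPs.
#'
#' @param h1,h2 `hap_set` objects for groups 1 and 2 with identical variant
#'   tables.
#' @param grid Window grid from [window_grid()], or `NULL` to skip the
#'   window table.
#' @param cutoff,max_gap EHH truncation parameters (see [ehh()]).
#' @param min_snps Minimum SNPs per emitted window.  Default 1.
#' @return List with `snps` (per-SNP tibble: `chrom`, `pos`, `ies1`,
#'   `ies2`, `rsb`, `rsb_std`, `prsb`) and `windows` (window tibble,
#'   `method = "rsb"`, `raw` = max `P_Rsb`, `standardized` = max
#'   `|rsb_std|`, `p = 10^-raw`).
#' @export
rsb_scan <- function(h1, h2, grid = NULL, cutoff = 0.05, max_gap = 200000,
                     min_snps = 1) {
  if (!identical(paste(h1$variants$chrom, h1$variants$pos),
                 paste(h2$variants$chrom, h2$variants$pos))) {
    abort("the two groups must share one variant table")
  }
  ies1 <- ies_all(h1, cutoff, max_gap)
  ies2 <- ies_all(h2, cutoff, max_gap)
  ok <- ies1 > 0 & ies2 > 0
  if (any(!ok)) {
    inform(sprintf("excluded %d SNP(s) with zero iES", sum(!ok)))
  }
  raw <- log(ies1[ok] / ies2[ok])
  s <- sd_pop(raw)
  # a constant ratio (e.g. identical groups) carries no signal: all scores 0
  std <- if (!is.finite(s) || s == 0) rep(0, length(raw))
         else (raw - median(raw)) / s
  snps <- tibble(chrom = h1$variants$chrom[ok], pos = h1$variants$pos[ok],
                 ies1 = ies1[ok], ies2 = ies2[ok],
                 rsb = raw, rsb_std = std, prsb = prsb(std))
  windows <- NULL
  if (!is.null(grid)) {
    snps2 <- mutate(snps, abs_std = abs(.data$rsb_std))
    w <- grid_window_max(snps2, grid, c("prsb", "abs_std"))
    w <- w[w$n_snps >= max(min_snps, 1), , drop = FALSE]
    windows <- tibble(chrom = w$chrom, start = w$start, end = w$end,
                      method = "rsb", raw = w$prsb,
                      standardized = w$abs_std, p = 10^(-w$prsb),
                      n_snps = w$n_snps)
  }
  list(snps = snps, windows = windows)
}
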