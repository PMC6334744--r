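#' Per-SNP FLK statistic
#'
#' The kinship-corrected Lewontin-Krakauer test: for each SNP with
#' population frequency vector `p`, the ancestral frequency is estimated as
#' `p0 = (1' K^-1 p) / (1' K^-1 1)` and the statistic is the quadratic form
#' `(p - p0)' V^-1 (p - p0)` with drift covariance `V = K p0 (1 - p0)`.
#' Under neutrality the statistic is approximately chi-squared with
#' `n_pops - 1` degrees of freedom.  SNPs with estimated `p0` of 0 or 1 are
#' excluded (`NA`).
#'
#' @param f A `freq_table` (all populations are used, in kinship order).
#' @param kinship Shared-drift kinship matrix with population names, e.g.
#'   from [kinship_from_tree()].
#' @return Tibble with `chrom`, `pos`, `variant_id`, `p0`, `flk`.
#' @export
flk_snp <- function(f, kinship) {
  pops <- rownames(kinship)
  if (is.null(pops)) abort("kinship matrix needs population names")
  idx <- match(pops, f$pops)
  if (anyNA(idx)) {
    abort(paste("populations missing from freq_table:",
                paste(pops[is.na(idx)], collapse = ", ")))
  }
  if (length(pops) < 2) abort("FLK needs at least 2 populations")
  P <- f$freqs[idx, , drop = FALSE]
  Kinv <- tryCatch(solve(kinship), error = function(e) {
    abort(paste("kinship matrix is singular for populations:",
                paste(pops, collapse = ", ")))
  })
  u <- Kinv %*% rep(1, length(pops))
  p0 <- as.vector(crossprod(u, P)) / sum(u)
  dev <- sweep(P, 2, p0)
  quad <- colSums(dev * (Kinv %*% dev))
  het0 <- p0 * (1 - p0)
  flk <- ifelse(het0 > 0 & !is.na(p0) & colSums(is.na(P)) == 0,
                quad / het0, NA_real_)
  tibble(chrom = f$variants$chrom, pos = f$variants$pos,
         variant_id = f$variants$variant_id, p0 = p0, flk = flk)
}

#' Windowed FLK scan with chi-square-scaled p-values
#'
#' Per-SNP FLK values are averaged within windows; window means are
#' standardized to Z-scores, and p-values come from a scaled chi-square
#' fitted to the empirical window distribution by moment matching
#' (effective scale `s = var/(2 mean)` and df `k = 2 mean^2 / var`, upper
#' tail at `raw/s` with `k` df).
#'
#' @param snp_flk Output of [flk_snp()].
#' @param grid Window grid from [window_grid()].
#' @param min_snps Minimum usable SNPs per emitted window.  Default 1.
#' @return Tibble of window statistics (`method = "flk"`).
#' @export
flk_windows <- function(snp_flk, grid, min_snps = 1) {
  ok <- !is.na(snp_flk$flk)
  snps <- tibble(chrom = snp_flk$chrom[ok], pos = snp_flk$pos[ok],
                 value = snp_flk$flk[ok])
  w <- grid_window_stats(snps, grid)
  w <- w[w$n_snps >= max(min_snps, 1), , drop = FALSE]
  if (nrow(w) == 0) abort("no windows with usable SNPs")
  mu <- mean(w$raw)
  v <- sd_pop(w$raw)^2
  if (v == 0) abort("cannot fit chi-square scaling: window FLK variance is zero")
  s <- v / (2 * mu)
  k <- 2 * mu^2 / v
  w$method <- "flk"
  w$standardized <- standardize(w$raw)
  w$p <- pchisq(w$raw / s, df = k, lower.tail = FALSE)
  select(w, "chrom", "start", "end", "method", "raw", "standardized", "p",
         "n_snps")
}
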