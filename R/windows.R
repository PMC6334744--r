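#' Standardize values to Z-scores
#'
#' `(x - mean) / sd` with the population (divide-by-N) standard deviation;
#' shared by the windowed FST and FLK arms of the scan.
#'
#' @param values Numeric vector.
#' @return Z-scores with mean 0 and (population) SD 1.
#' @export
standardize <- function(values) {
  s <- sd_pop(values)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize: zero variance across values")
  }
  (values - mean(values)) / s
}

#' Sliding-window grid over the genome
#'
#' Windows of `size` bp sliding by `step` bp along each chromosome; starts
#' are `1 + k * step` and ends `start + size - 1`, with the final window
#' truncated at the chromosome end.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp.  Default 200,000.
#' @param step Slide distance in bp.  Default 60,000.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
window_grid <- function(chrom_lengths, size = 200000, step = 60000) {
  purrr::map_dfr(names(chrom_lengths), function(chr) {
    L <- chrom_lengths[[chr]]
    starts <- seq(1, max(L - size + 1, 1), by = step)
    last_end <- starts[length(starts)] + size - 1
    if (last_end < L) starts <- c(starts, starts[length(starts)] + step)
    tibble(chrom = chr, start = starts, end = pmin(starts + size - 1, L))
  })
}

# Mean of a per-SNP statistic in every window: positions and values must be
# from a single chromosome, sorted by position. Returns raw mean and n_snps
# per window (0-SNP windows included; caller filters).
window_means <- function(pos, value, starts, ends) {
  cs <- c(0, cumsum(value))
  lo <- findInterval(starts - 0.5, pos)   # SNPs strictly before start
  hi <- findInterval(ends + 0.5, pos)     # SNPs at or before end
  n <- hi - lo
  raw <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
  list(raw = raw, n_snps = n)
}

# Apply window_means across chromosomes of a grid; snp tibble needs
# chrom/pos/value (pre-sorted by chrom_key, pos).
grid_window_stats <- function(snps, grid) {
  purrr::map_dfr(unique(grid$chrom), function(chr) {
    g <- grid[grid$chrom == chr, , drop = FALSE]
    s <- snps[snps$chrom == chr, , drop = FALSE]
    if (nrow(s) == 0) {
      return(tibble(chrom = chr, start = g$start, end = g$end,
                    raw = NA_real_, n_snps = 0L))
    }
    wm <- window_means(s$pos, s$value, g$start, g$end)
    tibble(chrom = chr, start = g$start, end = g$end,
           raw = wm$raw, n_snps = as.integer(wm$n_snps))
  })
}

# Max of a per-SNP statistic in every window (same contract as above).
grid_window_max <- function(snps, grid, cols) {
  purrr::map_dfr(unique(grid$chrom), function(chr) {
    g <- grid[grid$chrom == chr, , drop = FALSE]
    s <- snps[snps$chrom == chr, , drop = FALSE]
    out <- tibble(chrom = chr, start = g$start, end = g$end, n_snps = 0L)
    for (cl in cols) out[[cl]] <- NA_real_
    if (nrow(s) == 0) return(out)
    lo <- findInterval(g$start - 0.5, s$pos)
    hi <- findInterval(g$end + 0.5, s$pos)
    out$n_snps <- as.integer(hi - lo)
    for (k in seq_len(nrow(g))) {
      if (out$n_snps[k] > 0) {
        idx <- (lo[k] + 1):hi[k]
        for (cl in cols) out[[cl]][k] <- max(s[[cl]][idx])
      }
    }
    out
  })
}
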