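#' Greedy LD pruning towards approximate linkage equilibrium
#'
#' Slides a `window_snps`-wide window along each chromosome in steps of
#' `step_snps`; within a window, for every pair of retained SNPs whose
#' squared genotype correlation exceeds `r2_max`, the SNP with the lower MAF
#' is removed (ties remove the later position).  Deterministic for a fixed
#' input.
#'
#' @param d A post-QC `geno_dataset`.
#' @param window_snps Window width in SNPs.  Default 50.
#' @param step_snps Step in SNPs.  Default 5.
#' @param r2_max Maximum tolerated r-squared.  Default 0.5.
#' @return The pruned `geno_dataset`.
#' @export
ld_prune <- function(d, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  m <- nrow(d$variants)
  if (m < 2) return(d)
  p <- colMeans(d$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  for (chr in unique(d$variants$chrom)) {
    idx <- which(d$variants$chrom == chr)
    if (length(idx) < 2) next
    starts <- seq(1, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- suppressWarnings(
        cor(d$calls[, win, drop = FALSE], use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      for (i in seq_len(length(win) - 1)) {
        if (!keep[win[i]]) next
        for (j in seq((i + 1), length(win))) {
          if (!keep[win[j]]) next
          if (r2[i, j] > r2_max) {
            drop <- if (maf[win[i]] < maf[win[j]]) win[i]
                    else if (maf[win[j]] < maf[win[i]]) win[j]
                    else win[j]  # tie: later position
            keep[drop] <- FALSE
            if (drop == win[i]) break
          }
        }
      }
    }
  }
  subset_variants(d, keep)
}

#' Linkage-disequilibrium decay from phased haplotypes
#'
#' Pairwise haplotype r-squared for SNP pairs within `max_dist` of each
#' other on the same chromosome, averaged within equal-width distance bins.
#' Monomorphic SNPs (r-squared undefined) are excluded.
#'
#' @param h A `hap_set`.
#' @param max_dist Maximum pair distance in bp.
#' @param n_bins Number of distance bins.
#' @return Tibble with `bin_mid` (bp), `mean_r2` and `n_pairs`.
#' @export
ld_decay <- function(h, max_dist, n_bins) {
  H <- h$haplotypes
  poly <- col_vars(H) > 0
  dists <- numeric(0)
  r2s <- numeric(0)
  for (chr in unique(h$variants$chrom)) {
    idx <- which(h$variants$chrom == chr & poly)
    if (length(idx) < 2) next
    pos <- h$variants$pos[idx]
    for (i in seq_len(length(idx) - 1)) {
      jmax <- i
      while (jmax < length(idx) && pos[jmax + 1] - pos[i] <= max_dist) jmax <- jmax + 1
      if (jmax == i) next
      js <- (i + 1):jmax
      r <- suppressWarnings(cor(H[, idx[i]], H[, idx[js], drop = FALSE]))
      dists <- c(dists, pos[js] - pos[i])
      r2s <- c(r2s, as.vector(r)^2)
    }
  }
  if (!length(dists)) abort("no SNP pairs within max_dist")
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dists, breaks, include.lowest = TRUE, labels = FALSE)
  tibble(bin = seq_len(n_bins),
         bin_mid = (breaks[-1] + breaks[-(n_bins + 1)]) / 2) |>
    left_join(tibble(bin = bin, r2 = r2s) |>
                group_by(.data$bin) |>
                summarise(mean_r2 = mean(.data$r2), n_pairs = n()),
              by = "bin") |>
    select(-"bin")
}

# column variances
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Plot an LD-decay curve
#'
#' @param decay Output of [ld_decay()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(x = .data$bin_mid / 1e3, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
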