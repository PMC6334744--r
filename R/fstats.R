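jackknife_blocks <- function(per_snp, block_snps) {
  g <- ceiling(length(per_snp) / block_snps)
  if (g < 2) abort("need at least 2 jackknife blocks of SNPs")
  block <- (seq_along(per_snp) - 1) %/% block_snps
  est <- mean(per_snp)
  loo <- vapply(0:(g - 1), function(b) mean(per_snp[block != b]), numeric(1))
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(value = est, se = se, n_blocks = g)
}

new_fstat <- function(kind, pops, jk) {
  structure(list(kind = kind, pops = pops, value = jk$value, se = jk$se,
                 z = if (jk$se > 0) jk$value / jk$se else NA_real_,
                 n_blocks = jk$n_blocks),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  (se %.3g, Z %.2f, %d blocks)\n",
              x$kind, paste(x$pops, collapse = ", "),
              x$value, x$se, x$z, x$n_blocks))
  invisible(x)
}

#' @export
tidy.fstat_result <- function(x, ...) {
  tibble(kind = x$kind, pops = paste(x$pops, collapse = ","),
         value = x$value, se = x$se, z = x$z, n_blocks = x$n_blocks)
}

#' @export
glance.fstat_result <- tidy.fstat_result

fstat_freqs <- function(f, pops) {
  idx <- match(pops, f$pops)
  if (anyNA(idx)) {
    abort(paste("population not in freq_table:",
                paste(pops[is.na(idx)], collapse = ", ")))
  }
  p <- f$freqs[idx, , drop = FALSE]
  cnt <- f$counts[idx, , drop = FALSE]
  ok <- colSums(is.na(p)) == 0 & colSums(cnt == 0) == 0
  list(p = p[, ok, drop = FALSE], cnt = cnt[, ok, drop = FALSE])
}

#' f3 admixture statistic with block-jackknife standard error
#'
#' `f3(A; B, C)` is the mean over SNPs of `(p_A - p_B)(p_A - p_C)`.  A
#' significantly negative value indicates that the target A derives from an
#' admixture of sources related to B and C.  With `bias_correction = TRUE`
#' (default) the within-target sampling bias `p_A(1-p_A)/(c_A - 1)` (`c_A`
#' = non-missing allele count in A) is subtracted per SNP, as required for
#' finite samples.  Standard errors come from a delete-one block jackknife
#' over consecutive blocks of `block_snps` SNPs in genome order.
#'
#' @param f A `freq_table`.
#' @param target Target population A.
#' @param sources Length-2 character vector (B, C).
#' @param block_snps SNPs per jackknife block.  Default 500.
#' @param bias_correction Subtract the finite-sample bias term.
#' @return An `fstat_result` (value, se, z, n_blocks).
#' @export
f3_stat <- function(f, target, sources, block_snps = 500,
                    bias_correction = TRUE) {
  if (length(sources) != 2) abort("f3 needs exactly 2 source populations")
  fr <- fstat_freqs(f, c(target, sources))
  pa <- fr$p[1, ]; pb <- fr$p[2, ]; pc <- fr$p[3, ]
  d <- (pa - pb) * (pa - pc)
  if (bias_correction) {
    ca <- fr$cnt[1, ]
    d <- d - ifelse(ca > 1, pa * (1 - pa) / (ca - 1), 0)
  }
  new_fstat("f3", c(target, sources), jackknife_blocks(d, block_snps))
}

#' f4 statistic with block-jackknife standard error
#'
#' `f4(A, B; C, D)` is the mean over SNPs of `(p_A - p_B)(p_C - p_D)`;
#' significant deviation from zero indicates gene flow violating the tree
#' `((A,B),(C,D))`.
#'
#' @param f A `freq_table`.
#' @param quartet Length-4 character vector (A, B, C, D).
#' @param block_snps SNPs per jackknife block.  Default 500.
#' @return An `fstat_result`.
#' @export
f4_stat <- function(f, quartet, block_snps = 500) {
  if (length(quartet) != 4) abort("f4 needs exactly 4 populations")
  fr <- fstat_freqs(f, quartet)
  d <- (fr$p[1, ] - fr$p[2, ]) * (fr$p[3, ] - fr$p[4, ])
  new_fstat("f4", quartet, jackknife_blocks(d, block_snps))
}
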