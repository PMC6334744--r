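#' Per-population (or per-group) allele-frequency table
#'
#' Alt-allele frequencies and non-missing allele totals, one row per
#' population (or pooled group), aligned to the dataset's variant table.
#'
#' @param d A `geno_dataset` with labels in the chosen column.
#' @param by Sample column to group by: `"population"` (default) or
#'   `"group"`.
#' @return A `freq_table`: list with `pops`, `freqs` (pops x variants),
#'   `counts` (non-missing allele totals) and `variants`.
#' @export
allele_freqs <- function(d, by = "population") {
  labels <- d$samples[[by]]
  if (anyNA(labels)) abort(paste("every sample needs a non-missing", by, "label"))
  pops <- unique(labels)
  m <- nrow(d$variants)
  freqs <- matrix(NA_real_, length(pops), m, dimnames = list(pops, NULL))
  counts <- matrix(0, length(pops), m, dimnames = list(pops, NULL))
  for (i in seq_along(pops)) {
    calls <- d$calls[labels == pops[i], , drop = FALSE]
    nm <- colSums(!is.na(calls))
    counts[i, ] <- 2 * nm
    freqs[i, ] <- ifelse(nm > 0, colMeans(calls, na.rm = TRUE) / 2, NA_real_)
  }
  freq_table(pops, freqs, counts, d$variants)
}

#' Construct a frequency table directly
#'
#' @param pops Character vector of population labels.
#' @param freqs Numeric matrix (pops x variants) of alt-allele frequencies.
#' @param counts Numeric matrix of non-missing allele totals (same shape);
#'   may be a single value recycled.
#' @param variants Variant table (`chrom`, `pos`, at least).
#' @return A `freq_table`.
#' @export
freq_table <- function(pops, freqs, counts, variants) {
  freqs <- as.matrix(freqs)
  if (length(counts) == 1) {
    counts <- matrix(counts, nrow(freqs), ncol(freqs))
  }
  counts <- as.matrix(counts)
  if (!identical(dim(freqs), dim(counts))) abort("freqs/counts shape mismatch")
  if (nrow(freqs) != length(pops)) abort("one frequency row per population required")
  ok <- freqs[!is.na(freqs)]
  if (length(ok) && (any(ok < 0) || any(ok > 1))) abort("frequencies must lie in [0, 1]")
  variants <- as_tibble(variants)
  if (ncol(freqs) != nrow(variants)) abort("variant table length mismatch")
  rownames(freqs) <- pops
  rownames(counts) <- pops
  structure(list(pops = as.character(pops), freqs = freqs, counts = counts,
                 variants = variants),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d populations x %d variants\n",
              length(x$pops), ncol(x$freqs)))
  invisible(x)
}

#' Pool populations of a frequency table into groups
#'
#' Pooled frequencies are allele-count weighted means of the member
#' populations' frequencies (equivalent to pooling the samples).
#'
#' @param f A `freq_table`.
#' @param groups Named list mapping group label to member populations.
#' @return A `freq_table` with one row per group.
#' @export
pool_freqs <- function(f, groups) {
  freqs <- matrix(NA_real_, length(groups), ncol(f$freqs))
  counts <- matrix(0, length(groups), ncol(f$freqs))
  for (i in seq_along(groups)) {
    idx <- match(groups[[i]], f$pops)
    if (anyNA(idx)) abort(paste("unknown population in group", names(groups)[i]))
    cnt <- f$counts[idx, , drop = FALSE]
    alt <- f$freqs[idx, , drop = FALSE] * cnt
    counts[i, ] <- colSums(cnt)
    freqs[i, ] <- ifelse(counts[i, ] > 0,
                         colSums(alt, na.rm = TRUE) / counts[i, ], NA_real_)
  }
  freq_table(names(groups), freqs, counts, f$variants)
}

#' Binomial-sample estimated frequencies from true frequencies
#'
#' Draws `n_alleles` alleles per population per SNP from the table's
#' frequencies, returning the estimated-frequency table; used to emulate
#' finite-sample estimation from a simulated truth.  Uses the current RNG
#' state.
#'
#' @param f A `freq_table` of true frequencies.
#' @param n_alleles Alleles sampled per population per SNP (2 x diploids).
#' @return A `freq_table` of sample frequencies with `counts = n_alleles`.
#' @export
sample_freq_table <- function(f, n_alleles) {
  k <- length(f$freqs)
  draws <- rbinom(k, size = n_alleles, prob = as.vector(f$freqs))
  freqs <- matrix(draws / n_alleles, nrow(f$freqs), ncol(f$freqs),
                  dimnames = dimnames(f$freqs))
  freq_table(f$pops, freqs, n_alleles, f$variants)
}
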