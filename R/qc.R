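#' Quality-control filter chain
#'
#' Applies, in a fixed order, the standard SNP-array filters: (1) drop
#' non-autosomal variants, (2) drop samples with a missing-call rate at or
#' above `sample_miss`, (3) drop variants with a missing rate at or above
#' `variant_miss`, (4) drop variants with minor allele frequency at or below
#' `maf_max_excl` (MAF computed on the retained samples).  The MAF boundary
#' is inclusive-remove: a SNP is kept only if `MAF > maf_max_excl`.
#'
#' @param d A `geno_dataset`.
#' @param maf_max_excl MAF threshold; variants with MAF `<=` this are
#'   removed.  Default 0.01.
#' @param sample_miss Sample missing-rate threshold (remove if `>=`).
#'   Default 0.10.
#' @param variant_miss Variant missing-rate threshold (remove if `>=`).
#'   Default 0.05.
#' @return A list with `data` (the filtered `geno_dataset`) and `report`
#'   (a `qc_report` recording per-stage removals).
#' @export
apply_qc <- function(d, maf_max_excl = 0.01, sample_miss = 0.10,
                     variant_miss = 0.05) {
  if (nrow(d$samples) == 0 || nrow(d$variants) == 0) abort("empty dataset")
  n_var_in <- nrow(d$variants)
  n_samp_in <- nrow(d$samples)

  # stage 1: autosomes only
  keep_v <- d$variants$autosomal
  n_nonauto <- sum(!keep_v)
  calls <- d$calls[, keep_v, drop = FALSE]
  variants <- d$variants[keep_v, , drop = FALSE]
  if (ncol(calls) == 0) abort("no autosomal variants left")

  # stage 2: sample missingness
  miss_s <- rowMeans(is.na(calls))
  keep_s <- miss_s < sample_miss
  n_samp_rm <- sum(!keep_s)
  if (!any(keep_s)) abort("all samples removed by the missingness filter")
  calls <- calls[keep_s, , drop = FALSE]
  samples <- d$samples[keep_s, , drop = FALSE]

  # stage 3: variant missingness
  miss_v <- colMeans(is.na(calls))
  keep_v <- miss_v < variant_miss
  n_miss_rm <- sum(!keep_v)
  calls <- calls[, keep_v, drop = FALSE]
  variants <- variants[keep_v, , drop = FALSE]

  # stage 4: MAF (on retained samples)
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_v <- !is.na(maf) & maf > maf_max_excl
  n_maf_rm <- sum(!keep_v)
  calls <- calls[, keep_v, drop = FALSE]
  variants <- variants[keep_v, , drop = FALSE]
  if (ncol(calls) == 0) abort("no variants left after QC")

  out <- genotype_dataset(samples,
                          variants[, c("chrom", "pos", "variant_id", "ref", "alt")],
                          calls)
  report <- structure(list(
    n_variants_in = n_var_in, n_variants_out = nrow(out$variants),
    n_samples_in = n_samp_in, n_samples_out = nrow(out$samples),
    removed = tibble(stage = c("non_autosomal", "sample_missingness",
                               "variant_missingness", "maf"),
                     unit = c("variant", "sample", "variant", "variant"),
                     n_removed = c(n_nonauto, n_samp_rm, n_miss_rm, n_maf_rm)),
    params = list(maf_max_excl = maf_max_excl, sample_miss = sample_miss,
                  variant_miss = variant_miss)),
    class = "qc_report")
  list(data = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> variants %d -> %d, samples %d -> %d\n",
              x$n_variants_in, x$n_variants_out,
              x$n_samples_in, x$n_samples_out))
  print(as.data.frame(x$removed), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$removed

#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_variants_in = x$n_variants_in, n_variants_out = x$n_variants_out,
         n_samples_in = x$n_samples_in, n_samples_out = x$n_samples_out)
}
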