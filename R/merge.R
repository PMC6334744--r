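#' Merge two genotype datasets on shared variants
#'
#' Standard array-merge hygiene: variants are matched by (chromosome,
#' position); when the second dataset's ref/alt labels are swapped relative
#' to the first, its calls are recoded `2 - x`; strand-ambiguous A/T and C/G
#' sites and sites with irreconcilable allele pairs are dropped (counts
#' reported via a message).  Samples are concatenated.
#'
#' @param a,b `geno_dataset` objects sharing a coordinate system.
#' @return A merged `geno_dataset` restricted to the reconcilable shared
#'   variants.
#' @export
merge_datasets <- function(a, b) {
  dup <- intersect(a$samples$sample_id, b$samples$sample_id)
  if (length(dup)) {
    abort(paste("duplicate sample_id across datasets:",
                paste(head(dup, 5), collapse = ", ")))
  }
  key_a <- paste(a$variants$chrom, a$variants$pos)
  key_b <- paste(b$variants$chrom, b$variants$pos)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  ra <- toupper(a$variants$ref[ia]); aa <- toupper(a$variants$alt[ia])
  rb <- toupper(b$variants$ref[ib]); ab <- toupper(b$variants$alt[ib])
  ambiguous <- (pmin(aa, ra) == "A" & pmax(aa, ra) == "T") |
    (pmin(aa, ra) == "C" & pmax(aa, ra) == "G")
  same <- ra == rb & aa == ab
  swapped <- ra == ab & aa == rb
  irrec <- !same & !swapped
  keep <- !ambiguous & !irrec
  if (any(ambiguous)) {
    inform(sprintf("dropped %d strand-ambiguous (A/T, C/G) site(s) at merge",
                   sum(ambiguous)))
  }
  if (any(irrec & !ambiguous)) {
    inform(sprintf("dropped %d site(s) with irreconcilable alleles",
                   sum(irrec & !ambiguous)))
  }
  if (!any(keep)) abort("no reconcilable shared variants between datasets")
  ia <- ia[keep]; ib <- ib[keep]; swapped <- swapped[keep]
  calls_b <- b$calls[, ib, drop = FALSE]
  if (any(swapped)) {
    calls_b[, swapped] <- 2L - calls_b[, swapped]
  }
  variants <- a$variants[ia, c("chrom", "pos", "variant_id", "ref", "alt")]
  samples <- bind_rows(a$samples, b$samples)
  calls <- rbind(a$calls[, ia, drop = FALSE], calls_b)
  genotype_dataset(samples, variants, calls)
}
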