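#' Construct a genotype dataset
#'
#' The central container of the package: a sample table, a variant table and
#' an allele-count matrix.  Calls count copies of the variant's `alt` allele
#' (0, 1, 2) with `NA` for missing; variants are kept sorted by
#' (chromosome, position) and the call matrix is reordered to match.
#'
#' @param samples Tibble/data frame with at least `sample_id`; optional
#'   `population`, `group`, `tail_type` columns.  `sample_id` must be unique.
#' @param variants Tibble/data frame with `chrom`, `pos` (1-based bp),
#'   `variant_id`, `ref`, `alt`.
#' @param calls Integer matrix, samples in rows, variants in columns, values
#'   in 0/1/2/`NA`.
#' @return An object of class `geno_dataset`.
#' @export
genotype_dataset <- function(samples, variants, calls) {
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  if (!"sample_id" %in% names(samples)) abort("samples needs a sample_id column")
  if (anyDuplicated(samples$sample_id)) abort("sample_id values must be unique")
  for (col in c("population", "group", "tail_type")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  }
  need <- c("chrom", "pos", "variant_id", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) abort(paste("variants missing columns:", paste(miss, collapse = ", ")))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.numeric(variants$pos)
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  if (any(!is.na(variants$ref) & !is.na(variants$alt) &
          variants$ref == variants$alt)) {
    abort("ref and alt alleles must be distinct")
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(variants)) {
    abort(sprintf("call matrix is %d x %d but there are %d samples and %d variants",
                  nrow(calls), ncol(calls), nrow(samples), nrow(variants)))
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("calls must be 0, 1, 2 or NA")
  }
  ord <- order(chrom_key(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  variants$autosomal <- is_autosome(variants$chrom)
  rownames(calls) <- samples$sample_id
  colnames(calls) <- variants$variant_id
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  npop <- length(unique(x$samples$population[!is.na(x$samples$population)]))
  cat(sprintf("<geno_dataset> %d samples x %d variants (%d populations, %d chromosomes)\n",
              nrow(x$samples), nrow(x$variants), npop,
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.geno_dataset <- function(x) c(nrow(x$samples), nrow(x$variants))

#' Construct a phased haplotype set
#'
#' Two binary haplotypes per diploid sample, aligned to a variant table.
#' Phased statistics (EHH, iES, Rsb, LD decay) refuse missing values, so the
#' matrix must be complete.
#'
#' @param haplotypes Integer 0/1 matrix with `2 * n_samples` rows.
#' @param sample_id Character vector mapping each haplotype row to its sample
#'   (each sample appears exactly twice).
#' @param variants Variant table as for [genotype_dataset()].
#' @return An object of class `hap_set`.
#' @export
haplotype_set <- function(haplotypes, sample_id, variants) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (anyNA(haplotypes)) abort("haplotypes must be complete (no missing values)")
  if (!all(haplotypes %in% c(0L, 1L))) abort("haplotypes must be 0/1")
  if (nrow(haplotypes) != length(sample_id)) {
    abort("sample_id must have one entry per haplotype row")
  }
  tab <- table(sample_id)
  if (any(tab != 2L)) abort("each sample must contribute exactly 2 haplotypes")
  variants <- as_tibble(variants)
  if (nrow(variants) != ncol(haplotypes)) {
    abort("variant table and haplotype matrix disagree on variant count")
  }
  ord <- order(chrom_key(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  haplotypes <- haplotypes[, ord, drop = FALSE]
  structure(list(haplotypes = haplotypes, sample_id = as.character(sample_id),
                 variants = variants),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> %d haplotypes (%d samples) x %d variants\n",
              nrow(x$haplotypes), length(unique(x$sample_id)),
              ncol(x$haplotypes)))
  invisible(x)
}

#' Collapse phased haplotypes to diploid genotype calls
#'
#' Sums each sample's haplotype pair; the left inverse of reading a phased
#' VCF.
#'
#' @param h A [haplotype_set()].
#' @param samples Optional sample table to carry over (populations etc.).
#' @return A `geno_dataset`.
#' @export
collapse_haplotypes <- function(h, samples = NULL) {
  ids <- unique(h$sample_id)
  calls <- t(vapply(ids, function(s) {
    colSums(h$haplotypes[h$sample_id == s, , drop = FALSE])
  }, numeric(ncol(h$haplotypes))))
  if (is.null(samples)) samples <- tibble(sample_id = ids)
  genotype_dataset(samples, h$variants[, c("chrom", "pos", "variant_id", "ref", "alt")], calls)
}

#' Subset samples of a dataset or haplotype set
#'
#' @param x A `geno_dataset` or `hap_set`.
#' @param sample_ids Character vector of samples to keep.
#' @return Object of the same class.
#' @export
subset_samples <- function(x, sample_ids) UseMethod("subset_samples")

#' @export
subset_samples.geno_dataset <- function(x, sample_ids) {
  keep <- x$samples$sample_id %in% sample_ids
  if (!any(keep)) abort("no samples left after subsetting")
  genotype_dataset(x$samples[keep, , drop = FALSE],
                   x$variants[, c("chrom", "pos", "variant_id", "ref", "alt")],
                   x$calls[keep, , drop = FALSE])
}

#' @export
subset_samples.hap_set <- function(x, sample_ids) {
  keep <- x$sample_id %in% sample_ids
  if (!any(keep)) abort("no samples left after subsetting")
  haplotype_set(x$haplotypes[keep, , drop = FALSE], x$sample_id[keep], x$variants)
}

#' Subset variants of a dataset or haplotype set
#'
#' @param x A `geno_dataset` or `hap_set`.
#' @param keep Logical or integer index over variants, or character
#'   `variant_id`s.
#' @return Object of the same class.
#' @export
subset_variants <- function(x, keep) UseMethod("subset_variants")

variant_index <- function(variants, keep) {
  if (is.character(keep)) keep <- match(keep, variants$variant_id)
  if (is.logical(keep)) keep <- which(keep)
  if (anyNA(keep)) abort("unknown variant in subset")
  keep
}

#' @export
subset_variants.geno_dataset <- function(x, keep) {
  idx <- variant_index(x$variants, keep)
  genotype_dataset(x$samples,
                   x$variants[idx, c("chrom", "pos", "variant_id", "ref", "alt")],
                   x$calls[, idx, drop = FALSE])
}

#' @export
subset_variants.hap_set <- function(x, keep) {
  idx <- variant_index(x$variants, keep)
  haplotype_set(x$haplotypes[, idx, drop = FALSE], x$sample_id,
                x$variants[idx, , drop = FALSE])
}

#' Align a haplotype set to a genotype dataset's variants
#'
#' Keeps, in order, the variants of `d` that are present in `h` (matched by
#' chromosome and position); used after QC to carry filtering over to the
#' phased data.
#'
#' @param h A `hap_set`.
#' @param d A `geno_dataset`.
#' @return A `hap_set` with `d`'s variants.
#' @export
align_haplotypes <- function(h, d) {
  key_h <- paste(h$variants$chrom, h$variants$pos)
  key_d <- paste(d$variants$chrom, d$variants$pos)
  idx <- match(key_d, key_h)
  if (anyNA(idx)) abort("dataset contains variants absent from the haplotype set")
  subset_variants(h, idx)
}

# population labels for a set of samples, erroring if absent
pop_labels <- function(d, required = TRUE) {
  p <- d$samples$population
  if (required && anyNA(p)) {
    abort("every sample needs a population label for per-population statistics")
  }
  p
}
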