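#' Read genotypes (and optionally phased haplotypes) from a VCF
#'
#' Keeps biallelic SNP records only (multiallelic or indel records are
#' skipped with a message).  Calls count the ALT allele.  With
#' `require_phased = TRUE` every GT must use the phased `|` separator and be
#' complete, and a haplotype set is returned alongside the genotypes.
#'
#' @param path VCF path (plain or bgzipped).
#' @param require_phased Return phased haplotypes and insist on `|` GTs.
#' @param pop_file Optional sample-to-population TSV (see
#'   [read_populations()]).
#' @return With `require_phased = FALSE`, a `geno_dataset`; otherwise a list
#'   with elements `genotypes` and `haplotypes`.
#' @export
read_vcf <- function(path, require_phased = FALSE, pop_file = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    inform(sprintf("skipped %d non-biallelic-SNP record(s)", n_skip))
    vcf <- vcf[is_snp, ]
    fix <- fix[is_snp, , drop = FALSE]
  }
  if (nrow(fix) == 0) abort("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  gt_chr <- as.vector(gt)  # variants x samples, column-major
  gt_chr[is.na(gt_chr) | gt_chr == "."] <- NA
  phased <- grepl("|", gt_chr, fixed = TRUE)
  if (require_phased && any(!phased & !is.na(gt_chr))) {
    abort("require_phased: VCF contains unphased (\"/\") genotypes")
  }
  if (require_phased && anyNA(gt_chr)) {
    abort("require_phased: VCF contains missing genotypes")
  }
  a1 <- suppressWarnings(as.integer(substr(gt_chr, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt_chr, 3, 3)))
  calls_vm <- matrix(a1 + a2, nrow = nrow(fix))  # variants x samples
  variants <- tibble(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                     variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                         paste0(fix$CHROM, ":", fix$POS), fix$ID),
                     ref = fix$REF, alt = fix$ALT)
  samples <- tibble(sample_id = sample_ids, population = NA_character_)
  if (!is.null(pop_file)) samples <- apply_pop_file(samples, pop_file)
  d <- genotype_dataset(samples, variants, t(calls_vm))
  if (!require_phased) return(d)
  hap <- matrix(0L, nrow = 2 * length(sample_ids), ncol = nrow(fix))
  hap[seq(1, by = 2, length.out = length(sample_ids)), ] <- t(matrix(a1, nrow = nrow(fix)))
  hap[seq(2, by = 2, length.out = length(sample_ids)), ] <- t(matrix(a2, nrow = nrow(fix)))
  h <- haplotype_set(hap, rep(sample_ids, each = 2), variants)
  list(genotypes = d, haplotypes = h)
}

#' Write a dataset as a plain-text VCF
#'
#' Emits VCF v4.2.  When `haplotypes` is supplied, GT fields are phased
#' (`a|b`) from the haplotype pairs; otherwise unphased genotypes are
#' written from the diploid calls (`./.` for missing).
#'
#' @param d A `geno_dataset`.
#' @param path Output path (plain text).
#' @param haplotypes Optional `hap_set` aligned to `d`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(d, path, haplotypes = NULL) {
  n <- nrow(d$samples)
  m <- nrow(d$variants)
  header <- c("##fileformat=VCFv4.2",
              "##source=sweepscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", d$samples$sample_id), collapse = "\t"))
  if (is.null(haplotypes)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[d$calls + 1L], nrow = n)
    gt[is.na(d$calls)] <- "./."
  } else {
    if (!identical(paste(haplotypes$variants$chrom, haplotypes$variants$pos),
                   paste(d$variants$chrom, d$variants$pos))) {
      abort("haplotype set is not aligned to the dataset variants")
    }
    # rows come in pairs per sample; find both rows for each sample
    gt <- matrix("", nrow = n, ncol = m)
    for (i in seq_len(n)) {
      rows <- which(haplotypes$sample_id == d$samples$sample_id[i])
      gt[i, ] <- paste0(haplotypes$haplotypes[rows[1], ], "|",
                        haplotypes$haplotypes[rows[2], ])
    }
  }
  body <- vapply(seq_len(m), function(j) {
    paste(c(d$variants$chrom[j],
            format(d$variants$pos[j], scientific = FALSE, trim = TRUE),
            d$variants$variant_id[j], d$variants$ref[j], d$variants$alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
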