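#' Read a PLINK 1 binary fileset
#'
#' Decodes the `.bed`/`.bim`/`.fam` triplet (SNP-major `.bed`).  By default
#' calls count copies of the bim allele-1 column (PLINK's usual
#' minor-allele-first convention), which becomes the dataset's `alt` allele;
#' `count_allele = "A2"` flips the convention.
#'
#' @param prefix Path prefix (without extension).
#' @param pop_file Optional two-column TSV (`sample_id`, `population`);
#'   overrides the fam family-ID column, which is otherwise used as the
#'   population label.
#' @param count_allele `"A1"` (default) or `"A2"`: which bim allele the
#'   0/1/2 calls count.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(prefix, pop_file = NULL, count_allele = c("A1", "A2")) {
  count_allele <- match.arg(count_allele)
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(paste("missing PLINK file:", p))
  }
  bim <- read.table(bim_path, header = FALSE, colClasses = "character")
  names(bim) <- c("chrom", "variant_id", "cm", "pos", "a1", "a2")
  fam <- read.table(fam_path, header = FALSE, colClasses = "character")
  names(fam)[1:2] <- c("fid", "sample_id")
  n <- nrow(fam)
  m <- nrow(bim)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK bed file (magic bytes missing)")
  }
  if (raw[3] != as.raw(0x01)) abort("only SNP-major bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * m) {
    abort(sprintf("bed payload has %d bytes, expected %d for %d samples x %d variants",
                  length(payload), bytes_per_snp * m, n, m))
  }
  # 2-bit codes, sample-major within each byte, LSB first:
  # 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2
  ints <- as.integer(payload)
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = m)
  shifted <- ints
  for (k in 1:4) {
    codes[seq(k, by = 4, length.out = bytes_per_snp), ] <- shifted %% 4L
    shifted <- shifted %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)  # A1 dosage
  calls <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  if (count_allele == "A1") {
    alt <- bim$a1; ref <- bim$a2
  } else {
    alt <- bim$a2; ref <- bim$a1
    calls <- 2L - calls
  }
  samples <- tibble(sample_id = fam$sample_id, population = fam$fid)
  if (!is.null(pop_file)) {
    samples <- apply_pop_file(samples, pop_file)
  }
  variants <- tibble(chrom = bim$chrom, pos = as.numeric(bim$pos),
                     variant_id = bim$variant_id, ref = ref, alt = alt)
  genotype_dataset(samples, variants, calls)
}

#' Write a PLINK 1 binary fileset
#'
#' Writes SNP-major `.bed` plus `.bim`/`.fam`; the dataset's `alt` allele is
#' written as bim allele-1 so a default [read_plink()] round-trips exactly.
#'
#' @param d A `geno_dataset`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(d, prefix) {
  n <- nrow(d$samples)
  m <- nrow(d$variants)
  fam <- data.frame(fid = ifelse(is.na(d$samples$population), "0", d$samples$population),
                    iid = d$samples$sample_id, pat = "0", mat = "0",
                    sex = "0", phe = "-9")
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = d$variants$chrom, id = d$variants$variant_id,
                    cm = "0", pos = format(d$variants$pos, scientific = FALSE, trim = TRUE),
                    a1 = d$variants$alt, a2 = d$variants$ref)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  # alt dosage -> 2-bit code
  code_of <- function(x) ifelse(is.na(x), 1L, c(3L, 2L, 0L)[x + 1L])
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  codes <- apply(d$calls, 2, code_of)
  codes <- rbind(matrix(codes, nrow = n), matrix(0L, nrow = pad, ncol = m))
  w <- codes[seq(1, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    4L * codes[seq(2, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    16L * codes[seq(3, 4 * bytes_per_snp, by = 4), , drop = FALSE] +
    64L * codes[seq(4, 4 * bytes_per_snp, by = 4), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(w)), con)
  invisible(prefix)
}

#' Read a sample-to-population TSV
#'
#' Two columns (`sample_id`, `population`), with or without a header line.
#'
#' @param path File path.
#' @return Tibble with `sample_id` and `population`.
#' @export
read_populations <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  tab <- read.table(path, header = has_header, sep = "\t",
                    colClasses = "character")
  names(tab)[1:2] <- c("sample_id", "population")
  as_tibble(tab[, 1:2])
}

apply_pop_file <- function(samples, pop_file) {
  pops <- read_populations(pop_file)
  idx <- match(samples$sample_id, pops$sample_id)
  samples$population <- ifelse(is.na(idx), samples$population,
                               pops$population[idx])
  samples
}
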