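test_that("PLINK round-trip preserves calls, sample order and coordinates", {
  calls <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 2)
  d <- toy_dataset(calls, pops = c("A", "B"))
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_plink(d, prefix)
  d2 <- read_plink(prefix)
  expect_identical(d2$calls, d$calls)
  expect_identical(d2$samples$sample_id, d$samples$sample_id)
  expect_identical(d2$samples$population, c("A", "B"))
  expect_equal(d2$variants$pos, d$variants$pos)
  expect_identical(d2$variants$ref, d$variants$ref)
})

test_that("bed decoding matches a hand-encoded byte-level fixture", {
  # 2 samples, 3 SNPs; codes (LSB-first pairs): 00=homA1(2), 01=missing,
  # 10=het(1), 11=homA2(0)
  dir <- withr::local_tempdir()
  writeLines(c("F1\ts1\t0\t0\t0\t-9", "F1\ts2\t0\t0\t0\t-9"),
             file.path(dir, "hand.fam"))
  writeLines(c("1\tv1\t0\t100\tG\tA", "1\tv2\t0\t200\tG\tA",
               "1\tv3\t0\t300\tG\tA"), file.path(dir, "hand.bim"))
  # SNP1: s1=homA1 (00), s2=het (10)   -> byte 0b00001000 = 0x08
  # SNP2: s1=missing (01), s2=homA2(11)-> byte 0b00001101 = 0x0d
  # SNP3: s1=het (10), s2=homA1 (00)   -> byte 0b00000010 = 0x02
  con <- file(file.path(dir, "hand.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x08, 0x0d, 0x02)), con)
  close(con)
  d <- read_plink(file.path(dir, "hand"))
  expect_identical(d$calls[1, ], c(v1 = 2L, v2 = NA_integer_, v3 = 1L))
  expect_identical(d$calls[2, ], c(v1 = 1L, v2 = 0L, v3 = 2L))
  expect_identical(sum(is.na(d$calls)), 1L)
})

test_that("malformed bed magic bytes raise a format error", {
  dir <- withr::local_tempdir()
  writeLines("F1\ts1\t0\t0\t0\t-9", file.path(dir, "bad.fam"))
  writeLines("1\tv1\t0\t100\tG\tA", file.path(dir, "bad.bim"))
  writeBin(as.raw(c(0x00, 0x00, 0x01, 0x00)), file.path(dir, "bad.bed"))
  expect_error(read_plink(file.path(dir, "bad")), "magic")
})

test_that("phased VCF round-trips and collapses back to the genotypes", {
  set.seed(7)
  hap <- matrix(rbinom(6 * 8, 1, 0.5), nrow = 6)
  h <- toy_hapset(hap)
  d <- collapse_haplotypes(h)
  path <- file.path(withr::local_tempdir(), "toy.vcf")
  write_vcf(d, path, haplotypes = h)
  rv <- read_vcf(path, require_phased = TRUE)
  expect_identical(unname(rv$genotypes$calls), unname(d$calls))
  expect_identical(unname(rv$haplotypes$haplotypes), unname(h$haplotypes))
  # pair-sum collapse is a left inverse of phased reading
  expect_identical(unname(collapse_haplotypes(rv$haplotypes)$calls),
                   unname(d$calls))
})

test_that("GT parsing follows the VCF spec and unphased input is rejected when phased is required", {
  dir <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
           "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1")
  writeLines(vcf, file.path(dir, "p.vcf"))
  rv <- read_vcf(file.path(dir, "p.vcf"), require_phased = TRUE)
  expect_identical(unname(rv$genotypes$calls[1, 1]), 1L)
  expect_identical(unname(rv$haplotypes$haplotypes[, 1]), c(0L, 1L))
  vcf[4] <- "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1"
  writeLines(vcf, file.path(dir, "u.vcf"))
  expect_error(read_vcf(file.path(dir, "u.vcf"), require_phased = TRUE),
               "unphased")
  expect_identical(unname(read_vcf(file.path(dir, "u.vcf"))$calls[1, 1]), 1L)
})

test_that("multiallelic VCF records are skipped with a count", {
  dir <- withr::local_tempdir()
  rows <- sprintf("1\t%d\tv%d\tA\tG\t.\tPASS\t.\tGT\t0/1", 1:5 * 100, 1:5)
  rows[3] <- "1\t300\tv3\tA\tG,T\t.\tPASS\t.\tGT\t1/2"
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
           rows)
  writeLines(vcf, file.path(dir, "m.vcf"))
  expect_message(d <- read_vcf(file.path(dir, "m.vcf")), "skipped 1")
  expect_identical(nrow(d$variants), 4L)
})

test_that("merge intersects variants, reconciles swapped alleles and drops ambiguous sites", {
  # a: 5 SNPs; b: 4 SNPs; shared: pos 1000 (same), 2000 (swapped),
  # 3000 (A/T ambiguous), 4000 (irreconcilable) -> 2 merged variants
  a <- toy_dataset(matrix(c(0L, 1L, 2L, 1L, 0L), nrow = 1), pos = 1:5 * 1000,
                   ref = c("A", "C", "A", "A", "A"),
                   alt = c("G", "T", "T", "G", "G"))
  b <- genotype_dataset(
    tibble::tibble(sample_id = "t1", population = "B"),
    tibble::tibble(chrom = "1", pos = 1:4 * 1000,
                   variant_id = paste0("w", 1:4),
                   ref = c("A", "T", "A", "C"), alt = c("G", "C", "T", "G")),
    matrix(c(2L, 2L, 1L, 1L), nrow = 1))
  expect_message(m <- merge_datasets(a, b), "ambiguous")
  expect_identical(nrow(m$variants), 2L)
  expect_identical(nrow(m$samples), 2L)
  # swapped site pos 2000: b call 2 recoded to 0
  expect_identical(unname(m$calls[2, m$variants$pos == 2000]), 0L)
  # symmetric in variant content
  mm <- suppressMessages(merge_datasets(b, a))
  expect_setequal(paste(m$variants$chrom, m$variants$pos),
                  paste(mm$variants$chrom, mm$variants$pos))
  # duplicate sample ids refused
  expect_error(suppressMessages(merge_datasets(a, a)), "duplicate")
})

test_that("gene features read from BED and GFF3 with coordinate conversion", {
  dir <- withr::local_tempdir()
  writeLines("1\t100\t200\tG1", file.path(dir, "g.bed"))
  g <- read_gene_features(file.path(dir, "g.bed"))
  expect_identical(g$start, 101L)
  expect_identical(g$end, 200L)
  expect_identical(g$name, "G1")
  gff <- c("##gff-version 3",
           "7\t.\tgene\t63450344\t63456226\t.\t+\t.\tID=gene1;Name=BMP4",
           "7\t.\tmRNA\t63450344\t63456226\t.\t+\t.\tID=m1;Parent=gene1",
           "7\t.\tmRNA\t63450400\t63456000\t.\t+\t.\tID=m2;Parent=gene1")
  writeLines(gff, file.path(dir, "g.gff3"))
  g2 <- read_gene_features(file.path(dir, "g.gff3"))
  expect_identical(nrow(g2), 1L)
  expect_identical(g2$name, "BMP4")
  expect_identical(c(g2$start, g2$end), c(63450344L, 63456226L))
})

test_that("dataset invariants are enforced", {
  expect_error(toy_dataset(matrix(3L, 1, 1)), "calls")
  expect_error(toy_dataset(matrix(0L, 1, 1), ref = "A", alt = "A"), "distinct")
  d <- toy_dataset(matrix(0L, 1, 2), pos = c(5000, 1000))
  expect_equal(d$variants$pos, c(1000, 5000))  # sorted on construction
  # haplotype pair sums must be complete and binary
  expect_error(toy_hapset(matrix(c(0L, NA), 2, 1)), "complete")
})
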