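#' Read gene features from BED or GFF3
#'
#' Parsed with `rtracklayer`, so BED's half-open 0-based intervals arrive as
#' 1-based inclusive coordinates.  For GFF3 only `gene`-type records are
#' kept.  Output is sorted by (chromosome, start).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
read_gene_features <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(md)) gr <- gr[as.character(md$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(md) && !all(is.na(md$Name))) {
      as.character(md$Name)
    } else if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  } else {
    nm <- if ("name" %in% names(md)) as.character(md$name) else NA_character_
  }
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr),
                name = nm)
  if (any(out$start > out$end)) abort("gene feature with start > end")
  arrange(out, chrom_key(.data$chrom), .data$start)
}
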