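method_logp_threshold <- function(cfg, method) {
  switch(method, flk = cfg$flk_logp_min, rsb = cfg$prsb_min,
         abort(paste("unknown method:", method)))
}

#' Significant windows merged into per-method intervals
#'
#' Applies each method's threshold (FST: `standardized >= zfst_min`; FLK
#' and Rsb: `-log10(p) >=` the method's cutoff) and the window SNP minimum,
#' then merges overlapping or adjacent (gap of at most 1 bp) significant
#' windows into maximal intervals.
#'
#' @param windows Window tibble as produced by the scan (possibly several
#'   methods bound together).
#' @param config A [scan_config()].
#' @return Tibble with `method`, `chrom`, `start`, `end`,
#'   `peak_standardized`.
#' @export
significant_windows <- function(windows, config = scan_config()) {
  purrr::map_dfr(unique(windows$method), function(mth) {
    w <- windows[windows$method == mth & windows$n_snps >= config$min_snps, ,
                 drop = FALSE]
    sig <- if (mth == "fst") {
      w$standardized >= config$zfst_min
    } else {
      -log10(w$p) >= method_logp_threshold(config, mth)
    }
    w <- w[sig, , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    purrr::map_dfr(unique(w$chrom), function(chr) {
      wc <- w[w$chrom == chr, , drop = FALSE]
      ir <- IRanges::IRanges(start = wc$start, end = wc$end)
      merged <- IRanges::reduce(ir, min.gapwidth = 2)
      hits <- IRanges::findOverlaps(ir, merged)
      peak <- tapply(wc$standardized[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits), max)
      tibble(method = mth, chrom = chr,
             start = IRanges::start(merged), end = IRanges::end(merged),
             peak_standardized = as.numeric(peak))
    })
  })
}

#' Consensus candidate regions across methods
#'
#' Positions covered by at least `min_methods` methods' significant
#' intervals define consensus cores; each reported region is the union
#' (range) of all member intervals intersecting a core, so printed bounds
#' span every contributing method's evidence.  Overlapping reported regions
#' are merged and their method sets united.
#'
#' @param intervals Per-method intervals from [significant_windows()].
#' @param min_methods Methods required.  Default 2 (1 reproduces
#'   single-method regions).
#' @return Tibble with `chrom`, `start`, `end`, `methods`
#'   (comma-separated), `n_methods`, `peak_standardized`.
#' @export
consensus_regions <- function(intervals, min_methods = 2) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  methods = character(), n_methods = integer(),
                  peak_standardized = numeric()))
  }
  purrr::map_dfr(unique(intervals$chrom), function(chr) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = iv$start, end = iv$end)
    cov <- IRanges::coverage(ir)
    cores <- IRanges::slice(cov, lower = min_methods, rangesOnly = TRUE)
    if (length(cores) == 0) return(NULL)
    out <- purrr::map_dfr(seq_along(cores), function(k) {
      core <- cores[k]
      member <- S4Vectors::queryHits(IRanges::findOverlaps(ir, core))
      tibble(chrom = chr,
             start = min(iv$start[member]), end = max(iv$end[member]),
             methods = paste(sort(unique(iv$method[member])), collapse = ","),
             n_methods = length(unique(iv$method[member])),
             peak_standardized = max(iv$peak_standardized[member]))
    })
    # merge overlapping reported regions, uniting method sets
    rr <- IRanges::reduce(IRanges::IRanges(out$start, out$end))
    hits <- IRanges::findOverlaps(IRanges::IRanges(out$start, out$end), rr)
    out$grp <- S4Vectors::subjectHits(hits)
    out |>
      group_by(.data$grp) |>
      summarise(chrom = chr, start = min(.data$start), end = max(.data$end),
                methods = paste(sort(unique(unlist(
                  strsplit(.data$methods, ",", fixed = TRUE)))), collapse = ","),
                peak_standardized = max(.data$peak_standardized),
                .groups = "drop") |>
      mutate(n_methods = lengths(strsplit(.data$methods, ",", fixed = TRUE))) |>
      select("chrom", "start", "end", "methods", "n_methods",
             "peak_standardized")
  })
}

#' Attach overlapping genes to candidate regions
#'
#' A gene is attached when `[gene.start - flank, gene.end + flank]`
#' intersects the region (1-based inclusive intervals); attached genes are
#' sorted by position.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (e.g. from
#'   [consensus_regions()]).
#' @param genes Gene features from [read_gene_features()].
#' @param flank Symmetric flank in bp.  Default 0.
#' @return `regions` with list-column `genes` and a comma-separated
#'   `gene_names` column.
#' @export
annotate_regions <- function(regions, genes, flank = 0) {
  regions$genes <- vector("list", nrow(regions))
  regions$gene_names <- ""
  if (nrow(regions) == 0 || nrow(genes) == 0) return(regions)
  for (i in seq_len(nrow(regions))) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$end + flank >= regions$start[i] &
      genes$start - flank <= regions$end[i]
    g <- genes[hit, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    regions$genes[[i]] <- g
    regions$gene_names[i] <- paste(g$name, collapse = ",")
  }
  regions
}

#' Write candidate regions as BED and a summary TSV
#'
#' The BED file uses the standard 0-based half-open convention; the TSV
#' keeps 1-based inclusive coordinates with method and gene columns.
#'
#' @param regions Annotated regions tibble.
#' @param prefix Output path prefix (writes `prefix.bed` and
#'   `prefix.tsv`).
#' @return `prefix`, invisibly.
#' @export
write_regions <- function(regions, prefix) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = regions$methods)
  write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv <- regions[, setdiff(names(regions), "genes")]
  readr::write_tsv(tsv, paste0(prefix, ".tsv"))
  invisible(prefix)
}
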