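#' Selection-scan configuration
#'
#' Thresholds and haplotype parameters shared by the scan and the
#' candidate-region caller.
#'
#' @param zfst_min ZFST significance threshold.  Default 4.
#' @param flk_logp_min FLK `-log10(p)` threshold.  Default 3.
#' @param prsb_min `P_Rsb` threshold.  Default 3 (two-sided p = 0.001).
#' @param ehh_cutoff EHH truncation.  Default 0.05.
#' @param ehh_max_gap Maximum inter-SNP gap for EHH, bp.  Default 200,000.
#' @param min_consensus_methods Methods required for a consensus region.
#'   Default 2.
#' @param min_snps Minimum SNPs for a window to be reported.  Default 2.
#' @param window_size,window_step Window grid geometry, bp.  Defaults
#'   200,000 and 60,000.
#' @return A `scan_config` list.
#' @export
scan_config <- function(zfst_min = 4, flk_logp_min = 3, prsb_min = 3,
                        ehh_cutoff = 0.05, ehh_max_gap = 200000,
                        min_consensus_methods = 2, min_snps = 2,
                        window_size = 200000, window_step = 60000) {
  cfg <- list(zfst_min = zfst_min, flk_logp_min = flk_logp_min,
              prsb_min = prsb_min, ehh_cutoff = ehh_cutoff,
              ehh_max_gap = ehh_max_gap,
              min_consensus_methods = min_consensus_methods,
              min_snps = min_snps, window_size = window_size,
              window_step = window_step)
  if (any(unlist(cfg[1:3]) <= 0)) abort("thresholds must be positive")
  structure(cfg, class = "scan_config")
}

#' Three-statistic selection-signature scan
#'
#' Runs the windowed FST, FLK and Rsb arms on a shared window grid for one
#' comparison of two groups.  FST and Rsb contrast the two groups of
#' `pair`; FLK uses every population (or group) in the dataset against the
#' kinship matrix, which is estimated from Reynolds distances via a
#' midpoint-rooted neighbour-joining tree when not supplied.
#'
#' @param d A post-QC `geno_dataset` with labels in `group_col`.
#' @param haps A `hap_set` covering (at least) the samples of the two
#'   contrasted groups, aligned to `d` (see [align_haplotypes()]); `NULL`
#'   skips the Rsb arm.
#' @param pair Length-2 character vector of group labels to contrast.
#' @param group_col Sample column holding the labels.  Default
#'   `"population"`.
#' @param grid Window grid; by default built from the observed chromosome
#'   extents with the config's geometry.
#' @param kinship Optional kinship matrix for FLK.
#' @param config A [scan_config()].
#' @return A `sweep_scan` object: `windows` (all methods, one tibble),
#'   `rsb_snps`, `pair`, `config`, `kinship`.
#' @export
scan_selection <- function(d, haps = NULL, pair, group_col = "population",
                           grid = NULL, kinship = NULL,
                           config = scan_config()) {
  labels <- d$samples[[group_col]]
  if (anyNA(labels)) abort(paste("missing", group_col, "labels"))
  if (!all(pair %in% labels)) abort("both groups of `pair` must have samples")
  f <- allele_freqs(d, by = group_col)
  if (is.null(grid)) {
    lens <- tapply(d$variants$pos, d$variants$chrom, max)
    grid <- window_grid(setNames(as.numeric(lens), names(lens)),
                        size = config$window_size, step = config$window_step)
  }
  fst_w <- fst_windows(f, pair, grid, min_snps = config$min_snps)
  if (is.null(kinship)) {
    kinship <- estimate_kinship(f)
  }
  flk_w <- flk_windows(flk_snp(f, kinship), grid, min_snps = config$min_snps)
  rsb <- NULL
  rsb_w <- NULL
  if (!is.null(haps)) {
    ids1 <- d$samples$sample_id[labels == pair[1]]
    ids2 <- d$samples$sample_id[labels == pair[2]]
    h1 <- align_haplotypes(subset_samples(haps, ids1), d)
    h2 <- align_haplotypes(subset_samples(haps, ids2), d)
    rsb <- rsb_scan(h1, h2, grid, cutoff = config$ehh_cutoff,
                    max_gap = config$ehh_max_gap, min_snps = config$min_snps)
    rsb_w <- rsb$windows
  }
  structure(list(windows = bind_rows(fst_w, flk_w, rsb_w),
                 rsb_snps = if (!is.null(rsb)) rsb$snps else NULL,
                 pair = pair, config = config, kinship = kinship),
            class = "sweep_scan")
}

# Reynolds -> NJ -> shared-branch kinship; falls back to a diagonal
# half-distance matrix when there are too few populations for a tree.
estimate_kinship <- function(f) {
  D <- reynolds_matrix(f)
  if (length(f$pops) >= 4) {
    kinship_from_tree(D, outgroup = NULL)
  } else {
    K <- diag(rep(mean(D[upper.tri(D)]) / 2, length(f$pops)))
    dimnames(K) <- list(f$pops, f$pops)
    K
  }
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("<sweep_scan> %s vs %s: %d window records (%s)\n",
              x$pair[1], x$pair[2], nrow(x$windows),
              paste(unique(x$windows$method), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.sweep_scan <- function(x, ...) x$windows

#' @export
glance.sweep_scan <- function(x, ...) {
  sig <- significant_windows(x$windows, x$config)
  x$windows |>
    group_by(.data$method) |>
    summarise(n_windows = n(), max_standardized = max(.data$standardized),
              min_p = min(.data$p)) |>
    left_join(sig |> group_by(.data$method) |> summarise(n_intervals = n()),
              by = "method") |>
    mutate(n_intervals = dplyr::coalesce(.data$n_intervals, 0L))
}

#' Manhattan-style plot of a scan
#'
#' One facet per method; FST shows ZFST, FLK and Rsb show `-log10(p)`, with
#' the configured thresholds as dashed lines.
#'
#' @param object A `sweep_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- object$windows |>
    mutate(mid = (.data$start + .data$end) / 2,
           y = if_else(.data$method == "fst", .data$standardized,
                       -log10(.data$p)))
  thr <- tibble(method = c("fst", "flk", "rsb"),
                y = c(object$config$zfst_min, object$config$flk_logp_min,
                      object$config$prsb_min))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$mid / 1e6, y = .data$y,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(data = thr[thr$method %in% w$method, ],
                        ggplot2::aes(yintercept = .data$y), linetype = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$method), scales = "free_y") +
    ggplot2::labs(x = "position (Mb)",
                  y = "ZFST / -log10(p)") +
    ggplot2::theme_minimal()
}
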