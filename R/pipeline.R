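#' Run the full analysis pipeline
#'
#' Chains the package end to end: load (or simulate) genotypes, QC, LD
#' pruning, per-population diversity, PCA, Reynolds distances and kinship,
#' optional f3/f4 statistics, the three-statistic selection scan for each
#' configured comparison, consensus candidate regions and (optionally) gene
#' annotation.  All tabular outputs are written as TSV with a provenance
#' header (package version, config hash); a rerun with the same
#' configuration and inputs reproduces identical outputs.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `simulate` (a [sim_config()] or list of its arguments) *or* `bfile` /
#'   `vcf` (+ optional `pop_file`); optional `qc` (list of [apply_qc()]
#'   arguments), `scan` (list of [scan_config()] arguments), `comparisons`
#'   (list of length-2 character vectors), `f3` / `f4` (population
#'   vectors), `genes` (BED/GFF3 path), `flank` (bp).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results (`qc`,
#'   `diversity`, `pca`, `kinship`, `scans`, `regions`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  stamp <- sprintf("# sweepscan %s; config_hash=%s",
                   as.character(utils::packageVersion("sweepscan")), cfg_hash)
  emit <- function(tb, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    writeLines(stamp, path)
    suppressWarnings(readr::write_tsv(tb, path, append = TRUE,
                                      col_names = TRUE))
    path
  }

  haps <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    if (!inherits(sc, "sim_config")) sc <- do.call(sim_config, sc)
    sim <- simulate_dataset(sc)
    geno <- sim$genotypes
    haps <- sim$haplotypes
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (!is.null(config$bfile)) {
    geno <- read_plink(config$bfile, pop_file = config$pop_file)
  } else if (!is.null(config$vcf)) {
    if (isTRUE(config$phased)) {
      rv <- read_vcf(config$vcf, require_phased = TRUE,
                     pop_file = config$pop_file)
      geno <- rv$genotypes
      haps <- rv$haplotypes
    } else {
      geno <- read_vcf(config$vcf, pop_file = config$pop_file)
    }
  } else {
    abort("config needs one of: simulate, bfile, vcf")
  }

  qc <- do.call(apply_qc, c(list(geno), config$qc))
  emit(tidy(qc$report), "qc_report")
  jsonlite::write_json(
    c(glance(qc$report), list(stages = tidy(qc$report))),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  d <- qc$data

  div <- diversity_table(d)
  emit(div, "diversity")

  pruned <- ld_prune(d)
  pca <- pca_genotypes(pruned, n_components = min(10, nrow(d$samples) - 1,
                                                  nrow(pruned$variants)))
  emit(pca$scores, "pca_scores")

  f <- allele_freqs(d)
  D <- reynolds_matrix(f)
  emit(as_tibble(D, rownames = "population"), "reynolds")
  kin <- estimate_kinship(f)
  emit(as_tibble(as.matrix(kin), rownames = "population"), "kinship")

  fstats <- list()
  for (spec3 in config$f3) {
    fs <- f3_stat(f, spec3[1], spec3[2:3])
    fstats <- c(fstats, list(tidy(fs)))
  }
  for (spec4 in config$f4) {
    fs <- f4_stat(f, spec4)
    fstats <- c(fstats, list(tidy(fs)))
  }
  if (length(fstats)) emit(bind_rows(fstats), "fstats")

  scan_cfg <- do.call(scan_config, config$scan %||% list())
  comparisons <- config$comparisons %||%
    list(unique(d$samples$population)[1:2])
  scans <- list()
  regions_all <- list()
  genes <- if (!is.null(config$genes)) read_gene_features(config$genes)
  for (pair in comparisons) {
    label <- paste(pair, collapse = "_vs_")
    sc <- scan_selection(d, haps = haps, pair = pair, config = scan_cfg)
    scans[[label]] <- sc
    emit(sc$windows, paste0("scan_", label))
    if (!is.null(sc$rsb_snps)) emit(sc$rsb_snps, paste0("rsb_snps_", label))
    sig <- significant_windows(sc$windows, scan_cfg)
    reg <- consensus_regions(sig, scan_cfg$min_consensus_methods)
    if (!is.null(genes) && nrow(reg)) {
      reg <- annotate_regions(reg, genes, flank = config$flank %||% 0)
      reg <- reg[, setdiff(names(reg), "genes")]
    }
    regions_all[[label]] <- reg
    emit(reg, paste0("regions_", label))
  }
  yaml::write_yaml(config[setdiff(names(config), "simulate")],
                   file.path(out_dir, "run_config.yaml"))
  invisible(list(qc = qc, diversity = div, pca = pca, kinship = kin,
                 scans = scans, regions = regions_all))
}
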