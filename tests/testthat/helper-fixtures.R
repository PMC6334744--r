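# Small in-code fixtures and independent oracles shared across tests.

# dataset from a calls matrix (samples x variants); default one population
toy_dataset <- function(calls, pops = NULL, chrom = "1", pos = NULL,
                        ref = "A", alt = "G") {
  n <- nrow(calls)
  m <- ncol(calls)
  if (is.null(pops)) pops <- rep("P1", n)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_dataset(
    samples = tibble::tibble(sample_id = paste0("s", seq_len(n)),
                             population = pops),
    variants = tibble::tibble(chrom = rep_len(chrom, m), pos = pos,
                              variant_id = paste0("v", seq_len(m)),
                              ref = rep_len(ref, m), alt = rep_len(alt, m)),
    calls = calls)
}

toy_hapset <- function(hap, pos = NULL, chrom = "1") {
  m <- ncol(hap)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  haplotype_set(hap,
                sample_id = rep(paste0("s", seq_len(nrow(hap) / 2)), each = 2),
                variants = tibble::tibble(chrom = rep_len(chrom, m), pos = pos,
                                          variant_id = paste0("v", seq_len(m)),
                                          ref = "A", alt = "G"))
}

# brute-force site-EHH by pair counting: identity over all SNPs from the
# focal out to each flanking SNP (focal allele included)
ehh_bruteforce <- function(hap, pos, focal, side) {
  n <- nrow(hap)
  idx <- if (side == "right") focal:ncol(hap) else focal:1
  out_pos <- pos[focal]
  out_ehh <- 1
  for (k in idx[-1]) {
    cols <- min(focal, k):max(focal, k)
    same <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (all(hap[i, cols] == hap[j, cols])) same <- same + 1
      }
    }
    out_pos <- c(out_pos, pos[k])
    out_ehh <- c(out_ehh, same / choose(n, 2))
    if (same == 0) break  # curve is truncated once identity is lost
  }
  data.frame(pos = out_pos, ehh = out_ehh)
}

# brute-force window membership: which windows contain each position
windows_containing <- function(grid, chrom, pos) {
  which(grid$chrom == chrom & grid$start <= pos & grid$end >= pos)
}
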