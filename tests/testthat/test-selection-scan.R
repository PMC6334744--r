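test_that("per-SNP FST matches the closed formula and its boundary cases", {
  expect_equal(fst_snp(0.5, 0.5), 0)
  expect_equal(fst_snp(1, 0), 1)
  expect_equal(fst_snp(0.8, 0.2), 1 - 0.32 / 0.5, tolerance = 1e-15)
  expect_true(is.na(fst_snp(0, 0)))  # monomorphic across groups: excluded
  # independent re-derivation on 1,000 random frequency pairs
  set.seed(14)
  p1 <- runif(1000)
  p2 <- runif(1000)
  pr <- (p1 + p2) / 2
  ref <- 1 - (p1 * (1 - p1) + p2 * (1 - p2)) / (2 * pr * (1 - pr))
  ref[pr * (1 - pr) == 0] <- NA
  expect_equal(fst_snp(p1, p2), ref, tolerance = 1e-12)
})

test_that("standardize gives population-SD Z-scores and rejects constants", {
  expect_equal(standardize(c(0.1, 0.3)), c(-1, 1), tolerance = 1e-12)
  set.seed(15)
  x <- rnorm(100)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-12)
  expect_error(standardize(rep(2, 5)), "zero variance")
})

test_that("window grid covers chromosomes and membership matches a brute-force scan", {
  grid <- window_grid(c(`1` = 1340000), size = 200000, step = 60000)
  expect_identical(nrow(grid), 20L)
  expect_true(all(grid$start == 1 + (0:19) * 60000))
  expect_true(all(grid$end == grid$start + 200000 - 1))
  # truncation at chromosome end
  g2 <- window_grid(c(`1` = 450000), size = 200000, step = 60000)
  expect_lte(max(g2$end), 450000)
  expect_gte(max(g2$end), 450000 - 59999)
  # membership: every SNP's covering-window set matches the brute force,
  # via window means of an indicator
  set.seed(16)
  pos <- sort(sample.int(1340000, 300))
  for (p in pos[c(1, 50, 150, 300)]) {
    wm <- sweepscan:::window_means(pos, as.numeric(pos == p),
                                   grid$start, grid$end)
    got <- which(wm$n_snps > 0 & wm$raw > 0)
    expect_identical(got, windows_containing(grid, "1", p))
  }
  n_covering <- vapply(pos, function(p) sum(grid$start <= p & grid$end >= p),
                       integer(1))
  expect_lte(max(n_covering), ceiling(200000 / 60000))
})

test_that("windowed FST standardizes across emitted windows and flags degenerate input", {
  m <- 400
  vt <- tibble::tibble(chrom = "1", pos = seq_len(m) * 3000,
                       variant_id = paste0("v", seq_len(m)), ref = "A",
                       alt = "G")
  grid <- window_grid(c(`1` = max(vt$pos)), size = 200000, step = 60000)
  set.seed(17)
  f <- freq_table(c("g1", "g2"),
                  rbind(runif(m, 0.2, 0.8), runif(m, 0.2, 0.8)), 40, vt)
  w <- fst_windows(f, c("g1", "g2"), grid)
  expect_lt(abs(mean(w$standardized)), 1e-12)
  expect_equal(w$method, rep("fst", nrow(w)))
  expect_true(all(w$n_snps >= 1))
  # identical group frequencies -> all raw 0 -> standardization error
  f0 <- freq_table(c("g1", "g2"), rbind(runif(m, .2, .8)[1:m],
                                        runif(m, .2, .8)[1:m] * 0 + 0.5), 40, vt)
  f0$freqs[2, ] <- f0$freqs[1, ]
  expect_error(fst_windows(f0, c("g1", "g2"), grid), "zero variance")
})

test_that("FLK matches its 2-population closed form and chi-square moments", {
  vt1 <- tibble::tibble(chrom = "1", pos = 1000, variant_id = "v1",
                        ref = "A", alt = "G")
  K <- diag(c(0.1, 0.1))
  dimnames(K) <- list(c("a", "b"), c("a", "b"))
  # equal frequencies -> 0
  f_eq <- freq_table(c("a", "b"), rbind(0.4, 0.4), 40, vt1)
  expect_equal(flk_snp(f_eq, K)$flk, 0)
  # closed form: diagonal kinship (c, c) -> (p1-p2)^2 / (2 c p0 q0)
  f1 <- freq_table(c("a", "b"), rbind(0.7, 0.3), 40, vt1)
  p0 <- 0.5
  expect_equal(flk_snp(f1, K)$flk,
               (0.7 - 0.3)^2 / (2 * 0.1 * p0 * (1 - p0)), tolerance = 1e-12)
  # neutral Balding-Nichols matched to the kinship: mean within 10% of k-1
  cfg <- sim_config(n_pops = 4, samples_per_pop = 20, n_snps = 5000,
                    chrom_length = 1e7, fst_drift = 0.05, sweep = NULL,
                    seed = 55)
  ft <- simulate_frequencies(cfg)
  K4 <- diag(rep(0.05, 4))
  dimnames(K4) <- list(cfg$pop_names, cfg$pop_names)
  flk <- flk_snp(ft, K4)$flk
  expect_lt(abs(mean(flk, na.rm = TRUE) - 3) / 3, 0.1)
  # singular kinship errors with the population names
  Ks <- matrix(0.05, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(flk_snp(f1, Ks), "singular")
})

test_that("windowed FLK p-values come from the moment-matched chi-square", {
  cfg <- sim_config(n_pops = 4, samples_per_pop = 20, n_snps = 2000,
                    chrom_length = 6e6, fst_drift = 0.05, sweep = NULL,
                    seed = 56)
  ft <- simulate_frequencies(cfg)
  K4 <- diag(rep(0.05, 4))
  dimnames(K4) <- list(cfg$pop_names, cfg$pop_names)
  snp <- flk_snp(ft, K4)
  grid <- window_grid(c(`1` = cfg$chrom_length))
  w <- flk_windows(snp, grid)
  # re-derive the fit by hand
  mu <- mean(w$raw)
  v <- mean((w$raw - mu)^2)
  s <- v / (2 * mu)
  k <- 2 * mu^2 / v
  expect_equal(w$p, pchisq(w$raw / s, df = k, lower.tail = FALSE),
               tolerance = 1e-12)
  # constant raw across windows -> fitting error
  snp0 <- snp
  snp0$flk <- rep(1, nrow(snp0))
  expect_error(flk_windows(snp0, grid), "variance is zero")
})

test_that("EHH matches brute-force pair counting and is non-increasing", {
  # 4 haplotypes in 2 equal classes over {focal, flank}:
  # 2 * C(2,2) / C(4,2) = 1/3 at the first flanking SNP
  hap <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
  h <- toy_hapset(hap, pos = c(100, 200))
  curve <- ehh(h, focal = 1, side = "right", cutoff = 0)
  expect_equal(curve$ehh, c(1, 1 / 3))
  # and singleton refinement drives EHH to 0
  hap0 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  expect_equal(ehh(toy_hapset(hap0, pos = c(100, 200)), 1, "right",
                   cutoff = 0)$ehh, c(1, 0))
  # all identical -> 1 until truncation
  hid <- toy_hapset(matrix(1L, 6, 5))
  expect_equal(ehh(hid, 3, "right", cutoff = 0.05)$ehh, rep(1, 3))
  # focal-only chromosome -> single point at 1
  h1 <- toy_hapset(matrix(c(0L, 1L, 0L, 1L), 4, 1))
  expect_equal(nrow(ehh(h1, 1, "left")), 1L)
  # oracle equivalence on random <= 8-haplotype fixtures, both sides
  set.seed(18)
  for (rep in 1:5) {
    hap2 <- matrix(rbinom(8 * 7, 1, 0.5), nrow = 8)
    h2 <- toy_hapset(hap2, pos = cumsum(sample(500:2000, 7)))
    for (side in c("left", "right")) {
      f <- sample(7, 1)
      got <- ehh(h2, f, side, cutoff = 0, max_gap = 1e9)
      ref <- ehh_bruteforce(hap2, h2$variants$pos, f, side)
      expect_equal(got$pos, ref$pos)
      expect_equal(got$ehh, ref$ehh, tolerance = 1e-12)
      expect_true(all(diff(got$ehh) <= 1e-12))
    }
  }
})

test_that("iES integrates the EHH curve: linear growth, hand trapezoid, symmetry", {
  # identical haplotypes: iES doubles when the flank doubles
  mk <- function(n_flank, spacing) {
    m <- 2 * n_flank + 1
    toy_hapset(matrix(1L, 4, m), pos = seq_len(m) * spacing)
  }
  i1 <- ies(mk(5, 100), focal = 6, cutoff = 0.05)
  i2 <- ies(mk(10, 100), focal = 11, cutoff = 0.05)
  expect_equal(i1, 2 * 5 * 100)
  expect_equal(i2, 2 * i1)
  # immediate randomization: area is the single first trapezoid per side
  hap <- cbind(rep(0L, 8),
               as.integer(seq_len(8) %% 2),
               as.integer(c(0, 0, 1, 1, 0, 0, 1, 1)))
  h <- toy_hapset(hap, pos = c(1000, 2000, 3000))
  e_right <- ehh(h, 1, "right", cutoff = 0, max_gap = 1e9)
  manual <- sum(0.5 * (e_right$ehh[-1] + e_right$ehh[-nrow(e_right)]) *
                  diff(e_right$pos))
  expect_equal(ies(subset_variants(h, 1:2), 1, cutoff = 0, max_gap = 1e9),
               0.5 * (1 + e_right$ehh[2]) * 1000)
  expect_equal(ies(h, 1, cutoff = 0, max_gap = 1e9), manual)
  # coordinate reversal leaves iES unchanged
  set.seed(19)
  hap3 <- matrix(rbinom(10 * 9, 1, 0.5), nrow = 10)
  pos <- cumsum(sample(200:900, 9))
  h3 <- toy_hapset(hap3, pos = pos)
  rev_h <- toy_hapset(hap3[, 9:1], pos = sort(max(pos) + 1 - rev(pos)))
  expect_equal(ies(h3, 4, cutoff = 0, max_gap = 1e9),
               ies(rev_h, 6, cutoff = 0, max_gap = 1e9), tolerance = 1e-9)
})

test_that("Rsb: identical groups give null scores, swapping groups flips signs, P_Rsb transform is exact", {
  set.seed(20)
  cfg <- sim_config(n_pops = 2, samples_per_pop = 15, n_snps = 400,
                    chrom_length = 1.2e6, sweep = NULL, seed = 21)
  sim <- simulate_dataset(cfg)
  ids1 <- sim$genotypes$samples$sample_id[sim$genotypes$samples$population == "P1"]
  ids2 <- setdiff(sim$genotypes$samples$sample_id, ids1)
  h1 <- subset_samples(sim$haplotypes, ids1)
  h2 <- subset_samples(sim$haplotypes, ids2)
  grid <- window_grid(c(`1` = cfg$chrom_length))
  # identical datasets in both groups: raw exactly 0 everywhere
  same <- rsb_scan(h1, h1, grid)
  expect_true(all(same$snps$rsb == 0))
  # swapped groups: standardized values negate, P_Rsb unchanged
  ab <- rsb_scan(h1, h2, grid)
  ba <- rsb_scan(h2, h1, grid)
  expect_equal(ab$snps$rsb, -ba$snps$rsb, tolerance = 1e-12)
  expect_equal(ab$snps$prsb, ba$snps$prsb, tolerance = 1e-6)
  # the printed two-sided transform: standardized 3.29 -> P_Rsb ~ 3.0
  prsb_329 <- -log10(2 * pnorm(3.29, lower.tail = FALSE))
  expect_equal(prsb_329, 3, tolerance = 2e-3)
  # windows carry the max P_Rsb of their SNPs
  j <- which.max(ab$windows$raw)
  in_w <- ab$snps$pos >= ab$windows$start[j] & ab$snps$pos <= ab$windows$end[j]
  expect_equal(ab$windows$raw[j], max(ab$snps$prsb[in_w]))
})
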