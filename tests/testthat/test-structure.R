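test_that("PCA: clones coincide, populations separate, 1-SNP case is total", {
  set.seed(12)
  calls <- matrix(rbinom(10 * 60, 2, 0.5), nrow = 10)
  calls[2, ] <- calls[1, ]  # clone
  d <- toy_dataset(calls)
  pc <- pca_genotypes(d, n_components = 3)
  expect_equal(as.numeric(pc$scores[1, c("PC1", "PC2", "PC3")]),
               as.numeric(pc$scores[2, c("PC1", "PC2", "PC3")]),
               tolerance = 1e-8)

  # two drifted populations separate on PC1 with zero score-range overlap
  cfg <- sim_config(n_pops = 2, samples_per_pop = 30, n_snps = 1500,
                    chrom_length = 5e6, fst_drift = 0.1, sweep = NULL,
                    seed = 77)
  sim <- simulate_dataset(cfg)
  pc2 <- pca_genotypes(sim$genotypes, n_components = 2)
  s1 <- pc2$scores$PC1[sim$genotypes$samples$population == "P1"]
  s2 <- pc2$scores$PC1[sim$genotypes$samples$population == "P2"]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  # agreement with an independent eigensolver (svd of the centred matrix)
  X <- sim$genotypes$calls
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Xs <- sweep(sweep(X[, keep], 2, 2 * p[keep]), 2,
              sqrt(p[keep] * (1 - p[keep])), "/")
  sv <- svd(Xs)
  ref <- sv$u[, 1] * sv$d[1] / sqrt(sum(keep))
  expect_gt(abs(cor(ref, pc2$scores$PC1)), 0.999999)

  # one-SNP dataset: PC1 explains all variance
  d1 <- toy_dataset(matrix(c(0L, 1L, 2L), ncol = 1))
  pc1 <- pca_genotypes(d1, n_components = 1)
  expect_equal(pc1$explained[1], 1)
  expect_error(pca_genotypes(d1, n_components = 5), "n_components")
})

test_that("Reynolds distance matches its closed form and boundary cases", {
  vt <- tibble::tibble(chrom = "1", pos = 1000, variant_id = "v1",
                       ref = "A", alt = "G")
  # identical populations -> 0
  f0 <- freq_table(c("a", "b"), rbind(0.3, 0.3), 1e9, vt)
  expect_equal(reynolds_distance(f0, "a", "b", correction = FALSE), 0)
  # opposite fixation at every locus -> 1
  f1 <- freq_table(c("a", "b"), rbind(c(0, 1), c(1, 0)), 1e9,
                   tibble::tibble(chrom = "1", pos = c(1, 2) * 1000,
                                  variant_id = c("v1", "v2"),
                                  ref = "A", alt = "G"))
  expect_equal(reynolds_distance(f1, "a", "b", correction = FALSE), 1)
  # worked single-locus example: p = 0.2 vs 0.8 -> 0.36 / 0.68
  f2 <- freq_table(c("a", "b"), rbind(0.2, 0.8), 1e9, vt)
  expect_equal(reynolds_distance(f2, "a", "b", correction = FALSE),
               0.36 / 0.68, tolerance = 1e-12)
  # identically fixed everywhere -> undefined
  ff <- freq_table(c("a", "b"), rbind(1, 1), 1e9, vt)
  expect_error(reynolds_distance(ff, "a", "b"), "undefined")
})

test_that("tree kinship reproduces hand-summed shared branch lengths", {
  # unrooted additive tree: centre R; X (0.5) with tips A (1), B (2);
  # Y (0.3) with tips C (1.5), D (1); outgroup OG at 3 from R.
  pops <- c("A", "B", "C", "D", "OG")
  D <- matrix(0, 5, 5, dimnames = list(pops, pops))
  D["A", "B"] <- 3; D["A", "C"] <- 3.3; D["A", "D"] <- 2.8
  D["B", "C"] <- 4.3; D["B", "D"] <- 3.8; D["C", "D"] <- 2.5
  D["A", "OG"] <- 4.5; D["B", "OG"] <- 5.5; D["C", "OG"] <- 4.8
  D["D", "OG"] <- 4.3
  D <- D + t(D)
  K <- kinship_from_tree(D, outgroup = "OG")
  expect_equal(K["A", "A"], 1.5, tolerance = 1e-9)
  expect_equal(K["B", "B"], 2.5, tolerance = 1e-9)
  expect_equal(K["C", "C"], 1.8, tolerance = 1e-9)
  expect_equal(K["D", "D"], 1.3, tolerance = 1e-9)
  expect_equal(K["A", "B"], 0.5, tolerance = 1e-9)
  expect_equal(K["C", "D"], 0.3, tolerance = 1e-9)
  expect_equal(K["A", "C"], 0, tolerance = 1e-9)
  expect_false("OG" %in% rownames(K))
  expect_true(isSymmetric(K))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > -1e-9))
  expect_error(kinship_from_tree(D, outgroup = "ZZ"), "outgroup")
})

test_that("equidistant populations give star kinship (zero shared drift)", {
  pops <- c("A", "B", "C", "OG")
  D <- matrix(2, 4, 4, dimnames = list(pops, pops))
  D[, "OG"] <- 5; D["OG", ] <- 5
  diag(D) <- 0
  K <- kinship_from_tree(D, outgroup = "OG")
  off <- K[upper.tri(K)]
  expect_true(all(abs(off) < 1e-9))
  expect_equal(unname(diag(K)), rep(1, 3), tolerance = 1e-9)
})

test_that("f3 and f4 obey their algebraic identities", {
  set.seed(8)
  m <- 1200
  vt <- tibble::tibble(chrom = "1", pos = seq_len(m) * 1000,
                       variant_id = paste0("v", seq_len(m)), ref = "A",
                       alt = "G")
  p <- runif(m, 0.1, 0.9)
  f <- freq_table(c("A", "B", "C", "D"),
                  rbind(p, p, runif(m, 0.1, 0.9), runif(m, 0.1, 0.9)),
                  40, vt)
  # A identical to B: f3(A; B, C) = 0 without correction, f4(A,B;C,D) = 0
  expect_equal(f3_stat(f, "A", c("B", "C"), block_snps = 100,
                       bias_correction = FALSE)$value, 0)
  expect_equal(f4_stat(f, c("A", "B", "C", "D"), block_snps = 100)$value, 0)
  # antisymmetry and pair-swap identities, exactly
  f2 <- freq_table(c("A", "B", "C", "D"),
                   matrix(runif(4 * m, 0.1, 0.9), 4), 40, vt)
  ab_cd <- f4_stat(f2, c("A", "B", "C", "D"), block_snps = 100)
  ba_cd <- f4_stat(f2, c("B", "A", "C", "D"), block_snps = 100)
  cd_ab <- f4_stat(f2, c("C", "D", "A", "B"), block_snps = 100)
  expect_equal(ab_cd$value, -ba_cd$value, tolerance = 1e-15)
  expect_equal(ab_cd$se, ba_cd$se, tolerance = 1e-15)
  expect_equal(ab_cd$value, cd_ab$value, tolerance = 1e-15)
  expect_error(f3_stat(f, "A", c("B", "C"), block_snps = m), "blocks")
})

test_that("f3 is negative under admixture and positive under pure drift", {
  cfg <- sim_config(n_pops = 3, samples_per_pop = 20, n_snps = 5000,
                    chrom_length = 1e7, fst_drift = 0.2,
                    admixture = list(target = "P1",
                                     sources = c("P2", "P3"), theta = 0.5),
                    sweep = NULL, seed = 99)
  ft <- simulate_frequencies(cfg)
  fs <- sample_freq_table(ft, 40)
  adm <- f3_stat(fs, "P1", c("P2", "P3"))
  expect_lt(adm$z, -3)
  # same scenario without admixture: independent drift -> f3 > 0
  cfg2 <- sim_config(n_pops = 3, samples_per_pop = 20, n_snps = 5000,
                     chrom_length = 1e7, fst_drift = 0.2, sweep = NULL,
                     seed = 100)
  fs2 <- sample_freq_table(simulate_frequencies(cfg2), 40)
  drift <- f3_stat(fs2, "P1", c("P2", "P3"))
  expect_gt(drift$value, 0)
  expect_gt(drift$z, 0)
})

test_that("tidy/glance methods return one-row summaries for f-statistics", {
  set.seed(2)
  m <- 1000
  vt <- tibble::tibble(chrom = "1", pos = seq_len(m) * 1000,
                       variant_id = paste0("v", seq_len(m)), ref = "A",
                       alt = "G")
  f <- freq_table(c("A", "B", "C"), matrix(runif(3 * m, 0.2, 0.8), 3), 40, vt)
  td <- tidy(f3_stat(f, "A", c("B", "C"), block_snps = 200))
  expect_identical(nrow(td), 1L)
  expect_identical(td$kind, "f3")
  expect_equal(td$z, td$value / td$se)
})
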