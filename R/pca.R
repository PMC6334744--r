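#' Principal component analysis of genotypes
#'
#' Missing calls are replaced by the per-SNP mean, calls are mean-centred
#' and scaled by `sqrt(p(1-p))`, and the sample-sample covariance is
#' eigendecomposed (the usual genotype-PCA construction).  Each component's
#' sign is fixed by making its largest-magnitude score positive.
#'
#' @param d A post-QC (ideally LD-pruned) `geno_dataset`.
#' @param n_components Number of components to return.
#' @return An object of class `geno_pca` with `scores` (tibble: sample_id,
#'   population, PC1..), `explained` (fraction of variance per component)
#'   and `n_snps`.
#' @export
pca_genotypes <- function(d, n_components = 10) {
  X <- d$calls
  n <- nrow(X)
  if (n_components > min(dim(X))) {
    abort("n_components exceeds min(n_samples, n_snps)")
  }
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(X)) abort("no polymorphic SNPs for PCA")
  mu <- 2 * p
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  Xs <- sweep(sweep(X, 2, mu), 2, sqrt(p * (1 - p)), "/")
  G <- tcrossprod(Xs) / ncol(Xs)
  eig <- eigen(G, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  k <- seq_len(n_components)
  scores <- eig$vectors[, k, drop = FALSE] %*% diag(sqrt(vals[k]), n_components)
  for (j in k) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", k)
  structure(list(
    scores = bind_cols(d$samples[, c("sample_id", "population")],
                       as_tibble(scores)),
    explained = vals[k] / sum(vals),
    n_snps = ncol(Xs)),
    class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d SNPs; PC1 explains %.1f%%\n",
              nrow(x$scores), x$n_snps, 100 * x$explained[1]))
  invisible(x)
}

#' @export
tidy.geno_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @export
glance.geno_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained)),
         explained = x$explained)
}

#' @export
autoplot.geno_pca <- function(object, x = "PC1", y = "PC2", ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[x]], y = .data[[y]],
                               colour = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", x,
                  100 * object$explained[as.integer(sub("PC", "", x))]),
      y = sprintf("%s (%.1f%%)", y,
                  100 * object$explained[as.integer(sub("PC", "", y))])) +
    ggplot2::theme_minimal()
}
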