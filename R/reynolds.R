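#' Reynolds coancestry distance between two populations
#'
#' The ratio-of-sums Reynolds distance for biallelic loci: numerator per
#' locus `(p_a - p_b)^2` (the half-sum of squared allele-frequency
#' differences over both alleles), denominator per locus
#' `1 - (p_a p_b + q_a q_b)`, summed over loci before taking the ratio.
#' With `correction = TRUE` (default) the sampling bias of the numerator is
#' removed by subtracting each population's estimated frequency variance
#' `p q / (c - 1)` (`c` = non-missing allele count); `correction = FALSE`
#' gives the infinite-sample form.
#'
#' @param f A `freq_table`.
#' @param a,b Population labels.
#' @param correction Apply the sample-size-unbiased numerator correction.
#' @return A non-negative distance.
#' @export
reynolds_distance <- function(f, a, b, correction = TRUE) {
  ia <- match(a, f$pops); ib <- match(b, f$pops)
  if (is.na(ia) || is.na(ib)) abort("population not present in freq_table")
  pa <- f$freqs[ia, ]; pb <- f$freqs[ib, ]
  ca <- f$counts[ia, ]; cb <- f$counts[ib, ]
  ok <- !is.na(pa) & !is.na(pb) & ca > 0 & cb > 0
  pa <- pa[ok]; pb <- pb[ok]; ca <- ca[ok]; cb <- cb[ok]
  num <- (pa - pb)^2
  if (correction) {
    num <- num - ifelse(ca > 1, pa * (1 - pa) / (ca - 1), 0) -
      ifelse(cb > 1, pb * (1 - pb) / (cb - 1), 0)
  }
  den <- 1 - (pa * pb + (1 - pa) * (1 - pb))
  if (sum(den) <= 0) {
    abort("Reynolds distance undefined: all loci fixed identically in both populations")
  }
  max(sum(num) / sum(den), 0)
}

#' Full Reynolds distance matrix
#'
#' @inheritParams reynolds_distance
#' @return Symmetric matrix with zero diagonal.
#' @export
reynolds_matrix <- function(f, correction = TRUE) {
  k <- length(f$pops)
  D <- matrix(0, k, k, dimnames = list(f$pops, f$pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <-
        reynolds_distance(f, f$pops[i], f$pops[j], correction = correction)
    }
  }
  D
}

#' Shared-drift kinship matrix from a distance matrix via a rooted tree
#'
#' Builds a neighbour-joining tree from the distances, roots it on the
#' outgroup branch (or at the midpoint when `outgroup = NULL`), and returns
#' the matrix of shared root-to-tip branch lengths: `K[i, j]` is the summed
#' branch length common to the root-to-`i` and root-to-`j` paths (the depth
#' of their most recent common ancestor), and `K[i, i]` the total
#' root-to-`i` length.  Negative NJ branch lengths are clamped to zero
#' (reported via a message).  The outgroup is removed from the output.
#'
#' @param distances Square symmetric distance matrix with population names.
#' @param outgroup Outgroup label, or `NULL` for midpoint rooting.
#' @return A symmetric positive-semidefinite kinship matrix.
#' @export
kinship_from_tree <- function(distances, outgroup = NULL) {
  distances <- as.matrix(distances)
  pops <- rownames(distances)
  if (is.null(pops)) abort("distance matrix needs population names")
  if (!is.null(outgroup) && !outgroup %in% pops) {
    abort(paste("outgroup not in distance matrix:", outgroup))
  }
  tr <- ape::nj(distances)
  if (any(tr$edge.length < 0)) {
    inform(sprintf("clamped %d negative NJ branch length(s) to 0",
                   sum(tr$edge.length < 0)))
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr <- if (is.null(outgroup)) {
    phangorn::midpoint(tr)
  } else {
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  depth <- ape::node.depth.edgelength(tr)
  mrca <- ape::mrca(tr)
  tips <- tr$tip.label
  K <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      K[i, j] <- if (i == j) depth[i] else depth[mrca[i, j]]
    }
  }
  keep <- setdiff(tips, outgroup)
  K[keep, keep, drop = FALSE]
}
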