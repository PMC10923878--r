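#' Principal component analysis of the genotype matrix
#'
#' Eigendecomposition of the sample covariance of the centered,
#' variance-scaled genotype matrix: monomorphic sites are dropped, each
#' site's dosages are centered by `2 * p` and scaled by `sqrt(p * (1 - p))`
#' (the binomial standard deviation of an allele draw), and sample
#' coordinates on the leading components are returned as the scaled
#' eigenvectors of the sample-by-sample covariance.
#'
#' @param g A filtered `"genotype_matrix"` with at least two samples.
#' @param k Number of leading components to return; truncated with a warning
#'   if it exceeds the matrix rank.
#' @return A `"pca_result"`: `scores` (samples x k), `eigenvalues`,
#'   `var_explained`, `n_sites` used.
#' @export
pca_genotypes <- function(g, k = 2) {
  if (anyNA(g$dosages)) stop("PCA requires complete genotypes; run filter_sites() first")
  x <- g$dosages
  if (nrow(x) < 2) stop("PCA requires at least two samples")
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites for PCA")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  xs <- sweep(x, 2, 2 * p, "-")
  xs <- sweep(xs, 2, sqrt(p * (1 - p)), "/")
  m <- ncol(xs)
  cov_s <- tcrossprod(xs) / m
  e <- eigen(cov_s, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  rank <- sum(e$values > tol)
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank, "; truncating")
    k <- rank
  }
  vals <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)] * m), nrow = k)
  rownames(scores) <- rownames(g$dosages)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, eigenvalues = vals,
         var_explained = vals / sum(vals), n_sites = m),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("Genotype PCA: %d samples, %d sites; top %d components explain %s\n",
              nrow(x$scores), x$n_sites, k,
              paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}
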