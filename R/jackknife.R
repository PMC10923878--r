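# Weighted delete-one block jackknife for ratio-of-sums statistics
# (Busing, Meijer & van der Leeden 1999), the form used throughout the
# f-statistics literature. Blocks are contiguous physical segments so the
# standard errors are robust to linkage disequilibrium.

# Integer block index per site: contiguous `block_size_bp` segments anchored
# at position 1 of each contig, numbered consecutively across contigs.
site_blocks <- function(g, block_size_bp) {
  if (block_size_bp <= 0) stop("block_size_bp must be positive")
  within <- (g$sites$pos - 1) %/% block_size_bp
  key <- paste(g$sites$contig, within, sep = ":")
  match(key, unique(key))
}

# num_j, den_j: per-block sums of the statistic's numerator and denominator;
# weights: per-block information content (site counts). Returns the full-data
# estimate, the jackknife SE and the number of informative blocks.
jackknife_ratio <- function(num_j, den_j, weights = den_j) {
  keep <- weights > 0 & !is.na(weights)
  num_j <- num_j[keep]; den_j <- den_j[keep]; w <- weights[keep]
  n_blocks <- length(w)
  if (n_blocks < 2) {
    stop("block jackknife needs at least 2 informative blocks; got ", n_blocks)
  }
  num_tot <- sum(num_j); den_tot <- sum(den_j)
  if (den_tot == 0) stop("jackknife denominator is zero")
  est <- num_tot / den_tot
  theta_j <- (num_tot - num_j) / (den_tot - den_j)
  n <- sum(w)
  h <- n / w
  theta_dot <- n_blocks * est - sum((1 - w / n) * theta_j)
  v <- mean((h * est - (h - 1) * theta_j - theta_dot)^2 / (h - 1))
  list(est = est, se = sqrt(v), n_blocks = n_blocks)
}
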