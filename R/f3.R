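#' Patterson's f3 three-population admixture test
#'
#' Computes the sample-size-corrected f3 statistic f3(A, B; C): the mean over
#' sites of `(pC - pA) * (pC - pB)` minus the bias term `pC * (1 - pC) /
#' (nC - 1)` (nC = allele copies in the target), which removes the sampling
#' variance of the target frequency and makes the site term unbiased. A
#' significantly *positive* f3 rejects the hypothesis that the target is an
#' admixture of the two sources; a significantly negative f3 supports it.
#'
#' The standard error comes from a weighted delete-one block jackknife over
#' contiguous physical blocks; `z = f3 / SE` and the one-sided p-value is
#' `P(N(0,1) >= z)`, matching the directional hypothesis "f3 greater than
#' zero".
#'
#' @param g A filtered `"genotype_matrix"` (complete genotypes).
#' @param pm A `"population_map"`.
#' @param sourceA,sourceB The two candidate source populations (f3 is exactly
#'   symmetric in them).
#' @param target The test population; needs at least two diploids for the
#'   bias correction.
#' @param block_size_bp Jackknife block length in bp (default 5 Mb).
#' @return An `"f3_result"`: `f3`, `se`, `z`, `p` (one-sided), `n_sites`,
#'   `n_blocks`, `pops`.
#' @export
f3_statistic <- function(g, pm, sourceA, sourceB, target,
                         block_size_bp = 5e6) {
  if (anyNA(g$dosages)) stop("f3 requires complete genotypes; run filter_sites() first")
  n_target <- length(pop_samples(g, pm, target))
  if (n_target < 2) stop("target must have >= 2 diploids for the bias correction")
  pA <- pop_freq(g, pm, sourceA)
  pB <- pop_freq(g, pm, sourceB)
  pC <- pop_freq(g, pm, target)
  n_chrom <- 2L * n_target
  tsite <- (pC - pA) * (pC - pB) - pC * (1 - pC) / (n_chrom - 1)

  blocks <- site_blocks(g, block_size_bp)
  num_j <- rowsum(tsite, blocks)[, 1]
  den_j <- tabulate(blocks)
  jk <- jackknife_ratio(num_j, den_j)
  z <- jk$est / jk$se
  structure(
    list(f3 = jk$est, se = jk$se, z = z,
         p = stats::pnorm(z, lower.tail = FALSE),
         n_sites = length(tsite), n_blocks = jk$n_blocks,
         block_size_bp = block_size_bp,
         pops = c(sourceA = sourceA, sourceB = sourceB, target = target)),
    class = "f3_result"
  )
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3(%s, %s; %s) = %.6g  SE %.3g  z = %.4g  one-sided p = %.3g\n",
              x$pops[["sourceA"]], x$pops[["sourceB"]], x$pops[["target"]],
              x$f3, x$se, x$z, x$p))
  cat(sprintf("  %d sites, %d jackknife blocks of %g bp\n",
              x$n_sites, x$n_blocks, x$block_size_bp))
  invisible(x)
}
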