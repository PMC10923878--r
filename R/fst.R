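#' Per-population alternate-allele frequencies
#'
#' Frequencies are computed from diploid dosages as `p = sum(dosages) /
#' (2 * n_nonmissing)` per site, with `n` the number of non-missing allele
#' copies.
#'
#' @param g A `"genotype_matrix"`.
#' @param pm A `"population_map"`.
#' @param pop Population label.
#' @return A data frame with one row per site: `contig`, `pos`, `p`
#'   (alternate-allele frequency) and `n` (allele copies observed).
#' @export
allele_frequencies <- function(g, pm, pop) {
  dos <- g$dosages[pop_samples(g, pm, pop), , drop = FALSE]
  n <- 2L * colSums(!is.na(dos))
  p <- ifelse(n > 0, colSums(dos, na.rm = TRUE) / n, NA_real_)
  data.frame(contig = g$sites$contig, pos = g$sites$pos, p = p, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: frequency vector only (complete data assumed).
pop_freq <- function(g, pm, pop) {
  dos <- g$dosages[pop_samples(g, pm, pop), , drop = FALSE]
  colMeans(dos) / 2
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# dA, dB: complete individuals x sites dosage matrices.
# Returns list(a, abc): the among-population component and the total a+b+c.
wc_components <- function(dA, dB) {
  nA <- nrow(dA); nB <- nrow(dB)
  if (nA < 2 || nB < 2) stop("Weir-Cockerham F_ST requires >= 2 diploids per population")
  pA <- colMeans(dA) / 2; pB <- colMeans(dB) / 2
  hA <- colMeans(dA == 1L); hB <- colMeans(dB == 1L)
  nbar <- (nA + nB) / 2
  nc <- 2 * nbar - (nA^2 + nB^2) / (2 * nbar)
  pbar <- (nA * pA + nB * pB) / (2 * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / nbar
  hbar <- (nA * hA + nB * hB) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, abc = a + b + cc)
}

#' Weir-Cockerham F_ST, genome-wide and per window
#'
#' Implements the Weir & Cockerham (1984) two-population theta estimator from
#' per-site variance components, aggregated as a ratio of sums: per window
#' `fst = sum(a) / sum(a + b + c)` over the window's sites. Sites monomorphic
#' in both populations contribute 0/0 and are skipped (they do not enter
#' `n_sites`). The estimator can be slightly negative; a window whose
#' component denominator is zero is flagged undefined.
#'
#' Requires complete genotypes (run [filter_sites()] first).
#'
#' @param g A filtered `"genotype_matrix"`.
#' @param pm A `"population_map"`.
#' @param popA,popB Population labels; each must have at least two diploids.
#' @param windows Optional `"window_table"`; `NULL` computes only the
#'   genome-wide aggregate.
#' @return An `"fst_result"`: list with `genome` (`sum_a`, `sum_bc`, `fst`,
#'   `n_sites`) and, when `windows` is given, a per-window data frame
#'   `windows` with `fst` and a `defined` flag.
#' @export
wc_fst <- function(g, pm, popA, popB, windows = NULL) {
  dA <- g$dosages[pop_samples(g, pm, popA), , drop = FALSE]
  dB <- g$dosages[pop_samples(g, pm, popB), , drop = FALSE]
  if (anyNA(dA) || anyNA(dB)) {
    stop("F_ST requires complete genotypes; run filter_sites() first")
  }
  comp <- wc_components(dA, dB)
  informative <- comp$abc != 0
  genome <- list(
    sum_a = sum(comp$a),
    sum_bc = sum(comp$abc) - sum(comp$a),
    fst = if (any(informative)) sum(comp$a) / sum(comp$abc) else NA_real_,
    n_sites = sum(informative)
  )
  out <- structure(list(genome = genome, windows = NULL,
                        pops = c(popA, popB)),
                   class = "fst_result")
  if (!is.null(windows)) {
    sums <- window_range_sums(windows,
                              list(a = comp$a, abc = comp$abc,
                                   informative = as.numeric(informative)))
    defined <- !is.na(sums$abc) & sums$abc != 0
    fst <- ifelse(defined, sums$a / sums$abc, NA_real_)
    out$windows <- data.frame(
      contig = windows$contig, start = windows$start, end = windows$end,
      n_sites = ifelse(is.na(sums$informative), 0L,
                       as.integer(sums$informative)),
      sum_a = sums$a, sum_bc = sums$abc - sums$a,
      fst = fst, defined = defined, stringsAsFactors = FALSE
    )
  }
  out
}

# Sum per-site vectors over window index ranges via cumulative sums.
# vecs: named list of per-site numeric vectors. Returns a list of per-window
# sums (NA for windows without sites).
window_range_sums <- function(windows, vecs) {
  f <- windows$first_site
  l <- windows$last_site
  lapply(vecs, function(v) {
    cs <- c(0, cumsum(v))
    ifelse(is.na(f), NA_real_, cs[l + 1L] - cs[f])
  })
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST (%s vs %s): genome-wide %.5g over %d sites\n",
              x$pops[1], x$pops[2], x$genome$fst, x$genome$n_sites))
  if (!is.null(x$windows)) {
    cat(sprintf("  windows: %d (%d undefined)\n", nrow(x$windows),
                sum(!x$windows$defined)))
  }
  invisible(x)
}
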