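# Frequency-based ABBA-BABA site terms for taxa ordered (P1, P2, P3, P4),
# in the allele-symmetric form: each pattern counts both the alt-derived and
# ref-derived configuration, so no outgroup polarization is imposed and the
# statistic is invariant under relabeling ref/alt at a site:
#   ABBA = (1-p1) p2 p3 (1-p4) + p1 (1-p2)(1-p3) p4
#   BABA = p1 (1-p2) p3 (1-p4) + (1-p1) p2 (1-p3) p4
# With the pipeline's roles (P1=sfC, P2=invasive, P3=sfR, P4=outgroup), an
# excess of ABBA (D > 0) indicates gene flow between P3 and P2.
d_site_terms <- function(g, pm, p1, p2, p3, p4) {
  f1 <- pop_freq(g, pm, p1)
  f2 <- pop_freq(g, pm, p2)
  f3 <- pop_freq(g, pm, p3)
  f4 <- pop_freq(g, pm, p4)
  list(abba = (1 - f1) * f2 * f3 * (1 - f4) + f1 * (1 - f2) * (1 - f3) * f4,
       baba = f1 * (1 - f2) * f3 * (1 - f4) + (1 - f1) * f2 * (1 - f3) * f4)
}

#' ABBA-BABA D statistic (genome-wide or windowed)
#'
#' The D statistic is the normalized difference between the summed
#' frequencies of the two discordant site patterns on the four-taxon tree
#' ((P1, P2), P3), P4: `D = (ABBA - BABA) / (ABBA + BABA)`, with per-site
#' frequency-weighted pattern contributions (see the package vignette).
#' Under incomplete lineage sorting alone E\[D\] = 0; gene flow between P3 and
#' P2 drives D positive.
#'
#' In `"genome"` mode the statistic is accompanied by a weighted block
#' jackknife standard error over contiguous physical blocks and `Z = D / SE`.
#' In `"windowed"` mode D is computed per window of a (typically SNV-count,
#' sliding) `"window_table"`; windows with `ABBA + BABA = 0` are flagged
#' undefined.
#'
#' @param g A filtered `"genotype_matrix"`.
#' @param pm A `"population_map"`.
#' @param p1,p2,p3,p4 Population labels in tree order; the pipeline's
#'   convention is P1=sfC, P2=invasive, P3=sfR, P4=outgroup, but the
#'   operation is role-agnostic.
#' @param mode `"genome"` or `"windowed"`.
#' @param windows A `"window_table"`, required in windowed mode.
#' @param block_size_bp Jackknife block length in bp (genome mode).
#' @return A `"d_result"`: in genome mode `d`, `abba`, `baba`, `se`, `z`,
#'   `n_sites` (informative), `n_blocks`; in windowed mode a per-window data
#'   frame `windows` with `abba`, `baba`, `d`, `defined`.
#' @export
d_statistic <- function(g, pm, p1, p2, p3, p4,
                        mode = c("genome", "windowed"),
                        windows = NULL, block_size_bp = 5e6) {
  mode <- match.arg(mode)
  if (anyNA(g$dosages)) stop("D requires complete genotypes; run filter_sites() first")
  terms <- d_site_terms(g, pm, p1, p2, p3, p4)
  pops <- c(P1 = p1, P2 = p2, P3 = p3, P4 = p4)
  if (mode == "genome") {
    den <- terms$abba + terms$baba
    if (sum(den) == 0) {
      return(structure(list(mode = mode, d = NA_real_, abba = 0, baba = 0,
                            se = NA_real_, z = NA_real_, n_sites = 0L,
                            n_blocks = 0L, defined = FALSE, pops = pops),
                       class = "d_result"))
    }
    blocks <- site_blocks(g, block_size_bp)
    num_j <- rowsum(terms$abba - terms$baba, blocks)[, 1]
    den_j <- rowsum(den, blocks)[, 1]
    w_j <- rowsum(as.numeric(den > 0), blocks)[, 1]
    jk <- jackknife_ratio(num_j, den_j, weights = w_j)
    structure(
      list(mode = mode, d = jk$est, abba = sum(terms$abba),
           baba = sum(terms$baba), se = jk$se, z = jk$est / jk$se,
           n_sites = sum(den > 0), n_blocks = jk$n_blocks,
           block_size_bp = block_size_bp, defined = TRUE, pops = pops),
      class = "d_result"
    )
  } else {
    if (is.null(windows)) stop("windowed mode requires a window_table")
    sums <- window_range_sums(windows, terms)
    den <- sums$abba + sums$baba
    defined <- !is.na(den) & den > 0
    d <- ifelse(defined, (sums$abba - sums$baba) / den, NA_real_)
    structure(
      list(mode = mode,
           windows = data.frame(
             contig = windows$contig, start = windows$start,
             end = windows$end, first_site = windows$first_site,
             last_site = windows$last_site, n_sites = windows$n_sites,
             abba = sums$abba, baba = sums$baba, d = d, defined = defined,
             stringsAsFactors = FALSE),
           pops = pops),
      class = "d_result"
    )
  }
}

#' One-sided Z test for a positive D statistic
#'
#' Tests the directional hypothesis D > 0 (gene flow from P3 into P2):
#' `p = P(N(0,1) >= D / SE)` with the jackknife SE. `D = 0` gives p = 0.5.
#'
#' @param d A genome-mode `"d_result"` with a jackknife SE, or a list with
#'   numeric elements `d` and `se`.
#' @return The one-sided p-value.
#' @export
z_test_positive <- function(d) {
  if (is.null(d$se) || is.na(d$se)) stop("z_test_positive needs a jackknife SE")
  stats::pnorm(d$d / d$se, lower.tail = FALSE)
}

#' @export
print.d_result <- function(x, ...) {
  if (x$mode == "genome") {
    if (!isTRUE(x$defined)) {
      cat("D statistic: undefined (ABBA + BABA = 0)\n")
    } else {
      cat(sprintf("D(%s, %s; %s, %s) = %.5g  SE %.3g  Z = %.4g\n",
                  x$pops[["P1"]], x$pops[["P2"]], x$pops[["P3"]],
                  x$pops[["P4"]], x$d, x$se, x$z))
      cat(sprintf("  ABBA %.4g, BABA %.4g over %d informative sites; %d blocks\n",
                  x$abba, x$baba, x$n_sites, x$n_blocks))
    }
  } else {
    cat(sprintf("Windowed D: %d windows (%d undefined), median D = %.4g\n",
                nrow(x$windows), sum(!x$windows$defined),
                stats::median(x$windows$d, na.rm = TRUE)))
  }
  invisible(x)
}
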