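#' Aggregate the pipeline's evidence into a strain-assignment verdict
#'
#' Combines the f3 admixture test, the genome-wide D statistic, the windowed
#' F_ST ratio scan with its randomization null, and the windowed D scan into
#' one of three verdicts:
#'
#' * `"pure-source-A"` — the target population derives purely from popA
#'   (sfC in the default pipeline): f3 z >= `z_threshold`, the flagged-window
#'   randomization p >= `alpha` (or no window was flagged at all), and no
#'   positive-D window stays significant at `alpha` after adjustment;
#' * `"admixed"` — positive evidence of gene flow: genome-wide D with
#'   Z >= `z_threshold`, a significantly negative f3 (z <= -`z_threshold`),
#'   or concordant window-level evidence (at least one significant
#'   positive-D window together with a flagged-window F_ST excess beating
#'   the randomization null at `alpha`);
#' * `"inconclusive"` — anything else, with reasons listed.
#'
#' @param fst_scan An `"fst_scan"` (carries the genome-wide F_ST pair).
#' @param f3 An `"f3_result"` for (popA, popB; target).
#' @param d_genome A genome-mode `"d_result"`.
#' @param randomization A `"randomization_test"`, or `NULL` when the scan
#'   flagged no windows (then the condition is vacuously met).
#' @param d_windows A `"d_scan"`.
#' @param alpha Significance level (default 0.05).
#' @param z_threshold Z threshold for "significantly positive" (default 3).
#' @return A `"verdict_report"` embedding every input statistic.
#' @export
build_verdict <- function(fst_scan, f3, d_genome, randomization, d_windows,
                          alpha = 0.05, z_threshold = 3) {
  components <- list(fst_scan = fst_scan, f3 = f3, d_genome = d_genome,
                     d_windows = d_windows)
  missing <- names(components)[vapply(components, is.null, logical(1))]
  if (is.null(randomization) &&
      !is.null(fst_scan) && fst_scan$n_flagged > 0) {
    missing <- c(missing, "randomization")
  }
  if (length(missing)) {
    return(structure(
      list(verdict = "inconclusive",
           reasons = paste("missing component:", missing),
           alpha = alpha, z_threshold = z_threshold,
           statistics = components),
      class = "verdict_report"
    ))
  }

  admixed_signals <- character(0)
  if (isTRUE(d_genome$defined) && d_genome$z >= z_threshold) {
    admixed_signals <- c(admixed_signals,
                         sprintf("genome-wide D = %.4g with Z = %.3g >= %g",
                                 d_genome$d, d_genome$z, z_threshold))
  }
  if (f3$z <= -z_threshold) {
    admixed_signals <- c(admixed_signals,
                         sprintf("f3 = %.4g significantly negative (z = %.3g)",
                                 f3$f3, f3$z))
  }
  # concordant window-level evidence: loci with significantly positive D
  # together with a flagged-window F_ST excess beating the randomization null
  if (d_windows$n_significant > 0 && !is.null(randomization) &&
      randomization$p < alpha) {
    admixed_signals <- c(admixed_signals, sprintf(
      "%d significant positive-D window(s) and flagged-window F_ST excess (randomization p = %.3g)",
      d_windows$n_significant, randomization$p))
  }

  f3_ok <- f3$z >= z_threshold
  rand_ok <- fst_scan$n_flagged == 0 || randomization$p >= alpha
  dwin_ok <- d_windows$n_significant == 0

  reasons <- character(0)
  if (!f3_ok) reasons <- c(reasons, sprintf(
    "f3 z = %.3g below threshold %g: admixture not excluded", f3$z, z_threshold))
  if (!rand_ok) reasons <- c(reasons, sprintf(
    "flagged-window F_ST excess significant under randomization (p = %.3g)",
    randomization$p))
  if (!dwin_ok) reasons <- c(reasons, sprintf(
    "%d window(s) with significantly positive D after adjustment",
    d_windows$n_significant))

  verdict <- if (length(admixed_signals)) "admixed"
             else if (f3_ok && rand_ok && dwin_ok) "pure-source-A"
             else "inconclusive"
  structure(
    list(verdict = verdict,
         reasons = if (verdict == "admixed") admixed_signals else reasons,
         alpha = alpha, z_threshold = z_threshold,
         statistics = c(components, list(randomization = randomization))),
    class = "verdict_report"
  )
}

#' @export
print.verdict_report <- function(x, ...) {
  cat("Strain-assignment verdict:", x$verdict, "\n")
  if (length(x$reasons)) {
    for (r in x$reasons) cat("  -", r, "\n")
  }
  s <- x$statistics
  if (!is.null(s$fst_scan)) {
    cat(sprintf("  genome-wide F_ST: A-target %.4g, B-target %.4g; flagged windows %d/%d (%g%%)\n",
                s$fst_scan$genome$fst_A_target, s$fst_scan$genome$fst_B_target,
                s$fst_scan$n_flagged, s$fst_scan$n_windows,
                s$fst_scan$flagged_pct))
  }
  if (!is.null(s$f3)) {
    cat(sprintf("  f3 = %.5g (z = %.3g, p = %.3g)\n", s$f3$f3, s$f3$z, s$f3$p))
  }
  if (!is.null(s$d_genome) && isTRUE(s$d_genome$defined)) {
    cat(sprintf("  genome-wide D = %.4g (Z = %.3g)\n", s$d_genome$d,
                s$d_genome$z))
  }
  if (!is.null(s$randomization)) {
    cat(sprintf("  randomization p = %.4g\n", s$randomization$p))
  }
  if (!is.null(s$d_windows)) {
    cat(sprintf("  positive-D windows: %d (%d significant after adjustment)\n",
                s$d_windows$n_positive, s$d_windows$n_significant))
  }
  invisible(x)
}

#' Write a verdict report as JSON
#'
#' Serializes the verdict and every supporting statistic (window tables
#' included) to a JSON file.
#'
#' @param report A `"verdict_report"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_verdict_json <- function(report, path) {
  stopifnot(inherits(report, "verdict_report"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full strain-assignment pipeline on a VCF + popmap
#'
#' Reads the cohort, applies the biallelic/complete-genotype filters, runs
#' the windowed F_ST ratio scan with its randomization null, the f3 test,
#' genome-wide D, and the windowed D scan, and returns the aggregated
#' verdict. Roles are fixed to the package convention: popA = sfC,
#' popB = sfR, target = invasive, outgroup = outgroup.
#'
#' @param vcf_path,popmap_path Input files (see [read_cohort()]).
#' @param window_bp Physical window size for the F_ST scan.
#' @param snv_window,snv_step SNV-count window size/step for the D scan.
#' @param n_reps Randomization replicates.
#' @param alpha,z_threshold Decision thresholds (see [build_verdict()]).
#' @param block_size_bp Jackknife block length for f3 and genome-wide D.
#' @param n_subblocks Sub-blocks per window for windowed-D standard errors.
#' @param seed Seed for the randomization test.
#' @return A `"verdict_report"`.
#' @export
run_strain_scan <- function(vcf_path, popmap_path,
                            window_bp = 5e5, snv_window = 1e4,
                            snv_step = 1e3, n_reps = 1000,
                            alpha = 0.05, z_threshold = 3,
                            block_size_bp = 5e6, n_subblocks = 20,
                            seed = 1) {
  cohort <- read_cohort(vcf_path, popmap_path)
  g <- filter_sites(cohort$genotypes)$genotypes
  pm <- cohort$popmap

  w_phys <- assign_windows(g, "physical", window_bp)
  w_snv <- assign_windows(g, "snv_count", snv_window, snv_step)

  scan <- fst_ratio_scan(g, pm, w_phys)
  rand <- if (scan$n_flagged > 0) {
    fst_randomization_test(g, pm, scan, n_reps = n_reps, seed = seed)
  } else NULL
  f3 <- f3_statistic(g, pm, "sfC", "sfR", "invasive", block_size_bp)
  dg <- d_statistic(g, pm, "sfC", "invasive", "sfR", "outgroup",
                    mode = "genome", block_size_bp = block_size_bp)
  ds <- d_scan(g, pm, w_snv, alpha = alpha, n_subblocks = n_subblocks)
  build_verdict(scan, f3, dg, rand, ds, alpha = alpha,
                z_threshold = z_threshold)
}
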