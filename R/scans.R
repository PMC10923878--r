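# Run code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Windowed F_ST log-ratio scan
#'
#' For every physical window, computes Weir-Cockerham F_ST between `popA`
#' (default sfC) and the target (default invasive) and between `popB`
#' (default sfR) and the target, and the log ratio
#' `ln(fst_A_target / fst_B_target)`. A window is *flagged* when the target
#' is more differentiated from popA than from popB (`fst_A > fst_B`,
#' equivalently log ratio > 0) — under a pure-popA origin such windows should
#' be rare. Windows where either F_ST is undefined or non-positive are
#' excluded from the ratio and reported separately, not silently dropped.
#'
#' @param g A filtered `"genotype_matrix"`.
#' @param pm A `"population_map"`.
#' @param windows A physical `"window_table"` (e.g. 500 kb non-overlapping).
#' @param popA,popB,target Population labels.
#' @return An `"fst_scan"`: per-window data frame (`fst_A`, `fst_B`,
#'   `log_ratio`, `flagged`, `ratio_defined`), counts `n_windows`,
#'   `n_flagged`, `n_excluded`, `flagged_pct` (percentage of all windows,
#'   3 significant figures), and the `genome`-wide F_ST pair.
#' @export
fst_ratio_scan <- function(g, pm, windows, popA = "sfC", popB = "sfR",
                           target = "invasive") {
  rA <- wc_fst(g, pm, popA, target, windows)
  rB <- wc_fst(g, pm, popB, target, windows)
  fA <- rA$windows$fst
  fB <- rB$windows$fst
  ratio_defined <- rA$windows$defined & rB$windows$defined & fA > 0 & fB > 0
  if (!any(ratio_defined)) stop("no window yields a defined F_ST ratio; empty scan")
  log_ratio <- rep(NA_real_, length(fA))
  log_ratio[ratio_defined] <- log(fA[ratio_defined] / fB[ratio_defined])
  flagged <- ratio_defined & fA > fB
  win <- data.frame(
    contig = windows$contig, start = windows$start, end = windows$end,
    n_sites = rA$windows$n_sites,
    fst_A = fA, fst_B = fB, log_ratio = log_ratio,
    ratio_defined = ratio_defined, flagged = flagged,
    first_site = windows$first_site, last_site = windows$last_site,
    stringsAsFactors = FALSE
  )
  structure(
    list(windows = win,
         n_windows = nrow(win),
         n_flagged = sum(flagged),
         n_excluded = sum(!ratio_defined),
         flagged_pct = signif(100 * sum(flagged) / nrow(win), 3),
         genome = list(fst_A_target = rA$genome$fst,
                       fst_B_target = rB$genome$fst),
         pops = c(popA = popA, popB = popB, target = target)),
    class = "fst_scan"
  )
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf("F_ST ratio scan (%s vs %s, target %s): %d windows\n",
              x$pops[["popA"]], x$pops[["popB"]], x$pops[["target"]],
              x$n_windows))
  cat(sprintf("  genome-wide F_ST: %s-%s %.4g, %s-%s %.4g\n",
              x$pops[["popA"]], x$pops[["target"]], x$genome$fst_A_target,
              x$pops[["popB"]], x$pops[["target"]], x$genome$fst_B_target))
  cat(sprintf("  flagged (F_ST_%s > F_ST_%s): %d (%g%%); excluded from ratio: %d\n",
              x$pops[["popA"]], x$pops[["popB"]], x$n_flagged, x$flagged_pct,
              x$n_excluded))
  invisible(x)
}

#' Randomization null for the flagged-window F_ST contrast
#'
#' Tests whether the F_ST excess observed in the flagged windows (mean over
#' flagged windows of `fst_A_target - fst_B_target`) could arise from
#' arbitrary groupings of the native individuals. Each replicate re-partitions
#' the pooled native samples (popA and popB) into two random groups of the
#' original sizes without replacement — the group of size |popA| playing the
#' popA role, preserving the sample-size asymmetry — and recomputes the same
#' mean F_ST difference over the same windows. The one-sided p-value with
#' continuity correction is `(#\{null >= observed\} + 1) / (n_reps + 1)`.
#'
#' @param g A filtered `"genotype_matrix"`.
#' @param pm A `"population_map"`.
#' @param scan An `"fst_scan"` with at least one flagged window.
#' @param n_reps Number of randomization replicates (>= 1).
#' @param seed Optional seed; the caller's RNG stream is left untouched.
#' @return A `"randomization_test"`: `observed_diff`, `null_diffs`
#'   (length `n_reps`), `p`, `n_reps`, `seed`.
#' @export
fst_randomization_test <- function(g, pm, scan, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(scan, "fst_scan"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  flg <- scan$windows[scan$windows$flagged, , drop = FALSE]
  if (nrow(flg) == 0) stop("randomization test requires >= 1 flagged window")

  popA <- scan$pops[["popA"]]; popB <- scan$pops[["popB"]]
  target <- scan$pops[["target"]]
  idA <- pop_samples(g, pm, popA)
  idB <- pop_samples(g, pm, popB)
  natives <- c(idA, idB)
  nA <- length(idA)

  # restrict to the flagged windows' sites; remap window ranges locally
  site_idx <- unlist(mapply(seq.int, flg$first_site, flg$last_site,
                            SIMPLIFY = FALSE))
  range_len <- flg$last_site - flg$first_site + 1L
  local_first <- cumsum(c(1L, head(range_len, -1L)))
  local_last <- cumsum(range_len)
  d_nat <- g$dosages[natives, site_idx, drop = FALSE]
  d_tgt <- g$dosages[pop_samples(g, pm, target), site_idx, drop = FALSE]

  window_fst_diff <- function(rows1, rows2) {
    c1 <- wc_components(d_nat[rows1, , drop = FALSE], d_tgt)
    c2 <- wc_components(d_nat[rows2, , drop = FALSE], d_tgt)
    csa1 <- c(0, cumsum(c1$a)); cst1 <- c(0, cumsum(c1$abc))
    csa2 <- c(0, cumsum(c2$a)); cst2 <- c(0, cumsum(c2$abc))
    f1 <- (csa1[local_last + 1L] - csa1[local_first]) /
      (cst1[local_last + 1L] - cst1[local_first])
    f2 <- (csa2[local_last + 1L] - csa2[local_first]) /
      (cst2[local_last + 1L] - cst2[local_first])
    mean(f1 - f2, na.rm = TRUE)
  }

  observed <- window_fst_diff(seq_len(nA), nA + seq_along(idB))
  null_diffs <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      perm <- sample(length(natives))
      window_fst_diff(perm[seq_len(nA)], perm[-seq_len(nA)])
    }, numeric(1))
  })
  structure(
    list(observed_diff = observed, null_diffs = null_diffs,
         p = (sum(null_diffs >= observed) + 1) / (n_reps + 1),
         n_reps = n_reps, seed = seed, n_flagged_windows = nrow(flg)),
    class = "randomization_test"
  )
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf("Randomization test over %d flagged windows: observed diff %.4g, one-sided p = %.4g (%d replicates)\n",
              x$n_flagged_windows, x$observed_diff, x$p, x$n_reps))
  invisible(x)
}

#' Windowed D-statistic scan with per-window Z tests
#'
#' Computes D in every (typically sliding SNV-count) window, collects the
#' windows with D > 0, and tests each one-sidedly for D significantly greater
#' than zero using a jackknife SE computed over contiguous sub-blocks of the
#' window's own sites. With few sub-blocks the ratio D/SE is compared against
#' a Student-t reference with (sub-blocks - 1) degrees of freedom rather than
#' the normal, which would be anti-conservative. Because sliding windows
#' overlap and many are tested,
#' the per-window p-values are also reported Bonferroni-adjusted by the
#' number of positive windows tested; the summary quotes the maximum-Z
#' window.
#'
#' @param g A filtered `"genotype_matrix"`.
#' @param pm A `"population_map"`.
#' @param windows A `"window_table"` (SNV-count scheme, e.g. size 10000 step
#'   1000).
#' @param p1,p2,p3,p4 Population labels in tree order.
#' @param alpha Significance level applied to adjusted p-values.
#' @param n_subblocks Sub-blocks per window for the jackknife SE.
#' @return A `"d_scan"`: per-window data frame `windows`, `positive` data
#'   frame (with `se`, `z`, `p`, `p_adj`), counts, and `max_z` (the
#'   maximum-Z positive window's row, or `NULL`).
#' @export
d_scan <- function(g, pm, windows, p1 = "sfC", p2 = "invasive", p3 = "sfR",
                   p4 = "outgroup", alpha = 0.05, n_subblocks = 20) {
  if (nrow(windows) == 0) stop("no windows to scan")
  dres <- d_statistic(g, pm, p1, p2, p3, p4, mode = "windowed",
                      windows = windows)
  win <- dres$windows
  terms <- d_site_terms(g, pm, p1, p2, p3, p4)
  pos_idx <- which(win$defined & win$d > 0)

  positive <- NULL
  if (length(pos_idx)) {
    stats_list <- lapply(pos_idx, function(i) {
      sites <- seq.int(win$first_site[i], win$last_site[i])
      chunk <- cut(seq_along(sites), breaks = n_subblocks, labels = FALSE)
      num_j <- rowsum((terms$abba - terms$baba)[sites], chunk)[, 1]
      den_j <- rowsum((terms$abba + terms$baba)[sites], chunk)[, 1]
      w_j <- rowsum(as.numeric((terms$abba + terms$baba)[sites] > 0), chunk)[, 1]
      jk <- jackknife_ratio(num_j, den_j, weights = w_j)
      c(se = jk$se, z = jk$est / jk$se, df = jk$n_blocks - 1)
    })
    se <- vapply(stats_list, `[[`, numeric(1), "se")
    z <- vapply(stats_list, `[[`, numeric(1), "z")
    df <- vapply(stats_list, `[[`, numeric(1), "df")
    # few sub-blocks per window: t reference, not normal (see vignette)
    p <- stats::pt(z, df = df, lower.tail = FALSE)
    positive <- data.frame(
      contig = win$contig[pos_idx], start = win$start[pos_idx],
      end = win$end[pos_idx], d = win$d[pos_idx], se = se, z = z, df = df,
      p = p,
      p_adj = pmin(1, p * length(pos_idx)), stringsAsFactors = FALSE
    )
  }
  max_z <- if (!is.null(positive) && nrow(positive)) {
    positive[which.max(positive$z), , drop = FALSE]
  } else NULL
  structure(
    list(windows = win, positive = positive,
         n_windows = nrow(win),
         n_positive = length(pos_idx),
         n_undefined = sum(!win$defined),
         n_significant = if (is.null(positive)) 0L
                         else sum(positive$p_adj < alpha),
         alpha = alpha, max_z = max_z,
         pops = dres$pops),
    class = "d_scan"
  )
}

#' @export
print.d_scan <- function(x, ...) {
  cat(sprintf("Windowed D scan: %d windows, %d with D > 0 (%d undefined)\n",
              x$n_windows, x$n_positive, x$n_undefined))
  if (!is.null(x$max_z)) {
    cat(sprintf("  max-Z positive window %s:%d-%d: D = %.4g, Z = %.3g, p = %.3g (adjusted %.3g)\n",
                x$max_z$contig, x$max_z$start, x$max_z$end, x$max_z$d,
                x$max_z$z, x$max_z$p, x$max_z$p_adj))
  }
  cat(sprintf("  windows significant after adjustment at alpha = %g: %d\n",
              x$alpha, x$n_significant))
  invisible(x)
}
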