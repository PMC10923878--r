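test_that("flagged-window bookkeeping matches the constructed truth", {
  co <- build_scan_cohort(40, 3)
  scan <- fst_ratio_scan(co$g, co$pm, co$windows)
  expect_equal(scan$n_windows, 40)
  expect_equal(scan$n_flagged, 3)
  expect_identical(which(scan$windows$flagged), 1:3)
  # flagged <=> log_ratio > 0 among ratio-defined windows
  expect_identical(scan$windows$flagged[scan$windows$ratio_defined],
                   scan$windows$log_ratio[scan$windows$ratio_defined] > 0)
  expect_equal(scan$flagged_pct, signif(100 * 3 / 40, 3))
})

test_that("identical native groups give log-ratio zero everywhere and no flags", {
  base <- c(0L, 1L, 2L, 1L)
  dos <- rbind(matrix(base, 4, 30), matrix(base, 4, 30),
               matrix(c(0L, 0L, 1L, 2L), 4, 30))
  set.seed(4)
  dos[1:8, ] <- dos[1:8, ] + sample(0:1, 8 * 30, replace = TRUE)
  dos[dos > 2L] <- 2L
  dos[5:8, ] <- dos[1:4, ]           # same genotypes under both labels
  rownames(dos) <- paste0("s", 1:12)
  g <- make_genotypes(dos, pos = as.integer(seq_len(30) * 1000L - 500L),
                      contig_lengths = c(chr1 = 30000L))
  pm <- make_popmap(rownames(dos), rep(c("sfC", "sfR", "invasive"), each = 4))
  scan <- fst_ratio_scan(g, pm, assign_windows(g, "physical", 1000))
  expect_true(all(abs(scan$windows$log_ratio[scan$windows$ratio_defined])
                  < 1e-12))
  expect_equal(scan$n_flagged, 0)
})

test_that("randomization null is reproducible and hand-recomputable", {
  co <- build_scan_cohort(20, 2)
  scan <- fst_ratio_scan(co$g, co$pm, co$windows)
  r1 <- fst_randomization_test(co$g, co$pm, scan, n_reps = 3, seed = 77)
  r2 <- fst_randomization_test(co$g, co$pm, scan, n_reps = 3, seed = 77)
  expect_identical(r1$null_diffs, r2$null_diffs)
  expect_equal(r1$p, (sum(r1$null_diffs >= r1$observed_diff) + 1) / 4)

  # manual recomputation of each replicate with wc_fst on the regrouped data
  natives <- c(paste0("s", 1:4), paste0("s", 5:8))
  invisible(runif(1))   # ensure .Random.seed exists
  manual <- local({
    old <- .Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(77)
    vapply(1:3, function(i) {
      perm <- sample(8)
      relabel <- co$pm
      relabel$population[match(natives[perm[1:4]], relabel$sample)] <- "sfC"
      relabel$population[match(natives[perm[5:8]], relabel$sample)] <- "sfR"
      f1 <- wc_fst(co$g, relabel, "sfC", "invasive", co$windows)$windows$fst
      f2 <- wc_fst(co$g, relabel, "sfR", "invasive", co$windows)$windows$fst
      mean((f1 - f2)[scan$windows$flagged], na.rm = TRUE)
    }, numeric(1))
  })
  expect_equal(r1$null_diffs, manual, tolerance = 1e-12)

  # RNG state of the caller is untouched
  invisible(runif(1))
  before <- .Random.seed
  fst_randomization_test(co$g, co$pm, scan, n_reps = 2, seed = 5)
  expect_identical(before, .Random.seed)
})

test_that("an unreachable observed difference gives p = 1/(n_reps + 1)", {
  # 12 + 8 natives: the chance of regenerating the exact original grouping
  # within 1000 draws is ~1%, and only that grouping ties the observed diff
  n_win <- 6
  dosA <- matrix(0L, 12, n_win)
  dosB <- matrix(c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L), 8, n_win)
  dosT <- matrix(c(2L, 2L, 2L, 2L, 2L, 1L), 6, n_win)
  dos <- rbind(dosA, dosB, dosT)
  rownames(dos) <- paste0("s", 1:26)
  g <- make_genotypes(dos, pos = as.integer(seq_len(n_win) * 1000L - 500L),
                      contig_lengths = c(chr1 = n_win * 1000L))
  pm <- make_popmap(rownames(dos),
                    rep(c("sfC", "sfR", "invasive"), c(12, 8, 6)))
  scan <- fst_ratio_scan(g, pm, assign_windows(g, "physical", 1000))
  expect_gt(scan$n_flagged, 0)
  rand <- fst_randomization_test(g, pm, scan, n_reps = 1000, seed = 19)
  expect_true(all(rand$null_diffs < rand$observed_diff))
  expect_equal(rand$p, 1 / 1001)
})

test_that("randomization preconditions are enforced", {
  co <- build_scan_cohort(10, 0)
  scan <- fst_ratio_scan(co$g, co$pm, co$windows)
  expect_equal(scan$n_flagged, 0)
  expect_error(fst_randomization_test(co$g, co$pm, scan, n_reps = 10),
               "flagged window")
})

test_that("an all-BABA cohort yields D = -1 in every window and no positives", {
  freqs <- matrix(rep(c(1, 0, 1, 0), 40), nrow = 4)  # BABA at every site
  dos <- do.call(rbind, lapply(1:4, function(i) {
    matrix(rep(2L * freqs[i, ], each = 2), nrow = 2)
  }))
  rownames(dos) <- paste0("s", 1:8)
  g <- make_genotypes(dos, pos = seq_len(40) * 250L)
  pm <- make_popmap(rownames(dos),
                    rep(c("sfC", "invasive", "sfR", "outgroup"), each = 2))
  w <- assign_windows(g, "snv_count", 10, 5)
  ds <- d_scan(g, pm, w, n_subblocks = 5)
  expect_true(all(ds$windows$d == -1))
  expect_equal(ds$n_positive, 0)
  expect_equal(ds$n_significant, 0)
  expect_null(ds$max_z)
})

test_that("windowed-D false positives stay near the nominal rate without admixture", {
  co <- small_cohort(91, 0, n_chromosomes = 2, chromosome_length_bp = 4e6)
  w <- assign_windows(co$g, "snv_count", 500, 500)   # disjoint windows
  ds <- d_scan(co$g, co$pm, w, n_subblocks = 5)
  n <- ds$n_windows
  # unadjusted per-window p < 0.05 should stay within binomial 4-sigma slack
  raw_sig <- if (is.null(ds$positive)) 0 else sum(ds$positive$p < 0.05)
  expect_lte(raw_sig, ceiling(n * 0.05 + 4 * sqrt(n * 0.05 * 0.95)))
})

test_that("scan plots build without evaluation errors", {
  skip_if_not_installed("ggplot2")
  co <- build_scan_cohort(20, 2)
  scan <- fst_ratio_scan(co$g, co$pm, co$windows)
  p1 <- plot_fst_scan(scan)
  expect_s3_class(p1, "ggplot")

  freqs <- matrix(rep(c(0, 1, 1, 0, 1, 0, 1, 0), 10), nrow = 4)
  dos <- do.call(rbind, lapply(1:4, function(i) {
    matrix(rep(2L * freqs[i, ], each = 2), nrow = 2)
  }))
  rownames(dos) <- paste0("s", 1:8)
  g <- make_genotypes(dos, pos = seq_len(ncol(dos)) * 250L)
  pm <- make_popmap(rownames(dos),
                    rep(c("sfC", "invasive", "sfR", "outgroup"), each = 2))
  ds <- d_scan(g, pm, assign_windows(g, "snv_count", 5, 5), n_subblocks = 3)
  p2 <- plot_d_scan(ds)
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
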