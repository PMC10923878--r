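test_that("read_cohort transcribes GT fields into dosages regardless of phasing", {
  paths <- write_toy_vcf()
  cohort <- read_cohort(paths$vcf, paths$popmap)
  g <- cohort$genotypes
  expect_equal(dim(g$dosages), c(4, 3))
  # hand-read dosages; "./." and half-calls are NA; allele "2" not counted
  expect_equal(unname(g$dosages[, 1]), c(0L, 1L, 2L, 0L))
  expect_equal(unname(g$dosages[, 2]), c(1L, NA_integer_, 0L, 2L))
  expect_equal(unname(g$dosages[, 3]), c(0L, 0L, 1L, 0L))
  expect_equal(g$sites$pos, c(100L, 200L, 300L))
  expect_equal(cohort$popmap$population, c("sfC", "sfC", "sfR", "invasive"))
  expect_equal(g$contig_lengths, c(chr1 = 10000L))
})

test_that("sample manifest mismatches are reported by name", {
  paths <- write_toy_vcf()
  short_map <- file.path(tempdir(), "short.popmap.tsv")
  writeLines(paste(c("s1", "s2", "s3"), c("sfC", "sfC", "sfR"), sep = "\t"),
             short_map)
  expect_error(read_cohort(paths$vcf, short_map), "s4")
  bad_label <- file.path(tempdir(), "bad.popmap.tsv")
  writeLines(paste(c("s1", "s2", "s3", "s4"),
                   c("sfC", "sfC", "sfR", "corn"), sep = "\t"), bad_label)
  expect_error(read_cohort(paths$vcf, bad_label), "corn")
})

test_that("read_cohort dimensions match a text scan of a simulated VCF", {
  co <- small_cohort(17, missing_rate = 0.01, multiallelic_rate = 0.01)
  raw <- read_cohort(co$paths$vcf, co$paths$popmap)
  n_records <- sum(!grepl("^#", readLines(co$paths$vcf)))
  expect_equal(ncol(raw$genotypes$dosages), n_records)
  expect_equal(nrow(raw$genotypes$dosages), 18)  # 6 + 5 + 6 + 1
})

test_that("filter_sites applies the multiallelic-then-missing rule and is idempotent", {
  # 1 triallelic, 1 with a missing call, 2 clean
  dos <- rbind(c(1L, 0L, 2L, 1L),
               c(0L, NA, 1L, 0L),
               c(2L, 1L, 0L, 1L))
  g <- make_genotypes(dos, alt = c("T", "C", "T,G", "C"))
  res <- filter_sites(g)
  expect_equal(res$report$multiallelic, 1)
  expect_equal(res$report$missing, 1)
  expect_equal(res$report$retained, 2)
  expect_equal(res$genotypes$sites$pos, c(100L, 400L))
  expect_false(anyNA(res$genotypes$dosages))

  # a site failing both rules counts once, under multiallelic
  g2 <- make_genotypes(rbind(c(NA, 1L), c(0L, 0L), c(1L, 2L)),
                       alt = c("T,G", "C"))
  res2 <- filter_sites(g2)
  expect_equal(res2$report$multiallelic, 1)
  expect_equal(res2$report$missing, 0)

  # identity on clean input, and idempotence
  clean <- filter_sites(res$genotypes)
  expect_identical(clean$genotypes$dosages, res$genotypes$dosages)
  expect_equal(clean$report$multiallelic + clean$report$missing, 0)

  # zero survivors is an explicit error
  expect_error(filter_sites(make_genotypes(matrix(NA_integer_, 2, 1))),
               "no sites survive")
})

test_that("simulated removal counts fall within binomial bounds", {
  co <- small_cohort(23, n_chromosomes = 2, chromosome_length_bp = 3e6,
                     missing_rate = 0.01, multiallelic_rate = 0.005)
  raw <- read_cohort(co$paths$vcf, co$paths$popmap)
  rep <- filter_sites(raw$genotypes)$report
  s <- rep$input
  n_samples <- nrow(raw$genotypes$dosages)
  p_tri <- 0.005
  # a biallelic site is lost to missingness if any of its calls is masked
  p_any_missing <- 1 - (1 - 0.01)^n_samples
  p_missing_only <- (1 - p_tri) * p_any_missing
  expect_lt(abs(rep$multiallelic - s * p_tri),
            4 * sqrt(s * p_tri * (1 - p_tri)) + 1)
  expect_lt(abs(rep$missing - s * p_missing_only),
            4 * sqrt(s * p_missing_only * (1 - p_missing_only)) + 1)
})

test_that("physical windows tile each contig from position 1", {
  g <- make_genotypes(matrix(1L, 1, 5),
                      contig = rep("chr1", 5),
                      pos = c(1L, 499999L, 500000L, 500001L, 1150000L),
                      contig_lengths = c(chr1 = 1200000L))
  w <- assign_windows(g, "physical", 500000)
  expect_equal(nrow(w), 3)
  expect_equal(w$start, c(1, 500001, 1000001))
  expect_equal(w$end, c(500000, 1000000, 1200000))
  expect_equal(w$n_sites, c(3, 1, 1))
  # sites partition across windows
  expect_equal(sum(w$n_sites), 5)
})

test_that("physical window count per contig is ceil(span / size) even with empty windows", {
  g <- make_genotypes(matrix(1L, 1, 4),
                      contig = c("chr1", "chr1", "chr2", "chr2"),
                      pos = c(10L, 2500L, 100L, 900L),
                      contig_lengths = c(chr1 = 3000L, chr2 = 1000L))
  w <- assign_windows(g, "physical", 1000)
  expect_equal(sum(w$contig == "chr1"), 3)
  expect_equal(sum(w$contig == "chr2"), 1)
  # middle chr1 window holds no site
  empty <- w[w$contig == "chr1" & w$start == 1001, ]
  expect_equal(empty$n_sites, 0)
  expect_true(is.na(empty$first_site))
})

test_that("snv_count windows slide by step and drop short trailing runs", {
  # scaled transcription of the 25,000-SNV / size 10,000 / step 1,000 layout
  n <- 250L; size <- 100L; step <- 10L
  g <- make_genotypes(matrix(1L, 1, n), pos = seq_len(n) * 10L)
  w <- assign_windows(g, "snv_count", size, step)
  # brute-force enumeration of admissible starts
  starts <- c()
  k <- 1L
  while (k + size - 1L <= n) { starts <- c(starts, k); k <- k + step }
  expect_equal(nrow(w), length(starts))   # 16 windows
  expect_equal(w$first_site, starts)
  expect_equal(w$last_site, starts + size - 1L)
  expect_true(all(w$n_sites == size))

  # size == step tiles disjointly over the first floor(n/size)*size sites
  w2 <- assign_windows(g, "snv_count", 100, 100)
  expect_equal(nrow(w2), 2)
  expect_equal(unlist(mapply(seq.int, w2$first_site, w2$last_site)),
               1:200, ignore_attr = TRUE)
  expect_error(assign_windows(g, "snv_count", 100, 150), "step")
  expect_error(assign_windows(g, "physical", 0), "size")
})

test_that("windows never span contigs", {
  g <- make_genotypes(matrix(1L, 1, 40),
                      contig = rep(c("chr1", "chr2"), each = 20),
                      pos = rep(seq_len(20) * 50L, 2))
  w <- assign_windows(g, "snv_count", 15, 5)
  expect_true(all(w$n_sites == 15))
  for (i in seq_len(nrow(w))) {
    sites <- seq.int(w$first_site[i], w$last_site[i])
    expect_length(unique(g$sites$contig[sites]), 1)
    expect_equal(unique(g$sites$contig[sites]), w$contig[i])
  }
})

test_that("dosages round-trip through VCF write and read on a clean cohort", {
  co <- small_cohort(31)
  raw <- read_cohort(co$paths$vcf, co$paths$popmap)
  # clean simulation: filtering changes nothing, read is the identity
  expect_identical(raw$genotypes$dosages, co$g$dosages)
  af <- allele_frequencies(co$g, co$pm, "sfC")
  # independent recount from the VCF text at the first site
  lines <- readLines(co$paths$vcf)
  header <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  sfc_cols <- which(header %in% co$pm$sample[co$pm$population == "sfC"])
  first <- strsplit(grep("^#", lines, invert = TRUE, value = TRUE)[1], "\t")[[1]]
  alleles <- unlist(strsplit(first[sfc_cols], "[/|]"))
  expect_equal(af$p[1], mean(alleles == "1"))
  expect_equal(af$n[1], length(alleles))
})
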