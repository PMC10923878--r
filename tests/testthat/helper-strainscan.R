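# Shared fixtures and independent oracles for the test suite.

# Build a genotype_matrix directly from a dosage matrix (samples x sites).
make_genotypes <- function(dosages, contig = NULL, pos = NULL,
                           ref = NULL, alt = NULL, contig_lengths = NULL) {
  s <- ncol(dosages)
  if (is.null(contig)) contig <- rep("chr1", s)
  if (is.null(pos)) pos <- seq_len(s) * 100L
  if (is.null(ref)) ref <- rep("A", s)
  if (is.null(alt)) alt <- rep("T", s)
  structure(
    list(dosages = dosages,
         sites = data.frame(contig = contig, pos = as.integer(pos),
                            ref = ref, alt = alt, stringsAsFactors = FALSE),
         contig_lengths = contig_lengths),
    class = "genotype_matrix"
  )
}

make_popmap <- function(samples, populations) {
  structure(data.frame(sample = samples, population = populations,
                       stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

# Dosage rows for a population with an exact allele frequency and exact
# heterozygote count at every site: n diploids, n_alt alt copies of which
# n_het sit in heterozygotes (n_alt - n_het must be even).
pop_rows <- function(n, n_alt, n_het, n_sites = 1) {
  n_hom <- (n_alt - n_het) / 2
  stopifnot(n_hom == round(n_hom), n_het + n_hom <= n)
  col <- c(rep(2L, n_hom), rep(1L, n_het), rep(0L, n - n_hom - n_het))
  matrix(rep(col, n_sites), nrow = n, ncol = n_sites)
}

# Independent scalar transcription of the Weir & Cockerham (1984) two-
# population variance components, written from the per-site definitions with
# r = 2; deliberately un-vectorized.
wc_oracle_site <- function(nA, pA, hA, nB, pB, hB) {
  r <- 2
  n_bar <- (nA + nB) / r
  n_c <- (r * n_bar - (nA^2 + nB^2) / (r * n_bar)) / (r - 1)
  p_bar <- (nA * pA + nB * pB) / (r * n_bar)
  s2 <- (nA * (pA - p_bar)^2 + nB * (pB - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (nA * hA + nB * hB) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  c_ <- h_bar / 2
  list(a = a, b = b, c = c_)
}

# Ratio-of-sums F_ST from dosage matrices via the scalar oracle, one site at
# a time.
wc_oracle_fst <- function(dA, dB) {
  sum_a <- 0; sum_abc <- 0
  for (j in seq_len(ncol(dA))) {
    comp <- wc_oracle_site(
      nrow(dA), mean(dA[, j]) / 2, mean(dA[, j] == 1),
      nrow(dB), mean(dB[, j]) / 2, mean(dB[, j] == 1)
    )
    sum_a <- sum_a + comp$a
    sum_abc <- sum_abc + comp$a + comp$b + comp$c
  }
  sum_a / sum_abc
}

# Simulate a small cohort to files and load it back filtered.
# Returns list(g, pm, paths).
small_cohort <- function(seed, admixture_fraction = 0,
                         samples = c(sfC = 6, sfR = 5, invasive = 6,
                                     outgroup = 1),
                         n_chromosomes = 2, chromosome_length_bp = 1.5e6,
                         locus_length_bp = 2.5e4,
                         missing_rate = 0, multiallelic_rate = 0) {
  cfg <- simulation_config(
    samples_per_pop = samples, n_chromosomes = n_chromosomes,
    chromosome_length_bp = chromosome_length_bp,
    locus_length_bp = locus_length_bp,
    missing_rate = missing_rate, multiallelic_rate = multiallelic_rate,
    seed = seed
  )
  out <- simulate_cohort(default_faw_model(admixture_fraction), cfg,
                         tempfile("cohort"))
  cohort <- read_cohort(out$vcf, out$popmap)
  g <- filter_sites(cohort$genotypes)$genotypes
  list(g = g, pm = cohort$popmap, paths = out)
}

# A deterministic toy VCF (4 samples, 3 sites) written to a temp file.
write_toy_vcf <- function(dir = tempdir()) {
  vcf <- file.path(dir, "toy.vcf")
  popmap <- file.path(dir, "toy.popmap.tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1|1\t0/0",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t0/1\t./.\t0/0\t1/1",
    "chr1\t300\t.\tT\tA,G\t.\tPASS\t.\tGT\t0/0\t0/2\t0/1\t0/0"
  ), vcf)
  writeLines(paste(c("s1", "s2", "s3", "s4"),
                   c("sfC", "sfC", "sfR", "invasive"), sep = "\t"), popmap)
  list(vcf = vcf, popmap = popmap)
}

# Deterministic scan fixture: one site per 1 kb window, three populations of
# 4 diploids. "low" windows put the target near popA; "high" windows invert
# the contrast so fst_A > fst_B.
build_scan_cohort <- function(n_windows, n_high) {
  stopifnot(n_high <= n_windows)
  low_A <- c(1L, 1L, 1L, 2L); low_B <- c(1L, 2L, 2L, 2L)
  tgt <- c(0L, 0L, 1L, 1L)
  high_A <- low_B; high_B <- low_A
  is_high <- seq_len(n_windows) <= n_high
  dosA <- sapply(is_high, function(h) if (h) high_A else low_A)
  dosB <- sapply(is_high, function(h) if (h) high_B else low_B)
  dosT <- matrix(tgt, 4, n_windows)
  dos <- rbind(dosA, dosB, dosT)
  rownames(dos) <- paste0("s", 1:12)
  g <- make_genotypes(dos, pos = as.integer(seq_len(n_windows) * 1000L - 500L),
                      contig_lengths = c(chr1 = n_windows * 1000L))
  pm <- make_popmap(rownames(dos), rep(c("sfC", "sfR", "invasive"), each = 4))
  list(g = g, pm = pm,
       windows = assign_windows(g, "physical", 1000))
}

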