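#' Simulate a synthetic cohort and write VCF + popmap
#'
#' Generates diploid genotypes for the four populations of a
#' [demographic_model()] under the structured coalescent (independent loci,
#' infinite-sites mutations), then writes a GT-only VCF v4.2 with contigs
#' `chr1..chrN` and a two-column popmap TSV. Missing genotype calls (`./.`)
#' and triallelic records are injected at the configured rates so that the
#' filtering stage has realistic work to do.
#'
#' One master seed (`config$seed`) is split deterministically into substreams
#' for the coalescent/mutations, allele labels, multiallelism and
#' missingness, so a fixed seed yields byte-identical output files.
#'
#' @param model A `"demographic_model"`.
#' @param config A `"simulation_config"`.
#' @param out_prefix Path prefix; writes `<out_prefix>.vcf` and
#'   `<out_prefix>.popmap.tsv`.
#' @return Invisibly, a list with elements `vcf`, `popmap` (paths) and
#'   `n_sites` (number of VCF records written).
#' @examples
#' \donttest{
#' cfg <- simulation_config(samples_per_pop = c(sfC = 4, sfR = 4,
#'                                              invasive = 4, outgroup = 1),
#'                          n_chromosomes = 1, chromosome_length_bp = 1e6,
#'                          seed = 7)
#' out <- simulate_cohort(default_faw_model(), cfg, tempfile("cohort"))
#' }
#' @export
simulate_cohort <- function(model, config, out_prefix) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(config, "simulation_config"))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)
  substream <- sample.int(.Machine$integer.max - 1L, 4L)

  set.seed(substream[1L])
  sim <- sim_genome(model, config)
  if (length(sim$pos) == 0) stop("simulation produced zero segregating sites")

  spp <- config$samples_per_pop
  sample_ids <- unlist(lapply(POP_LEVELS, function(p) {
    n <- spp[[p]]
    if (n == 0) character(0) else sprintf("%s_%02d", p, seq_len(n))
  }))
  pops <- rep(POP_LEVELS, times = spp)

  # haplotype pairs -> diploid genotype strings
  n_ind <- sum(spp)
  s <- ncol(sim$haps)
  a1 <- sim$haps[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE]
  a2 <- sim$haps[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(t(a1), "/", t(a2)), nrow = s, ncol = n_ind)

  # allele labels
  set.seed(substream[2L])
  nuc <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, s, replace = TRUE)
  alt_i <- ((ref_i - 1L + sample.int(3L, s, replace = TRUE)) %% 4L) + 1L
  ref <- nuc[ref_i]
  alt <- nuc[alt_i]

  # triallelic injection: add a second ALT allele and plant one "2" call
  set.seed(substream[3L])
  tri <- which(stats::runif(s) < config$multiallelic_rate)
  if (length(tri)) {
    third_i <- vapply(tri, function(j) {
      setdiff(1:4, c(ref_i[j], alt_i[j]))[sample.int(2L, 1L)]
    }, integer(1))
    alt[tri] <- paste0(alt[tri], ",", nuc[third_i])
    carrier <- sample.int(n_ind, length(tri), replace = TRUE)
    idx <- cbind(tri, carrier)
    gt[idx] <- sub("/.$", "/2", gt[idx])
  }

  # missingness mask
  set.seed(substream[4L])
  if (config$missing_rate > 0) {
    gt[stats::runif(length(gt)) < config$missing_rate] <- "./."
  }

  vcf_path <- paste0(out_prefix, ".vcf")
  popmap_path <- paste0(out_prefix, ".popmap.tsv")
  write_gt_vcf(vcf_path, sim$contig, sim$pos, ref, alt, gt, sample_ids,
               n_chromosomes = config$n_chromosomes,
               chromosome_length_bp = config$chromosome_length_bp)
  writeLines(paste(sample_ids, pops, sep = "\t"), popmap_path)
  invisible(list(vcf = vcf_path, popmap = popmap_path, n_sites = s))
}

# Minimal GT-only VCF v4.2 writer (sites x samples genotype-string matrix).
write_gt_vcf <- function(path, contig, pos, ref, alt, gt, sample_ids,
                         n_chromosomes, chromosome_length_bp) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=strainscan",
    sprintf("##contig=<ID=chr%d,length=%d>", seq_len(n_chromosomes),
            chromosome_length_bp),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  cols <- lapply(seq_len(ncol(gt)), function(j) gt[, j])
  body <- do.call(paste, c(list(contig, pos, ".", ref, alt, ".", "PASS", ".",
                                "GT"), cols, list(sep = "\t")))
  con <- file(path, open = "wb")  # fixed newline convention across platforms
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
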