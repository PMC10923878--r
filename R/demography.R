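#' Demographic model for the two-strain + invasive + outgroup design
#'
#' Constructs and validates the fixed four-population topology used throughout
#' the package: the invasive population branches off the sfC strain, the two
#' strains (sfC + invasive vs sfR) share a more ancient split, and an outgroup
#' lineage roots the tree. Optionally, an instantaneous admixture pulse
#' replaces a fraction of invasive ancestry with sfR ancestry at
#' `admixture_time`.
#'
#' Time is measured in generations before present; sizes are effective
#' *diploid* population sizes.
#'
#' @param pop_sizes Named numeric vector of effective diploid sizes with
#'   entries `sfC`, `sfR`, `invasive`, `outgroup`, `ancestral`. `ancestral`
#'   applies to the strain ancestor and the root.
#' @param split_time_sfC_invasive Generations before present at which the
#'   invasive lineage merges back into sfC.
#' @param split_time_strains Generations at which the (sfC + invasive)
#'   ancestor and sfR merge.
#' @param split_time_outgroup Generations at which the outgroup joins the
#'   root.
#' @param admixture_fraction Proportion in \[0, 1\] of invasive ancestry
#'   replaced by sfR at `admixture_time`; 0 removes the pulse entirely.
#' @param admixture_time Generations of the pulse; must be strictly less than
#'   `split_time_sfC_invasive`.
#' @param invasion_bottleneck_size Optional reduced effective size of the
#'   invasive lineage over its whole existence (founder bottleneck of the
#'   invasion). `NULL` keeps `pop_sizes["invasive"]`.
#' @return An object of class `"demographic_model"`.
#' @seealso [default_faw_model()] for calibrated defaults,
#'   [simulate_cohort()] to generate data under the model.
#' @export
demographic_model <- function(pop_sizes,
                              split_time_sfC_invasive,
                              split_time_strains,
                              split_time_outgroup,
                              admixture_fraction = 0,
                              admixture_time = NULL,
                              invasion_bottleneck_size = NULL) {
  required <- c("sfC", "sfR", "invasive", "outgroup", "ancestral")
  if (!all(required %in% names(pop_sizes))) {
    stop("pop_sizes must be named with: ", paste(required, collapse = ", "))
  }
  if (any(pop_sizes <= 0)) stop("all population sizes must be strictly positive")
  if (length(admixture_fraction) != 1 || is.na(admixture_fraction) ||
      admixture_fraction < 0 || admixture_fraction > 1) {
    stop("admixture_fraction must be a single value in [0, 1]")
  }
  if (admixture_fraction > 0 && is.null(admixture_time)) {
    stop("admixture_time is required when admixture_fraction > 0")
  }
  times <- c(split_time_sfC_invasive, split_time_strains, split_time_outgroup)
  if (any(times <= 0)) stop("all split times must be strictly positive")
  if (!(split_time_sfC_invasive < split_time_strains &&
        split_time_strains < split_time_outgroup)) {
    stop("require split_time_sfC_invasive < split_time_strains < split_time_outgroup")
  }
  if (!is.null(admixture_time)) {
    if (admixture_time <= 0 || admixture_time >= split_time_sfC_invasive) {
      stop("admixture_time must lie in (0, split_time_sfC_invasive)")
    }
  }
  if (!is.null(invasion_bottleneck_size) && invasion_bottleneck_size <= 0) {
    stop("invasion_bottleneck_size must be strictly positive")
  }
  structure(
    list(
      pop_sizes = pop_sizes[required],
      split_time_sfC_invasive = split_time_sfC_invasive,
      split_time_strains = split_time_strains,
      split_time_outgroup = split_time_outgroup,
      admixture_fraction = admixture_fraction,
      admixture_time = if (admixture_fraction > 0) admixture_time else NULL,
      invasion_bottleneck_size = invasion_bottleneck_size
    ),
    class = "demographic_model"
  )
}

#' Default calibrated fall-armyworm-like demographic model
#'
#' Returns the package's reference model of the fall armyworm strain system:
#' topology (((sfC, invasive), sfR), outgroup), with the invasive lineage
#' passing through a founder bottleneck. The split times and sizes are
#' calibrated (see the methods vignette) so that simulated genome-wide
#' Weir-Cockerham F_ST between sfC and sfR falls in the empirically observed
#' regime of roughly 0.1, with the invasive population markedly closer to sfC
#' than to sfR.
#'
#' @param admixture_fraction Proportion of invasive ancestry replaced by sfR
#'   in a single pulse 100 generations ago; 0 (the default) yields a pure-sfC
#'   invasive population.
#' @return A `"demographic_model"`; with `admixture_fraction = 0` the model
#'   contains no admixture event.
#' @examples
#' m <- default_faw_model()
#' m$admixture_time          # NULL: no pulse
#' default_faw_model(0.1)$admixture_time
#' @export
default_faw_model <- function(admixture_fraction = 0) {
  demographic_model(
    pop_sizes = c(sfC = 10000, sfR = 10000, invasive = 10000,
                  outgroup = 10000, ancestral = 10000),
    split_time_sfC_invasive = 300,
    split_time_strains = 2200,
    split_time_outgroup = 60000,
    admixture_fraction = admixture_fraction,
    admixture_time = if (admixture_fraction > 0) 100 else 100,
    invasion_bottleneck_size = 2000
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model: (((sfC, invasive), sfR), outgroup)\n")
  cat(sprintf("  splits (gen): sfC/invasive %g, strains %g, outgroup %g\n",
              x$split_time_sfC_invasive, x$split_time_strains,
              x$split_time_outgroup))
  cat("  diploid Ne:", paste(names(x$pop_sizes), x$pop_sizes,
                             sep = "=", collapse = ", "), "\n")
  if (!is.null(x$invasion_bottleneck_size)) {
    cat(sprintf("  invasive bottleneck Ne: %g\n", x$invasion_bottleneck_size))
  }
  if (x$admixture_fraction > 0) {
    cat(sprintf("  admixture pulse: %.3g of invasive ancestry from sfR at %g gen\n",
                x$admixture_fraction, x$admixture_time))
  } else {
    cat("  admixture pulse: none\n")
  }
  invisible(x)
}

#' Simulation configuration for synthetic cohorts
#'
#' Sampling design and genome layout for [simulate_cohort()]. Defaults mirror
#' the motivating study's design: 44 sfC, 17 sfR and 55 invasive diploids plus
#' a single outgroup individual.
#'
#' Recombination is modelled by partitioning each chromosome into loci that
#' coalesce independently (free recombination between loci, none within).
#' `locus_length_bp` sets that scale directly; alternatively a per-bp
#' `recombination_rate` r maps to a locus length of `1 / (4 * N * r)` (the
#' scale over which roughly one recombination occurs per coalescent time),
#' with N the ancestral size, clamped to \[2 kb, chromosome length\].
#'
#' @param samples_per_pop Named integer vector of diploid sample counts for
#'   `sfC`, `sfR`, `invasive`, `outgroup`.
#' @param n_chromosomes Number of chromosomes (VCF contigs `chr1..chrN`).
#' @param chromosome_length_bp Physical length of each chromosome.
#' @param mutation_rate Per-bp per-generation mutation rate.
#' @param recombination_rate Optional per-bp per-generation recombination
#'   rate; used only to derive `locus_length_bp` when the latter is `NULL`.
#' @param locus_length_bp Length of the independently coalescing loci tiling
#'   each chromosome.
#' @param missing_rate Probability, in \[0, 1), that an individual genotype
#'   call is masked to `./.` in the output VCF.
#' @param multiallelic_rate Probability, in \[0, 1), that a site is converted
#'   to a triallelic record (filter fodder for [filter_sites()]).
#' @param seed Integer seed governing every random draw (coalescent,
#'   mutations, missingness, multiallelism) through deterministic substreams.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(samples_per_pop = c(sfC = 44, sfR = 17,
                                                  invasive = 55, outgroup = 1),
                              n_chromosomes = 5,
                              chromosome_length_bp = 2e7,
                              mutation_rate = 4e-9,
                              recombination_rate = NULL,
                              locus_length_bp = 5e4,
                              missing_rate = 0,
                              multiallelic_rate = 0,
                              seed = 1L) {
  required <- c("sfC", "sfR", "invasive", "outgroup")
  if (!all(required %in% names(samples_per_pop))) {
    stop("samples_per_pop must be named with: ", paste(required, collapse = ", "))
  }
  samples_per_pop <- samples_per_pop[required]
  if (any(samples_per_pop < 0) || sum(samples_per_pop > 0) < 2) {
    stop("samples_per_pop must be non-negative with at least two sampled populations")
  }
  if (n_chromosomes < 1 || chromosome_length_bp < 1) {
    stop("n_chromosomes and chromosome_length_bp must be positive")
  }
  if (mutation_rate <= 0) stop("mutation_rate must be positive")
  for (r in c(missing_rate, multiallelic_rate)) {
    if (r < 0 || r >= 1) stop("missing_rate and multiallelic_rate must lie in [0, 1)")
  }
  if (is.null(locus_length_bp) && is.null(recombination_rate)) {
    stop("supply locus_length_bp or recombination_rate")
  }
  structure(
    list(
      samples_per_pop = setNames(as.integer(samples_per_pop), required),
      n_chromosomes = as.integer(n_chromosomes),
      chromosome_length_bp = as.integer(chromosome_length_bp),
      mutation_rate = mutation_rate,
      recombination_rate = recombination_rate,
      locus_length_bp = locus_length_bp,
      missing_rate = missing_rate,
      multiallelic_rate = multiallelic_rate,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Resolve the independent-locus length for a model/config pair.
resolve_locus_length <- function(model, config) {
  if (!is.null(config$locus_length_bp)) return(as.integer(config$locus_length_bp))
  n_anc <- model$pop_sizes[["ancestral"]]
  len <- round(1 / (4 * n_anc * config$recombination_rate))
  as.integer(min(max(len, 2000), config$chromosome_length_bp))
}
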