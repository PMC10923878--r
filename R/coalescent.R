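# Structured-coalescent engine for the fixed 4-population topology
# (((sfC, invasive), sfR), outgroup). Loci coalesce independently; mutations
# follow an infinite-sites model (each mutation founds a new biallelic site).
#
# Populations are indexed 1=sfC, 2=sfR, 3=invasive, 4=outgroup. All times are
# in generations; coalescence in a population of diploid size N occurs at
# rate choose(k,2)/(2N) for k active lineages.

POP_LEVELS <- c("sfC", "sfR", "invasive", "outgroup")

# Simulate one non-recombining locus: genealogy + Poisson mutations.
# hap_pop: integer population index per sampled haplotype.
# Returns a haplotype matrix (haplotypes x segregating sites), possibly with
# zero columns.
sim_locus <- function(hap_pop, model, mu_locus) {
  n_tips <- length(hap_pop)
  n_nodes <- 2L * n_tips - 1L
  desc <- vector("list", n_nodes)
  desc[seq_len(n_tips)] <- as.list(seq_len(n_tips))
  tb <- numeric(n_nodes)          # birth time of each node
  blen <- numeric(n_nodes)        # branch length above each node
  next_node <- n_tips

  act <- lapply(1:4, function(p) which(hap_pop == p))
  sizes <- c(model$pop_sizes[["sfC"]],
             model$pop_sizes[["sfR"]],
             if (is.null(model$invasion_bottleneck_size))
               model$pop_sizes[["invasive"]] else model$invasion_bottleneck_size,
             model$pop_sizes[["outgroup"]])
  t_now <- 0

  coalesce_until <- function(t_end) {
    repeat {
      k <- lengths(act)
      rates <- k * (k - 1) / (4 * sizes)
      tot <- sum(rates)
      if (tot == 0) {
        t_now <<- t_end
        return(invisible(NULL))
      }
      dt <- stats::rexp(1L, tot)
      if (t_now + dt > t_end) {
        t_now <<- t_end
        return(invisible(NULL))
      }
      t_now <<- t_now + dt
      p <- sample.int(4L, 1L, prob = rates)
      members <- act[[p]]
      pair <- sample.int(length(members), 2L)
      c1 <- members[pair[1L]]
      c2 <- members[pair[2L]]
      next_node <<- next_node + 1L
      blen[c1] <<- t_now - tb[c1]
      blen[c2] <<- t_now - tb[c2]
      tb[next_node] <<- t_now
      desc[[next_node]] <<- c(desc[[c1]], desc[[c2]])
      act[[p]] <<- c(members[-pair], next_node)
    }
  }

  # epoch 1: present back to the admixture pulse (if any)
  if (!is.null(model$admixture_time)) {
    coalesce_until(model$admixture_time)
    inv <- act[[3L]]
    if (length(inv)) {
      mv <- stats::runif(length(inv)) < model$admixture_fraction
      act[[2L]] <- c(act[[2L]], inv[mv])
      act[[3L]] <- inv[!mv]
    }
  }
  # back to the invasive/sfC split
  coalesce_until(model$split_time_sfC_invasive)
  act[[1L]] <- c(act[[1L]], act[[3L]])
  act[[3L]] <- integer(0)
  # back to the strain split
  coalesce_until(model$split_time_strains)
  act[[1L]] <- c(act[[1L]], act[[2L]])
  act[[2L]] <- integer(0)
  sizes[1L] <- model$pop_sizes[["ancestral"]]
  # back to the outgroup split, then to the grand MRCA
  coalesce_until(model$split_time_outgroup)
  act[[1L]] <- c(act[[1L]], act[[4L]])
  act[[4L]] <- integer(0)
  coalesce_until(Inf)

  # mutations: Poisson on every branch below the root
  branch_nodes <- seq_len(n_nodes - 1L)
  nmut <- stats::rpois(length(branch_nodes), mu_locus * blen[branch_nodes])
  carriers <- rep(branch_nodes, nmut)
  s <- length(carriers)
  haps <- matrix(0L, nrow = n_tips, ncol = s)
  if (s > 0) {
    for (j in seq_len(s)) haps[desc[[carriers[j]]], j] <- 1L
  }
  haps
}

# Simulate haplotypes for a whole genome: chromosomes tiled by independent
# loci. Returns list(haps = haplotypes x sites matrix, contig, pos).
sim_genome <- function(model, config) {
  spp <- config$samples_per_pop
  hap_pop <- rep(1:4, times = 2L * spp)
  locus_len <- resolve_locus_length(model, config)
  chrom_len <- config$chromosome_length_bp
  mu_locus <- config$mutation_rate * locus_len

  chrom_mats <- vector("list", config$n_chromosomes)
  contig <- list()
  pos <- list()
  for (chrom in seq_len(config$n_chromosomes)) {
    n_loci <- ceiling(chrom_len / locus_len)
    mats <- vector("list", n_loci)
    pos_c <- vector("list", n_loci)
    for (l in seq_len(n_loci)) {
      start <- (l - 1L) * locus_len
      this_len <- min(locus_len, chrom_len - start)
      m <- sim_locus(hap_pop, model, config$mutation_rate * this_len)
      s <- ncol(m)
      if (s > this_len) {            # infinite sites needs distinct positions
        m <- m[, seq_len(this_len), drop = FALSE]
        s <- this_len
      }
      if (s > 0) {
        m <- m[, sample.int(s), drop = FALSE]  # decouple site order from tree
        pos_c[[l]] <- start + sort(sample.int(this_len, s))
      } else {
        pos_c[[l]] <- integer(0)
      }
      mats[[l]] <- m
    }
    chrom_mats[[chrom]] <- do.call(cbind, mats)
    pos[[chrom]] <- unlist(pos_c)
    contig[[chrom]] <- rep(paste0("chr", chrom), length(pos[[chrom]]))
  }
  list(
    haps = do.call(cbind, chrom_mats),
    contig = unlist(contig),
    pos = unlist(pos),
    hap_pop = hap_pop
  )
}
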