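#' Read a multi-sample VCF and population map
#'
#' Loads every record of a VCF (plain or gzipped) into a genotype-dosage
#' matrix together with its sample-to-population map. No filtering is applied
#' at this stage; use [filter_sites()] for the biallelic/complete-genotype
#' rules. Dosages are alternate-allele counts computed from the GT field
#' regardless of the phasing separator; any genotype containing a missing
#' allele (including half-calls such as `0/.`) is recorded as `NA`.
#'
#' @param vcf_path Path to a VCF v4.2 file.
#' @param popmap_path Path to a two-column TSV `sample_id<TAB>population`,
#'   with populations drawn from `sfC`, `sfR`, `invasive`, `outgroup`.
#' @return A list with components `genotypes` (a `"genotype_matrix"`: integer
#'   samples-by-sites `dosages` matrix, per-site `sites` table, optional
#'   `contig_lengths` from the VCF header) and `popmap` (a
#'   `"population_map"` data frame).
#' @export
read_cohort <- function(vcf_path, popmap_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (!file.exists(popmap_path)) stop("popmap not found: ", popmap_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt_raw)

  pm <- read_popmap(popmap_path)
  missing_in_map <- setdiff(sample_ids, pm$sample)
  missing_in_vcf <- setdiff(pm$sample, sample_ids)
  if (length(missing_in_map) || length(missing_in_vcf)) {
    stop("sample manifest mismatch between VCF and popmap.",
         if (length(missing_in_map))
           paste0(" In VCF but not popmap: ",
                  paste(missing_in_map, collapse = ", "), "."),
         if (length(missing_in_vcf))
           paste0(" In popmap but not VCF: ",
                  paste(missing_in_vcf, collapse = ", "), "."))
  }
  pm <- pm[match(sample_ids, pm$sample), , drop = FALSE]
  rownames(pm) <- NULL

  # GT string -> dosage via a lookup over the (few) distinct genotype strings
  codes <- unique(as.vector(gt_raw))
  dos_of <- vapply(codes, function(s) {
    if (is.na(s)) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }, integer(1))
  dosages <- matrix(dos_of[match(as.vector(gt_raw), codes)],
                    nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  dosages <- t(dosages)                      # samples x sites
  rownames(dosages) <- sample_ids

  sites <- data.frame(
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  by_contig <- split(sites$pos, factor(sites$contig, unique(sites$contig)))
  if (any(vapply(by_contig, is.unsorted, logical(1), strictly = TRUE))) {
    stop("VCF positions must be strictly increasing within each contig")
  }

  contig_lengths <- parse_contig_lengths(vcf@meta)
  g <- structure(
    list(dosages = dosages, sites = sites, contig_lengths = contig_lengths),
    class = "genotype_matrix"
  )
  list(genotypes = g, popmap = pm)
}

read_popmap <- function(path) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (anyDuplicated(pm$sample)) {
    stop("popmap lists duplicated sample ids: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  }
  bad <- setdiff(unique(pm$population), POP_LEVELS)
  if (length(bad)) {
    stop("popmap contains unknown population labels: ",
         paste(bad, collapse = ", "),
         " (expected ", paste(POP_LEVELS, collapse = ", "), ")")
  }
  class(pm) <- c("population_map", "data.frame")
  pm
}

parse_contig_lengths <- function(meta) {
  lines <- grep("^##contig=", meta, value = TRUE)
  if (!length(lines)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", lines)
  lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", lines)))
  stats::setNames(lens, ids)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d sites (%d contigs)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$sites$contig))))
  n_na <- sum(is.na(x$dosages))
  cat(sprintf("  missing calls: %d; multiallelic records: %d\n",
              n_na, sum(grepl(",", x$sites$alt, fixed = TRUE))))
  invisible(x)
}

#' Apply the biallelic / complete-genotype site filters
#'
#' Removes sites that are non-biallelic (more than one ALT allele, or an ALT
#' that is not a single nucleotide) and sites at which any sample's genotype
#' is undetermined — the exclusion rules the downstream statistics assume.
#' Multiallelism is assessed first; a site failing both rules is counted once,
#' under `multiallelic`.
#'
#' @param g A `"genotype_matrix"` from [read_cohort()].
#' @return A list with `genotypes` (the filtered matrix; no `NA` dosages
#'   remain and every site has exactly one ALT allele) and `report` (a
#'   `"filter_report"` with counts `input`, `multiallelic`, `missing`,
#'   `retained`).
#' @export
filter_sites <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  alt <- g$sites$alt
  multi <- grepl(",", alt, fixed = TRUE) | !(alt %in% c("A", "C", "G", "T"))
  has_missing <- colSums(is.na(g$dosages)) > 0
  keep <- !multi & !has_missing
  report <- structure(
    list(input = length(alt),
         multiallelic = sum(multi),
         missing = sum(has_missing & !multi),
         retained = sum(keep)),
    class = "filter_report"
  )
  if (!any(keep)) {
    stop("no sites survive filtering; downstream statistics are undefined")
  }
  g2 <- g
  g2$dosages <- g$dosages[, keep, drop = FALSE]
  g2$sites <- g$sites[keep, , drop = FALSE]
  rownames(g2$sites) <- NULL
  list(genotypes = g2, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Site filter: %d input, %d removed multiallelic, %d removed missing, %d retained\n",
              x$input, x$multiallelic, x$missing, x$retained))
  invisible(x)
}

#' Assign filtered sites to physical or SNV-count windows
#'
#' Physical windows are non-overlapping, anchored at position 1 of each
#' contig, of fixed length `size` (1-based closed intervals
#' `[(k-1)*size + 1, k*size]`; the last window of a contig may be shorter).
#' SNV-count windows each span exactly `size` consecutive retained SNVs with
#' consecutive window starts `step` SNVs apart (sliding; a site may belong to
#' several windows); a trailing run shorter than `size` SNVs is dropped.
#' Windows never span contigs.
#'
#' @param g A filtered `"genotype_matrix"`.
#' @param scheme `"physical"` or `"snv_count"`.
#' @param size Window length in bp (physical) or in SNVs (snv_count).
#' @param step Start-to-start distance in SNVs (snv_count only);
#'   `0 < step <= size`. Ignored for physical windows.
#' @return A `"window_table"` data frame with columns `contig`, `start`,
#'   `end` (physical coordinates), `first_site`, `last_site` (column indices
#'   into the genotype matrix; `NA` for empty physical windows) and
#'   `n_sites`.
#' @export
assign_windows <- function(g, scheme = c("physical", "snv_count"),
                           size, step = size) {
  stopifnot(inherits(g, "genotype_matrix"))
  scheme <- match.arg(scheme)
  if (size <= 0) stop("size must be positive")
  if (scheme == "snv_count" && (step <= 0 || step > size)) {
    stop("snv_count windows require 0 < step <= size")
  }
  contigs <- unique(g$sites$contig)
  pieces <- vector("list", length(contigs))
  offset <- 0L
  for (i in seq_along(contigs)) {
    ctg <- contigs[i]
    pos <- g$sites$pos[g$sites$contig == ctg]
    m <- length(pos)
    if (scheme == "physical") {
      span <- if (!is.null(g$contig_lengths) && ctg %in% names(g$contig_lengths))
        g$contig_lengths[[ctg]] else max(pos)
      n_win <- ceiling(span / size)
      start <- (seq_len(n_win) - 1L) * size + 1L
      end <- pmin(start + size - 1L, span)
      win_of <- (pos - 1L) %/% size + 1L
      n_sites <- tabulate(win_of, nbins = n_win)
      last <- cumsum(n_sites)
      first <- last - n_sites + 1L
      first[n_sites == 0L] <- NA_integer_
      last[n_sites == 0L] <- NA_integer_
      pieces[[i]] <- data.frame(
        contig = ctg, start = start, end = end,
        first_site = offset + first, last_site = offset + last,
        n_sites = n_sites, stringsAsFactors = FALSE
      )
    } else {
      if (m >= size) {
        first_local <- seq(1L, m - size + 1L, by = step)
        last_local <- first_local + size - 1L
        pieces[[i]] <- data.frame(
          contig = ctg,
          start = pos[first_local], end = pos[last_local],
          first_site = offset + first_local, last_site = offset + last_local,
          n_sites = size, stringsAsFactors = FALSE
        )
      } else {
        pieces[[i]] <- data.frame(contig = character(0), start = integer(0),
                                  end = integer(0), first_site = integer(0),
                                  last_site = integer(0), n_sites = integer(0),
                                  stringsAsFactors = FALSE)
      }
    }
    offset <- offset + m
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  attr(out, "size") <- size
  attr(out, "step") <- if (scheme == "snv_count") step else NA_integer_
  class(out) <- c("window_table", "data.frame")
  out
}

# Samples belonging to one population, in genotype-matrix row order.
pop_samples <- function(g, pm, pop) {
  ids <- pm$sample[pm$population == pop]
  ids <- intersect(rownames(g$dosages), ids)
  if (!length(ids)) stop("population has no samples in the cohort: ", pop)
  ids
}
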