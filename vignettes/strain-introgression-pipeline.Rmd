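---
title: "Assigning an invasive population to a source strain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning an invasive population to a source strain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainscan)
```

## The problem

The fall armyworm (*Spodoptera frugiperda*) comprises two sympatric,
morphologically identical host-plant strains — the corn strain (sfC) and the
rice strain (sfR) — that are genomically differentiated at roughly the
F~ST~ ≈ 0.1 level. When such a species invades a new continent, the
management question is which strain invaded, and whether the invasive gene
pool carries introgressed ancestry from the other strain: a pure-sfC
invader poses little risk to rice, a (partial) hybrid does.

A genome-wide answer cannot rest on single markers; mitochondrial COX1 in
particular is misleading in this system because one sfC sub-strain carries
sfR-like mitochondria. strainscan therefore implements the whole-genome
evidence chain used in modern invasion genomics, against the fixed
four-population design

```
(((sfC, invasive), sfR), outgroup)
```

with the invasive population hypothesized to branch from sfC, and an
outgroup (the role a congener such as *S. litura* plays) anchoring the
ancestral allele at each site.

## The statistics

All statistics start from per-population alternate-allele frequencies at
biallelic SNVs with complete genotypes (see *Filtering* below).

**Weir–Cockerham F~ST~.** For two populations we compute the 1984
variance components *a* (among populations), *b* (among individuals) and
*c* (within individuals) per site, and aggregate as a ratio of sums,
`sum(a) / sum(a + b + c)`, per window and genome-wide. Ratio-of-sums is the
windowed estimator of the standard VCF tooling and avoids the rare-variant
bias of averaging per-site ratios. Sites monomorphic in both populations
contribute 0/0 and are skipped; the estimator may be slightly negative near
zero differentiation, which is expected behaviour, not an error.

**The log-ratio scan.** F~ST~ is computed in non-overlapping physical
windows (500 kb by default) between each native strain and the invasive
population, and each window is summarized by
`ln(Fst_sfC-inv / Fst_sfR-inv)`. Under a pure-sfC origin the ratio should
sit below zero essentially everywhere; windows with a positive log ratio
("flagged" windows) are candidate sfR-like loci. Windows where either
F~ST~ is undefined or non-positive cannot enter a log ratio; they are
excluded from it but still counted and reported, so the flagged percentage
is always relative to all windows.

**The randomization null.** Flagged windows are selected for an extreme
contrast, so their F~ST~ excess cannot be judged against a standard
distribution. Instead the pooled native individuals are re-partitioned at
random into two groups of the original sizes (the group of size |sfC|
playing the sfC role, preserving the estimator's sample-size asymmetry),
and the mean over flagged windows of `Fst_sfC-inv − Fst_sfR-inv` is
recomputed per replicate. The one-sided p-value uses the
`(#{null ≥ observed} + 1)/(n + 1)` continuity correction, so p = 0 is
impossible by construction and the smallest attainable p at 1,000
replicates is 1/1001.

**Patterson's f3.** `f3(sfC, sfR; invasive)` is the mean over sites of
`(p_inv − p_sfC)(p_inv − p_sfR)` minus the bias-correction term
`p_inv(1 − p_inv)/(n_chrom − 1)`, with `n_chrom` the number of target
allele copies; the correction removes the sampling variance of the target
frequency and makes each site term unbiased, which is why the target needs
at least two diploids. A significantly *negative* f3 is possible only if
the target is a mixture of the two sources; a significantly positive f3
therefore rejects admixture. The standard error is a weighted delete-one
block jackknife over contiguous physical blocks (5 Mb by default), with
weights proportional to block site counts; `z = f3/SE` and the one-sided
p-value follow.

**ABBA–BABA D.** With populations ordered (P1, P2, P3, P4) =
(sfC, invasive, sfR, outgroup), each site contributes the allele-symmetric
pattern masses
`ABBA = (1−p1) p2 p3 (1−p4) + p1 (1−p2)(1−p3) p4` and
`BABA = p1 (1−p2) p3 (1−p4) + (1−p1) p2 (1−p3) p4`, and
`D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA)`. The second term of each mass counts
the configuration in which the *reference* allele is the derived one, which
makes D invariant to how alleles were labelled at a site — the form the
standard windowed-D tools compute. Incomplete lineage sorting alone
makes the two discordant patterns equally frequent (E[D] = 0); gene flow
from sfR into the invasive population inflates ABBA and drives D positive.
We use population frequencies rather than single sampled alleles, including
for the single-diploid outgroup (whose frequency is then 0, ½ or 1), and we
impose no outgroup polarization: sites where the outgroup is polymorphic
simply contribute fractionally through (1 − p4). Genome-wide D carries a
block-jackknife SE and `Z = D/SE`; the windowed scan computes D in sliding
SNV-count windows (10,000 SNVs, step 1,000 by default, matching windowed-D
practice).

**Per-window D significance.** Each window with D > 0 is tested
one-sidedly with a jackknife SE over contiguous sub-blocks of the window's
own sites. Two calibration details matter here:

* with `n_subblocks` as small as 5–20, `D/SE` is not normal; we use a
  Student-t reference with `n_subblocks − 1` degrees of freedom. The
  normal reference would be anti-conservative and flag spurious windows;
* sliding windows overlap heavily and many are tested, so p-values are
  also reported Bonferroni-adjusted by the number of positive windows
  tested. Bonferroni is conservative under this positive correlation,
  which is the right direction for a claim of "no introgressed locus".

Sub-blocks should be longer than the local linkage scale; with the default
10,000-SNV windows and 20 sub-blocks each sub-block spans hundreds of kb in
typical data.

## The verdict rule

The pipeline's aggregate decision, `build_verdict()`, with defaults
`alpha = 0.05` and `z_threshold = 3`:

* **admixed** if there is positive evidence of gene flow: genome-wide D
  with Z ≥ 3, f3 significantly negative (z ≤ −3), or concordant
  window-level evidence (at least one significantly positive D window
  *and* a flagged-window F~ST~ excess beating the randomization null).
  The concordance requirement keeps a single marginal window, or a single
  marginal randomization p, from flipping the verdict on its own.
* **pure-source-A** if no admixed signal fired and all three pure
  conditions hold: f3 z ≥ 3, randomization p ≥ α (vacuously true when no
  window is flagged at all), and no positive-D window significant after
  adjustment.
* **inconclusive** otherwise, with the failing conditions listed.

## The synthetic cohort generator

No public benchmark provides a VCF with known strain history, so the
package ships a coalescent simulator for exactly this four-population
topology. It is a structured Kingman coalescent: each chromosome is tiled
by loci (50 kb by default) that coalesce independently — free recombination
between loci, none within — and mutations fall on branches as a Poisson
process under an infinite-sites model, so every record is a biallelic SNV.
An optional admixture pulse moves each invasive lineage to sfR with
probability `admixture_fraction` at `admixture_time` (looking backward in
time). Missing calls and triallelic records are injected afterwards at
configurable rates purely as filter fodder for the filtering stage, not as
a mechanistic mutation model.

**Calibrated defaults.** The motivating system gives no published
demographic parameters, so the defaults were calibrated once against the
observed differentiation regime and then frozen: all diploid effective
sizes 10,000; strain split 2,200 generations ago; invasive split from sfC
300 generations ago through a founder bottleneck of size 2,000; outgroup
split 60,000 generations ago; mutation rate 4 × 10⁻⁹ per bp per
generation. Under these values simulated genome-wide F~ST~(sfC, sfR) is
≈ 0.09–0.12 — inside the observed ≈ 0.1 regime — with
F~ST~(invasive, sfC) ≈ 0.04 well below F~ST~(invasive, sfR) ≈ 0.12, the
ordering a pure-sfC invasion forces. These are *scaled* parameters chosen
to reproduce differentiation levels, not an inferred demographic history;
absolute times and sizes should not be interpreted.

**Seeding.** One master seed is split into deterministic substreams for
the coalescent, allele labels, multiallelism and missingness, so a fixed
seed reproduces the VCF and popmap byte for byte.

**What the generator does not emulate.** Continuous migration, selection
(including the host-plant adaptation loci themselves), intra-locus
recombination gradients, mutation-rate heterogeneity, genotyping error
correlated with depth, and the Z chromosome's distinct inheritance. Tests
passing on these cohorts therefore validate the *estimators and the
decision logic* under the designed history — they do not certify the
pipeline against every artefact of real resequencing data.

## Numerical choices and degenerate inputs

* Windows are 1-based closed intervals anchored at position 1 of each
  contig (window *k* covers `[(k−1)·size + 1, k·size]`), the convention of
  the common windowed-F~ST~ tools; SNV-count windows drop a trailing run
  shorter than the window size.
* Half-calls (`0/.`) count as undetermined, and the outgroup sample is
  subject to the complete-genotype filter like every other sample — the
  filter is "undetermined in any sample", read strictly. A site failing
  both filters is counted once, under multiallelic (filters apply in that
  order).
* A window with `ΣABBA + ΣBABA = 0` or with a zero F~ST~ denominator is
  flagged undefined and excluded from scans but never silently dropped
  from counts.
* The jackknife requires at least two informative blocks; fewer is an
  error, not a silent NA. Jackknife weights are informative-site counts.
* F~ST~, f3 and D all refuse matrices containing missing dosages rather
  than guessing an imputation; `filter_sites()` is the supported path.

## Problem sizes used by the shipped tests

The test suite and acceptance script scale the study design down so the
whole pipeline runs comfortably on one CPU: cohorts of 16/10/16/1 diploids
(sfC/sfR/invasive/outgroup) on five to eight 10-Mb chromosomes (25-kb
loci), giving roughly 5–12 × 10⁴ SNVs per cohort, with 2.5-Mb jackknife
blocks, 8,000-SNV disjoint D windows with 5 sub-blocks (each sub-block
spanning several coalescent loci, which the t-referenced window test
requires), and 200–1,000
randomization replicates; micro-fixtures (tens of sites, built in code)
cover the exact-arithmetic cases. The verdict-recovery check runs ten
no-admixture and ten 20%-pulse cohorts end to end. The full 44/17/55/1
design on 5 × 20 Mb (~1.7 × 10⁵ SNVs) remains the generator's default and
runs in well under a minute.

## Known limitations

* The windowed-D significance machinery (t reference, Bonferroni over
  positive windows) is deliberately conservative; it trades power at
  single introgressed loci for robustness of the genome-wide verdict.
* f3 against a strongly bottlenecked target can stay positive even under
  substantial admixture (drift in the target inflates f3); this is a known
  property of the statistic, and it is why the verdict rule lets D-based
  evidence override a positive f3.
* The randomization null regroups native individuals only; it does not
  model spatial structure within strains.
* The physical-window anchor (position 1 versus first variant) changes
  window counts slightly on real assemblies; the package fixes the
  position-1 convention.
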