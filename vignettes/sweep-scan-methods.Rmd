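---
title: "Detecting selective sweeps in structured populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps in structured populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

A selective sweep — positive selection driving an allele toward fixation —
leaves two complementary footprints in resequencing data: locally *reduced
nucleotide diversity* in the selected population, and locally *elevated
differentiation* between the selected population and its relatives.
`sweepscan` implements the sliding-window scan that exploits both signals
jointly: a focal population is compared against a high-diversity,
low-selection *reference* population, and genomic windows that fall in the
upper tail of **both** the window F~ST~ distribution and the
π ln-ratio distribution are called candidate sweep regions. Requiring the
intersection of two independent statistics trades a little sensitivity for
a substantial reduction in false positives from drift, and is standard
practice in livestock and insect population genomics.

The package also covers the surrounding analyses such a study needs:
per-population diversity reports (Ho, He, PIC), pairwise F~ST~ matrices,
LD decay curves, and one-way ANOVA with compact significance letters
reconstructed from published summary tables.

## Statistics

### Window F~ST~

The estimator is the Weir–Cockerham (1984) variance-component θ for two
populations of diploids. At each biallelic site, the method decomposes
allele-frequency variance into among-population (*a*),
among-individual-within-population (*b*) and within-individual (*c*)
components from the diploid sample sizes, alt-allele frequencies and
observed heterozygosity of the two populations. A window's F~ST~ is the
"ratio of sums",

$$\hat\theta_W \;=\; \frac{\sum_{s \in W} a_s}{\sum_{s \in W} (a_s+b_s+c_s)},$$

not the mean of per-site ratios — the ratio-of-sums form is less biased at
low-information sites and is the conventional windowed combination. Small
negative values are legitimate near θ = 0 and are reported as computed; a
`hudson` estimator (Bhatia et al. 2013 form) is available as an
independent cross-check (`estimator = "hudson"`), and the two agree to
window correlation > 0.99 on Balding–Nichols simulations.

### Window π and the ln-ratio

Per-site nucleotide diversity is the unbiased mean pairwise difference
among the $2n$ called haplotypes, $\frac{2n}{2n-1}\,2\hat p(1-\hat p)$;
window π is the sum of site values divided by the window length in bp, so
truncated tail windows are normalised by their true length. The scan score
is

$$\ln\!\left(\frac{\pi_\text{reference}}{\pi_\text{focal}}\right),$$

oriented so that diversity *loss* in the scanned population gives positive
scores and only the upper tail need be examined. The ratio is undefined
(masked) when either π is zero in a window.

### Selection rule

Thresholds are the empirical 95th percentiles (type-7 quantiles) of each
statistic over unmasked windows; a window is selected iff it reaches both,
with ties at a threshold included. Merging overlapping or bookended
selected windows into maximal regions is the default (`merge = FALSE`
reports raw windows); genes are attached to regions by ≥ 1 bp interval
overlap on 1-based inclusive coordinates.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_size` | 100,000 | bp | resolves sweep-scale haplotypes while keeping hundreds of SNPs per window at ~1 SNP/100 bp density |
| `step` | 10,000 | bp | 10× overlap smooths the scan and refines region edges |
| `q` | 0.95 | — | "top 5%" empirical tail per statistic, intersected |
| `min_snps` | 10 | SNPs | windows below this are masked: both statistics are unstable on a handful of sites; masked windows are excluded from quantile estimation |
| `max_missing` | 0.20 | fraction | site kept iff missing fraction **<** 0.20 (strict) |
| `min_maf` | 0.05 | fraction | site kept iff pooled MAF **>** 0.05 (strict); removes monomorphic and near-private variants before any per-population statistic |

Both filters are applied to the pooled sample set once, before any
per-population analysis, which matches the usual filter-then-analyse
order. Sites unusable in a particular population (< 2 called diploids)
are dropped from that population's means only, never globally.

The quantile is computed per statistic over **all** windows genome-wide,
not per contig; with strong heterogeneity in SNP density across contigs a
per-contig threshold could be argued, but a global tail is reproducible
and matches how "top 5%" is conventionally read. PIC uses the biallelic
closed form of Botstein's expression, $1-(p^2+q^2)-2p^2q^2$, whose maximum
0.375 occurs at $p=0.5$.

## The synthetic-population generator

Real resequencing studies cannot be re-run at desk scale, so the package
ships a generator (`simulate_population()`) whose defaults *are* the
benchmark design point used throughout the test suite:

* one 2-Mb contig carrying 20,000 SNPs (≈ 1 per 100 bp, a realistic
  post-filter density for a small insect genome);
* a reference and a focal population of 20 diploids each — the per-site
  ancestral frequency is drawn Uniform(0.05, 0.95) and each population's
  frequency from the Balding–Nichols law
  Beta$(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ with background $F = 0.05$,
  so the expected pairwise F~ST~ is known in closed form and genotypes are
  Binomial(2, p) draws;
* 2% uniformly random missing calls;
* three planted 100-kb sweeps in the focal population, inside which the
  focal allele frequency is replaced by a draw within ε = 0.02 of whichever
  of 0/1 is nearer — erasing focal diversity and inflating differentiation,
  exactly the signature the scan targets;
* deterministically tiled 5-kb genes every 20 kb, giving a known truth
  gene set.

Monomorphic realized sites are deliberately retained in the output so the
MAF filter path is exercised. The same seed always yields byte-identical
VCF output.

What the generator does **not** emulate: linkage (sites are exchangeable
given their frequencies), demography (bottlenecks, migration,
recombination maps) and haploid drone genetics. Passing the recovery
benchmark therefore demonstrates that the estimator chain and the
selection rule are correct and calibrated, not that the scan is powerful
under every realistic demography. LD-decay analyses use a separate
haplotype *copying-chain* generator (`simulate_ld_genotypes()`): alleles
are copied from the previous site and redrawn with probability
$1-e^{-d/L}$, giving haplotype correlation $\approx e^{-d/L}$ with a
tunable correlation length $L$, which is what the r² decay curve and its
half-decay distance summarise. A population under stronger drift/selection
is emulated by a different $L$ than the reference; the test suite asserts
only that the half-decay *ranking* matches the generator's parameter
ranking.

## LD

r² is the squared Pearson correlation of alt-allele dosages over jointly
called samples (composite, Rogers–Huff-style LD). The genotypes are
unphased, so haplotype-level r² is not computable without phasing;
composite LD is the standard phase-free surrogate and is monotonically
related to it under Hardy–Weinberg proportions. Pairs monomorphic among
the jointly called samples are skipped and counted. Pair enumeration is
capped at `max_dist` (default 100 kb), keeping cost linear in sites times
neighbourhood rather than quadratic; the half-decay distance is read off
the binned curve with linear interpolation, and reported as `Inf` when the
curve never reaches half of its maximum bin mean within range.

## Morphometrics from printed summaries

Raw measurements are rarely published; a summary table of means ± SEM and
n per group is. `anova_oneway_summary()` reconstructs the exact one-way
ANOVA F (SD = SEM·√n), and `pairwise_letters()` assigns compact letters
from pairwise Welch t-tests: groups are ordered by descending mean and
letters are maximal runs of mutually non-significant neighbours. No
multiplicity correction is applied — the choice a three-group
"different letters at the 0.01 level" table is ordinarily read with — and
the ± column is taken as SEM (`pm_is_sd = TRUE` converts if a table
prints SD). A bundled table of published *Apis cerana* worker body-size
summaries (10 indicators, three populations, µm) exercises this module;
with it, 29 of the 30 pairwise contrasts separate at α = 0.01 and the
single exception (basitarsus width, between the two southern populations)
is non-significant even at α = 0.05.

## Numerical and degenerate-input choices

* Internal coordinates are 1-based inclusive everywhere; the only
  conversion to 0-based half-open happens when writing BED.
* Half-called genotypes (`0/.`) are missing, not imputed; `/` and `|` are
  equivalent since all statistics work on dosages.
* Windows with zero F~ST~ denominator are masked, not zero.
* Fewer than 20 unmasked windows is an error: a 95th percentile over fewer
  values is noise.
* `merge_regions()` is idempotent; bookended windows merge, bookended
  gene/region pairs do **not** overlap (≥ 1 shared bp required).
* With no called regions, recovery precision is undefined and reported as
  0 with a warning rather than NA, so benchmark summaries stay numeric.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
20,000-site fixtures for calibration and recovery, 5,000-site fixtures for
null checks, and a few hundred sites for LD and I/O round trips — sizes
chosen so the whole suite completes in well under a minute while leaving
Monte-Carlo error comfortably inside the asserted tolerances (e.g.
genome-wide F~ST~ at F = 0.2 lands within ±0.03, and bp-level recall of
the three planted sweeps is ≥ 0.8 with precision ≥ 0.5 at the benchmark
seed).

## Known limitations

* Two-population F~ST~ only; the multi-population θ generalisation is not
  implemented (the pairwise matrix covers the usual reporting need).
* No haplotype-based statistics (iHS, XP-EHH) or composite-likelihood
  methods; the scan is the F~ST~ × π ln-ratio intersection only.
* The simulator's lack of linkage means window statistics on simulated
  data are less autocorrelated than on real genomes; merged-region counts
  on real data will differ in character from the benchmark.
* Significance letters from summary statistics inherit whatever rounding
  the published table applied.
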