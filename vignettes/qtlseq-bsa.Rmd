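---
title: "Bulked-segregant QTL-seq: model, null band and filter cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant QTL-seq: model, null band and filter cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The method in one paragraph

Bulked-segregant analysis by whole-genome sequencing (QTL-seq) maps a
quantitative trait by sequencing two pools of phenotypically extreme
individuals from a segregating cross. At every biallelic site polarised
against the parents, each pool's **SNP-index** is the fraction of its reads
carrying the allele that differs from a designated reference parent — 0 if
the pool looks like that parent, 1 if it is completely different. The
contrast **Δ(SNP-index) = index(late pool) − index(early pool)** is near
zero at unlinked loci and departs from zero near a locus that the phenotypic
selection has driven toward opposite alleles in the two pools. Windowed
averages of Δ are compared against a simulation-based null band; runs of
windows escaping the band are called as QTL intervals, intersected with
intervals from independent experiments, and the consensus region is mined
for candidate genes by a cascade of variant-level filters.

`bsaqtl` implements this chain end to end for an F2 design, together with a
fully parameterised synthetic-cross generator used to validate every stage.

## The statistic

At a polarised site with pool read depths $(r, a)$ (reference-parent and
alternate alleles), the SNP-index is $a / (r + a)$, reported as missing when
$r + a$ falls below `min_depth` (default 7, common practice for pooled
data; configurable everywhere it appears). Polarisation
(`polarize_sites()`) keeps only sites where the two parents are opposite
homozygotes — the informative configuration in an F2 — and re-labels
alleles so "alternate" always means the allele of the late, sensitive
parent (P2). Sites with heterozygous, missing or concordant parent calls
are returned with a reason code rather than silently dropped.

The SNP-index is kept continuous rather than thresholded at its 0/1
anchors: windows averaged over near-fixed indicator values would be
degenerate, and the continuous ratio is the quantity whose expectation
reflects the pool allele frequency. For the same reason no near-fixation
pre-filter is applied before windowing.

Windows are `window_bp` = 1 Mb wide and advance by `step_bp` = 1 kb along
each chromosome, half-open $[s, s + W)$ internally with 1-based input
positions and 1-based inclusive reported intervals. Windows with fewer than
`min_sites` = 3 informative sites are reported missing (not zero) so a
single SNP cannot fabricate a peak.

## The null band

The no-QTL null is explicit: each pool of $b$ plants has allele frequency
equal to the mean of $b$ independent F2 genotype doses (0, ½, 1 with
probability ¼, ½, ¼), and the observed alternate depth at a site is
Binomial(observed total depth, pool frequency). The band is the two-sided
`level`% (default 95%, 1000 replicates) quantile of the simulated window
statistic. Three constructions are exposed by `add_null_band()`:

* **`"linkage"` (default).** A parametric bootstrap of the whole process:
  the pooled P2-gamete count ($2b$ gametes per pool) is simulated as a
  Markov chain along the chromosome, flipping between parental origins
  with the Haldane recombination fraction implied by the inter-site
  distance and the map scale `bp_per_cm`. Read depths are then re-sampled
  per member site. Because this reproduces both the bulk-sampling variance
  and its decay across the window, the per-window false-positive rate
  matches the nominal level (measured 4–5% at the reference design in the
  acceptance suite).
* **`"window"`.** One frequency draw per pool shared across the window —
  the limit of perfect within-window linkage. Needs no map scale; slightly
  conservative (about half the nominal exceedance in our calibration
  experiments).
* **`"site"`.** The construction common in the QTL-seq literature:
  per-site bands averaged over window members. We implement it for
  comparability but do not default to it: averaging member-site quantiles
  leaves the band at single-site width while read noise in the window
  *mean* shrinks with the number of member sites, so the band is markedly
  conservative at the window level (well under 1% exceedance at 30×
  depth). This is the one place where we deliberately depart from the
  common construction, and the choice is exposed rather than hidden.

QTL calling (`call_qtls()`) reports maximal runs of at least `min_run` = 10
consecutive windows outside the band (10 kb of support at the default
step), with sign +1 when the late pool is enriched for the P2 allele; runs
of equal sign separated only by short missing gaps are merged. Intervals
from independent experiments are intersected in Mb coordinates
(`intersect_intervals()`): the consensus is $[\max(\text{starts}),
\min(\text{ends})]$ when all experiments share a chromosome and overlap.
Genetic-map (cM) intervals from linkage studies must be supplied already
converted to physical coordinates; the package does not interpolate maps.

## The candidate cascade

`candidate_cascade()` reproduces the funnel used to nominate a causal gene
inside a consensus region, recording site and gene counts after every
stage:

1. **Δ threshold** — per-site Δ strictly greater than 0.7. The strict
   inequality matches the printed form of the filter; the threshold is a
   parameter. The filter is applied to per-site values (window-averaged
   input can be supplied instead by passing a window-aggregated site
   table).
2. **Effect annotation** — `annotate_effect()` translates the reference
   and mutated codon under the standard genetic code
   (`Biostrings::GENETIC_CODE`), reverse-complementing genomic alleles for
   minus-strand genes, and keeps non-synonymous changes (amino-acid
   replacements and stop gains/losses). Only single-nucleotide variants
   are handled; the candidate logic operates on non-synonymous SNVs.
3. **Region** — genes overlapping the consensus interval, any-overlap
   semantics with inclusive endpoints (the inclusive choice; containment
   would silently drop boundary-straddling genes).
4. **Allele pattern** — sites where every photoperiod-insensitive
   (north + south) accession matches the reference genome and all three
   sensitive (XIS) accessions share the same non-reference allele.
   Heterozygous calls count as non-matching: the panel accessions are
   inbred, so residual heterozygosity is more plausibly a call artefact
   than a genotype. Missing data fail by default (a candidate site must be
   fully observed); `missing_policy = "ignore"` relaxes this.
5. **Annotation keyword (optional)** — the final pick among pattern genes
   is a curator's functional judgement, not an algorithm; the cascade
   reproduces it only when an annotation table and keyword are supplied,
   and reports it as its own audited stage.

## The synthetic cross

`simulate_f2()` generates the data structure all of the above assumes.
Each individual receives two independent recombinant gametes; crossovers
are Poisson in map length with the Haldane map function and no
interference, on a uniform physical-to-genetic scale (`bp_per_cm`, default
250 kb/cM — cucumber-like; no finer map is assumed). The phenotype is

$$\text{DFF} = \text{baseline} + \text{effect} \cdot h(g) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

where $g$ is the P2-allele dose at the causal locus and $h$ interpolates
between additive ($h(1) = \tfrac12$ at `dominance = 0`) and complete
dominance of the early P1 allele ($h(1) = 0$ at the default
`dominance = 1`, reflecting the observation that F1 plants of such crosses
flower with the early parent). Defaults describe the reference design the
package is validated against: 234 F2 plants, tail bulks of 17, baseline 80
days (the short-day value of the sensitive accession), effect 20 days,
noise 2 days, mean pooled depth 30×. Bulk selection is deterministic —
ties break by ascending individual index — and both tail and day-threshold
selection (early pool within a day range, late pool beyond a cutoff) are
supported. Pooled sequencing draws per-site Poisson depths and binomial
alternate counts; a fixed-depth mode supports exact enumeration tests.

What the generator deliberately omits: sequencing error, indels and
multi-allelic sites, crossover interference, epistasis, segregation
distortion, and read-level artefacts (mapping bias, duplicates). Passing
tests therefore demonstrate correctness of the statistical chain under its
own assumptions, not robustness to real-data artefacts; on real data the
polarisation step and the `min_depth` filter carry that burden.

`simulate_variety_panel()` and `simulate_cds_with_variants()` plant
exactly recoverable truths for the pattern and annotation filters, and
`simulate_candidate_truth()` assembles a whole planted funnel (by default
298 sites in 150 genes above the Δ threshold, 15 in the region, 4 matching
the pattern, 1 with the target functional annotation, plus decoy genes
that fail each earlier stage).

## Numerical choices

* Quantiles use R's default type-7 estimator on the simulated replicates;
  with 1000 replicates the 2.5%/97.5% points carry a Monte-Carlo error of
  roughly ±0.01 on the band edge, which is why calibration checks use a
  ±2-percentage-point tolerance.
* Zero-depth sites get the uninformative band (−1, 1); sites below
  `min_depth` are missing and excluded from both the window mean and its
  band.
* Window means are computed with cumulative sums over position-sorted
  sites and verified exactly against naive summation in the test suite.
* Seeds: every stochastic function accepts a `seed` and restores the
  caller's RNG state (`withr::with_seed`); the pipeline derives one child
  seed per stage from the configured master seed.

## Validation problem sizes

The acceptance suite runs the chain at the reference design (234 plants,
bulks of 17, 30× depth, 1000 replicates, 95% level). Null-band calibration
uses 1000 independent causal-free chromosomes of 10 Mb with ten
non-overlapping 1 Mb windows each (10,000 windows); windows on one
chromosome remain linked, so independence comes from separate chromosomes.
Causal-locus recovery uses 50 independent crosses with a 20-day effect and
2-day noise on a 10 Mb chromosome with 1000 sites and a 10 kb scan step —
1000 windows per genome keeps the experiment comfortably fast while
leaving the 1 Mb window untouched. Oracle equivalence covers 1000 random
CDS fixtures and the complete $4^9$ single-site panel assignment space.

## Known limitations

* F2 bulks only: RIL, backcross or other designs change the null genotype
  distribution and are not modelled.
* The linkage-aware null requires a physical-to-genetic map scale; where
  none is defensible, the `"window"` method is the safe conservative
  choice.
* Expression utilities are deliberately minimal (RPKM, threshold flags on
  supplied differential-expression results with BH adjustment when no FDR
  is given, 2^−ΔΔCT): the differential-expression model itself is expected
  to come from a dedicated tool, and only its outputs enter this package.
* Candidate annotation handles SNVs in spliced CDS coordinates; splice
  mapping from genomic coordinates is the caller's responsibility.
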