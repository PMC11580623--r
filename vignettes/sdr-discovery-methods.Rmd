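---
title: "Methods: mapping a sex-determining region from resequencing cohorts"
author: "sdrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a sex-determining region from resequencing cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscan)
```

## The problem

Many fishes carry genetically determined sex on a chromosome pair that is
morphologically undifferentiated: recombination is suppressed only over a
small sex-determining region (SDR), sometimes just tens of kilobases. Given
whole-genome resequencing of a cohort of phenotypically sexed individuals,
the SDR leaves three complementary footprints:

1. **Sex-linked SNPs.** At a site fully linked to the sex-determining
   locus, every individual of the heterogametic sex (ZW females, or XY
   males) is heterozygous, while the homogametic sex is homozygous for a
   single allele.
2. **A hemizygous insertion.** Sequence present only on the W (or Y)
   appears at half the individual's genome-wide depth in the heterogametic
   sex and at near-zero depth in the other sex.
3. **Paralog length polymorphism.** A hemizygous stretch with a diploid
   paralog of different length yields a sex-diagnostic PCR band pattern
   from a single shared primer pair.

`sdrscan` implements the complete chain — genotype QC, sex-association
statistics, sex-specific SNP detection, coverage scanning, SDR assembly,
annotation, and marker design — together with a seeded synthetic-cohort
generator so that every stage is testable against planted ground truth.

## Genotype quality control

Calls are masked (set missing) when `GQ < 20` or `DP < 7`; sites are then
retained only if biallelic, `QUAL >= 30`, called in at least 90% of
individuals overall and in at least 12 individuals of each sex, and with a
global minor-allele frequency of at least 0.05 — or a within-sex MAF of at
least 0.20 in either sex, a rescue designed for alleles segregating in only
one sex. All thresholds are inclusive and configurable via
`filter_config()`. Masking acts per call rather than per site because the
depth/quality criteria are defined per individual; the call-rate criteria
therefore see post-masking counts (the cascade interpretation). MAF uses
allele counts of called genotypes only. Multi-allelic records are dropped,
not split.

Two arithmetic corollaries are worth knowing. With 24 + 20 individuals, a
90% call rate permits at most four missing calls, so the per-sex >= 12
clause cannot be the binding criterion; and the global MAF of a balanced
cohort is bounded below by roughly half the larger within-sex MAF, so the
local-MAF rescue only matters when called counts are strongly unbalanced.
Both clauses are implemented and tested as specified; they exist for the
general case, not for the balanced default.

## Sex association

For each site the alleles of called genotypes form a 2x2 table by sex.

* **Fisher's exact test**, two-sided by the minimum-likelihood rule: the
  p-value sums hypergeometric probabilities of all tables (at the observed
  margins) whose point probability does not exceed the observed one, with
  the conventional `1 + 1e-7` relative guard against floating-point ties.
* **Allele-frequency LRT**: `G = 2[l(p_F, p_M) - l(p_pooled)]` on binomial
  likelihoods of the allele counts, referred to chi-square with 1 df. This
  is the package's count-based stand-in for genotype-likelihood
  allele-frequency tests: the null (a shared allele frequency) is the same,
  but no genotype-likelihood fields are required and the statistic is
  desk-verifiable against a direct likelihood maximisation. `G` below
  `1e-10` is snapped to zero so exactly equal frequencies report `p = 1`.
* **BH-FDR**: standard step-up adjustment (`stats::p.adjust`), plus
  `fdr_threshold()`, the largest raw p-value whose q-value stays below the
  chosen level — the "significance line" of a Manhattan plot. It is always
  an element of the input, and data-dependent by construction.
* **Weir–Cockerham F_ST** (1984 two-population estimator): per-site
  variance components `a` (between sexes), `b` (between individuals), `c`
  (within individuals), with `fst = a/(a+b+c)`. Negative estimates are
  reported as-is, and the genome summary is the ratio of summed components
  — not the mean of ratios — which is why an undifferentiated genome can
  report a slightly negative value. A fully sex-linked site with 24
  heterozygous females and 20 fixed males evaluates to `a = 0.125`,
  `b = -3/22`, `c = 3/11`, `fst = 0.4783`.

## Sex-specific SNPs and system classification

A site is sex-specific for a focal sex when that sex shows at least
`min_het_count` heterozygotes with observed heterozygosity (het/called) of
at least `min_ho = 0.75`, while the other sex has **zero** heterozygotes
and all of its called genotypes are the same homozygote. The default count
floor of 18 is the value implied by 24 focal-sex individuals at the 0.75
floor; `derive_min_het(n, min_ho) = ceiling(min_ho * n)` generalises it to
other cohort sizes (used when `min_het_count = NULL`), since a fixed 18
would be unattainable tight or overly lax at other `n`. The tolerance for
miscalls lives entirely in the Ho floor: requiring literal 100%
heterozygosity would discard real sex-linked sites lost to allele dropout.

Heterozygosity excess in one sex cannot by itself distinguish ZW from XY
(all-female heterozygosity is also consistent with an XY reading of
segregating variation). `classify_system()` therefore labels the system
only with coverage corroboration: either depth at the hit sites comparable
between sexes (the hits then sit on sequence both sexes carry) or a
co-located sex-limited hemizygous region. Without corroboration the label
is *provisional*; discordant focal sexes above 10% or contradictory
coverage yield *ambiguous*.

Supporting statistics: per-hit and pooled depth by sex with a Welch test
per hit (a hit with no depth data is flagged, not dropped), and pairwise LD
as the squared Pearson correlation of genotype dosage (0/1/2) over samples
called at both sites — the genotype-r² convention appropriate for unphased
data; pairs sharing fewer than four called samples are undefined.

## Coverage scan for hemizygous regions

Per position, depths of the two sexes are compared with Welch's
unequal-variance t-test (Satterthwaite df). A position is a candidate for,
say, a female-limited region when `p < 1e-4`, the female depth ratio to
each individual's *own* genome-wide mean averages within `[0.35, 0.65]`
("approximately half", made robust to the 20–41X between-individual depth
range by normalising per individual before averaging), and mean male depth
is at most 2X. The absence bound is what separates hemizygosity from a
shared copy-number difference: a locus where males still run at 10X is
significant and half-depth in females, yet not sex-limited. The two
degenerate constant-depth cases are defined explicitly (equal constants
give `p = 1`; different constants give `p = 0`, flagged).

Candidate positions merge into regions when gaps do not exceed
`merge_gap = 200` bp, and regions shorter than `min_region_len = 1000` bp
are dropped. Both values are explicit guesses exposed as parameters — the
merging rule behind published region coordinates is rarely stated — chosen
so that isolated false positives at the 1e-4 level (about one per 10,000
positions scanned) can never form a reportable region, while a true
multi-kilobase region tolerates occasional candidate dropout. All
coordinates are 1-based fully closed (`length = end - start + 1`), matching
how such positions are printed; BED output converts to 0-based half-open at
the boundary.

## SDR assembly and annotation

Sex-specific SNPs within `snp_cluster_gap = 10` kb of each other share a
cluster; each cluster is flanked by 5 kb on both sides (clipped to the
chromosome), and flanked clusters that come to overlap merge — flanks are
annotation, not evidence. The SDR spans from the first to the last
sex-linked region and absorbs hemizygous regions lying between (or
overlapping) them; hemizygous regions outside the span are listed
separately. Kb figures round half-away-from-zero to one decimal for
components and to an integer for the SDR headline. Repeat content is the
length of the union of repeat intervals clipped to the region, divided by
region length.

Variant annotation applies within-transcript precedence CDS > UTR >
intron; variants outside all transcripts are upstream/downstream when
within 5 kb of a gene span (measured from the span boundary, not the TSS,
and resolved by strand), else intergenic. Overlapping genes resolve to the
highest-precedence category, ties to the smallest gene id (deterministic).
Single-base CDS substitutions are translated on the coding strand with the
standard genetic code into synonymous/missense/nonsense; indels receive
positional categories only. Exonic positions outside both CDS and
annotated UTRs are assigned the nearest UTR side with a warning. Per-exon
identity between transcripts pairs exons by order from the 3' end (the
conserved end of degenerating paralogs) and reports matches over alignment
columns of a global alignment, averaged **unweighted** across pairs — the
aggregation used by published averages is typically unstated, so the
simplest convention is taken and declared.

## Marker design

`paralog_scan()` is a self-contained seed-and-extend homology search:
exact 15-mer seeds, chained per diagonal band (breaks at subject jumps
beyond the query length or diagonal shifts above 200 bp), each chain
extended by a local affine-gap aligner written in C++ (match +1, mismatch
-2, gap open -5, gap extend -2; a length-L gap costs `5 + 2L`, the same
convention as `Biostrings::pairwiseAlignment`, which serves as the
independent dynamic-programming oracle in the tests). Hits under 80%
identity or 200 aligned bases are dropped, as is the query's own locus.
`select_marker_locus()` keeps pairs with exactly one copy inside a
sex-limited region and a length difference of at least 20 bp — smaller
differences do not resolve on an agarose gel — and reports gap-free,
100%-identity alignment windows of at least 20 bp as shared primer sites.

`in_silico_pcr()` matches the forward primer and the reverse complement of
the reverse primer on the plus strand (and the mirror orientation); the
product is the inclusive span between the two primers' outer 5' ends, so a
97 bp internal deletion shortens the product by exactly 97 bp. Matching is
exact by default; if mismatches are allowed, a 3'-terminal mismatch is
still disallowed because it abolishes extension. `band_pattern()` converts
amplicons to per-sex band multisets via copy number (haploid region: 1 in
the carrying sex, 0 in the other; elsewhere 2/2) and annotates 1-copy bands
as reduced dosage — the fainter gel band that betrays a haploid template.

## The synthetic cohort

`simulate_cohort()` generates the complete study from a seeded
`cohort_config()`: by default 24 females and 20 males (ZW; XY mirrors by
swapping sex roles in one code path), a 1 Mb autosome carrying 10,000 HWE
SNPs with minor-allele frequencies uniform on [0.05, 0.5] (a free choice —
no claim about real site-frequency spectra), and a 300 kb sex chromosome
carrying two fully sex-linked segments (46 planted SNPs by default, with
segment endpoints always occupied so the planted span is deterministic), a
21,326 bp hemizygous insertion between them, and a 590 bp stretch of that
insertion duplicated elsewhere on the chromosome with three planted
insertions of 40 + 30 + 27 = 97 bp. The reference represents the
heterogametic individual's assembly, so it contains the hemizygous
insertion; no VCF records are emitted inside it (a haploid region has no
biallelic diploid genotypes — it is found by coverage, not SNPs).

Depth is negative-binomial around each individual's mean (drawn uniformly
from 20–41X; dispersion parameter 8) — overdispersion a Poisson would
understate — at 0.5x the own mean for carrier-sex individuals inside the
hemizygous interval and a 0.3X mismapping background for the other sex.
The depth matrix covers a genome-wide grid (50 bp steps on the sex
chromosome, 200 bp elsewhere) plus every sex-chromosome SNP position, so
boundary resolution of recovered regions is limited by the grid step,
comfortably inside the 200 bp merge tolerance.

Genotype errors follow a two-component quality model: a fraction `2e` of
calls carry a Uniform(0,1) latent miscall probability, the rest are
near-certain, so the mean miscall rate is exactly the configured `e` (0.5%
by default) while GQ — the Phred transform of the latent probability,
clipped to [3, 99] — marks the error-enriched calls, as in real variant
calling. At the default rate this leaves roughly 1% of calls below GQ 20,
in line with high-coverage short-read callsets; only the calibration of
the filter thresholds matters here, not likelihood realism. Site QUAL
grows with total depth (floor 30). Missingness is independent at 2%.

What the generator does **not** emulate: read-level data (depth is drawn
directly, so mapping artefacts, GC bias and mappability structure are
absent), recombination and LD decay on autosomes, population structure
between sampling sites, indels outside the planted paralog gaps, and
partial sex-linkage (planted sites are fully penetrant). Consequently the
observed heterozygosity and LD of detected sex-specific SNPs sit at or
near their ceilings in synthetic data, whereas real cohorts show values
somewhat below 1; passing recovery tests demonstrates correctness of the
detection chain under the stated noise model, not robustness to
misalignment or reference bias.

## Problem sizes and numerical choices

The default validation runs use ten replicate cohorts of 44 individuals
with 10,000 autosomal and 20 planted sex-linked SNPs, and roughly 11,000
depth positions — sizes chosen so a full replicate simulates and analyses
in about two seconds while keeping Monte-Carlo error on recovery rates
small. Fisher p-values agree with enumeration to near machine precision;
alignment scores are integers under the chosen scoring, compared exactly;
Welch tests are evaluated vectorised across positions with the explicit
degenerate-case definitions above. Determinism: one seed drives the whole
generator, and identical seeds produce byte-identical FASTA/VCF/TSV
outputs.

## A worked run

```{r, eval = FALSE}
co <- simulate_cohort(cohort_config(seed = 1))
sc <- sdr_scan(co$genotypes, co$sexframe, depth = co$depth,
               genes = co$genes, repeats = co$repeats,
               reference = co$reference)
print(sc)
amp <- in_silico_pcr(co$reference, co$truth$primers)
band_pattern(amp, sc$haploid_regions)
```

## Known limitations

* The LRT is a count-based surrogate; with genotype likelihoods available,
  a GL-aware test could differ near the detection boundary.
* `classify_system()` encodes a conservative evidence rule; species with
  both a hemizygous region and strong autosomal depth artefacts may need
  manual review of the coverage corroboration.
* The seed-and-extend scanner targets desk-scale genomes (megabases); for
  whole vertebrate genomes an external aligner remains preferable.
* Annotation handles SNV coding effects only; splice-site and regulatory
  classes are out of scope.
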