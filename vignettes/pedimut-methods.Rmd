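---
title: "Detecting de novo mutations in selfed pedigrees: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting de novo mutations in selfed pedigrees: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A single de novo mutation is a needle in a genome-sized haystack: in a
woody perennial such as peach, roughly one point mutation per hundred
million bases per generation. The design `pedimut` supports is a
parent–progeny pedigree: an F1 tree is selfed, a few dozen F2 seedlings are
whole-genome sequenced to ~40x alongside the parent, and a mutation is an
allele seen in exactly one F2 and in no other sample. At these rates almost
every raw candidate is an artifact, so the value of the pipeline lies in
its filters, in knowing which genome fraction those filters leave
observable (the *callable sites*), and in honest uncertainty on the
resulting per-site per-generation rate.

`pedimut` implements the full chain — genotype classification, confident
markers, candidate detection with soft-masking, callable-fraction
estimation by injection, Poisson-exact rates, spectrum/selection
statistics, and heterozygosity-compartment analyses — together with a
pedigree simulator with known ground truth, so every stage is testable
without any external data.

## Genotype classification and confident sites

Per-sample genotypes are classified from ref/alt read counts alone
(`classify_genotype()`). With the reference-allelic ratio r = ref/(ref+alt):

* `hom_ref` for r in [0.95, 1], `hom_alt` for r in [0, 0.05];
* `het` for r in [0.30, 0.70];
* `missing` when depth (the sum of the two allele depths) is below 10 or
  above 80 — the callable-depth window;
* `ambiguous` otherwise.

All bounds are inclusive. The five classes partition every count pair,
which the test suite verifies by brute force. A *confident site*
(`filter_confident_sites()`) is bi-allelic, has record quality >= 50, and
a strict majority (> 0.5) of group samples informative (classified
hom/het). A *marker* is a confident site where the F1 is a confident
heterozygote, outside the structural-variant BED mask; markers in SV
regions are removed because paralog collapse mimics heterozygosity.
"Informative" at non-variant sites is taken as "meets the depth and ratio
rules" — the one place where the underlying GVCF semantics are summarised
rather than modelled.

## Candidate detection and soft-masking

Detection starts from *rare* alleles: alleles carried by fewer than three
samples of the group, counting carrier samples rather than allele copies.
Every F2 carrier becomes a focal candidate and is evaluated
(`evaluate_candidates()`) against:

1. **read support** — at least 5 reads of the derived allele in the focal
   sample with both strands represented (>= 1 per strand by default; the
   stricter >= 5 per strand reading of the rule is exposed as
   `min_strand_reads`);
2. **background** — the parent informative, and at most 5 missing calls
   among the other F2s;
3. **exclusivity** — zero reads supporting the allele in the parent or any
   other F2.

Failing candidates are *soft-masked* with reason codes
(`low_support`, `no_strand_pair`, `parental_background_missing`,
`excess_missing`, `allele_elsewhere`, `cluster`, `sv_mask`) rather than
dropped; conservation (candidates = PASS + masked) is a tested invariant.
Clusters — more than three substitutions in any 10 bp window or more than
two indels in any 20 bp, per focal sample — are masked as likely
contamination. The boundary reading is strict: exactly three substitutions
in 10 bp do *not* mask. Cluster evidence is pooled across callers so that
a record one caller dropped still counts toward the other's windows.

Two variant callers are supported end to end: each caller's PASS set is
normalised (indels trimmed/left-shifted) and merged with provenance
(`merge_caller_sets()`), reporting per-type consistency counts; conflicting
alleles at one locus and sample are flagged for review, never auto-merged.
A separate scan (`scan_shared_mutations()`) looks for point mutations in
two to five F2s absent from the parent — the signature of a parental
somatic mutation transmitted through multiple gametes.

## Callable sites and the mutation rate

The accessible genome is estimated by simulation
(`estimate_callable_fraction()`): synthetic derived alleles at allele
fraction ~0.5 are injected at uniformly sampled sites of one F2, and the
fraction that the *entire* chain recovers is the callable fraction c. The
rate is then

mu = (mean mutations per F2) / (2 c L),

with L the haploid reference length, and the factor 2 for the diploid
genome. Confidence intervals treat the total count k as Poisson and use
the exact Garwood construction (chi-square quantiles), scaled onto the
rate; at k = 0 the interval is one-sided. `stats::poisson.test` serves as
an independent cross-check in the tests, not as the implementation.

Two subtleties the simulator makes visible:

* even with error-free reads, ~2% of true heterozygous mutations draw an
  allelic ratio outside the 30–70% band at 40x and are correctly not
  called; the injection simulation loses the same fraction, so the
  *within-callable* false-negative rate stays near zero;
* with sequencing errors at 1e-3, the exclusivity rule removes true
  mutations whenever a stray error read mimics the mutant allele in
  another sample (~10% at a dozen samples); again the injection estimate
  absorbs this loss into c, which is exactly why rates must be corrected
  by c rather than by genome length alone.

## Spectrum, context and selection

Base substitutions collapse onto six strand-symmetric classes
(`classify_substitution()`). Because each site offers one transition and
two transversions, the transition/transversion *rate* ratio is twice the
event ratio (`titv_rate_ratio()`). The composition-corrected AT-bias fold
(`at_bias_fold()`) divides the per-G:C-site rate of G:C>A:T changes by the
per-A:T-site rate of A:T>G:C changes.

Trinucleotide context (`triplet_analysis()`) counts each mutation in three
registers (mutated base at triplet start, centre and end) against a
background of all overlapping genomic triplets, the convention that makes
expected compartment counts comparable; expectations are divided by three
so they sum to the observed total over a genome partition. A conventional
centre-only mode is deliberately not the default, since the three-register
form is what the compartment expectations are built on. CpG context is a
mutated C with 3' G (or G with 5' C).

Selection checks (`selection_tests()`) are Yates-corrected chi-square
goodness-of-fit tests — coding vs non-coding against the annotated coding
fraction, non-synonymous vs synonymous against the mutational 3:1 null —
plus a one-tailed Fisher test for an excess of multiple-of-three indels in
coding sequence. The Yates statistic clamps |O−E|−0.5 at zero, which is
required to reproduce a statistic of exactly 0 when observed and expected
differ by less than half a count. Synonymy uses the standard nuclear code
on the annotated frame; the simulator's annotation is plus-strand, frame-0
CDS intervals, which is all the classifier needs exercised.

## Compartments and the heterozygosity-distance profile

Each F2's genome is partitioned into heterozygous and homozygous
compartments from runs of same-state confident markers
(`assign_compartments()`). Boundaries between discordant neighbouring
markers are set at their midpoint — the paper-silent choice that keeps
interior sequence fully tiled; only chromosome ends beyond the outermost
markers (and marker-less chromosomes) are `unassigned`, and mutations
falling there are excluded from compartment tests. Homozygous runs inherit
the parental haplotype label of their allele when grandparental origin
tags are available. Observed versus expected counts per compartment
(`compartment_counts()`) use bp shares, optionally re-weighted by
triplet-content expectations; the published coverage-and-triplet-corrected
haplotype-of-origin counts are not pinned in tests because the correction
arithmetic is under-specified — the weighted mode is the package's
best-effort rendering, with the unique-coverage fractions (93.5%/79.5%)
taken as configuration inputs.

The distance profile (`window_het_profile()`) pools, for each mutation,
the two 100 bp flanks at distance i*100 bp (window 0 is the surrounding
2 x 100 bp), computes het/informative per window, discards
mutation-windows with fewer than 80 informative bp, and averages across
mutations. Under uniform mutation placement the profile is flat at the
genome average; planted proximity to heterozygous sites produces the
declining enrichment shape — both are property tests, and no figure-read
values are asserted.

Group comparisons of per-F2 counts use the Brunner–Munzel rank test
(`brunner_munzel()`): mid-ranks for ties, the t approximation on
Satterthwaite degrees of freedom, and a studentised-permutation fallback
(with a warning) when the rank variance degenerates. The test is written
in the package because no installed library provides it; a permutation
oracle checks it in the suite.

## The simulator: what it emulates, and what it does not

`simulate_group()` generates an F1 heterozygous at a configurable marker
density — defaults 0.29% (intraspecific) and 1.24% (interspecific), the
observed F1 haplotype diversities — with F2 genotypes drawn 1:2:1 per
marker, de novo mutations at `true_mutation_rate` (default 1e-8) over the
diploid genome with an indel share of 46/286 and uniform 1–10 bp indel
lengths (the observed length distribution is unpublished; the default is
configurable), Poisson depth around 40x (the stated minimum coverage; a
Poisson is the standard shotgun approximation), binomial 0.5 allele and
strand splits, and errors that relocate a read to a uniformly chosen
different base at `error_rate` (default 1e-3). Two caller profiles drop
candidate records independently (defaults 4.6%/6.7%, matching the observed
caller-exclusive call shares), optional contamination clusters exercise
the cluster mask, and optional shared mutations in 2–5 F2s exercise the
somatic scan.

Deliberately not modelled: read-level artifacts (mapping bias, PCR
duplicates), linkage between markers by default — each marker segregates
independently, with a whole-chromosome block mode available — and somatic
branch structure in the F1. Passing tests therefore demonstrate that the
*rules* are implemented faithfully and self-consistent, not that the
thresholds are optimal for any particular real instrument or aligner.

## Problem sizes and numerical choices

The shipped tests run the simulator at genome sizes from 20 kb (literal
brute-force comparisons of the detection rules) through 1 Mb (segregation
and heterozygosity checks) up to sequence-free 20–100 Mb genomes with
sparse markers for rate-recovery and false-negative studies — sizes chosen
so the whole suite exercises every stage at meaningful mutation counts
while staying quick. Rate recovery uses 99 replicates across true rates of
5e-9, 1e-8 and 2e-8 and requires the exact interval to cover truth in at
least 93%. Reference constants for the published peach numbers (genome
length 2.2571e8 bp — back-solved so that the published group-I rate and
both interval endpoints round correctly — coverages 84.3/64.9/76.9%, G:C
fraction 0.375) ship in `peach_constants()`, and the published per-F2
count, spectrum and selection tables in `peach_*` loaders.

Known limitations: indel support evaluation trusts the per-allele counts
table (no local re-assembly); compartment boundaries are symmetric
midpoints regardless of marker spacing; the within-F1 placement of shared
mutations is not modelled beyond carrier sets; and the published
composition-corrected compartment expectations (48.9/34.3) are
reproducible only in spirit, as discussed above.
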