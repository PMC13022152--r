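---
title: "Methods: haplotype calling and diversity analysis at the rice SD1 locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype calling and diversity analysis at the rice SD1 locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sd1hap)
```

## The problem

The rice semi-dwarf gene *SD1* encodes gibberellin 20-oxidase-2 (GA20ox-2).
Loss-of-function alleles at this locus reduce culm length without a yield
penalty and were the genetic core of the Green Revolution: the 383-bp
deletion carried by the landrace Dee-Geo-Woo-Gen (DGWG) and by IR8 is the
most widely used. Natural variation at the locus falls into twelve allele
classes: the residue-100/340 combinations *GR* (wild type), *EQ* and *ER*;
seven point loss-of-function alleles (missense, premature stops, a 2-bp
frameshift); and two long deletions of 1,279 bp and 383 bp whose 3' ends
are only 13 bp apart.

`sd1hap` implements the full analysis around this catalogue as reusable,
tested components: assigning one of the twelve haplotypes to each accession
from VCF genotypes plus read-pair deletion evidence, tabulating allele
frequencies by subpopulation, computing windowed diversity and neutrality
statistics, building neighbor-joining phylogenies with bootstrap support,
and comparing exact tandem-repeat catalogues. Because the resequencing
panels behind the original analyses are large external resources, the
package also ships a first-class synthetic-data generator that reproduces
the locus structure with recorded ground truth, so every stage can be
validated end to end.

## The synthetic locus

The generator builds a 25-kb locus containing a three-exon, two-intron gene
whose concatenated CDS (1,170 bp, 389 residues plus stop) starts with ATG,
ends with a stop codon, contains no internal stop, and carries canonical
GT/AG intron boundaries. Published chromosome-1 coordinates are mapped onto
the locus by a single offset (38,372,465), so the shipped definition table
quotes the catalogue positions verbatim. The exon layout
(10,001–10,450; 10,553–10,952; 12,424–12,743) was chosen so that each
diagnostic site falls at exactly the codon and phase implied by its
amino-acid change — for example the residue-100 site maps to the second
base of codon 100 and the premature-stop site to the third base of codon
342 — and so the gene span coincides with the published ±10-kb analysis
window anchors. One geometric fact cannot be reproduced under a single
offset: the 2-bp frameshift indel falls at codon 127 of the synthetic CDS
rather than codon 130 of the real protein (the real gene's untranslated
and intron structure shifts residue numbering). The definition table
carries the canonical `Arg130fs` label; the annotator reports what the
synthetic CDS implies.

The historical record is internally inconsistent on whether the type-9
frameshift is a 2-bp insertion or deletion; the package defaults to a
deletion (the reading supported by the narrative descriptions) and exposes
`indel_as = "insertion"` as the alternative.

Defaults the generator treats as study conditions: paired-end reads with
truncated-normal template lengths (mean 400 bp, SD 30 bp, read length
150 bp — free parameters, since the source datasets' library geometry is
not recorded; the values are typical for Illumina resequencing), 30-fold
coverage, population mutation parameter theta = 5 per locus for neutral
samples, and plant heights of 150 cm (GR, ER), 110 cm (EQ), 60 cm (the
japonica semi-dwarfs, types 3–5), and 85–90 cm (the remaining
loss-of-function classes) with an 8-cm within-group SD — a pattern matching
the published ordering of group means.

What the generator does **not** emulate: sequencing error and base
qualities, alignment artefacts, recombination within the locus, selection,
population structure beyond a subpopulation label, and heterozygous
structural variants. Passing tests therefore demonstrate correctness of
the algorithms under clean, known-truth conditions, not robustness to
every artefact of real resequencing data.

## Genotype filtering and the heterozygote question

The site-level quality rule is: keep a call iff read depth > 5 **and**
alternate-read fraction > 0.8, both strict. `filter_variants()` implements
exactly this. "SNP frequency" is read as the per-sample alternate-read
fraction rather than a population allele frequency, because the filter is
applied per VCF genotype before any cohort aggregation; the thresholds are
configurable should the other reading be wanted.

A strict 0.8 fraction filter removes heterozygous calls (alternate
fraction near 0.5), yet the classifier must be able to label accessions
heterozygous at a deciding site. The pipeline therefore applies the depth
rule to every call but the fraction rule only to homozygous-alternate
calls, keeping heterozygous genotypes visible; the frequency tabulation
then excludes heterozygous accessions under its default
`homozygous_only = TRUE`, which reproduces the convention that only
homozygous alleles are counted.

## Haplotype classification

Classification follows the catalogue's precedence rule, because a
structural or point loss-of-function accession can share the residue
100/340 substitutions of the combination types:

1. **Structural** (types 6, 7): a detected deletion matching a defined
   interval at reciprocal overlap ≥ 0.9. Insert-size breakpoints are
   imprecise by roughly a read length on each side, so exact-interval
   matching would be wrong; 0.9 is loose enough for that imprecision and
   tight enough to separate the two defined deletions. Two distinct
   structural matches in one accession raise an error — on real data this
   pattern flags sample-purity problems.
2. **Point LOF** (types 3, 4, 5, 8, 9, 10, 12): a homozygous genotype
   matching the diagnostic SNP or the 2-bp indel.
3. **Combination**: the residue-100/340 state pair G/R → 1, E/Q → 2,
   E/R → 11. The fourth combination G/Q gets the explicit label
   `GQ_unobserved` rather than an error: its absence from natural
   populations is a finding, not invalid input. A heterozygous genotype at
   any deciding site yields `heterozygous`.

## Deletion detection from read pairs

Properly oriented (forward–reverse) pairs whose template length exceeds
the insert model's mean by more than `k_sigma` SDs are discordant — the
larger insert size of properly oriented pairs is the signature of a
deletion between the mates. The insert model is fitted robustly (median
and 1.4826·MAD, scale floored at 1) so the discordant tail does not
inflate it. Discordant pairs are clustered while their inner spans
mutually overlap; the reported interval is the intersection of the
cluster's inner spans — the maximal region consistent with every
supporting pair, which always contains the true deletion and converges to
it within a read length as coverage grows. The size estimate is the median
discordant template length minus the model mean. Defaults `k_sigma = 4`
and `min_support = 3` are package choices (no numeric thresholds are
recorded in the source workflow): four sigma puts the per-pair false
discordance probability near 3×10⁻⁵ so that three mutually overlapping
false pairs are vanishingly unlikely at 30-fold coverage, which the
wild-type false-positive tests confirm. Same-strand pairs are discarded:
they indicate inversions, which are out of scope. When both sequences are
available, `refine_deletion_breakpoints()` recovers exact breakpoints by
longest shared prefix/suffix (leftmost placement under microhomology).

## Diversity and neutrality statistics

For an aligned sample, columns containing any gap or missing state are
removed first (complete deletion). Then, with `n` sequences and `L_used`
sites: `S` counts polymorphic columns; `eta` counts mutations as (distinct
alleles − 1) per column, so `eta ≥ S` at multi-allelic columns; `k` is the
mean pairwise difference; `pi = k / L_used`; theta per sequence is
`eta / a1(n)` with `a1(n) = sum(1/(1:(n-1)))`; Watterson's theta per site
divides by `L_used`. Tajima's D uses the 1989 constants and is undefined
for `S = 0` or `n < 4`; its two-sided significance comes from the
scaled-beta approximation of the null density over the statistic's
theoretical range (the convention of standard DNA-polymorphism software),
not from tabulated confidence limits. Negative D indicates an excess of
low-frequency polymorphism.

The neutral reference model is a Hudson coalescent without recombination
under infinite sites — the simplest model matching the statistics tested.
Mutations are Poisson with mean theta/2 times total branch length, so the
expected segregating-site count is Watterson's `theta · a1(n)`; the test
suite and acceptance script verify recovery within three standard errors
over 1,000 replicates at n = 20, theta = 5.

## Phylogenetics

SNP genotypes convert to an aligned matrix (IUPAC codes for heterozygotes,
N for missing). Distances follow the Tamura–Nei (TN93) model with base
frequencies pooled across all sequences — a composite-likelihood-style
sharing that approximates the usual maximum-composite-likelihood
distances; the full simultaneous-estimation scheme is not reproduced, so
agreement with other implementations is expected at the topology level,
not to distance-level bit-exactness. Sites ambiguous in either member of a
pair are skipped for that pair (pairwise deletion). In the
equal-frequency, uniform-substitution limit the distance reduces to the
Jukes–Cantor closed form, which the tests verify to 1e-3. Saturated pairs
are flagged inestimable rather than clamped.

Neighbor joining follows Saitou–Nei exactly, with two documented
conventions: ties in the Q criterion break toward the lexicographically
smallest label pair (internal nodes inherit the smaller child label), so
results are order-independent; and negative branch lengths are clamped to
zero with the deficit moved to the sister branch, preserving the joined
pair's summed length. On additive matrices the algorithm provably recovers
the generating topology, which the suite checks against an independent NJ
implementation.

Bootstrap support resamples alignment columns with replacement; support
for each internal bipartition of the point-estimate tree is the percentage
of replicates containing it (supports attach to the point tree, not to a
majority-rule consensus). Replicates producing an inestimable pair are
dropped and counted. Edges below the collapse threshold (default 60%)
contract into polytomies; 1,000 replicates is the default.

## Tandem repeats

A reported locus is a maximal run of at least two full copies of a unit at
100% identity whose **minimal** period lies within 8–10 bp. Filtering on
the minimal period keeps homopolymers and dinucleotide runs from
masquerading as period-8 repeats; fractional trailing copies are allowed;
each locus is reported once, leftmost-maximal. Catalogue comparison
projects accession coordinates through the known edit list, then matches
loci whose units agree up to cyclic rotation (run phase is arbitrary) with
projected starts within 50 bp; unmatched accession loci are gained,
unmatched reference loci lost, and reference loci inside a deleted
interval are lost with an explicit flag. The scanner is validated by
exhaustive brute force on sequences up to 1 kb.

## Cohort statistics

Plant-height comparisons use one-way ANOVA with all-pairs Tukey HSD at
alpha = 0.05 and a compact letter display: two groups share a letter iff
not significantly different. Groups with fewer than two observations are
excluded with a warning. SNP sharing among 2–5 accessions is summarised as
the full Venn partition (all 2^k − 1 membership patterns), whose counts
sum to the union size by construction.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
data: a 120-accession cohort (10 per haplotype class) at 30-fold coverage
for classifier recovery, 100 deletion-carrying plus 100 wild-type
accessions for the detector, 1,000 neutral replicates for the estimator
checks, 100 random additive trees for NJ, and 200 random ≤1-kb sequences
for the repeat scanner — sizes chosen to make sampling error negligible
relative to each tolerance while keeping a full run in the minutes range.
Every stochastic component takes an explicit seed; a fixed configuration
reproduces byte-identical FASTA/VCF/TSV outputs, which the pipeline tests
assert.

## Known limitations

- The classifier assumes the offset-mapped coordinate frame of the shipped
  definition table; applying it to arbitrary reference builds requires a
  matching offset.
- Deletion detection needs homozygous deletions at reasonable coverage;
  heterozygous structural variants are out of scope.
- The annotator handles a single forward-strand transcript (coordinate
  logic is strand-parameterised, but no multi-transcript logic exists).
- TN93 distances with pooled frequencies approximate, not reproduce,
  maximum-composite-likelihood distances.
- No imputation or phasing; missing genotypes simply fall back to the
  reference state during classification.
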