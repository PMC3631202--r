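---
title: "Comparing plastomes pairwise: variants, cpSSRs, minute inversions and parsimony networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing plastomes pairwise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdiff)
```

## The problem

Chloroplast genomes (plastomes) are small, non-recombining and mostly
uniparentally inherited, which makes them the marker system of choice for
plant phylogeography. Their drawback is low variability: to find informative
regions within a species one compares two complete plastome sequences
end-to-end, classifies every difference, and designs markers around the most
variable windows. `cpdiff` implements that comparison as a tested pipeline:

1. **Minute-inversion detection** — short blocks carried in opposite
   orientation, usually the loop of a hairpin whose stem is a flanking
   inverted repeat.
2. **Variant scanning** — SNPs and indels, with the inversion columns masked
   so their internal mismatches are not double-counted.
3. **Classification** — transition/transversion, LSC/SSC/IR region, genic
   context, and synonymous/nonsynonymous effect for coding SNPs.
4. **cpSSR survey** — indels that change the repeat count of a mono- or
   dinucleotide tandem tract.
5. **Divergence statistics** — substitution rates per region class, SNP
   densities per context, the transition/transversion ratio
   $R = \mathrm{Tn}/\mathrm{Tv}$, and a sliding-window ranking of variable
   regions for marker design.
6. **Haplotype networks** — collapsing multi-sample marker alignments into
   haplotypes and connecting them under a statistical-parsimony step limit,
   with gaps treated as a fifth character state and each indel as a single
   mutational event.

The package consumes alignments; it never computes them. Intraspecific
plastome pairs are typically alignable by eye and arrive curated, and
re-aligning would silently change every downstream count.

## Conventions and the data model

All coordinates are 1-based and inclusive, reported on the *reference*
genome (row 1 of the alignment). Only one inverted-repeat copy is modeled,
so the partition is a linear LSC/IR/SSC tiling; `region_of()` and
`context_of()` are total functions over the genome. Unannotated positions
are implicitly intergenic. `N` bases are legal but uncallable: a column
containing `N` yields no variant, and a gap run containing an uncallable
column yields no indel.

Counting rules, each chosen to keep the arithmetic of a published-style
summary table self-consistent (`total = SNPs + indels + inversions`,
`Tn + Tv = SNPs`, `syn + nonsyn + unresolved = coding SNPs`):

* **One maximal gap run is one indel event**, whether 1 bp or 141 bp. This
  matches how indels are counted as single mutational events in parsimony
  networks.
* **Adjacent mismatching columns are separate SNPs** (no MNP merging) — SNP
  totals are per-site counts.
* **Coding effect is evaluated per SNP** against the reference codon with
  all other positions held at reference state, so several SNPs in one codon
  each get their own effect. Codons are reconstructed strand- and
  phase-aware, splicing exons in order; a codon truncated at a feature edge
  is reported `unresolved` and excluded from the syn/nonsyn totals rather
  than guessed. Stop gain/loss counts as nonsynonymous.
* **Region and context are recorded independently**: a SNP inside a gene
  that lies in the IR is `IR` by region and `coding` by context.
* **Indels are anchored** at the first deleted reference base (deletions) or
  the 5′ flanking reference base (insertions) for classification.

## Minute inversions and the CG/GC corner case

A candidate block is a maximal run of at least two consecutive gap-free
mismatch columns whose two alleles are reverse complements (e.g. `GTA` vs
`TAC`). One subtlety deserves spelling out: for a segment that is its own
reverse complement (such as `CG`), a true inversion is invisible in an
alignment — `revcomp(CG) = CG`. What one actually observes at such sites is
a *reversed* block (`CG` vs `GC`), which is the classic "potential
inversion" signature. The detector therefore accepts either a
reverse-complement match or a plain base-order reversal, flagging the latter
`potential`. Both kinds are masked before SNP calling; without the mask each
2–3 bp block would be double-counted as 2–3 SNPs.

The hairpin test extends outward from the block while the 5′ flank base is
the perfect Watson–Crick complement of the matching 3′ flank base (no G·U
pairs, no mismatch tolerance, no thermodynamic model). The stem length is
the extension length, measured on both genomes and reported separately if
they differ. The default `min_stem = 4` separates real hairpins from chance
1–3 bp complementarity; it is configuration-exposed because no standard
threshold exists.

## cpSSR thresholds

A locus qualifies when the *longer* allele forms a perfect mono- or
dinucleotide tract of at least `min_mono = 5` (or `min_di = 5`) repeat
units and the indel length is a whole number of units. Dinucleotide tracts
are treated phase-free (a maximal run of two distinct alternating bases,
count = ⌊run/2⌋), so `TA` vs `AT` phasing is irrelevant. The thresholds are
calibrated, not canonical: published surveys rarely state their inclusion
rule, and 5 units is the smallest setting at which every locus of the
bundled 28-locus reference table qualifies while sub-threshold repeat
context around ordinary indels does not. Reported coordinates span the
union of both alleles' tracts, on the reference genome. Mean tract lengths
pool both genomes' alleles, which is how the reference table's printed
means (8.3 bp mono, 13 bp di) are reproduced.

## Divergence denominators

"Per nucleotide" rates use reference-genome region lengths, not alignment
column counts (the two differ by well under 1 % at intraspecific
divergence; the alternative is one line of code away via
`ungapped_span_length()`). Densities use exon length for `coding` and
intron + intergenic length for `noncoding`. Display rounding follows the
conventional report precision — rates to 5 decimals, densities to whole bp,
$R$ to 2 decimals — while raw values are kept alongside. Cross-set
percentages of the form "x % higher" are genuinely ambiguous between
$(a-b)/a$ and $(a-b)/b$; `relative_excess()` returns both with explicit
labels instead of picking silently.

## The statistical-parsimony limit

TCS-style networks connect two haplotypes only when their step distance can
be explained without any site having mutated twice, at a stated confidence
(conventionally 95 %). The published implementations differ in their exact
probability estimator, so `connection_limit()` treats the estimator as a
swappable strategy. The default, `parsimony_probability()`, is the uniform
multiple-hit (collision) model: $j$ mutations thrown independently at $L$
sites all land on distinct sites with probability

$$P(j) = \prod_{i=1}^{j-1}\left(1 - \frac{i}{L}\right),$$

and the limit is the largest $j$ with $P(j) \ge$ confidence. This estimator
is exactly monotone in $L$, non-increasing in confidence, collapses to a
1-step limit as confidence approaches 1, and for a 4072-bp marker set at
95 % yields a limit of 20 steps — comfortably separating haplotype pairs a
dozen steps apart (connected) from pairs 48 steps apart (left in separate
components). Network assembly adds edges in ascending distance order,
keeping an edge only if the pair is not already connected through strictly
smaller distances (minimum-spanning behavior with ties retained;
lexicographic id order breaks remaining ties, making output deterministic).
Manual bridges between unconnected components are supported but flagged:
they demonstrate observed minimum distances and never merge components.

## What the synthetic generator emulates — and what it does not

Every stage is tested against *planted truth*: `plant_mutations()` writes a
known mutation set into a genome and emits the true alignment, so the
scanner's output can be compared event-for-event, classification-for-
classification. Two deliberate design points:

* Planted events never overlap and never touch feature or partition
  boundaries, so the default tests avoid the `unresolved`-codon edge case
  (which has its own dedicated tests).
* The truth-side coding effect is computed from a literal 64-entry codon
  table through its own splicing code, while the scanner uses the genetic
  code shipped with Biostrings — two independent paths that must agree.

The package's default study conditions (`elodea_plastome()`,
`elodea_mutation_spec()`, `elodea_haplotype_plan()`) reproduce the
divergence profile published for a native-vs-introduced pair of *Elodea
canadensis* plastid sequences: a 112,193 bp working sequence (one IR copy)
carrying 235 variable sites — 186 SNPs (79 transitions, 107 transversions;
42 nonsynonymous, 35 synonymous among 77 coding), 47 indels (28 of them
length-polymorphic cpSSRs with a 4×A/19×T/1×C/1×G mononucleotide motif
tally; longest plain indels 141/38/23 bp), and two minute inversions (a
GTA/TAC loop with an 8-bp stem, and a CG/GC reversal that forms no
hairpin). The annotation grid is fixed — partition LSC 1–60,543 /
IR 60,544–87,543 / SSC 87,544–112,193 and 66,450 bp of exons — chosen so
that the published rate and density denominators are exact: 154 single-copy
and 32 IR SNPs give 0.00181 and 0.00119 substitutions per nucleotide, and
77/109 coding/noncoding SNPs give one SNP per 863/420/603 bp. Only the
sequence itself and the event placements are random, so any seed reproduces
the same headline numbers.

What passing these tests shows: the scanner, classifiers, SSR survey,
hairpin test, statistics and network builder implement their definitions
exactly, at realistic scale and composition. What it does not show: the
generator plants ideal data. Real plastome comparisons bring assembly gaps
and low-coverage artifacts, alignment ambiguity around repeats (where
equally optimal gap placements shift SSR coordinates by a unit), nested or
overlapping events, and annotation errors. The package will faithfully
analyze whatever alignment it is given — the alignment's quality is the
user's responsibility.

## Problem sizes used by the test suite

The bundled tests run the full 112 kb study-condition pair across 20 seeds
for truth recovery, 15 kb genomes for general pipeline properties, a
150 kb / 10,000-SNP run for the transition-fraction convergence check, and
the 4072-bp seven-haplotype marker set for all network properties. These
sizes were chosen as the smallest that exercise every code path at
realistic composition.

## Known limitations

* No de-novo annotation, IR-boundary detection or circular-rotation
  normalization: the feature table is trusted as given.
* Tri- and longer-nucleotide SSR units are out of scope (none occur in the
  reference table; the tract finder's design extends naturally if needed).
* The hairpin test has no energy model; "forms a hairpin" means a perfect
  stem of at least `min_stem` bp.
* `compare_marker_sets()` analyses pairwise alignments per locus; three-way
  comparisons are three invocations.
* The parsimony estimator is an approximation chosen for its monotonicity
  properties; an exact coalescent-based estimator can be slotted in through
  the `estimator` argument without touching the network builder.
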