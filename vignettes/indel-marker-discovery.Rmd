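---
title: "InDel marker discovery by electronic PCR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{InDel marker discovery by electronic PCR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelscout)
```

## The problem and the approach

Insertion/deletion polymorphisms (InDels) make excellent PCR markers for
plant breeding: they are co-dominant, abundant, and — unlike SNPs — can be
scored as a simple product-*length* difference on an ordinary gel. With
thousands of resequenced accessions available for crops such as rice, one
can discover gel-ready InDel markers entirely in silico.

`indelscout` implements an electronic-PCR (e-PCR) pipeline for this. e-PCR
simulates the PCR reaction computationally: a primer pair "amplifies" a
target wherever the forward primer and, downstream on the same strand, the
reverse-primer footprint both match within a mismatch budget; the predicted
amplicon is the sequence between the outer primer ends. The pipeline:

1. **Tiling design.** 20-bp forward and reverse primers separated by a
   20-bp gap are extracted along the template genome; each next window
   starts on the 20-bp region upstream of the previous reverse primer, so
   the window advances 20 bp per pair and every reference product is 60 bp,
   overlapping its neighbours by 40 bp. Final windows shorter than 60 bp
   are discarded rather than truncated, which gives the closed form
   `floor((L - 60) / 20) + 1` pairs for a template of length `L`
   (`expected_pair_count()`).
2. **Uniqueness filter.** Each pair is amplified in silico against *two*
   reference genomes (a within-subspecies and a cross-subspecies
   reference) with up to 3 mismatches per primer; only pairs predicting
   exactly one product in each genome are kept. Uniqueness is defined at
   the pair (amplicon) level, not the single-primer level: in a genome-sized
   target the expected number of spurious 3-mismatch neighbours of any
   20-mer is far above one, so single-primer uniqueness would reject nearly
   everything, while requiring a single *properly oriented, properly
   spaced* primer configuration captures the intent of mapping to a unique
   genomic region.
3. **Read amplification.** Unique pairs are amplified against
   quality-filtered resequencing reads, allowing up to 1 mismatch per
   primer — a tighter budget that trades SNP tolerance against InDel
   accuracy. Both primers must sit in the *same read*, so an insertion
   longer than `read length − 40` bp is undetectable by construction; this
   detection bias is inherent to single-read e-PCR.
4. **Genotyping.** Per locus and sample, the most frequent product is the
   consensus (ties break toward the smaller length, then the
   lexicographically smaller sequence). Allele identity is the product
   length in bp: these are length polymorphisms scored on gels, so two
   same-length products differing only by substitutions collapse to one
   allele. A locus typed in at least 20 samples with at least two length
   alleles becomes a marker.
5. **Scoring.** Each marker gets its polymorphism information content,
   `PIC = 1 − Σ p_j²` over allele frequencies among typed samples
   (missing cells are excluded from denominators), its major allele
   difference (size difference between the most and second most frequent
   alleles; count ties ranked toward the smaller length), allele number
   and size range.
6. **Reporting and selection.** Markers are assigned to one of seven
   genomic categories and summarised per category and per chromosome
   (density = count per 1000 bp; spacing = length/count; 2 decimals,
   rounding half away from zero). Two gel tiers are selected from the
   PIC ≥ 0.5 set: a polyacrylamide (PAGE) tier requiring a major allele
   difference ≥ 3 bp with 60–100-bp validation products, and an agarose
   tier requiring ≥ 8 bp with 150–300-bp products.
7. **Validation primers.** For each selected marker a 100-bp template (the
   20-bp variable inter-primer region plus 40-bp flanks) is extracted and
   the best validation pair is chosen by exhaustive enumeration under hard
   constraints, scored by a weighted penalty.

## The mismatch-tolerant matcher

Primer-site search is ungapped, full-length Hamming matching of a 20-mer
over both strands (`find_primer_sites()`); `N` never matches a primer base,
and pairs whose primers contain `N` are designed but flagged unusable. The
production path decomposes the mismatch budget by pigeonhole: a 20-mer
match with at most `k` mismatches must contain an exact block of length
`floor(20/(k+1))`, so an Aho–Corasick dictionary scan per block (Biostrings
`PDict` with a trusted band) enumerates all candidates, each then verified
by exact mismatch counting. The test suite checks this indexed path against
a naive base-R Hamming scan on hundreds of random instances, and checks
that hit sets grow monotonically with the budget.

Genomic amplification accepts products of 40–400 bp by default: the lower
bound forbids overlapping primer footprints, the upper bound tolerates
InDels between diverged references while excluding distant spurious
pairings. Read-level amplification is bounded only by the read length.

## Melting temperature and validation-primer design

No installed dependency provides oligonucleotide nearest-neighbor melting
temperatures, so `melting_temperature()` implements the unified
nearest-neighbor thermodynamics directly: dinucleotide ΔH/ΔS sums with
terminal initiation corrections, the entropic salt correction
`0.368 (N−1) ln[Na⁺]` at 50 mM monovalent salt, and duplex concentration
`CT/4` at 250 nM total oligo. Reference values computed with an independent
published-parameter implementation are frozen in the tests (agreement to
10⁻⁴ °C), together with two structural properties: Tm is invariant under
reverse complementation, and raising GC at fixed length never lowers Tm.

Validation primers are enumerated on each flank at lengths 20–28 nt and
must satisfy Tm ∈ [60, 65] °C, GC ∈ [30, 70] %, a G/C 3′ terminus (a
stricter ≥ 2-of-last-5 GC clamp is available behind `gc_clamp`), and a
product length inside the tier window spanning the variable region. The
returned pair minimises

`penalty = 1·(|len−23|) + 2·(|Tm−63|) + 0.5·(|GC−50|) + 2·|ΔTm|`

(length, Tm and GC terms summed over both mates). Tm deviations are
weighted hardest because inter-primer Tm agreement dominates PCR success;
ties go to the leftmost forward primer, then the shortest product, so
results are deterministic. The optimizer is validated against an
independent exhaustive enumeration on random templates.

The agarose tier needs 150–300-bp products, which a 100-bp template cannot
host; agarose-mode templates therefore use 150-bp flanks (320-bp
templates). This is a deliberate extension of the 100-bp recipe, which is
only defined for the short-product tier.

## Genomic region categories

`build_region_index()` derives seven categories from a GFF3 annotation:
0.5-kb windows upstream of the transcription start site and downstream of
the transcription end site (on the coding strand, truncated at chromosome
ends), 5′-UTR, CDS, intron (gene span minus exons) and intergenic (the
complement of every gene-derived interval, flanks included). Categories may
overlap — a CDS base also lies in its gene span, and flanks of adjacent
genes can cross — so disjoint assignment happens only at marker level:
each marker takes the category of its reference-product midpoint under the
precedence CDS > 5′-UTR > 3′-UTR > intron > TSS-up > TES-down >
intergenic. Midpoint-plus-precedence is a deterministic, testable rule for
producing the disjoint per-category counts that summary tables need;
coding categories outrank flanks so that functional (genic) assignments
are never diluted by neighbouring-gene flank overlaps.

Internally all coordinates are 0-based half-open; every user-facing table
prints 1-based positions, and marker ids are `chrom-<1-based forward
start>`.

## What the simulator emulates — and what it does not

`sim_config()` describes a small diploid-free (inbred) resequencing study:

* one 10-kb chromosome at 44 % GC (rice-like) by default;
* a diverged second reference carrying planted InDels plus background
  substitutions at 0.5 %, the scale of indica–japonica divergence;
* InDel lengths from a geometric distribution (p = 0.4, truncated at
  50 bp), reflecting the strong dominance of 1–2-bp events in real
  surveys; deletions are additionally capped at the 20-bp inter-primer gap
  so that each planted deletion sits wholly inside one pair's variable
  region, which keeps truth matching unambiguous;
* planted loci at least 100 bp apart and from chromosome ends;
* 87-bp reads (the rounded observed average of public rice runs) at 2×
  default depth, uniform starts, both strands, with per-base errors at a
  configurable rate and Phred scores equal to the promised error rate
  (Q40 when the rate is zero).

One seed drives a single RNG stream through all stages
(`simulate_dataset()`), so datasets are byte-reproducible.

The simulator does **not** model rice repeat structure, transposons,
segmental duplications, heterozygosity, indels in reads, or empirical
quality profiles. Passing the end-to-end tests therefore demonstrates the
*internal correctness* of the pipeline — that planted signal of the
modelled kind is recovered essentially completely with no spurious calls —
not its performance on real genomes, where repeats shrink the unique-pair
fraction and low coverage dominates typing rates.

### End-to-end verification conditions

The headline verification runs 200 samples over a 10-kb genome at 30×
error-free coverage with biallelic 3–10-bp InDels at frequency 0.5, and
requires ≥ 95 % of detectable planted loci (alternate product within the
read length, owning pair unique) to be recovered with the exact planted
size difference, and zero markers whose product contains no planted InDel.
These sizes keep the check minutes-scale on a single core while leaving no
slack for silent breakage: at 30× the probability that a sample lacks any
read spanning a 60–70-bp product is a fraction of a percent, so almost
every locus is typed in almost all 200 samples.

One subtlety: tiling products overlap by 40 bp, so the immediate
neighbours of a planted locus carry the InDel at the *edge* of a primer
footprint. When the event sits within one base of the footprint boundary,
a shifted match within the 1-mismatch budget still amplifies — exactly as
real PCR would with a primer landing across a 1-bp-displaced junction.
Such neighbour markers are genuine detections of the planted event, so the
false-locus check is defined at event level (does the called product
contain a planted InDel?) rather than by owning pair id.

## Numerical conventions and degenerate inputs

* Report rounding is 2 decimals, half away from zero, everywhere
  (`summarize_counts()`, `panel_statistics()`, printed PIC).
* PIC is kept at full precision internally; `0 ≤ PIC ≤ 1 − 1/n` always.
* Templates shorter than one 60-bp window yield a warning and an empty
  pair list, not an error; validation templates truncated by chromosome
  ends shrink with a warning.
* Empty product multisets are missing genotypes; under-typed, untyped and
  monomorphic loci are reported with reasons via `excluded_loci()`.
* Tie-breaks (consensus, allele ranking, primer selection) are all pinned
  so identical inputs give byte-identical outputs; the pipeline manifest
  contains no timestamps for the same reason.

## Known limitations

* Absolute unique-pair fractions on real genomes depend on the aligner's
  reporting conventions and repeat content; the 40–400-bp product window
  and pair-level uniqueness are this package's pinned interpretation.
* Single-read e-PCR cannot see insertions longer than
  `read length − 40 bp` and cannot phase heterozygotes (inbred material is
  assumed — one consensus product per sample).
* PIC "patterns" are product lengths; sequence-level patterns (counting
  same-length SNP variants separately) would raise PIC at some loci.
* The gel tiers inherit their thresholds (PIC ≥ 0.5; Δ ≥ 3 bp short
  products, Δ ≥ 8 bp long products) from gel resolution, not from any
  statistical optimality criterion.
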