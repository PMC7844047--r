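---
title: "Cataloguing polymorphic CGG repeats: models, parameters and design"
author: "cggcat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing polymorphic CGG repeats: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cggcat)
```

# The problem

CGG short tandem repeats are a small, disease-prone class of STR: expansions
of a CGG tract silence or dysregulate nearby genes (fragile X syndrome,
FXTAS, and the folate-sensitive fragile sites), and lengths in the 55–200
unit "premutation" range carry their own late-onset risk. Characterising
*all* CGG repeats in a genome — where they are, how long they are in a
reference, and how variable they are across a population — requires chaining
several analyses that are usually run as one-off scripts: reference repeat
detection, STR genotyping output parsing, population summarisation, and gene
annotation. `cggcat` implements that chain as a reusable, fully seeded
package in which each stage has a contract and a test, and in which a
synthetic-data generator replaces the two inputs that cannot be shipped (a
human reference genome and cohort WGS genotypes).

# Repeat detection

## Motif class

A trinucleotide repeat can be read in three rotations on each strand, so
`canonical_motif_frames("CGG")` expands the motif to the six frames
{CGG, GGC, GCG, CCG, CGC, GCC}; all detection, refinement and filtering act
on the class, never on a single frame. Strand symmetry of the catalogue
follows directly and is asserted as a test property.

## Scoring model

Candidates are seeded from exact frame copies: every maximal run of
consecutive copies is chained, runs separated by at most `max_seed_gap`
(default 7 bp) merge into one candidate, and a candidate must contain at
least one run of `seed_units` (default 2) exact copies. Chaining *all*
copies — including single ones — matters for interrupted repeats: a repeat
whose interruption sits one unit from its edge would otherwise lose that
outermost unit to the candidate boundary and the refinement stage could
never recover it.

Each candidate is scored by wraparound dynamic programming against an
unbounded periodic extension of its dominant frame: the candidate is
consumed globally, the motif phase is free at both ends, and

```
score = match_score · matches − mismatch_penalty · mismatches − indel_penalty · indels
```

with defaults match 2, mismatch 5, indel 17, MinScore 24, MaxLength 1000,
MaxPeriod 20, PM 80, PI 10 (the parameter vocabulary of Tandem Repeats
Finder, with penalties positive). Two consequences anchor the thresholds:

* a pure 4-unit repeat scores exactly 4·3·2 = 24 = MinScore, so 4 units is
  the smallest retained pure repeat and 3 units is rejected;
* an interrupted repeat with `u` units and `k` single-base interruptions
  scores `6u − 7k`, so one interruption is detectable from 6 units up and
  two from 7 units up.

PM/PI are applied as post-hoc purity filters on the refined span (percent
matches ≥ PM, percent indels ≤ PI) rather than as detection priors: the
probabilistic candidate model of a general-purpose repeat finder is not
reproduced here, only its scoring arithmetic, because one motif class with
period 3 is all the downstream analysis consumes.

The scorer is verified against an independent oracle: global–local
`Biostrings::pairwiseAlignment` of the candidate against an explicit
periodic motif extension with linear gap costs, which is mathematically the
same optimisation reached by entirely different code.

## Refinement

Boundaries come from Smith–Waterman local alignment of the candidate region
against a pure periodic repeat longer than the region, under a separate
parameter set (defaults: match 2, mismatch 2, gap open 5, gap extend 1; the
first base of a gap costs the open penalty). The published parameter listing
this follows was ambiguous about whether the match reward was 1 or 2; this
package fixes match = 2 as its own default — consistent with the detection
match score — and exposes every knob rather than guessing further. Ties on
alignment score break towards more units, then fewer interruptions, then the
leftmost start, carried through the DP deterministically. Interruptions
count mismatched plus inserted positions inside the refined span; units are
span/3 reported to one decimal, while the retention filter uses whole units
(`floor`), since repeats are counted in whole copies.

Overlapping refined loci deduplicate to the single best (higher score, then
longer, then leftmost): the catalogue reports *distinct* loci and no merging
rule is imposed beyond that.

# Genotype ingestion and exclusion

`read_str_vcf()` accepts the two common REPCN dialects (`"a/b"` strings and
`"a,b"` integer pairs), treats `.`/absent as a missing call, duplicates
haploid records to homozygous pairs, and normalises genotypes ascending
(they are unphased). Missingness is all-or-nothing per call. Read-class
evidence (spanning / in-repeat / flanking, summed across alleles) is parsed
when present and left *unknown* otherwise; exclusion only ever acts on known
evidence: a locus is dropped as `no_coverage` when no sample has any reads
of any class, and as `flanking_only` when flanking reads are the only
evidence anywhere — loci that cannot be genotyped rather than loci that
happened to be uncalled.

# Population statistics

The reference repeat length is replaced by the **population median repeat
length**: the *lower* median of the called allele multiset, which is always
an observed integer allele. An interpolated median would sit between alleles
at any even split and declare every allele polymorphic there, which is why
the lower median is fixed rather than configurable. A locus is *polymorphic*
iff any called allele differs from its median (at locus level the
individual-based and allele-based wordings coincide), and the polymorphism
rate is the fraction of differing alleles. Missing alleles are excluded from
medians and denominators throughout; no imputation is performed. Per-sample
summaries count *loci* at which the sample carries at least one
off-median allele (locus-level counting; the allele-level alternative is a
one-line change but is not what is implemented).

# Genotyper concordance

Causes of disagreement between two STR genotypers (interruption handling,
read compounding) are not inferable from genotypes alone, so the taxonomy is
purely sign/magnitude/missingness-based: identical, off-by-one (|Δ| = 1),
A-larger (Δ ≥ 2), B-larger, and the no-call categories. Alleles pair by
ascending sort within each genotype — the simplest reproducible rule — and
fractions are reported over allele pairs where A is called, so "B failed to
genotype" is itself a categorised outcome. Consistency is the identical plus
off-by-one fraction. Which denominator a published comparison used (A-called,
B-called, or union) is generally unstated; A-called is implemented and
documented.

# Annotation and enrichment

Region labels follow a fixed precedence — exonic (CDS) > 5′-UTR > 3′-UTR >
ncRNA > intronic > upstream > downstream > intergenic — approximating
refGene-style annotation without external tooling. Upstream and downstream
are strand-aware 1000-bp windows off the transcript ends; a locus
overlapping any gene body is never flanking; over 1 kb from every gene is
intergenic. UTR labels apply to the exonic portion of the UTR span, so a
locus in an intron interrupting a UTR is intronic. The `ncRNA` label applies
when the best overlapping gene is non-coding.

Panel enrichment is a 2×2 Pearson chi-squared (no continuity correction by
default; Yates available behind a flag — at the gene counts this analysis
targets the choice is immaterial). Genes count once regardless of how many
repeats they carry. HI/pLI flags use strict inequalities (HI < 40,
pLI > 0.75) and genes missing from the score table get NA flags, not FALSE.

# The synthetic world

The generator is an explicit stand-in for a reference genome and cohort; its
distributions are chosen for testability and qualitative realism, not
claimed as biology.

* **Genome.** Background is i.i.d. at 41% GC. Runs of ≥ 3 tandem frame
  copies are scrubbed from the background (replaced with A/T), and planted
  repeats get 12-bp A/T guard flanks. Both choices exist so that refinement
  can never profitably extend a planted repeat into chance background hits:
  with guards in place the worst remaining background run (2 copies, ≥ 12 bp
  away) always costs more to reach than it scores. This is what makes
  "planted coordinates recovered exactly" a meaningful test rather than a
  statistical one.
* **Interruptions** are single-base A/T substitutions in interior units, at
  least 3 units apart. Interruption counts are capped at
  `floor((6u − 24)/7)` per locus: beyond that the repeat scores below
  MinScore under the stated detection arithmetic and is unrecoverable *by
  construction*, so planting it would fabricate an unmeetable truth.
* **Cohort alleles.** Each allele mutates away from its planted central
  length with probability `min(1, floor + slope·units)`; mutated alleles
  move by `Geom(p) + 1` units up or down, truncated at 1. The defaults
  (floor 5e-4, slope 3e-4/unit, p 0.5) were fitted once to two anchor
  points of a 544-genome cohort description — about 85% of 4-unit-median
  loci and 96% of 8-unit-median loci polymorphic — giving per-allele rates
  of 1.7e-3 and 3.0e-3 over 1088 alleles, and were not revisited
  afterwards. Every mutated allele differs from the central value, so the
  expected polymorphism rate of a locus equals its per-allele mutation
  probability, which the parameter-recovery tests exploit.
* **Censoring.** With 150-bp reads a genotyper without fully in-read repeat
  evidence cannot size a repeat beyond ~50 units; reported length is
  `min(true, cap)` for true lengths in `(cap, 3·cap)` and the true length
  beyond, a deliberately crude encoding of "far past read length, in-read
  repeats reappear". Missingness is 0.1% per allele (≈ 99.8% of alleles
  genotyped), collapsed to call level because missingness is all-or-nothing
  per call.
* **Gene models.** Toy genes are placed around eight planted loci so every
  region label is realised, with the downstream gene on the minus strand to
  exercise strand awareness. Panels are drawn by weighted sampling without
  replacement (odds ratio for repeat-associated genes), giving a null at
  odds ratio 1 and a positive control above it.

What a green synthetic test does **not** establish: recovery rates on a real
genome's repeat landscape (segmental duplications, near-CGG impure tracts,
assembly gaps), genotyper error modes beyond censoring and missingness, or
any of the study-scale headline numbers (total locus counts, 93% polymorphic
fraction, 91% inter-genotyper consistency), all of which depend on hg19 and
cohort data this package deliberately does not require. One consequence
worth knowing: with planted lengths up to 60 units and the 50-unit cap, the
censoring model *flattens* observed variability at high-median loci, so the
monotone polymorphism-vs-median property is asserted on the uncensored
cohort, and the censoring behaviour is tested separately.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; BED output is 0-based,
  variant-catalog JSON and VCF are 1-based inclusive.
* `N` bases never match and score as mismatches (conservative for assembly
  gaps).
* Candidates longer than MaxLength are truncated at MaxLength.
* Empty sequences, all-missing loci, empty universes and degenerate 2×2
  margins raise typed errors rather than returning NaN.
* All generators consume a single integer seed; derived stages use small
  fixed offsets from it, so whole-pipeline reruns are byte-identical
  (asserted on the report files).
* The run configuration is JSON (no TOML parser among the pinned
  dependencies).

# Known limitations

* The detector targets one motif class at period 3; it is not a
  general-purpose repeat finder (MaxPeriod is honoured but nothing above
  the configured class is searched for).
* Tie-breaking inside the refinement DP is greedy per cell; the (score,
  units, interruptions, start) preference is deterministic but secondary
  criteria are not guaranteed globally optimal in pathological ties.
* Per-gene association counts recompute locus–gene relations geometrically,
  so a locus upstream of one gene and exonic in another counts for both —
  intentional, but different from the single-label locus table.
* The concordance module classifies magnitudes only; it cannot attribute
  causes (interruptions, read compounding) without read-level data, which is
  out of scope.
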