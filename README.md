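# cggcat

Genome-wide cataloguing and population analysis of CGG-class short tandem
repeats (STRs), in R.

Expanded CGG repeats cause fragile X syndrome, FXTAS and a growing list of
other neurological disorders, and cytogenetically visible folate-sensitive
fragile sites have been cloned as expanded CGG tracts. Population-scale
short-read WGS plus STR genotypers (ExpansionHunter, GangSTR) make it
possible to catalogue every CGG repeat in a reference genome and measure how
variable each locus is across a cohort. `cggcat` packages that whole
workflow — repeat detection, genotype ingestion, polymorphism statistics,
genotyper comparison, gene annotation and disease-panel enrichment —
together with a seeded synthetic-data generator, so every stage runs and is
testable without access to a reference genome or cohort data.

## What it computes

**Repeat catalogue.** A CGG repeat can be read in any rotation of its motif
on either strand, so detection operates on the six frames
{CGG, GGC, GCG, CCG, CGC, GCC}. Candidate regions are seeded from exact
frame copies, then scored by a wraparound dynamic-programming alignment of
the candidate against an unbounded periodic motif, with Tandem Repeats
Finder style parameters:

    score = 2·matches − 5·mismatches − 17·indels,  MinScore = 24

so a pure 4-unit repeat (score 4·3·2 = 24) is the smallest retained pure
repeat. Boundaries are then refined by Smith–Waterman local alignment
against a pure periodic repeat (match 2, mismatch 2, gap open 5, gap
extend 1), which finds the longest repeat span with fewest interruptions.
Retained loci pass `floor(units) ≥ 4` plus PM/PI purity filters, are
deduplicated, and are exported as BED and ExpansionHunter-style variant
catalog JSON.

**Population statistics.** The reference length at every locus is replaced
by the *population median repeat length* (lower median of the called allele
multiset). A locus is *polymorphic* when at least one called allele differs
from that median, and its *polymorphism rate* is the fraction of called
alleles that differ. Per-sample summaries, allele-deviation tables
(allele − median), and polymorphic-fraction-by-median curves follow.

**Genotyper concordance.** Two call sets are compared allele by allele
(alleles paired by ascending sort within each genotype) and classified as
identical / off-by-one / A-larger / B-larger / no-call; *consistency* is the
identical + off-by-one fraction over A-called pairs.

**Annotation and enrichment.** Each locus gets exactly one region label with
precedence exonic(CDS) > 5′-UTR > 3′-UTR > ncRNA > intronic > upstream >
downstream > intergenic, where upstream/downstream are strand-aware 1-kb
windows off the transcript ends. Gene-panel enrichment among
repeat-associated genes is a 2×2 Pearson chi-squared test
(`n(ad−bc)²/(r₁r₂c₁c₂)`, 1 df, no continuity correction by default), plus
haploinsufficiency (HI < 40%) and pLI (> 0.75) flags from a score table.

**Synthetic data.** `generate_genome()` plants CGG-class repeats of known
coordinates, units and interruptions on a scrubbed background;
`simulate_population()` draws diploid alleles whose mutation probability
rises linearly with the central repeat length; `emit_vcf()` writes
ExpansionHunter-dialect VCFs with read-evidence fields and a read-length
censoring model (reported = min(true, 50) for true lengths between 50 and
150 units at 150-bp reads — the genotyper "soft limit").

## Worked example

```r
library(cggcat)

cfg <- simulation_config(seed = 42, genome_length = 50000, n_loci = 8,
                         n_samples = 50, spacing = 3000)
gen <- generate_genome(cfg)
cat <- build_catalog(gen$genome)
cat
#> CGG repeat catalogue: 8 loci on 1 sequence(s)
#>   chrom start   end motif units interruptions score   locus_id
#> 1  chr1  4537  4645   CGG    36             0   216  chr1_4538
#> 2  chr1  9396  9531   GGC    45             2   256  chr1_9397
#> 3  chr1 17305 17347   GCG    14             2    70 chr1_17306
#> 4  chr1 20944 21097   GCC    51             0   306 chr1_20945
#> ...
```

Every planted locus is recovered at its exact coordinates (`cat$start`
equals `gen$truth$start`). Simulate a 50-genome cohort, genotype it to VCF,
and summarise polymorphism:

```r
pop <- simulate_population(gen$truth, cfg)
vcf <- tempfile(fileext = ".vcf")
emit_vcf(pop, gen$truth, cfg, vcf)
cs  <- read_str_vcf(vcf)
summarize_loci(cs)[1:4, c("locus_id", "median_units", "max_units",
                          "polymorphic", "polymorphism_rate")]
#>     locus_id median_units max_units polymorphic polymorphism_rate
#> 1  chr1_4538           36        36       FALSE              0.00
#> 2  chr1_9397           45        47        TRUE              0.01
#> 3 chr1_17306           14        14       FALSE              0.00
#> 4 chr1_20945           50        50       FALSE              0.00
```

Locus `chr1_20945` was planted with 51 units: every allele is reported at
the 50-unit censoring cap, so it *appears* uniform — the read-length soft
limit in action. Annotate against generated toy gene models and test panel
enrichment (here with a null, unenriched panel):

```r
gm  <- generate_gene_models(gen$truth, cfg)
assign_region(cat, gm$models)$region
#> [1] "upstream" "five_utr" "exonic" "intronic" "three_utr" "downstream"
#> [7] "ncRNA" "intergenic"
enr <- enrichment_chi2(gm$repeat_genes, gm$panel, gm$universe)
c(chi2 = enr$chi2, p = enr$p_value)
#>      chi2         p
#> 0.4799597 0.4884406
```

## Command line

```sh
inst/bin/cggcat catalog  --fasta genome.fa --motif CGG --out-bed cat.bed --out-catalog cat.json
inst/bin/cggcat ingest   --vcf calls.vcf --out-table calls.tsv
inst/bin/cggcat popstats --calls calls.tsv --out-prefix pop
inst/bin/cggcat concord  --a eh.vcf --b gangstr.vcf --out-prefix conc
inst/bin/cggcat annotate --loci cat.bed --genes genes.gff3 --panel panel.txt \
                         --universe universe.txt --out-prefix ann
inst/bin/cggcat run      --config run.json     # full pipeline
```

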