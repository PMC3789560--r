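---
title: "Genome-wide SSR marker discovery with ssrmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide SSR marker discovery with ssrmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

## The problem

Simple sequence repeats (microsatellites, SSRs) are tandem arrays of 1–6 bp
motifs. Because their repeat number mutates quickly and they are flanked by
unique sequence that serves as a PCR primer template, they make co-dominant,
multi-allelic genetic markers. Given whole-genome sequences for a panel of
related genotypes — a reference plus resequenced lines anchored to its
coordinates — `ssrmine` walks the full marker-development cascade:

1. **detect** perfect SSR tracts in every genome (`find_ssrs()`);
2. **screen** the 300 bp flanks of each tract for genome-wide uniqueness
   (`extract_flanks()`, `screen_uniqueness()`);
3. **design** one primer pair per unique-flank locus (`design_primers()`);
4. **verify** primer specificity by electronic PCR (`epcr()`,
   `epcr_batch()`);
5. **merge** per-genome calls into panel loci and classify polymorphism
   (`merge_panel()`);
6. **summarise** density, repeat-class composition, genomic-region
   distribution, GC content and PIC (`interval_stats()`,
   `repeat_class_table()`, `region_summary()`, `pic()`).

Every stage takes and returns tibbles, so the cascade composes with the
pipe; `tidy()`, `glance()` and `autoplot()` methods summarise the heavier
result types.

## Detection model

A tract is a *maximal* run of whole copies of a 1–6 bp motif. Minimum
repeat counts default to 10, 7, 6, 5, 4 and 4 for mono- through
hexanucleotide motifs — the MISA-style thresholds used in genome-wide plant
surveys (`detection_config()`). Conventions:

* only perfect tracts are called; abutting different-motif repeats are
  reported as separate tracts, never as compounds;
* a motif that is itself periodic (e.g. `ATAT`) is reported under its
  shortest period (`AT`);
* `N` terminates any tract, so assembly/consensus gaps cannot fabricate
  repeats;
* overlapping candidates resolve deterministically: longer tract wins, ties
  go to the shorter motif, then leftmost. Reported tracts never share a
  base;
* the reported motif keeps its observed phase (the rotation starting at
  the tract's first base). `classify_motif()` groups a motif only with its
  reverse complement (`AG/CT` vs `GA/TC` stay distinct, as repeat-class
  tables conventionally list them); `canonical_motif()` additionally
  collapses rotation and is used only for cross-genome merging, where
  boundary jitter between genomes shifts the observed phase.

The scanner is pinned, coordinate for coordinate, to an independent
brute-force oracle that tests every (position, motif length) by direct
string comparison, over hundreds of seeded random sequences.

## Flank uniqueness

A usable locus needs two unique 300 bp flanks. `screen_uniqueness()` runs a
seeded ungapped search: exact 16-mer seeds on both strands (2-bit-coded
k-mer join), each seed diagonal extended without gaps across the whole
flank. A *hit* is any interval with identity strictly above 0.90 over
strictly more than 85% of the flank's columns; hits overlapping the flank's
own location by at least half a flank collapse into the single self-hit,
which is always found. A locus is unique when both flanks have exactly one
hit.

This stands in for a BLASTN screen. The e-value cutoff such screens quote
is deliberately not modelled: at 300 bp and >90% identity it is never the
binding constraint — identity and coverage are. Users who want their own
aligner's behaviour can pass 12-column tabular alignments via the `hits`
argument (or `--hits-from` on the CLI); only the filtering logic is then
applied. Ungapped extension is a simplification: a duplicated flank that
has accumulated internal indels since duplication can escape the screen,
which is the price of having no external aligner dependency.

## Primer design

Candidates are enumerated exhaustively inside each flank under the box
constraints (defaults: length 18/20/27 nt min/opt/max, GC 20–80%, Tm
57/60/63 °C, product 30–500 bp spanning the whole tract, no homopolymer
longer than 5, a crude 8-mer self-dimer screen). Melting temperatures use
the unified SantaLucia nearest-neighbor model at 50 mM monovalent cation
and 50 nM total oligo with the $C_T/4$ concentration term — conditions are
part of `primer_config()`, and the implementation agrees with an
independent nearest-neighbor implementation to hundredths of a degree. The
returned pair minimises

$$|L_f - L_{opt}| + |L_r - L_{opt}| + w\,(|T_f - T_{opt}| + |T_r - T_{opt}|),
\qquad w = 1\ \mathrm{per\ ^\circ C},$$

with ties broken to the smaller product, then the leftmost forward primer.
Penalties are rounded to 9 decimals so that exact ties are not broken by
floating-point summation order. On small flanks the search is verified
against exhaustive all-pairs enumeration. Absence of a feasible pair is a
value, not an error: infeasible loci are reported via the `"failed_loci"`
attribute. Only the listed constraints are modelled — no salt-correction
variants, full Primer3 penalty terms, or multiplexing.

## Electronic PCR

`find_binding_sites()` emulates hash-based e-PCR: the primer's 3'-terminal
9-mer (word size 9) must match the genome exactly, except that one position
of the word may mismatch ("discontiguous word = 1") — but never the
3'-terminal base itself, since a mismatched 3' terminus cannot prime
extension. The remaining 5' portion aligns immediately upstream with
budgets of at most 1 mismatch and 1 indel (per primer, tracked
separately). For indel budgets ≤ 1 the single-gap placements are enumerated
exactly; larger budgets use a small dynamic program, and the two paths
cross-check each other in the tests together with a full-scan oracle that
visits every genome position on both strands.

`epcr()` pairs every forward-strand site of one primer with every
reverse-strand site of the other (both role assignments) into amplicons of
at most 5 kb and classifies the marker: `unique` (exactly one amplicon,
within ±100 bp of the expected size), `multi_site` (two or more amplicons),
`no_site` (anything else — including a lone amplicon of badly wrong size,
which is a failed marker either way).

## Cross-genome merging and polymorphism

Panel genomes are reference-anchored, so corresponding loci sit at nearly
identical coordinates. `merge_panel()` clusters tracts per sequence and
canonical motif group by single linkage on start positions with a 5 kb
window. Within a chain, a start-order sweep opens a new locus whenever a
genome contributes a second tract, so surplus same-genome tracts found
their own locus — a deterministic, input-order-invariant rule. Locus ids
derive from coordinates, making the whole result invariant to genome input
order.

Per-genome alleles are tract lengths from detection (not e-PCR product
sizes — polymorphism classification precedes and exceeds the primered
subset). Classes: `monomorphic` (present everywhere, one length),
`length_polymorphic` (≥2 lengths), `presence_absence` (≥1 genome lacking
the locus), `both`. Absence means "no tract of this motif group within the
window in that genome"; low-coverage absence is indistinguishable from
biological absence at this level, which is why the simulator models a
low-coverage genome explicitly (below). `pic()` computes
$\mathrm{PIC} = 1 - \sum_i p_i^2$ over allele frequencies; `panel_pic()`
applies it per locus, treating each genome as one sampled line.

## Genomic regions and summaries

`build_region_model()` partitions every base into CDS, 5'-UTR, 3'-UTR,
intron (gene span minus exons), promoter (2 kb upstream of the
transcription initiation site, strand-aware, clipped at contig ends) or
intergenic. Overlaps resolve by a configurable precedence in which CDS wins
— a conservative protein-coding assignment when transcripts disagree. A
tract's region is the region of its *start base*: tracts are tens of bp at
most and no table convention exists for straddlers, so a fixed rule keeps
assignment deterministic; only boundary-straddling tracts would differ
under a midpoint rule.

Marker intervals are `genome_size / count` in kb (`interval_stats()`,
default genome size 2.1 Gb); all reported percentages and intervals round
half-up to two decimals (`round_half_up()`, `pct_of()`), matching how such
tables are conventionally printed.

## The synthetic panel generator

`simulate_panel()` makes the whole cascade testable with no downloads. A
founder genome carries one planted tract per locus on a 7 kb cell grid;
every other genome inherits the founder and mutates it:

* repeat counts change with probability `p_length_mut` by a symmetric
  geometric step (stepwise mutation model, the standard SSR model);
* loci drop out with probability `p_absent`; the last genome multiplies
  that rate (default ×4), emulating a wild-relative sample whose reads map
  poorly to the reference;
* flanks accumulate SNPs at `flank_snp_rate`;
* a `duplication_rate` fraction of loci have their tract-plus-flank window
  copied verbatim onto an extra `chrDup` contig, making their flanks
  non-unique by construction; `hard_mode` adds decoy copies at ~80%
  identity — below the screen's >90% cutoff — to stress the screen without
  changing the expected outcome.

Design choices that make the truth table exact rather than approximate:

* **grid spacing.** Merging is single-linkage within 5 kb per canonical
  motif group, and mononucleotide motifs have only two canonical groups —
  at a realistic ~58% mono mix, same-group neighbours are unavoidable. The
  7 kb cell grid guarantees that no two planted loci can chain, so every
  planted locus maps to exactly one merged locus.
* **guards.** Six-bp non-repetitive guards flank each tract; the left
  guard's last base differs from the motif's last base and the right
  guard's first base from the motif's first base, so a tract can neither
  extend by a full copy nor acquire an equally long phase-shifted variant
  starting one base earlier.
* **background hygiene.** The i.i.d. uniform background is scanned for
  tandem runs within one repeat of a detection threshold and each is broken
  by a single substitution, leaving a one-repeat safety margin against
  extension at segment junctions.
* **detectability.** Mutated repeat counts are floored at the detection
  threshold, so "present" always implies "detectable". Recovery statistics
  therefore measure the pipeline, not the dropout model.

Defaults describe a 17-genome panel (16 lines plus one low-coverage wild
relative) with a motif-length mix of roughly 58/25/10/2/3/2% for mono-
through hexanucleotides — the composition reported for maize-scale surveys.
Validation runs in this package use 5 genomes × ~1.45 Mb × 200 loci, a size
at which every stage completes in seconds to a couple of minutes while
still exercising duplication, dropout, low coverage and all polymorphism
classes.

What the generator does **not** emulate: repeat-rich plant genome
background (uniform background makes flank uniqueness easier than in a
real 2.1 Gb maize genome, where many more flanks fail), read-level
sequencing error and coverage gaps (absence is an abstraction, not a
mapping model), imperfect/interrupted repeats, and structural variation
beyond locus dropout. Passing the end-to-end tests therefore demonstrates
algorithmic correctness on clean signals, not performance on real
resequencing data.

## Numerical and degenerate-input conventions

* All in-memory coordinates are 0-based half-open; conversion happens only
  in readers/writers (GFF3 1-based inclusive, BED 0-based half-open).
* Non-ACGTN input bases become `N` on load, with a logged count; flanks
  with ≥10% `N` are dropped before screening.
* An empty genome or tract set flows through every stage as an empty tibble
  rather than an error; infeasible primer design and zero-amplicon e-PCR
  are values, not exceptions.
* `interval_stats(0)` is an error (undefined), as is a PIC input that does
  not sum to 1 (±1e-9).
* Determinism: every tie in every stage has a documented break; the
  simulator restores the caller's RNG state.

## Known limitations

The flank screen's ungapped extension misses diverged duplicates with
internal indels; e-PCR models no binding thermodynamics or degenerate
bases; merging assumes reference-anchored coordinates and performs no
liftover between independent assemblies; PIC here treats each genome as one
unweighted sample, which is the convention for inbred-line panels but not
for outbred population data.
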