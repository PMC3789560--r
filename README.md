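# ssrmine

Genome-wide microsatellite (SSR) marker discovery across panels of
resequenced, reference-anchored genomes.

SSRs — tandem repeats of 1–6 bp motifs — are the workhorse co-dominant
markers of plant genetics: multi-allelic, cheap to score, and surrounded by
unique sequence that templates locus-specific PCR primers. Given one or
more genome FASTA files, `ssrmine` runs the complete marker-development
funnel used in genome-wide SSR surveys:

| stage | function | rule |
|---|---|---|
| detect | `find_ssrs()` | maximal perfect tracts; ≥ 10/7/6/5/4/4 repeats for mono–hexa motifs |
| screen | `screen_uniqueness()` | both 300 bp flanks unique: no second hit with identity > 90% over > 85% of the flank |
| design | `design_primers()` | Primer3-style box: 18–27 nt, GC 20–80%, Tm 57–63 °C (nearest-neighbor), product 30–500 bp spanning the tract |
| verify | `epcr_batch()` | e-PCR: 3'-anchored 9-mer seed word with 1 wildcard, ≤ 1 mismatch and ≤ 1 indel per primer, product within ±100 bp |
| merge | `merge_panel()` | cross-genome single-linkage within 5 kb per canonical motif group; polymorphism = length differences and presence/absence |
| summarise | `interval_stats()`, `repeat_class_table()`, `region_summary()`, `pic()` | density/intervals, repeat classes, UTR/CDS/intron/promoter/intergenic distribution, PIC = 1 − Σ pᵢ² |

A synthetic panel generator (`simulate_panel()`) plants SSR loci with known
per-genome alleles, dropout, flank SNPs and duplications, and emits a truth
table — so the whole pipeline is testable end to end without downloading a
genome.

## Worked example

One locus from detection to an e-PCR-verified marker:

```r
library(ssrmine)

set.seed(1)
bg <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
g <- genome_seq(c(chr1 = paste0(bg(400), strrep("AG", 12), bg(400))), "demo")

(tr <- find_ssrs(g))
#> # A tibble: 1 × 9
#>   genome_id seq_id start   end motif motif_len repeat_count tract_seq    motif_class
#> 1 demo      chr1     400   424 AG            2           12 AGAGAGAGAG…  AG/CT

fl <- screen_uniqueness(extract_flanks(tr, g), g)
fl[, c("left_hits", "right_hits", "unique")]
#>   left_hits right_hits unique
#> 1         1          1   TRUE

(pp <- design_primers(fl))[, c("fwd_seq", "rev_seq", "product_len", "fwd_tm", "rev_tm")]
#>   fwd_seq               rev_seq                product_len fwd_tm rev_tm
#> 1 ATGATCACCCGACGGGGCGA  TCCTCACATGGGACCCTGGGC          455  60.04  59.90

epcr(pp$fwd_seq, pp$rev_seq, g, pp$expected_size)
#> <specificity_call> status: unique - 1 amplicon(s)
```

The tract is the 24 bp (AG)₁₂ array at chr1:400–424 (0-based half-open);
both flanks hit the genome exactly once (their own location), the designed
pair sits at the Tm optimum within a penalty of 1.14, and e-PCR finds
exactly one amplicon of the expected 455 bp size — a usable marker.

At survey scale the same arithmetic applies to published counts: 135,693
loci in a 2.1 Gb genome is one SSR every
`round_half_up(interval_stats(135693), 2)` = 15.48 kb, and
`pic(c(0.5, 0.5))` = 0.5 is the PIC of a balanced two-allele marker.

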