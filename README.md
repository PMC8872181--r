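# mitorearr

Comparative analysis of vertebrate mitochondrial genomes, aimed at the
kind of question raised by intraspecific gene-order variation in
toad-headed agamas (*Phrynocephalus*): conspecific mitogenomes that
differ in the position of tRNA-Pro, carry a duplicated tRNA-Phe, and
hold two or three control regions (CRs). The package is for molecular
evolution researchers who have annotated mitogenomes (GenBank flat
files) and want the standard comparative battery plus an explicit,
checkable model of how the rearranged orders arose.

## What it computes

* **Composition and skews.** Per-region base composition with
  AT-skew = (A − T)/(A + T) and GC-skew = (G − C)/(G + C); ambiguous
  bases excluded from all denominators.
* **Codon usage.** In-frame codon counts per protein-coding gene under
  the vertebrate mitochondrial code (table 2), with terminal complete
  stops (TAA/TAG/AGA/AGG) and incomplete `T--`/`TA-` stops tabulated
  separately, and RSCU(c) = degeneracy × count(c) / family total.
* **Structure.** Start/stop codon tables, intergenic spacer and
  gene-overlap reports on the circular order, and uncorrected
  p-distances from supplied alignments.
* **Gene orders.** Extraction from annotations, canonical rotation
  (anchor: 12S rRNA), classification of the tRNA-Thr..12S "hotspot"
  segment plus the Ile/Gln/Met cluster state (IQM vs QIM) against a
  registry of named arrangement types (`typical`, `V`, `IX` shipped;
  extensible via TSV).
* **TDRL scenarios.** A tandem duplication/random loss event calculus:
  an event duplicates a contiguous block in tandem, then deletes any
  subset of post-duplication positions, constrained only by gene
  essentiality (every non-CR gene must survive). The package validates
  hypothesised scenarios step by step and searches exhaustively for
  minimal ones, deduplicated by intermediate-state sequence.
* **Synthetic data.** A seeded generator of fully annotated synthetic
  mitogenomes (known composition, codon structure, arrangement and
  ground-truth manifest), so the entire pipeline is testable offline.

## Worked example

Simulate one type V and two type IX mitogenomes — the arrangement
configuration reported for three conspecific toad-headed agama
mitogenomes — and analyze them:

```r
library(mitorearr)

recs <- Map(function(lab, s) {
  generate_record(synthetic_spec(arrangement = lab, seed = s))$record
}, c("V", "IX", "IX"), 1:3)

analyze(recs)
#> <analysis_report> 3 record(s), 2 distinct arrangement type(s)
#>   SYN_V_1: 17,299 bp, type V, 2 TDRL event(s) from ancestral hotspot
#>   SYN_IX_2: 18,261 bp, type IX, 2 TDRL event(s) from ancestral hotspot
#>   SYN_IX_3: 18,265 bp, type IX, 2 TDRL event(s) from ancestral hotspot
```

Three genomes, two distinct arrangement types, and each derived hotspot
is reachable from the ancestral Pro–CR–Phe segment in a minimum of two
duplication events. The classification of one record:

```r
classify_order(extract_gene_order(recs[[2]]))
#> <arrangement_call> IX; hotspot CR-F-P-CR-F-CR; QIM cluster;
#>   trnP between-CRs; 2 trnF, 3 CR
```

Type IX carries the duplicated tRNA-Phe (23 tRNAs in total) and three
CR copies, with tRNA-Pro translocated between the duplicated CR/Phe
blocks. The TDRL search, and a shipped two-event scenario replayed
step by step:

```r
search_min_scenarios(c("P", "CR", "F"),
                     c("CR", "F", "P", "CR", "F", "CR"))$min_events
#> [1] 2

sc <- read_tdrl_scenario(system.file("extdata", "fig_branchB_typeIX.json",
                                     package = "mitorearr"))
v <- validate_tdrl_scenario(sc$start, sc$end, sc)
cat(render_trace(v$trace))
#> P-CR-F -> CR(a)-F(a)-P-CR(b)-F(b) -> CR(a)-F(a)-P-CR(b)-F(b)-CR(c)
```

The trace reads: duplicate the whole Pro–CR–Phe block and lose the
first Pro copy; then duplicate the second CR–Phe pair and lose the
final Phe copy, leaving CR–Phe–Pro–CR–Phe–CR — the type IX hotspot.
Losing instead the first Phe and the middle CR yields the type V
hotspot CR–Pro–Phe–CR; both branches of the pathway ship as JSON
scenario files under `inst/extdata/`.

See `vignettes/mitogenome-rearrangement.Rmd` for the model, parameter
and convention details.

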