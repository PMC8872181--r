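---
title: "Mitogenome composition statistics and TDRL rearrangement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome composition statistics and TDRL rearrangement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

## The problem

Vertebrate mitochondrial genomes are compact circular molecules with a
strongly conserved gene content — 13 protein-coding genes (PCGs), 22
tRNAs, two rRNAs and a control region (CR, also called the D-loop) —
but their gene *order* is not always conserved. In some lizard groups,
notably the toad-headed agamas (*Phrynocephalus*), rearranged orders
occur even within a single species: conspecific mitogenomes can differ
in the position of tRNA-Pro, carry a duplicated tRNA-Phe, and hold two
or three control-region copies. The standard explanation is the tandem
duplication/random loss (TDRL) model: a contiguous block of genes is
duplicated in tandem, and redundant copies subsequently decay or are
deleted, leaving a shuffled order behind.

`mitorearr` packages the comparative analysis such a study needs:

* **mito_io** — GenBank flat-file reading and writing with a controlled
  gene-name vocabulary and circular (origin-spanning) coordinates;
* **seq_stats** — nucleotide composition, AT/GC strand skews, codon
  usage and RSCU under the vertebrate mitochondrial code, start/stop
  codon tabulation, spacer/overlap reports, uncorrected p-distances;
* **gene_order** — extraction, canonical rotation and classification of
  circular gene orders against a registry of named arrangement types;
* **tdrl** — an explicit TDRL event calculus that validates hypothesised
  rearrangement scenarios and searches for minimal ones;
* **synthetic_data** — a seeded generator of annotated mitogenomes with
  ground-truth manifests, so every stage is testable offline;
* **pipeline** — `analyze()` plus a thin command-line interface.

## Composition and codon statistics

The composition statistics follow the standard definitions. For a
sequence with base counts $A, C, G, T$ (ambiguous bases excluded from
every denominator):

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C}.$$

Skews are undefined (reported as `NA`, never 0) when a denominator is
zero, always lie in $[-1, 1]$, and are antisymmetric under reverse
complementation — a property the test suite exercises on random
sequences. Per-region rows concatenate the features of each class on
their own coding strand (light-strand genes contribute their reverse
complement), and the whole-genome row uses the heavy strand.

Relative synonymous codon usage for codon $c$ in a synonymous family of
degeneracy $d$ with observed family total $n$ is

$$\mathrm{RSCU}(c) = \frac{d \cdot \mathrm{count}(c)}{n},$$

so an unbiased family has RSCU 1 for every member and family RSCU sums
equal $d$. Families follow the vertebrate mitochondrial genetic code
(translation table 2): AGA/AGG are stops, ATA is Met, TGA is Trp.
Codon totals count in-frame triplets from the annotated start codon;
the *terminal* complete stop (TAA/TAG/AGA/AGG) and any trailing
incomplete `T--`/`TA-` stop (completed by polyadenylation in vivo) are
tabulated separately and excluded from the totals. Published codon
totals for mitogenomes vary by exactly this convention (whether stops
are counted), so the convention is stated here and kept fixed.

The p-distance between aligned sequences is the proportion of differing
columns among columns where both sequences carry an unambiguous base;
gap and N columns are excluded pairwise. Corrected distances (K2P and
relatives) are deliberately out of scope; for the shallow intraspecific
divergences this package targets (~1.5%), the correction is smaller
than the biological signal.

## Gene orders and arrangement types

A gene order is a circular token list. To compare orders we rotate them
to a canonical anchor, by default **rrnS** (12S rRNA): it is single-copy
in every arrangement handled here, whereas tRNA-Phe — the obvious
first-gene convention — is duplicated in some derived arrangements and
cannot anchor. Copy labels `a`, `b`, `c` are assigned in genome order
from position 0, matching the conventional CR I/II/III numbering; they
are positional bookkeeping, not homology claims, and are ignored in
classification.

All of the order variation treated here is confined to the **hotspot
segment** strictly between tRNA-Thr and rrnS, which in the ancestral
vertebrate order reads Pro–CR–Phe, plus the state of the Ile/Gln/Met
tRNA cluster (ancestral `IQM` vs the derived `QIM` shared by agamids
and chamaeleonids). Classification therefore matches the hotspot token
sequence plus the IQM/QIM state exactly against a registry; the first
match wins (registry order is the deterministic tie-break), and
anything else is reported as `novel` together with diagnostics: the
cluster state, the position class of tRNA-Pro relative to tRNA-Phe,
and the tRNA-Phe and CR copy numbers.

The shipped registry holds the three arrangements whose full orders are
unambiguous in the comparative literature:

```{r}
default_registry()
```

Other reported types exist but their complete orders are only published
in figure form; rather than guessing, the registry is extensible via a
TSV (`read_registry()`). Inversions are not considered: none of the
registered types involves a strand flip, but strands are still recorded
so an inverted order surfaces as `novel`.

One wording subtlety is worth flagging: descriptions of the type V
arrangement sometimes say tRNA-Pro moved *downstream* of tRNA-Phe,
while the printed type V order (Thr–CR–Pro–Phe–CR–12S) places it
upstream. The package treats printed orders as authoritative; the type
V diagnostics therefore report `trnP_position = "before-F"`.

## The TDRL event calculus

A `tdrl_event(block, losses)` duplicates the contiguous `block`
(1-based inclusive indices) in tandem and then deletes the `losses`
positions of the post-duplication segment. Three modelling choices
matter:

* **Losses are genome-wide, not block-confined.** After a duplication,
  *any* now-redundant copy may decay, including one left over from an
  earlier duplication outside the newly duplicated block. The described
  pathway to the type V order requires exactly this (it loses a
  tRNA-Phe copy that lies upstream of the second duplicated block), so
  the loss set is any subset of post-duplication positions.
* **Essentiality.** An event may not extinguish the last copy of any
  gene other than CR; control-region copies are freely gained and lost.
  An empty loss set is legal — that is how a duplicate tRNA-Phe and
  supernumerary CRs persist.
* **Linear domain.** Events operate on the linear hotspot segment
  between the fixed anchors tRNA-Thr and rrnS, because that is where
  all the described variation occurs; this bounds the combinatorics.
  Each event performs one duplication (no triplication); building three
  CR copies takes two events.

Scenarios are ordered event lists with a JSON serialization; two
shipped files encode the two-branch duplication pathway from the
ancestral Pro–CR–Phe hotspot:

```{r}
branchB <- read_tdrl_scenario(system.file(
  "extdata", "fig_branchB_typeIX.json", package = "mitorearr"))
res <- validate_tdrl_scenario(c("P", "CR", "F"),
                              c("CR", "F", "P", "CR", "F", "CR"), branchB)
res$valid
cat(render_trace(res$trace))
```

`search_min_scenarios()` finds the smallest number of duplication
events between two segments. The cost of a scenario is its event
count; losses are free byproducts. Two scenarios are *the same* when
they pass through the same sequence of intermediate segments, so the
search enumerates distinct successor states (distinct retained
subsequences of the doubled block context) rather than raw loss masks,
and attaches a deterministic witness event to every step: the first
feasible block in (i, j) order with the leftmost embedding of the next
state. Reachability of the final target within one event is decided by
a subsequence test, which keeps two-event searches fast. The default
bounds (3 events, segments up to 12 tokens) cover every case treated
here with large margin:

```{r}
search_min_scenarios(c("P", "CR", "F"),
                     c("CR", "F", "P", "CR", "F", "CR"))$min_events
```

"Unreachable within the event budget" is an explicit result, not an
error. The test suite cross-checks the search against an independent
brute-force enumerator (exhaustive loss subsets via `combn`) on every
pair of shipped hotspots and against generated random scenarios.
Whether a multi-copy state could instead arise by a single multi-step
amplification is a modelling question the event calculus does not
decide; the search answers reachability under the one-duplication-per-
event convention only.

## The synthetic generator

`generate_record()` builds an annotated mitogenome whose ground truth
is known exactly, so round-trip and recovery tests need no downloads.
Defaults emulate the published scale of agamid mitogenomes and are
fixed once:

* base frequencies A = 0.34, C = 0.245, G = 0.13, T = 0.285 — A+T near
  62.5% with a positive AT-skew and negative GC-skew, the pattern
  reported for these genomes;
* 13 PCGs totalling ~11.3 kb with the reported start/stop pattern:
  GTG starts for ATP8, ND4L and ND6; AGA stops for ND2 and COX1, AGG
  for ND6; incomplete `T--` stops for COX2, ATP6, COX3, ND3 and CYTB;
* tRNA placeholders of 70 bp (22 × 70 = 1540 bp, the scale of reported
  tRNA length totals); rRNAs of 950 and 1600 bp; control regions of
  890 bp each carrying the CSB1 motif `CTTTTCATGCTCAGTAGACATA`
  verbatim;
* a 13 bp ND5/ND6 overlap and random 0–5 bp spacers elsewhere;
* ND6 and the eight light-strand tRNAs reverse-complemented in place.

The arrangement is produced structurally: the canonical vertebrate
order is laid out, the hotspot is replaced by the result of a TDRL
scenario (named arrangements `V` and `IX` also switch the cluster to
QIM), and the manifest records the intended order, coordinates and
scenario. Sequence content is filled by a single seeded i.i.d. stream,
then a constraint pass re-imposes start/stop codons and CSB1 motifs so
overlaps cannot clobber them; two calls with one spec are
byte-identical.

What the generator does **not** emulate: codon bias beyond enforced
start/stops, realistic tRNA secondary structure, among-site rate
variation, or compositional heterogeneity along the molecule. Passing
tests on synthetic data therefore demonstrate the *formula and
plumbing* correctness of the statistics (RSCU family sums, skew
antisymmetry, round trips, classification identities), not that real
genomes will show any particular codon ranking. `mutate_copy()`
substitutes bases i.i.d. at a fixed rate (uniform among alternatives),
which matches the uncorrected p-distance definition by construction;
at rate 0.015 on a ~18 kb genome the binomial standard error is about
0.001, and tests allow ±0.004.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally, 1-based inclusive in
  GenBank files; the conversion is an involution, tested as such.
  Origin-spanning features are stored unwrapped (`end` beyond the
  genome length) so lengths never need modular special cases.
* Unknown feature names in a GenBank file are logged and skipped, not
  fatal: deposited annotations are inconsistent, and one bad feature
  should not discard a record. Curation is explicit via
  `apply_annotation_patch()` (the package never re-annotates
  automatically).
* Reports round percentages to 1 decimal and skews to 3; all internal
  computation is full precision.
* Ties in feature sorting (equal starts) put the longer feature first,
  deterministically.
* In `analyze()`, a record failing any stage is excluded with a logged
  reason; the pipeline errors only if every record fails.

## Problem sizes

The default test and verification runs use synthetic genomes of
~16–18 kb, three-record comparisons, hotspot segments of 3–6 tokens
and TDRL searches of up to two events with segments capped at 8–12
tokens — the sizes at which the brute-force oracle remains exhaustive
and the whole suite runs in well under a minute, while matching the
scale of the real genomes the methods target.

## Known limitations

* Classification is exact token matching; it does not compute
  breakpoint or DCJ distances, and cannot place arrangements whose
  full orders are unknown.
* The TDRL search is exhaustive, not heuristic: it is intended for the
  short hotspot segments where these rearrangements occur, not for
  whole-genome permutation analysis.
* p-distances require externally built alignments (alignment
  construction is out of scope).
* Tree inference, divergence dating and de novo annotation are out of
  scope by design.
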