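---
title: "Antisense siRNA discovery and 3' tail calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antisense siRNA discovery and 3' tail calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtail)
```

## The model

Endogenous siRNAs in nematodes (and secondary siRNAs in plants) are largely
direct RdRP products synthesized antisense to their target mRNAs. They are
therefore not identifiable as discrete genome-encoded loci the way miRNAs
or piRNAs are; what identifies them is *orientation*: a population of short
reads mapping antisense to an annotated feature. `sirtail` operationalizes
exactly that pattern and makes no assumption about biogenesis (Dicer
processing, dsRNA precursors, phasing).

The procedure has three strand-aware steps.

**Candidate regions.** Features of one kind (exons by default) are taken
from a GTF/GFF. Per strand, overlapping features are merged into maximal
covered runs; merging requires at least one shared base, so bookended
features (end of one equals start of the next in half-open coordinates)
stay separate. Then every base covered by features on *both* strands is
excised from both strands' regions. The rationale: a read falling on a
base annotated on both strands is antisense to one feature and sense to
the other, so it cannot be classified by orientation. Excision happens
after merging and operates on bases, not whole features — a region may be
split in two surviving fragments, each keeping the gene-id set of its
merged cluster. When a merged region contains features of several genes,
all gene ids are reported (semicolon-joined) rather than a majority gene;
we prefer reporting ambiguity to silently resolving it.

**Antisense filtering and clustering.** Each primary, mapped alignment is
decomposed into reference-matched blocks, split at intron (`N`) CIGAR
segments, so a junction-spanning read contributes one block per exon side.
A block is kept if it shares at least one base with a candidate region of
the opposite strand; one base is the weakest faithful reading of
"mapping antisense to", and a fractional-overlap requirement would
penalize reads hanging off region edges. Kept blocks are merged by
single-linkage (transitive) interval clustering within each (chromosome,
read-strand) group. A cluster is reported when its distinct supporting
read count is at least *r* and its merged span at least *s*.

**Tail calling.** Nontemplated 3' additions (uridylation most commonly)
are recovered by re-deriving, for each read, the maximal length *L* at or
above `min_prefix` such that the read's first *L* nucleotides occur
exactly (zero mismatches; `N` matches nothing) somewhere in the genome,
on either strand. Matchability is monotone in *L* — every prefix of a
match is a match — so the search walks down from the full read length and
the first success is maximal at every reported location. The suffix
beyond *L* is the tail. Re-deriving from the read sequence, rather than
trusting soft-clip operations in the input BAM, keeps the result
independent of aligner clipping heuristics.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `r` | 10 | reads | minimum cluster support; the gate is `count >= r`. The threshold is *named* "more than r", but with a printed default of 10 a strictly-greater reading would mean "at least 11"; we treat it as a minimum and expose `strict_greater_r` for the literal reading. |
| `s` | 10 | bp | minimum merged span; inclusive. |
| `len_min`/`len_max` | 17/35 | nt | small-RNA libraries conventionally fall in this range; `c(0, Inf)` disables the filter. |
| `min_prefix` | 18 | nt | shortest admissible templated prefix; 18 nt gives near-unique matches in small genomes and is the conventional lower bound of mature small-RNA length. |
| `multimap` | fractional | — | reads whose maximal prefix matches k locations get weight 1/k; `random` (seeded) and `drop` are alternatives. Fractional avoids biased losses near repeats but makes table counts non-integer. |
| CPM threshold | 25 | CPM | inclusive (`>=`), the customary abundance floor for calling an siRNA target gene. |

Region assignment in tail mode requires *same*-strand agreement between a
call and the BED record, because sirna-mode BEDs record the read strand.
For user-supplied BEDs annotated on the genomic sense strand,
`antisense_assign = TRUE` flips the test. CPM normalization offers two
denominators because published analyses differ: the counted siRNA subset
itself (`sirna-only`, under which CPMs sum to 10^6) or the siRNA counts
plus an exon-mapped background library (`exon-background`); the
exon-mapped total is supplied as a number rather than recounted from a
second BAM.

## What the synthetic generator emulates — and what it does not

`make_fixture()` builds an i.i.d. uniform-base genome, a non-overlapping
gene layout (optionally with injected same-strand and cross-strand overlap
pairs for the region-algebra tests), and reads planted antisense to chosen
exons: evenly tiled 22-nt reads whose coverage footprint is exactly the
requested span, with tails drawn from a stated distribution and appended
as soft-clipped bases, the way a real aligner would emit them. Planted
tails are constrained to be *recoverable*: a drawn tail whose first base
continues the genome at that locus would be templated, not nontemplated,
so it is redrawn — the manifest records what was actually planted, and
downstream recovery is compared to the manifest, never to the
distribution's expectation. Sense-strand decoys inside exons and
intergenic reads are added at 10% of planted reads so the antisense filter
has nontrivial work.

The generator does not simulate sequencing error, quality variation,
RdRP biology, repeat structure, or realistic read-length distributions
(reads default to a fixed 22 nt). A green planted-recovery test therefore
establishes the correctness of the interval algebra, strand logic, gating
arithmetic and tail recovery on structurally faithful input — not
robustness to alignment artifacts or biological noise. Genome uniqueness
of 22-mers is probabilistic in a random genome; all fixtures are seeded,
so every test is reproducible bit for bit.

## Numerical and degenerate-input choices

- Coordinates are `GRanges` (1-based, closed) internally — the idiom of
  the R genomics stack — with conversion at the format boundaries: GTF/GFF
  in (1-based inclusive), BED out (0-based half-open).
- Empty inputs propagate as empty outputs (empty feature set, empty BAM
  selection, empty BED) rather than errors; a zero-region BED in tail mode
  warns and writes a header-only CSV.
- Ties and ordering: BED rows sort by (chrom, start); tail CSV rows sort
  by target with `untailed` first, tail types alphabetically, `all_tails`
  last; region names get a `.sirN` serial so duplicate gene sets stay
  unique.
- Fractional multimapper weights make the conservation identity
  (`untailed + all_tails = total`) exact only to floating point; tests
  assert it within 1e-9, integer policies exactly.
- An unstranded annotation record cannot participate in strand-resolved
  algebra and is excluded (counted in a warning) rather than guessed.
- Unstranded or missing gene attributes flag the record (`NA` gene id)
  instead of dropping it; such regions serialize with gene name `NA`.

## Known limitations

- Multiple BAMs are pooled before clustering; per-sample discovery is a
  loop over files by the caller. Whether the discovery thresholds should
  apply per sample or to the pool is application-dependent.
- Junction-spanning reads support each exon-side cluster they touch; a
  read id is counted once per cluster. Counting blocks instead of reads
  would inflate support for clusters containing both blocks of one read.
- Tail calling scans candidate prefix lengths with exact string matching;
  this is intended for desk-scale genomes (fixtures, small references,
  transposon consensus sets), not whole mammalian genomes, where an
  FM-index implementation would be the right tool.
- The abundance filter and CPM modes reproduce customary thresholds; no
  differential-expression or IP-enrichment statistics are provided.
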