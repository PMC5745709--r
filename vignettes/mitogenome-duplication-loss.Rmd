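---
title: "Gene-order evolution by tandem duplication and random loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-order evolution by tandem duplication and random loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodrl)
```

## The problem

Vertebrate mitochondrial genomes are circular molecules of roughly 16.5 kb
carrying a conserved set of 37 genes (13 electron-transport proteins, 2
rRNAs, 22 tRNAs) plus non-coding spacers and the control region. Although
the gene *content* is conserved, the gene *order* varies across lineages.
The dominant mechanism producing new orders is **tandem duplication
followed by random loss (DRL)**: a contiguous block of genes is duplicated
in tandem; for each gene, one of the two copies eventually sustains a
loss-of-function mutation, leaving selection to preserve the other; the
dead copy decays — accumulating substitutions and indels, losing its
reading frame, and eventually being deleted or degrading into
unrecognizable repetitive DNA. Which copy survives at each position
determines whether the original order is restored or a novel order is
fixed.

`mitodrl` implements the full analysis chain for studying this process on
annotated mitogenomes:

1. **genome I/O** — FASTA and a GFF3-subset feature table for circular
   genomes, including origin-wrapping features;
2. **gene orders** — circular, strand-signed orders with rotation-invariant
   comparison, and inference of every minimal single-DRL scenario that
   explains a derived order;
3. **paralog decay** — a native global affine-gap aligner, exact
   substitution/indel accounting, ORF scanning under the vertebrate
   mitochondrial genetic code, and paralog status calls;
4. **divergence** — Jukes-Cantor-corrected average between-group distance
   (D~XY~) on concatenated protein-coding genes, used to place the decay on
   a relative timescale;
5. **event mapping** — Fitch parsimony placement of gene-order states on a
   species tree;
6. **simulation** — a seeded generator of annotated mitogenomes undergoing
   duplication, sequence decay and segmental deletion, with byte-exact
   ground-truth records, so every stage is testable without external data.

The `analysis/` directory runs these stages in order as a narrative
pipeline over a simulated two-event scenario patterned on the plethodontid
salamander system in which one rearrangement is fixed genus-wide and a
second, recent duplication still segregates within a species with its
duplicates in intermediate stages of decay.

## The DRL scenario model

A `gene_order` is an ordered sequence of `(label, strand)` pairs, circular
by default; spacers (IGS) and the control region (CR) are first-class
elements because duplicated spacers are part of observed events, and
elements can carry a pseudogene mark. Circular orders are compared after
canonical rotation (anchored on `trnF`, the conventional start of the
vertebrate order).

A single DRL event on an ancestral order is a contiguous arc (the *span*)
plus a per-position retention outcome. Mechanistically, the duplicated
region reads copy 1 then copy 2 in tandem, so after losses the region must
read as the **concatenation of two subsequences, each strictly ascending in
span order**, jointly covering every span position; elements surviving only
as recognizable pseudogenes are *remnant* retentions. `infer_single_drl()`
searches every span, aligns the unchanged genes outside the span against
the derived order (at every feasible rotation for circular genomes), and
applies this two-chain test to the remaining region, with backtracking over
ambiguous label matches (repeated spacers, ancestral paralogs). Every
candidate is verified by forward replay (`drl_apply()`) before being
reported, and only containment-minimal spans are returned. Larger
alternative spans that are not supersets of a reported span are genuine
alternative explanations on a circle and are reported as such; an empty
result means no single DRL event explains the derivation. Strand changes
are never explained (DRL does not invert genes), and multi-event
compositions are out of scope — the pipeline analyses each event against
its own ancestral background.

Correctness of the search is pinned in the test suite against an exhaustive
oracle that enumerates every span and every retention pattern on orders of
length ≤ 7.

## Decay quantification

The aligner is a Gotoh three-state dynamic programme (match state plus one
affine gap state per sequence), with the horizontal gap state computed by a
running-maximum sweep so each row is a vectorised operation. Scores are
integers by default — `match +1, mismatch −1, gap open −2, gap extend −1`
per gap run of length L costing `open + L·extend` — which keeps test
oracles bit-exact; the scheme is configurable. Traceback is deterministic:
diagonal, then gap-in-query (deletion), then gap-in-reference. Optimality
is tested against brute-force enumeration of all alignments for short
pairs and against an independent library implementation on random pairs.

`summarize_differences()` counts a maximal gap run in the reference row as
one insertion event in the candidate (and symmetrically for deletions), and
defines **identity as matches / total columns, gap columns included**. This
convention is the one that exactly reproduces a published worked example:
a 682-bp reference with 30 substitutions, one 2-bp deletion and two
insertions totalling 5 bp gives 687 columns, 650 matches, identity 94.6%.
Columns containing `N` count toward the total but are neither matches nor
substitutions (reported separately as `ambiguous`).

ORF scanning uses the vertebrate mitochondrial code — stops `TAA, TAG,
AGA, AGG`, starts `ATG, ATA, GTG` — over the three forward frames
(duplicates retain their paralog's strand; reverse scanning is available
behind a flag). Within a stop-free stretch only the leftmost start is
reported, since nested ORFs add no information about residual coding
potential; ORFs reaching the sequence end are flagged open-ended.

`classify_paralog()` calls `unrecognizable` below 50% identity (a global
alignment of unrelated random DNA lands well below this),
`pseudogene` on positive disruption evidence — premature stop,
frameshifting net indel, or length ratio < 0.9 — and `intact` otherwise.
Loss of function is deliberately *not* called on divergence alone: a
full-length, undisrupted tRNA copy a few substitutions away from its
paralog is called intact, which matches the observed behaviour of
duplicate tRNAs, while a protein copy at comparable identity whose
substitutions created stop codons is a pseudogene. The intact-identity
threshold (default 0.98) only separates "effectively identical" from
"divergent but apparently functional" in the reported evidence.

## Divergence (D~XY~)

`p_distance()` uses pairwise complete deletion (columns with a gap or `N`
in either sequence are excluded). `jukes_cantor()` applies
`d = −(3/4)·ln(1 − 4p/3)`, defined for `p < 0.75`. `dxy()` averages `p`
over all between-group pairs and corrects the mean — the usual D~XY~
definition; correcting per pair before averaging is available via
`per_pair = TRUE` (the two differ negligibly at the shallow divergences
this analysis targets, ~2% per site). No confidence interval is attached;
the sampling error at L sites is approximately
`sqrt(p(1−p)/L) / (1 − 4p/3)`, which the recovery tests use as their
tolerance unit.

## Event mapping

`fitch_min_changes()` treats the gene order as an unordered multistate
character with unit cost per change (each rearrangement is one event; no
step matrix). The bottom-up set pass gives the minimum change count; a
unit-cost Sankoff pass independently verifies it and counts
most-parsimonious reconstructions; one deterministic reconstruction is
reported (ties broken toward the parent's state, then lexicographically).
Counts are rooting-invariant; placement reporting requires a root, taken
from the `outgroup` argument when the input is unrooted. Within-species
polymorphism is represented by expanding the species tip into one tip per
individual (`polymorphic_species_expand()` + `expand_tip()`); the analysis
groups individuals into their sampling populations when expanding, since
an arbitrary resolution of a within-species polytomy can artificially
split a haplotype and inflate the event count.

## The simulator and what it does (and does not) emulate

`make_reference_genome()` tiles a circular genome from segments in the
typical vertebrate gene order — 37 genes plus one intergenic spacer
(between trnT and trnP, the spacer that participates in the plethodontid
rearrangement) and a control region. Every protein gene is a valid ORF
(start codon, no internal in-frame stop, terminal stop); minus-strand
genes are stored reverse-complemented. Template lengths are typical
vertebrate values, with ND6 = 519 bp, ND1 = 960 bp and an rRNA block
(rrnS + trnV + rrnL) of 2520 bp matching the published salamander system
so worked examples carry realistic sizes; the total is ~16.5 kb.

Operations: `apply_duplication()` (tandem copy of a contiguous arc, copies
tagged `copy1`/`copy2`, length bookkeeping exact), `evolve()` (per-site
substitutions at the given rate with uniform replacement; Poisson indels
with geometric lengths, mean 2, matching the small observed indels),
`apply_segmental_deletion()` (whole segments deleted, partial overlaps
truncated and flagged), and deterministic `plant_edits()`/`edit_segment()`
for reproducing exact published edit budgets. Every event is recorded in a
truth record; `truth_replay()` re-derives the final genome byte-for-byte,
which is the simulator's core invariant and is property-tested on random
scenarios.

`aneides_preset()` composes the two-event scenario: the basal six-gene
duplication (`ND6, trnE, CYTB, trnT, IGS, trnP`) whose losses swap
ND6/CYTB; then, on that background, an eleven-gene duplication spanning
the control region, both rRNAs and tRNAs F, V and L, followed by excision
of the duplicate control region, deletion of the duplicate rRNA block down
to a 111-bp randomized remnant, decay of the duplicate ND6 (10
substitutions including a premature stop, one 2-bp insertion) and ND1
(truncation to its first 682 bp, 30 substitutions, one 2-bp deletion, 5 bp
of insertions), and light decay of the duplicate tRNAs.

What the simulator does **not** emulate: read-level data (coverage is
modelled only as a depth track consumed by `depth_ratio()`), selection or
among-site rate heterogeneity, tRNA secondary structure (functionality of
tRNA copies is proxied by identity and length, not by folding), and
tandem-repeat expansion of decayed spacers. Passing tests therefore show
that the *method* recovers planted truth under a JC-with-indels decay
process on a clean assembly — not that assembly, annotation or
repeat-resolution problems in real data are handled.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based inclusive GFF3 on
  disk. Origin-wrapping features use `end > genome length` internally and
  `end < start` on disk, so each feature stays a single row.
* The depth-ratio background uses a trimmed mean (5% per tail) to resist
  control-region pileups; the multi-copy flag threshold is 2.0 (a region
  present twice should roughly double its relative depth).
* Coding-feature overlap above 10 bp is an annotation error; smaller
  overlaps (common at mitochondrial gene junctions) are tolerated.
* Alignment traceback ties and Fitch reconstruction ties are broken
  deterministically, so identical inputs give identical outputs
  everywhere; all simulation randomness flows from one seed per run.
* Problem sizes in the shipped tests and acceptance script — e.g. 200
  random aligner pairs at length ≤ 8, DRL oracle batteries at order length
  ≤ 7, 50-replicate recovery suites, D~XY~ at 10^4 sites — were chosen as
  the smallest sizes at which the exhaustive oracles remain exhaustive and
  the Monte-Carlo tolerances are tight enough to be informative.

## Known limitations

* Only single-DRL events are inferred; composing the two events of the
  study system is done by analysing each against its own ancestral order.
* The aligner is quadratic in time and memory; it is meant for gene-scale
  pairs (≤ a few kb), not whole-genome alignment.
* D~XY~ assumes the concatenated genes are already aligned per gene across
  individuals; codon-aware alignment is not implemented, and at the
  shallow divergences targeted here a nucleotide alignment of intact genes
  is gap-free in practice.
* `classify_paralog()` on non-coding features has only identity and length
  to work with; a structurally dead but full-length tRNA copy will be
  called intact.

## A worked run

```{r, eval = FALSE}
sc <- aneides_preset(seed = 1)

# both planted spans are recovered as the smallest minimal scenarios
s1 <- infer_single_drl(sim_gene_order(sc$reference),
                       sim_gene_order(sc$aneides))
s2 <- infer_single_drl(sim_gene_order(sc$aneides),
                       sim_gene_order(sc$hardii, drop_labels = "REP"))
min(drl_spans(s1)$span_length)  # 6
min(drl_spans(s2)$span_length)  # 11

# decay of the duplicate ND6: 521 bp, ~97.7% identity, pseudogene
seg <- sc$hardii$segments
nd6f <- extract_feature_sequence(as_seq_record(sc$hardii),
  as_feature_table(sc$hardii)[seg$label == "ND6" &
                              seg$feature_class == "protein", ])
nd6p <- extract_feature_sequence(as_seq_record(sc$hardii),
  as_feature_table(sc$hardii)[seg$label == "ND6" &
                              seg$feature_class == "pseudogene", ])
classify_paralog(nd6f, nd6p)

# divergence between the two gene-order haplotypes
g <- sim_divergent_groups(d = 0.024, L = 10000, seed = 1)
dxy(g$group_a, g$group_b)
```
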