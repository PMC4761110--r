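---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comparakit)
```

`comparakit` reimplements the post-processing stages of a comparative
genomics production pipeline at desk scale. This vignette documents the
models behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## Coordinates and formats

All internal coordinates are 0-based, half-open, on the forward strand of
the named sequence. External dialects keep their native conventions at
the file boundary: AXT is 1-based inclusive with minus-strand query
coordinates in query-strand (reverse-complement) space — AXT does not
carry the chromosome length needed to flip them, so they stay in that
space internally too — and MAF reverse-strand starts are measured from
the reverse complement and converted on read using the source-size field.
Gap characters are normalised to `-` (`.` is accepted on input). Writers
sort rows by (species, sequence, start) so that re-written files are
reproducible byte for byte.

The EMF dialect emitted by `write_emf()` (one `SEQ` header line per row
segment, one output line per alignment column, optional trailing score
column) is self-documented and is *not* claimed byte-compatible with any
particular archive's EMF dumps, which are specified only loosely in
public descriptions.

Trees are held in a small recursive structure with per-node NHX tags
rather than a flat edge matrix, because the reconciliation stage
annotates every node with an event, a mapping and a consistency score and
repeatedly performs subtree surgery; `ape` remains the independent
cross-check in the test suite.

## Chains and nets

Blocks compatible in order and orientation on both genomes are joined
into chains when separated by at most `max_chain_gap` on each genome.
The default is 300 kb; chaining gap bounds are not standardised, and this
value is wide enough that desk-scale fixtures are never split by
accident while still preventing pathological mega-gaps. The chain score
is the total number of match-state bases: deterministic,
data-independent, and sufficient for greedy ranking. Substitution-matrix
rescoring is deliberately out of scope.

Netting is greedy by descending score (ties broken by reference start,
then query sequence name): a chain is placed where its reference span
fits entirely into unclaimed space (level 1) or entirely inside one
internal gap of an already-placed net (parent level + 1); otherwise it is
dropped whole. The classical netting tool truncates chains to fit
leftover space; `comparakit` does not — placement is all-or-nothing,
which keeps every placed alignment intact and makes the hierarchy easy
to reason about. This is a documented divergence. No minimum net score is
imposed, but `build_nets(min_score=)` provides a configurable floor.

## Two-pass synteny

Pass 1 (`group_collinear`) scans blocks in reference order and extends a
group while the next block is on the same query sequence, in the same
orientation, in consistent query order, and separated by at most
`max_group_gap` — 200 kb — on *both* genomes. The bound is inclusive: a
gap of exactly 200 kb still joins, "more than 200 kb" breaks. Overlapping
blocks count as separation zero; overlap handling is not specified
anywhere authoritative, and clamping at zero is the only choice that
keeps the separation measure monotone.

Pass 2 (`join_groups`) merges same-order, same-orientation groups on one
(reference, query) sequence pair when the intervening material — other
groups or plain gap — spans strictly less than `max_internal` (3 Mb) on
both genomes. The bound is strict, mirroring the "< 3 Mb" phrasing, and
the intervening span is measured as the maximum over the two genomes (a
max, not a sum — the per-genome gaps are what a rearrangement physically
occupies). Merging is transitive, so a long block absorbs a chain of
small internal inversions one at a time.

Pass 2 never joins groups of opposite orientation, even when the
flanking context agrees; an inversion therefore always surfaces as its
own block. This is the conservative reading of "same order and
orientation" and is the behaviour the tests pin down.

## Reconciliation, consistency, homologies

`reconcile()` is standard LCA reconciliation on a binary gene tree
(non-binary input is rejected rather than resolved — tree inference is
out of scope, and silently resolving polytomies would manufacture
events). The duplication consistency score is
intersection-over-union of the two child species sets. The union equals
"the species under the node", so the two natural readings of the
denominator coincide; the code states the union form explicitly.

Zero-consistency duplications — supported by no extant species — are
relabelled `dubious` by `flag_dubious()` and treated as speciations for
orthology extraction, with their pairs marked `tree_compliant = FALSE`.
For duplication nodes with consistency below 25% (strict), cross-species
pairs are rescued as non-compliant orthologues when at least one member
has no orthologue in the partner's species through regular
speciation/dubious routes. The rescue consults the LCA node only (not
other duplications on the path), and the orthologue registry is frozen
after the regular pass so the outcome cannot depend on emission order.
Rescued pairs are typed `ortholog_many2many`: copy counts at an
unreliable duplication node are themselves unreliable, so no finer claim
is made.

Gene-split detection considers pairs of same-species leaves whose
connecting path contains only duplication/dubious nodes and whose
occupied alignment column ranges overlap by at most
`max_overlap_columns` (default 10 columns — a "small overlap" that
tolerates boundary over-prediction without merging genuinely distinct
paralogues, configurable). Parts merge into one composite leaf carrying
all gene ids; the joining node is relabelled `gene_split`, and when the
merge leaves it unary (the cherry case) the node is suppressed and the
composite leaf carries the event; every merge is also recorded in
`attr(tree, "gene_splits")` so split events stay countable either way.
Merging cascades transitively, and events and consistency scores are
recomputed after surgery — scores computed before a merge would still
count the artefactual copies.

Phylogenetic dating (`date_node`, and the `age` column of
`extract_homologies`) returns the species-tree taxon a node maps to and
its calibration age when one is supplied (NHX `Age` tags or an explicit
table); extant species have age 0.

## Low-coverage projection

`project_secondary()` walks the run-length gap structure of each
top-level net block: bases aligned to reference bases are written into
that reference base's column, query-only bases are dropped and counted
(`attr(result, "dropped_insertions")` makes the information loss
measurable), reference-gap columns and unaligned columns are padded with
gaps. Existing rows and the column count are never modified. Overlapping
nets are resolved by level then score — top-level, highest score first,
first writer per column wins; child nets never contribute, so each
column receives at most one secondary base. Alignment blocks are treated
independently; whether secondary rows should be spliced across block
boundaries is left open, and nothing downstream depends on it.

## Conservation stores and element accounting

`build_store()` keeps the raw track plus 10/100/500 bp window means.
Undefined (unaligned) positions are `NA` and are excluded from means
rather than treated as zero — a zero is a strong statement about
neutrality, absence is not — and a window with no defined base is itself
undefined. Trailing partial windows average over their defined bases.
Whether production databases average over defined bases or all bases per
window is not documented; this is flagged as a divergence risk, and the
mass-conservation test covers fully defined tracks where the two
readings agree. `select_resolution()` returns the smallest stored window
`w` with `ceiling(region_length / w) <= pixels`, falling back to the
coarsest. Interval union/intersection arithmetic for element coverage
and overlap is delegated to `IRanges`; the test oracle is an independent
per-base bitmap.

## Stable identifiers

Matching operates on *shared* member sets (members present in both
releases); release-specific newcomers and retirees are ignored, and a
cluster whose shared set is empty can never inherit an id. Perfect
matches keep id and version. The greedy pass orders candidate links by
new-cluster size descending (favouring larger families), then overlap
descending, then old id ascending, then the lexicographically smallest
member of the new cluster — the published criterion names only the first
key, so the remainder is this package's documented total order, chosen
to make the assignment independent of input iteration order. Inherited
ids get a version bump; unmatched clusters get fresh ids at version 1.
Ids on the losing side of a merge are retired permanently rather than
banked. External classification ids (e.g. an RNA family accession) can
serve as pass-through stable ids simply by using them as the id on the
previous release's clusters.

## Family naming

Descriptions are normalised (lowercase, punctuation stripped,
isoform/fragment suffixes removed) and filtered by a documented
stop-pattern list (empty, "uncharacterized", "hypothetical protein",
"novel protein", "open reading frame", cDNA clone labels, bare
accession-like tokens). The consensus is the most frequent normalised
description among informative entries, ties broken toward the longer
description then lexicographically. The score counts informative entries
whose description contains or is contained by the consensus —
bidirectional containment is the concrete reading of "or part of it" —
over informative entries only (the 40% requirement is scoped to proteins
*with* an informative description; counting all members would conflate
annotation coverage with naming confidence). At 40% and above the family
takes the consensus name, strictly below it is `AMBIGUOUS`, and with no
informative entries it is `UNKNOWN` at score 0. Note `UNKNOWN` and score
0 coincide by construction: any informative entry matches itself, so a
non-empty informative set always scores above zero.

## Synthetic fixtures

Every generator is a pure function of `(seed, parameters)`; each draws
from its own stream (seed plus a fixed per-generator tag) so adding
generators never perturbs existing fixtures, and the caller's RNG state
is restored afterwards.

* `simulate_rearranged_genomes()` partitions a 20 Mb reference into
  `n_rearrangements + 1` segments of at least 1 Mb — matching the
  regime where vertebrate syntenic regions are mostly megabase-scale —
  translocates each to its own query scaffold (inverting with
  probability 0.3), and cuts segments into blocks with jitter gaps up to
  150 kb, safely inside the 200 kb grouping bound. Placing each segment
  on its own scaffold makes the planted truth unambiguous: adjacent
  segments can never merge by coincidence.
* `simulate_gene_family()` runs a birth–death process along the species
  tree (Poisson duplications, Bernoulli losses per lineage per branch)
  and returns the true gene tree, a synthetic family alignment, the
  event log, and the definitional homology pair set computed from the
  *known* events — not from any reconciliation, so recovery tests
  compare two genuinely independent routes. Planted gene splits bisect a
  leaf's row into complementary, non-overlapping partial rows joined by
  a spurious duplication.
* `simulate_release_pair()`, `simulate_score_track()` and
  `simulate_descriptions()` plant split/merge fractions, sparse random
  tracks, and consensus fractions whose expected outcomes are known by
  construction.

The generators guarantee *structural* truth, not evolutionary realism:
no substitution model, no indel length distribution, no rate variation,
no assembly error beyond the planted splits. Passing the recovery tests
therefore shows the algorithms implement their definitions exactly; it
does not show how the thresholds behave on real genomes, where block
fragmentation, segmental duplication and annotation noise are far
messier.

## Problem sizes and numerical notes

The test suite runs the reconciliation oracle exhaustively over all gene
tree shapes times all species assignments for up to 4 leaves over a
4-species tree, and over seeded random samples of shapes and assignments
for 5–7 leaves (the full 7-leaf space is ~10^8 trees; the sampled check
covers the same size range against the same oracle). Netting is checked
against a flat greedy oracle on up to 5 chains, interval accounting
against a per-base bitmap on 200 random intervals over 20–30 kb, and
conservation stores against a re-mean on 10 000 random scores. Synteny
truth recovery uses 20 Mb genomes with 5–7 planted segments. These sizes
keep the whole suite under a minute while leaving each property space
densely covered.

Ties are broken deterministically everywhere (documented per function);
degenerate inputs — empty block lists, empty tracks, zero-row MAF
blocks, all-gap projections — either produce the natural empty result or
raise a contract violation naming the offending entity, never silent
misbehaviour.
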