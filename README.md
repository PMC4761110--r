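# comparakit

Comparative genomics production pipelines turn raw whole-genome alignments
and gene families into the reference resources most evolutionary analyses
rely on: pairwise alignment nets, chromosome-scale synteny maps,
reconciled gene trees with orthologue/paralogue calls, per-base
conservation tracks, and identifiers that stay stable from release to
release. The algorithms behind those post-processing stages are simple to
state but easy to get subtly wrong at the boundaries. `comparakit`
reimplements them as a desk-scale, fully tested R toolkit, together with
deterministic synthetic-data generators, so every stage can be exercised,
checked against independent oracles, and run end to end without
downloading a single genome.

What is in scope is the *post-processing*: the toolkit consumes alignment
blocks, trees and score tracks; it does not run an aligner, infer trees,
or compute conservation scores.

## The algorithms

**Chains and nets.** Local alignment blocks that are compatible in order
and orientation on both genomes are joined into *chains*; greedy selection
by score then keeps the best chain in each reference region as a *net*,
with weaker chains allowed to nest inside the internal gaps of a stronger
net (one level deeper per nesting). Chains are placed whole or dropped —
no truncation.

**Two-pass synteny.** Pass 1 groups consecutive collinear blocks separated
by at most 200 kb on either genome (inclusive bound). Pass 2 joins the
nascent groups into macro-synteny blocks across internal rearrangements
spanning strictly less than 3 Mb on either genome.

**Reconciliation and homology.** Each gene-tree node is mapped to the
species-tree LCA of the species beneath it; a node whose mapping equals a
child's mapping is a duplication, otherwise a speciation. Duplication
nodes are scored with the *duplication consistency score*

```
consistency(v) = |S(left(v)) ∩ S(right(v))| / |S(left(v)) ∪ S(right(v))|
```

where `S(·)` is the species set under a child. Zero-consistency
duplications are relabelled *dubious* and treated as speciations for
orthology. Every gene pair is typed by its LCA node: speciation/dubious →
orthologue (`one2one`/`one2many`/`many2many` by copy counts), duplication
→ paralogue; cross-species pairs under duplications with consistency below
25% are rescued as non-tree-compliant orthologues when a member has no
orthologue in the partner species. Same-species genes with non-overlapping
alignment footprints connected only through duplication nodes are merged
as *gene splits* (assembly artefacts), allowing a 10-column overlap by
default.

**Low-coverage projection.** A fragmented genome is placed into an
existing reference-anchored multiple alignment via its pairwise nets
against the reference: bases aligned to reference bases land in that
base's column, insertions relative to the reference are dropped (and
counted), reference-gap columns are padded. Existing rows are never
touched; the new row is a mosaic of segments, possibly from many
scaffolds.

**Conservation stores, stable IDs, family names.** Score tracks are kept
at 1 bp plus 10/100/500 bp window means, and the display resolution is the
smallest window giving at most one value per pixel. Cluster stable IDs are
kept on perfect shared-membership matches, otherwise resolved greedily in
favour of larger families with a version bump, and minted fresh at
version 1. Protein families are named by the most frequent informative
description; below a 40% consensus score the family is `AMBIGUOUS`, with
no informative description at all it is `UNKNOWN`.

## Worked example

```r
library(comparakit)

st <- parse_newick("((((human,mouse)eug,dog)eut,chicken)amn,zebrafish)vert;")
gt <- parse_newick("(((h1_human,(m1_mouse,m2_mouse)),d1_dog),c1_chicken);")
rt <- flag_dubious(reconcile(gt, st))
extract_homologies(rt)
```

```
        gene1    gene2 species1 species2                   type taxon age tree_compliant
1  c1_chicken   d1_dog  chicken      dog       ortholog_one2one   amn  NA           TRUE
2  c1_chicken h1_human  chicken    human       ortholog_one2one   amn  NA           TRUE
3  c1_chicken m1_mouse  chicken    mouse      ortholog_one2many   amn  NA           TRUE
...
10   m1_mouse m2_mouse    mouse    mouse within_species_paralog mouse   0           TRUE
```

The mouse-specific duplication makes `m1`/`m2` within-species paralogues
dated to the mouse lineage, and turns every mouse orthology into
`one2many`; all other pairs are one-to-one orthologues dated by their
species-tree taxon (`eug`, `eut`, `amn`).

Synteny from a simulated genome pair with two planted rearrangements:

```r
sim <- simulate_rearranged_genomes(seed = 42, genome_length = 1e7, n_rearrangements = 2)
synteny_table(build_synteny(sim$blocks))
```

```
  ref_seq ref_start  ref_end   qry_seq qry_start qry_end orientation n_groups
1    chr1         0  1062347 scaffold1         0 1062347        same        1
2    chr1   1062347  5369639 scaffold2         0 4307292        same        1
3    chr1   5369639 10000000 scaffold3         0 4630361        same        1
```

Each planted segment is recovered as exactly one block. The same
operations are scriptable from a shell via `inst/cli/compara-kit`
(subcommands `chain`, `net`, `synteny`, `reconcile`, `homologies`,
`project`, `conswin`, `overlap`, `stableids`, `famname`, `simulate`);
every run writes a JSON manifest recording the thresholds in force and
input/output digests.

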