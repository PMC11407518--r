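---
title: "Conserved signature indels and core-protein phylogenomics with csindel"
author: "csindel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved signature indels and core-protein phylogenomics with csindel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csindel)
```

## The scientific problem

Bacterial genera and families are increasingly demarcated with two kinds of
whole-proteome evidence. The first is quantitative: phylogenomic trees built
from concatenated core proteins, and the average amino-acid identity (AAI)
between genome pairs, which separates clades by overall divergence. The
second is discrete: **conserved signature indels (CSIs)** — insertions or
deletions of fixed length, lying in otherwise conserved protein regions,
that are shared by all members of a clade and absent outside it. Because a
fixed-length indel at a precise position is an improbable event to occur
twice independently, a CSI behaves as a molecular synapomorphy: a one-bit
diagnostic character for clade membership that complements branch support
values.

`csindel` implements this workflow end to end: core-family construction
from proteomes, per-family alignment, trimming, concatenation into a
partitioned super-matrix, AAI with per-clade summaries and a
neighbor-joining diagnostic tree, and a CSI scanner with the bookkeeping
(isolated exceptions, missing homologues) that real surveys need. A
synthetic proteome generator plants CSIs with a ground-truth manifest so
that every stage can be validated quantitatively.

## Core families

`clusterGreedy()` emulates greedy incremental clustering as used by
CD-HIT-style tools. Sequences are sorted by decreasing length (ties broken
by sequence id so the procedure is deterministic) and each sequence joins
the first existing family whose *representative* (the founder, which by the
sort order is the longest member) it matches at both thresholds:

* **identity** — exactly matching columns divided by alignment columns in
  which both sequences carry a residue, under global Needleman–Wunsch
  alignment with BLOSUM62 scores and affine gap penalties (open 10,
  extend 1; a gap of length $L$ costs $10 + L$);
* **coverage** — both-residue columns divided by the length of the
  *shorter* sequence.

Both thresholds default to 0.5 ("homologues sharing at least half their
length and identity"). Published protocols leave two details open, and we
fix them explicitly: identity is measured over aligned both-residue columns
(not over the shorter sequence), and coverage is measured against the
shorter sequence, which is the behaviour of the clustering tools this
emulates. An unknown residue `'X'` never counts as a match anywhere in the
package: an unknown must not create signal.

`selectCore()` applies the core criterion — keep families with members in
at least a fraction (default 0.8) of the genomes — and picks one sequence
per genome per family: the member most identical to the family
representative (ties broken by length, then id). This one-row-per-genome
rule is what makes concatenation well defined. `familiesFromBlast()`
offers the alternative entry point used in CSI surveys: single-linkage
components over imported BLAST tabular hits below an e-value threshold
(default 1e−20), with every edge re-checked against the same
identity/coverage thresholds.

## Alignment, trimming, concatenation

`alignFamily()` is a progressive aligner: a UPGMA guide tree from cosine
distances between 3-mer count vectors, then profile–profile global
alignment with affine gaps, column scores being the frequency-weighted
mean BLOSUM62 score (gap characters carry zero mass). Tie-breaks in the
traceback prefer the diagonal, then a gap in the second profile, making the
output deterministic; de-gapping any row reproduces its input exactly.
External alignments of the same members can be imported with
`readMsaFasta()` and behave identically downstream — the aligner is a
convenience, not a dependency of the statistics.

`trimAlignment()` removes columns whose gap fraction exceeds a threshold
(default 0.2). Published pipelines typically use heuristic trimmers whose
behaviour depends on unstated modes and versions; a pure gap-fraction rule
is fully specified, reproducible, idempotent, and equivalent on clean
alignments. A column with no gaps is never removed, and removing every
column is an error that suggests raising the threshold.

`concatenateMsas()` joins trimmed families in lexicographic family-id
order (the field has no convention here; determinism decides), filling
genomes absent from a family with `'-'` across that partition, and emits
the partition table (1-based inclusive column intervals) alongside. The
super-matrix exports as aligned FASTA or relaxed PHYLIP for external
maximum-likelihood inference — tree building itself is deliberately out of
scope.

## Average amino-acid identity

`aaiPair()` counts, over super-matrix columns where both genomes carry a
residue other than `'-'` and `'X'`, the fraction of exact matches, as a
percentage. Computing AAI from the trimmed core alignment (rather than
from genome-wide reciprocal BLAST hits) keeps it consistent with the tree
and less affected by horizontal transfer; by construction it equals the
length-weighted mean of per-family identities, an identity the test suite
asserts to 1e−12 relative error. Pairs with no qualifying columns are
reported `NA` rather than 0 or 100. `cladeAaiSummary()` reports min, mean
and max per clade pair — unordered member pairs for intra-clade rows
(singleton clades are omitted with a message), all cross pairs for
inter-clade rows. `njTree()` runs classic neighbor joining on
$d = 1 - \mathrm{AAI}/100$ with negative branch lengths clamped to zero;
it is a diagnostic of clade separation, not a substitute for
maximum-likelihood inference.

## The CSI scanner

The scanner decomposes into three tests, each exported for independent use.

**Block finding** (`findIndelBlocks()`). A candidate indel is a maximal
column interval over which every row is entirely gap or entirely residue,
with at least one row in each state. Strict block consistency is
deliberate: genuine CSIs are indels of *fixed* length, and ragged,
partially gapped intervals are the signature of alignment noise, not of a
shared indel. Maximality means extending the interval one column either
way breaks consistency. Admissible lengths default to 1–10 columns
(observed CSIs at genus/family rank are mostly 1–4 aa).

**Clade specificity** (`classifyBlock()`). All clade members present in
the family must share one state; any within-clade disagreement fails
outright — exceptions can never rescue it. Genomes outside the clade that
share the clade state are the *isolated exceptions*; up to
`maxExceptions` (default 0) are tolerated and reported, mirroring the
footnote convention of published CSI tables. At least one outside genome
must hold the opposite state, otherwise there is no contrast to call an
indel against. Clade genomes with no row in the family are reported as
*missing homologues*; they neither support nor refute specificity, are
tolerated when `allowMissing = TRUE`, and at least two clade rows must
remain — a consequence is that singleton clades cannot host a CSI under
the defaults, a deliberately conservative stance. The clade state decides
the type: residues in the clade where outgroups are gapped is an
insertion; the reverse is a deletion.

**Flank conservation** (`flankConservation()`). Each side of the block
must contain at least `minConservedFlank` (default 4) conserved columns
within the neighbouring `flankWindow` (default 40, configurable to 50)
columns. A column is conserved when it is gap-free and a single residue
other than `'X'` reaches frequency `conservedFraction` (default 1.0 —
strict identity; 0.8 is offered for noisier data, the conservative default
being the stricter reading of "conserved"). Windows are clamped at
alignment edges, so a block too close to an edge cannot pass. Whether the
classical "neighbouring 40–50 aa" is meant in alignment columns or
reference residues is ambiguous in the literature; we use alignment
columns for the test and report the flanked region as a residue span, so
both readings are visible in the output.

All coordinates in emitted `CsiRecord`s are 1-based inclusive, matching
how such tables are printed: `blockStart`/`blockEnd` in alignment columns,
and `refStart`/`refEnd` as the residue span of block plus flank windows in
the reference sequence — the clade member with the lexicographically
smallest genome id. `validateCsi()` re-derives every claim of a record
and is the package's own audit trail: the generator's manifest must pass
it, and a tampered record must fail it.

One deliberate substitution relative to classical CSI surveys: the
confirmation step that re-queries each candidate against a comprehensive
public protein database is replaced by specificity within the supplied
genome set, with `exportCsiRegions()` writing each flanked region as FASTA
for manual external checking. This keeps the pipeline deterministic and
free of network dependencies; users surveying real genera should still run
that external check.

## The synthetic generator and what it does (not) emulate

`simulateProteomes()` generates families on a star-of-clades tree: a root
sequence drawn i.i.d. uniformly over the 20 amino acids, one ancestor per
clade at per-site substitution fraction `betweenRate` from the root, one
sequence per genome at `withinRate` from its ancestor. Substitutions
always change the residue, uniformly over the 19 alternatives, so two
same-clade genomes match at a site with probability
$(1-p)^2 + p^2/19$ — a closed form the tests exploit directly. This
i.i.d. model is chosen *because* it is analytically tractable; the biology
of CSIs does not constrain it.

The defaults are the package's standard study design: 30 genomes in five
clades (8, 6, 5, 4, 7), `withinRate` 0.03, `betweenRate` 0.12, 200
families of 150–400 aa. These rates put intra-clade AAI in the low 90s
and inter-clade AAI near the low 70s — inside the spread reported for
real congeneric versus confamilial proteomes (roughly 79 to >95% within
clades, 58–81% between) while leaving a clean margin between the two
distributions. Validation problem sizes (10 seeds for recovery, 50 for
tree monophyly, hundreds of random alignments for the brute-force
equivalence check) are the package's choice of a thorough-but-quick
default; all are driven from user-visible seeds.

`plantCsis()` plants at most one CSI per family: an insertion adds one
motif, drawn once and shared identically by all clade members (matching
the conserved appearance of real CSIs); a deletion removes the stated run
from all clade members. The `minConservedFlank` columns adjacent to the
block on each side are reverted to the root residues in **all** genomes —
the minimal intervention that guarantees detectability under the default
parameters without sanitising the rest of the flank window. Planting
positions must leave a full flank window of residues on both sides.
Optionally a named outside genome receives the clade state (an isolated
exception) and a named genome loses its family member (a missing
homologue); both are recorded in the `TruthManifest`, whose records are
asserted against `validateCsi()`.

What the generator does **not** emulate: rate heterogeneity across sites
and lineages, realistic substitution matrices, background indel processes
(available only as a simple per-site deletion option, default off),
paralogy, gene transfer, domain rearrangements, and alignment error.
Passing tests therefore demonstrate that the *logic* of the pipeline is
exact — recovery of what was planted, agreement with brute-force
enumeration and closed forms — not that real alignments are this clean.
On real data the flank-conservation and strict-block rules are precisely
the filters that absorb most of that extra noise, at the cost of missing
CSIs in fast-evolving regions.

## Numerical choices and degenerate inputs

* Gap character is `'-'` everywhere; `'.'` in inputs is normalised on
  read. Missing genomes in the super-matrix are encoded `'-'`, not `'?'`
  (exporters may translate).
* `'X'` never matches and never counts as conserved; columns containing
  `'X'` in either row are excluded from both AAI numerator and
  denominator.
* Ties: greedy clustering order and family representatives break ties by
  sequence id; the per-genome representative by identity, then length,
  then id; aligner traceback prefers diagonal, then gap-in-second-profile;
  concatenation orders families lexicographically; NJ inherits `ape`'s
  deterministic joins and clamps negative branch lengths to zero.
* Degenerate inputs fail loudly: single-member families cannot be aligned;
  trimming away every column, unresolvable sequence ids, duplicate FASTA
  ids, residues outside the 20 letters plus `'X'`, two rows for one genome
  in a family, and missing AAI values for tree building are all errors
  with actionable messages. A terminal `'*'` (stop codon) is stripped
  silently on read.

## Known limitations

Singleton clades cannot carry a CSI under the two-clade-rows rule;
nucleotide-level indels, conserved signature proteins, HMM-based homology
and automatic clade proposal are out of scope (clades are user input, as
they are in practice, informed by trees and reference taxonomies). The
progressive aligner is adequate for the package's validation scale but is
not tuned for speed on thousands of large families; for production-scale
surveys, align externally and import. Exact reproduction of any particular
published survey's counts is not a goal: those depend on database versions
and unstated tool settings, which is exactly the reproducibility gap this
package is meant to close going forward.
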