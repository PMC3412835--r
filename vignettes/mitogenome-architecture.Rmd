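---
title: "Methods: mitogenome architecture, skew, repeats and rearrangement"
author: "mitoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome architecture, skew, repeats and rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

This vignette documents the models, conventions and design decisions behind
`mitoarch`, in the spirit of a methods section: what each stage computes,
under which assumptions, which knobs matter, and where the edges are.

## The genome model

An `AnnotatedGenome` is a circular molecule with 1-based inclusive
coordinates — the convention of GenBank records and published feature
tables — and strand-aware features. A feature may wrap the origin at most
once, encoded as `end > genomeLength`; all coordinate arithmetic
(`featureLength()`, `extractRegion()`, spacer accounting) treats positions
modulo the genome length, so results do not depend on where the origin was
placed. Sequences are plain A/C/G/T/N strings on the major strand, 5′→3′;
minor-strand features are extracted as reverse complements.

Validation (`validateAnnotation()`) is deliberately non-fatal: published
feature tables contain survivable inconsistencies (the shipped earwig
annotation carries an anticodon coordinate outside its gene span), and the
right behaviour is to report findings, not to refuse the record. Errors are
reserved for claims the sequence itself contradicts (anticodon or start
codon not present at the annotated position) and out-of-range coordinates;
incomplete stop codons (`T`, `TA`, completed by transcript polyadenylation)
and unusual start codons are warnings.

Intergenic accounting walks consecutive gene pairs — protein, tRNA and rRNA
features only — in circular order, including the wrap-around pair. Repeat
and control regions are excluded from the chain: a tandem repeat unit lies
*inside* an intergenic spacer (the shipped genome's 2,856-bp repeat inside
the 2,888-bp trnI–trnW spacer), and the A+T-rich region is conventionally
reported separately from the spacer census, so the record that spans it is
flagged `is_control_region` and left out of the positive-spacer summary.
Signed lengths follow `start(downstream) − end(upstream) − 1`: positive
spacer, zero abutting, negative overlap.

## Strand asymmetry

AT-skew = (A−T)/(A+T) and GC-skew = (G−C)/(G+C). A zero denominator yields
an explicit `NA` ("undefined"), never NaN. Classification is a pure
function of the signs (positive AT-skew reads "A", negative "T"; GC-skew
likewise "G"/"C"; zero or undefined GC-skew maps to the `*_only_gc_zero`
categories and zero AT-skew to `undefined`), reproducing the categories
used in strand-asymmetry surveys.

Partitioned skew reports four quantities: the whole genome (the entire
major strand — non-coding regions and the control region included, since
the statistic describes the strand, not the genes), all protein genes, and
the major- and minor-strand protein genes separately. Each gene partition is
computed on the concatenation of *coding-strand* (sense) sequences: a
minor-strand gene contributes its own sense composition rather than a
re-read of the major strand. This is the convention under which a genome
with reversed asymmetry shows T- and G-skew on the major strand and A- and
C-skew on the minor-strand gene set. Codon-position composition is anchored
at each annotated start codon and drops the trailing incomplete codon left
by incomplete stops. Printed values round half-away-from-zero to 3 decimals
(1 decimal for percentages), matching how such tables are typeset.

## Tandem repeat units

For each candidate period $\ell \in [\text{minUnit}, \text{maxUnit}]$ the
sequence is compared with itself at lag $\ell$. A repeat candidate is a
maximal stretch over which every sliding $\ell$-window of that
self-alignment — equivalently every adjacent-copy comparison — has identity
$\ge$ `minIdentity`. A plain identity threshold lets a boundary copy absorb
up to $1-\text{minIdentity}$ of flanking noise, so boundaries are then
trimmed to the maximum-scoring segment of the self-alignment (match $+1$,
mismatch $-3$; the penalty makes random flank, which matches at about 25%,
strictly score-negative while copies at the identity threshold remain
positive). The trimmed stretch of length $s$ holds
$c = \lfloor s/\ell \rfloor$ full copies and a partial copy of
$p = s \bmod \ell$ bp — the leftover lag-matched repeat content, which is by
construction a prefix of the unit, mirroring the "partial copy of the
beginning of the repeat" structure of real control-region repeats. The
consensus is the column-wise majority over full copies (ties broken
alphabetically).

Two deterministic resolution rules produce the final call set. *Harmonic
suppression*: a repeat of period $\ell$ is re-detected at overlapping
multiples of $\ell$ with near-identical spans; an overlapping larger period
is kept only when it explains at least one extra unit of the smaller
period's sequence. *Greedy acceptance*: longest span, then smallest unit,
then leftmost start. Defaults (`minUnit = 10`, `maxUnit = 600`,
`minCopies = 2`, `minIdentity = 0.85`) span the unit lengths reported in
insect control regions (135-, 189-, 297- and 554-bp units) while excluding
homopolymer noise.

A single flanking base that happens to match the consensus is
indistinguishable from repeat content, so the reported partial length can
exceed a planted value by a base or two depending on the flank draw; unit
length and copy number are robust to this, which is why the recovery
properties in the test suite pin the period exactly but treat the partial
as data-dependent. Indel-containing (length-impure) repeats are out of
scope: identity is computed on ungapped columns only.

## Non-coding motif scanning

Secondary structure is treated combinatorially, not thermodynamically: the
scanners assert what can base-pair under arm-length constraints, not how
stably it folds. Free-energy minimisation is intentionally outside the
package's scope; the structural grammar is the contract.

The cloverleaf grammar: 7-bp acceptor stem; 0–2-nt connector; DHU arm with
3–4-bp stem and 4–12-nt loop, or — when `dhuOptional` — a bare 7–14-nt DHU
loop (the form of serine-AGN tRNAs); 0–1-nt connector; 5-bp anticodon stem
with an exactly 7-nt loop, the anticodon read at loop positions 3–5 (5′→3′
on the coding strand); a 3–21-nt variable loop (the upper default
accommodates the unusually long 19–20-nt variable loops seen in some insect
tRNAs); TψC arm with 3–5-bp stem and 4–9-nt loop; the acceptor 3′ side.
Pairing is Watson–Crick plus G-U wobble, with at most `maxStemMismatch`
(default 1) mismatches per stem — published secondary-structure figures for
mitochondrial tRNAs routinely show both wobble pairs and imperfect stems.
Both strands are scanned; per (start, end, strand) only the best folding
(fewest mismatches, most paired bases) is kept, and candidates are ranked
by the same key. The isotype is the translation, under the invertebrate
mitochondrial genetic code, of the codon complementary to the anticodon.

`scanRegionForTrnaLike()` pairs each candidate with the genome's own
annotated tRNA sharing its anticodon (falling back to highest alignment
identity) and reports one hit per locus by default, so a repeat region with
one planted cloverleaf per copy yields exactly one hit per copy. Alignment
identity uses Needleman–Wunsch with match 1, mismatch 0, linear gap −1;
among score-optimal alignments the tie-break (most matched columns, then
shortest alignment) is symmetric in the two sequences and fully
deterministic. Published tRNA-like similarity percentages rarely state
their alignment method, so identity values are comparable within this
package but only approximately against other software.

Stem-loops are maximal inverted repeats per loop interval (loop 3–`maxLoop`
nt, outermost position must truly pair, mismatch budget inside), annotated
with the conserved control-region flanks — `TATA` ending within 10 nt
upstream and `G(A)nT` (n ≥ 2) starting within 10 nt downstream — that mark
replication-origin-associated hairpins. Poly-T runs are maximal T-stretches
containing at most `maxInterruptions` non-T bases, counted inclusively, the
minor-strand replication-initiation signal of many insects. ORF scanning
uses the mitochondrial start set (ATG/ATA/ATT/ATC/TTG/GTG), TAA/TAG stops
(TGA is tryptophan in this code), and optionally a trailing `T`/`TA` flush
with the region boundary; the amino-acid length counts codons from the
start codon inclusive up to the last full codon before the stop, the
convention under which a 131-nt region reading TTG + 42 codons + TA encodes
43 residues.

## Gene-order rearrangement

A `GeneOrder` is a signed circular sequence over the canonical 37 genes
plus the control region; equality is rotation-invariant, and orientation is
the coding strand under the major-strand convention. The built-in reference
is the ancestral insect arrangement (identical to *Drosophila*).

Classification proceeds in three steps. First, the *in-place backbone*: the
largest gene set whose restriction of the observed circular order (labels
and orientations) equals the restriction of the ancestral order. It is
computed exactly by exhaustive search over flag sets seeded by broken
signed adjacencies and orientation changes, smallest flag set first, with
deterministic tie-breaking: prefer flag sets that keep protein-coding and
rRNA genes as anchors, then the lexicographically smallest set. The control
region always anchors the backbone. Second, *adjacent-swap expansion*: when
a flagged gene and a backbone neighbour form an adjacent transposition
(either one could equally have been flagged), both genes are reported as
moved. This follows how rearrangement maps are drawn — both members of a
swapped pair are marked as translocations — while the event table still
counts the swap as a single duplication/random-loss event, matching how
mechanisms are counted ("one identical tRNA translocation" for a
lineage-diagnostic two-gene swap). A pure minimal-flag rule would
arbitrarily mark only one member of a swap; the symmetric rule was chosen
deliberately and is the package's documented convention. Third, per-gene
classes: orientation unchanged and context changed → `translocated`;
orientation flipped within the same inter-backbone interval (identical
nearest backbone neighbours on both sides) → `local_inversion`; orientation
flipped and moved → `shuffle_with_remote_inversion`. "Position" is thus
defined by adjacency context relative to the backbone, not by absolute
index — circular orders have no canonical origin.

Operators model the mechanisms: `applyDupLoss()` (tandem duplication of a
contiguous block followed by deletions that leave each gene exactly one
survivor), `applyInversion()` (reverse and flip — an involution), and
`applyTranslocation()` (move intact, optionally inverting in transit).
`breakpointCount()` counts signed circular adjacencies of one order absent
from the other, identifying an adjacency with its reverse-complement
reading. Beyond breakpoints, no rearrangement-distance machinery (sorting
by reversals, DCJ) is included, and event *order* is never inferred — with
independent events there is no way to determine their sequence, so the
package reports classes, not histories.

## Synthetic data: what it emulates, and what it does not

`generateGenome()` builds a fully annotated circular genome from a single
seed: background sequence i.i.d. from per-strand base probabilities (the
default mirrors the shipped genome's published composition, A 28.2%,
C 13.9%, G 17.6%, T 40.3% — a T- and G-skewed major strand); protein genes
with valid mitochondrial start/stop codons and stop-free interiors, at the
published gene lengths so synthetic genomes are realistic in scale; tRNAs
built constructively from the cloverleaf grammar with the correct anticodon
per label (serine-AGN DHU-less), which guarantees detectability by the
scanner; a tandem repeat unit with configurable (unit, copies, partial,
divergence), optionally carrying one planted cloverleaf per copy; optional
control-region motifs (a flanked stem-loop and a poly-T stretch); and an
optional rearrangement script applied to the gene order.
`generateOrder()` emits rearranged orders together with the per-gene ground
truth their script implies; events must be non-interacting (disjoint
two-gene guard zones), otherwise the ground truth would be ambiguous and
the generator refuses.

What passing tests on this generator show: coordinate arithmetic, detector
contracts, and classifier correctness under planted truth. What they do not
show: behaviour on real sequence, whose repeats contain indels, whose
tRNAs deviate from the grammar's arm lengths, whose composition is not
i.i.d., and whose rearrangements can interact. The generator is a
verification instrument, not an evolutionary simulation — there is no
substitution model, no tree, no selection.

## Numerical conventions and test scale

- Identity thresholds are compared with a `1e-12` slack so that exact
  ratios at the threshold are not lost to floating-point rounding.
- All tie-breaks (repeat resolution, cloverleaf ranking, backbone choice,
  consensus ties, alignment tie-breaks) are total orders, so every output
  is deterministic; generator output is byte-identical for equal seeds.
- Degenerate inputs fail fast with messages (empty tables, malformed
  coordinates, duplicate gene names, gene-set mismatches, infeasible
  packing) except where the contract is explicitly non-fatal
  (`validateAnnotation()`).
- The test suite verifies detectors against independent brute-force oracles
  at small scale (two-letter repeat instances up to 60 bp; exhaustive
  alignment enumeration on 4-mers; stem-loop enumeration on a 120-mer;
  breakpoint adjacency sets on orders of up to 7 genes) and planted-recovery
  properties at moderate scale (100 repeat constructions at up to 5%
  per-copy divergence; 50 cloverleaf constructions; 200 random rearrangement
  scripts; 100-kb composition samples), sizes chosen so the whole suite
  completes in about a minute on one CPU while keeping the statistical
  assertions (3-standard-error bands, ≥95/100 recovery) meaningful.

## Known limitations

- Repeat detection is ungapped; indel-containing repeat families are not
  modelled, and nested repeat structures are resolved greedily rather than
  jointly.
- The cloverleaf scanner trades thermodynamic realism for exhaustive
  combinatorial coverage; it will fold things a free-energy model would
  reject, which is the appropriate bias for flagging tRNA-*like* sequences
  whose functionality is unknown anyway.
- The rearrangement classifier is exact for the small flag sets that real
  mitogenome comparisons produce; a pathological order rearranging most of
  its genes would make the exhaustive backbone search expensive.
- The published total of non-coding nucleotides in the shipped annotation
  differs by one from the value recomputed from its own coordinates
  (3,783 bp); the package always reports the recomputed value. Similarly,
  the repeat region's span follows its annotated coordinates
  (2,856 = 21 × 135 + 21), the self-consistent reading of the published
  table.
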