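---
title: "Methods and design of rbpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of rbpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpkit)
```

rbpkit is a toolkit for curated RNA-binding-protein (RBP) motif data: a
record store with normalization and deduplication rules, position
probability matrices (PPMs) with a per-motif quality score, an FM-index
scanner with genomic-functional-context enrichment scores, and extraction
of binding-site motifs from protein–RNA 3D complexes. This vignette
explains each model, its assumptions, the tunable parameters, and the
design decisions taken where the underlying rules leave room.

## Motif records and the distinct-entry rule

A motif record couples one IUPAC motif (4–12 nt, RNA alphabet) to one RBP,
one experiment type and one organism, with provenance (PubMed id, binding
domain, gene id) and an optional quality score. Two conventions keep the
store non-redundant:

* **Name normalization.** Upstream motif collections disagree on gene
  nomenclature (the human CELF1 protein is called CUGBP1 in some sources).
  `normalizeRecords()` rewrites gene names to their official form using a
  per-organism synonym table and moves the replaced alias into the
  record's synonym list, so later deduplication and synonym queries work.
  The mapping is table-driven rather than a live UniProt lookup so that
  everything runs offline and reproducibly; official names are fixed
  points, which makes normalization idempotent.
* **Distinctness.** A motif is a distinct entry if it binds a different
  RBP, or was identified with a different experimental approach, or in a
  different organism. The deduplication key is therefore exactly
  `(motif, gene_name, experiment, organism)` — deliberately *not*
  `gene_id`, which is redundant with the gene name once records are
  normalized. The canonical example: `ACGCGCC` bound by both SRSF1 and
  RBM8A stays two entries.

Queries combine criteria conjunctively (all given criteria must hold),
matching the way a faceted search over such a table behaves. No
canonicalization of experiment strings is attempted: "SELEX" and
"in vitro selection" from different sources remain distinct experiment
labels, because no authority defines the merge.

`T` is unified to `U` at ingestion and everywhere else; all matching is on
the RNA alphabet, since RNA motifs are scanned against RNA or DNA input
interchangeably.

## PPMs and the quality score

For motifs backed by selection experiments (SELEX, RNAcompete), the
aligned *winner sequences* define a PPM by per-position empirical
frequency — no pseudocounts, because the score below is meant to be a pure
product of observed frequencies. Winner sets are assumed pre-aligned to
equal length; multiple alignment of ragged winner sets is out of scope.
When only an IUPAC consensus is annotated, the PPM assigns equal
probability to each nucleotide an ambiguity letter encodes (`R` →
A = G = 0.5, `N` → 0.25 each).

The quality score of motif $m$ of length $l$ under matrix $M$ is

$$S = \prod_{i=1}^{l} P(m_i \mid M),$$

the probability of observing the motif under the matrix. A motif from a
single-sequence experiment (EMSA, UV cross-linking) scores exactly 1 —
its PPM is a 0/1 matrix built from that one sequence. Across all $4^l$
concrete motifs the scores sum to 1: $S$ is a probability measure.

One case the product formula leaves open is a *stored motif that itself
contains ambiguity codes*. rbpkit scores an IUPAC letter as the summed
column probability of its member nucleotides. This choice makes an
IUPAC-derived PPM score its own consensus as 1.0, consistent with the
single-sequence rule; it is a documented package decision, not an
externally fixed rule.

## FM-index scanning

`buildIndex()` concatenates the input sequences with per-sequence
sentinels, builds a suffix array by prefix doubling, and derives the
Burrows–Wheeler transform with occurrence checkpoints; `locateMotif()`
answers exact queries by backward search. Pure R turned out sufficient
here: at the default 20 000-nt input cap (configurable, applied to the
file total) index construction is a handful of vectorised sorting passes.
Each sentinel receives its own rank, ordered by position — this keeps the
transform invertible for multi-sequence texts (an internal integrity
check) and structurally prevents matches from crossing sequence
boundaries.

Semantics, all chosen for exact-match scanning:

* **Offsets are 1-based**: the first nucleotide is position 1, the usual
  biological coordinate convention.
* **`N` matches nothing**, in the text or in a pattern: an unknown base
  cannot satisfy a perfect-match criterion.
* **Ambiguous motifs are expanded** (`iupacExpand()`, default cap 4096
  expansions) and each concrete expansion located, keeping the index a
  pure exact-match structure.
* **Multiplicity `t` counts overlapping occurrences**, because the
  observed-frequency denominator $l_s - l_m + 1$ counts overlapping
  placements.
* Multi-FASTA entries are scanned independently; records with motif
  lengths outside 4–12 are skipped with a warning rather than failing the
  scan.

## Genomic-functional-context enrichment

Because 4–12-nt motifs occur in almost any input, each hit is weighed
against three background sets per organism, the *genomic functional
contexts*: all exons ±250 nt, all introns, all coding sequences. With a
motif of length $l_m$ found $t$ times in an input sequence of length
$l_s$, and occurring $c_m$ times across background sequences $s_i$:

$$\mathrm{Obs} = \frac{t}{l_s - l_m + 1}, \qquad
\mathrm{Exp} = \frac{c_m}{\sum_i (\mathrm{len}\, s_i - l_m + 1)}, \qquad
\mathrm{OR} = \log_2 \frac{\mathrm{Obs}}{\mathrm{Exp}}.$$

$\mathrm{Obs}$ uses the length of the *entry* the hit occurs in, not the
file total — the formula is defined per input sequence. Background
sequences shorter than the motif contribute zero placements. When a motif
is absent from a context ($\mathrm{Exp} = 0$) the ratio is undefined and
reported as `NA` rather than smoothed or clamped to infinity: the formula
is preserved exactly and the condition stays machine-detectable. Scanning
a FASTA against itself as its own background yields OR = 0 identically,
which the tests use as a self-consistency check.

Backgrounds are user-supplied FASTA per context and organism (or built
from the deterministic generators); deriving them from genome annotation
is content, not method, and is out of scope. Supplied background FASTA is
taken as given — no deduplication of overlapping exon windows is
attempted. Statistical significance (p-values) is deliberately not
attached to OR values.

## Binding-site extraction from 3D complexes

`readStructure()` parses PDB-format coordinate files (via bio3d, with a
supplementary scan of the header for the EXPDTA method, the REMARK 2
resolution and TER records, which bio3d does not expose). NMR ensembles
reduce to the first model. Eligibility mirrors the usual curation rule:
NMR and electron-microscopy entries qualify as such, X-ray entries only
with resolution better than 3.9 Å; an X-ray entry without a resolution
record is ineligible with a warning rather than an error.

Contacts are distance-based, per RNA nucleotide:

* **hydrogen bond** — any N/O atom of the nucleotide within **3.0 Å** of
  any N/O protein atom;
* **van der Waals** — any atom pair within **3.9 Å**.

Both cutoffs are inclusive, and comparisons are made on squared distances
so a pair planted exactly on a cutoff classifies as a contact without
floating-point drift from square-root round trips. This is a deliberate
simplification of full hydrogen-bond assignment: programs like HBPLUS
also apply angular criteria, which a pure distance rule cannot reproduce;
rbpkit implements the distance criterion only, and documents the
divergence. The implementation evaluates all residue-against-protein atom
pairs with vectorised arithmetic; an all-pairs double loop serves as the
independent oracle in the tests, and shrinking a cutoff can only remove
contacts (monotonicity, also tested).

A **binding site** is a maximal run of ≥ 4 contiguous contacted
nucleotides (consecutive residue numbers in one chain). Contiguity is
read conservatively: insertion codes break runs, modified nucleotides
(non-A/C/G/U residue names) are excluded and break runs, and TER records
break runs even when numbering continues across them. vdW-only contacts
do support a site — the rule requires interaction with any atom of the
protein, not specifically a hydrogen bond. The site's base sequence,
5′→3′ by residue number, is the extracted motif.

Extracted motifs are validated against reference motifs of the same RBP
by **ungapped alignment**: the shorter motif slides along the longer with
full overlap, a position mismatches when the two letters' IUPAC member
sets are disjoint, and the best offset (smallest on ties) wins. Counts are
binned into 0 / 1 / 2 / >2 mismatch classes.

## Synthetic data: what it emulates, what it does not

The generators make every module testable offline and deterministically —
each is a pure function of its arguments including the seed, using a
locally scoped Mersenne–Twister stream, so outputs are byte-identical
across runs and platforms.

* `genPlantedFasta()` plants motifs at non-overlapping random positions in
  uniform random background, with a truth table of every planted offset.
  Defaults (3 sequences × 200 nt) keep brute-force oracles instant.
* `genBackgroundPair()` constructs scan/background sequences whose motif
  densities are *exact by construction*: planted copies are separated by a
  filler nucleotide absent from the motif, so no spurious or overlapping
  matches can occur, and the generator re-verifies its counts by direct
  search. The implied OR is then available in closed form, e.g. a planted
  10-fold enrichment gives OR = log₂ 10 exactly.
* `genToyStructure()` writes a glycine chain and an RNA chain whose
  residues sit at exactly requested nearest-atom distances (residues are
  spaced 10 Å apart so only the planted pair can ever be within a cutoff),
  with EXPDTA/REMARK 2 headers so the eligibility path is exercised.
  Distances below 1 Å are rejected as atom clashes.

What the generators do **not** emulate: real base composition, repeat
structure or annotation geometry of genomic contexts; real winner-set
alignment ambiguity; real nucleotide geometry (one probe atom stands for
the residue), waters, or crystallographic artefacts. Passing tests
therefore demonstrate the correctness of the rules and algorithms, not
performance of the scores on real transcripts or complexes.

## Numerical choices and problem sizes

* PPM columns must sum to 1 within 1e-9; the quality score is computed in
  double precision with no rounding.
* Contact cutoff comparisons use squared distances (see above); reported
  minimum distances are square roots of those values.
* The test suite sizes simulations to stay quick while covering the
  property space: 1000 fuzzed locate-vs-naive pairs on sequences up to
  2 kb, quality-score normalization swept over all 4⁸ motifs, eight-way
  randomized contact fixtures against the brute-force oracle. The whole
  suite runs in well under a minute.
* Seeds in tests and the acceptance script are fixed or derived from the
  caller's `--seed`; generators never touch the global RNG state.

## Known limitations

* Only PDB-format input for structures (no mmCIF); caller curates the
  input set (e.g. excluding ribosomes).
* H-bond detection is distance-only — expect more permissive calls than
  geometry-aware tools on real structures.
* No mismatch-tolerant or PWM-threshold scanning, and no reverse-strand
  scanning (RNA is single-stranded; the given strand is scanned).
* Quality scores compare motifs *within* an experiment's PPM; they are not
  calibrated binding affinities across experiments.
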