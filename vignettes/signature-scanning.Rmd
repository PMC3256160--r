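---
title: "Scanning rRNA alignments for kingdom-signature nucleotides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning rRNA alignments for kingdom-signature nucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnasig)
```

## The question and the procedure

Ribosomal RNA genes can be aligned across all cellular life once their
variable-length regions are removed, and in such an alignment a column
can show a striking pattern: every archaeon and every eukaryote carries
a residue that no bacterium carries (or vice versa for any pair of
kingdoms), or one kingdom is fixed for a state absent everywhere else.
The first kind of column is evidence about the deep branching order of
the kingdoms — archaea+eukaryote exclusive columns support an archaeal
ancestry of the eukaryotic ribosome — and both kinds are candidate
determinants of kingdom-specific antibiotic susceptibility when they
fall in functional regions such as the peptidyl transferase centre
(PTC).  The macrolide-resistance position (A2058 in the bacterial 23S
numbering, G2400 in the yeast 25S numbering) is the canonical example.

`rrnasig` implements this scan as a deterministic pipeline:

1. read a pre-aligned rDNA matrix, a taxon→group map, and an optional
   region mask (the masked columns stand for the variable-length
   regions removed before alignment);
2. for every scannable column, collect the set of symbols observed in
   each group;
3. classify the column by exclusive-sharing pattern;
4. number each site in one or more reference coordinate systems and
   join it to functional annotations;
5. report a publication-style site table plus per-category counts.

Alignment computation itself is out of scope: the study design this
package supports aligns externally (e.g. MUSCLE) after masking, and
the pipeline begins with the aligned matrix.

## The symbol model

All classification happens over the five-symbol alphabet
`{A, C, G, T, -}`.  Two policy choices matter:

* **The gap is a first-class symbol.**  A column where archaea and
  eukaryotes are all gapped while bacteria keep a base is a shared
  deletion — as diagnostic as any substitution.  Making `-` an
  ordinary symbol lets indel signatures fall out of the same set
  algebra, including mixed group states like `-Y` (some taxa gapped,
  the rest C/T).
* **Ambiguity in input sequences is missing data.**  A sequencing `N`
  read as "evidence for all four bases" would veto a true signature
  every time one deposited sequence is sloppy, so `N`, `Y`, `R`, …
  in input residues contribute nothing for that taxon at that column.
  Degenerate IUPAC codes are used only on the output side, to
  summarize a group's observed set (`{C,T}` prints as `Y`, `{-,C,T}`
  as `-Y`).  U is identified with T and all output uses the DNA
  alphabet.

## The classification rule

Let the groups' observed symbol sets at a column be $s_1, \dots, s_k$
(three groups in the motivating design).  With strict scanning:

* **UNIVERSAL** — all sets equal one single non-gap symbol.
* **PAIR(X,Y)** — the excluded groups' symbols are disjoint from
  everything X and Y carry, and $x \cap y \neq \emptyset$.
* **ONLY(X)** — $|x| = 1$ and that symbol occurs in no other group,
  and no PAIR applies.
* **UNCLASSIFIED** otherwise, including any column where a group
  falls below the minimum data fraction.

Precedence is UNIVERSAL > PAIR > ONLY.  The PAIR rule deserves
emphasis: it requires only a *non-empty shared set* in the pair, not
an identical fixed base, because published consensus tables mix fixed
and degenerate group states (a eukaryotic consensus `D` = {A,G,T}
legitimately shares G with a fixed archaeal G while a bacterial C is
excluded).  This is the weakest rule consistent with every such
printed row, and the package states it prominently rather than
silently requiring fixation.  A site is an **INDEL** signature when
the diagnostic shared symbol (PAIR) or the group-specific symbol
(ONLY) is the gap.

Two determinism details.  For three groups no two PAIR patterns can
hold simultaneously (the test suite proves this exhaustively over all
29,791 ordered triples of non-empty symbol subsets), so PAIR needs no
tie-break.  Two groups *can* simultaneously satisfy ONLY (e.g. three
mutually disjoint fixed states); the scanner then reports the first
qualifying group in sorted label order.  This is an arbitrary but
deterministic convention, and such columns are rare in practice
because each is a double fixation.  With more than three groups the
same rules generalize, larger sharing subsets taking precedence
(category `SHARED`).

## Tunable parameters

* `min_group_fraction` (default **0.9**): the fraction of a group's
  taxa that must contribute a non-missing symbol for the column to be
  classifiable.  rDNA deposits are of uneven quality; requiring 90%
  keeps columns classifiable despite scattered `N`s while refusing to
  call a signature from a group that is mostly unobserved.  A group
  with *no* observation always makes the column UNCLASSIFIED.
* `tolerance` ε (default **0**, strict): fraction of each group's
  observed taxa whose symbols may be discarded (whole rarest symbols
  first) before re-classifying.  Strict conservation is the default
  because the motivating claim is about signatures present in *all*
  sampled members of a kingdom; ε exists because real resequencing
  noise exists.  Tolerance is implemented as a fallback — it is
  consulted only for columns strict scanning leaves unclassified — so
  the strict site list is always a subset of the tolerant one.  (The
  alternative, unconditionally discarding minorities, can delete the
  shared symbol itself and so *lose* strict calls; the fallback
  semantics preserve the monotonicity a user expects from a
  "tolerance" knob.)
* `include_universal` (default on): universally conserved columns are
  themselves part of a signature report (the "all cellular organisms"
  class) and are emitted unless switched off.
* Reference `offset` (default 0): published rRNA numbering (E. coli
  16S/23S, yeast 18S/25S) is a literature convention that cannot be
  derived from a sequence; reported positions are the ungapped index
  within the chosen reference row plus this offset.  Where a
  reference row's column is a gap, the site is rendered with its
  flanking bases, `(A412)-(T413)`; an absent flank at the alignment
  edge renders as `(5')` or `(3')`.

## Coordinate and interval conventions

All file-level intervals (masks, annotations) are 0-based half-open
in the BED style; all reported coordinates are 1-based inclusive in
the published-table style.  Conversion happens exactly once, at the
I/O boundary.  Masks may be given in alignment columns or in a
reference's published coordinates; a reference-space interval that
spans a reference gap masks every alignment column between the mapped
flanks, which is the conservative reading for variable-region
removal.  Annotation files use published coordinates, so a resistance
locus can be written down directly from the structural literature.

## Composite loci

Published signature tables contain composite entries whose group
states span two adjacent columns (a gap-state column followed by a
base column, printed like `-Y` / `BG` / `HR`).  The package represents
these as two adjacent single-column sites — the honest unit of the
scan — and a report-level merge collapses runs of adjacent columns
with identical category into one locus with concatenated codes.
Site-level outputs (and all recovery scoring) stay per-column.  The
same convention drives `classify_signature_table()`, which tokenizes
each printed cell into per-column codes (a flanked-gap cell like
`(Y)-(A)` is a single gap-state column) and requires the columns of a
composite row to agree on the category.

## The synthetic generator

`generate_alignment()` plants columns of every category into a
three-group alignment with a per-column truth table.  Defaults mirror
the motivating study's sampling — 124 bacteria, 21 archaea, 362
eukaryotes — with 12 planted columns per category (universal; each
pair, substitution and indel; each single group, substitution and
indel), 60 background columns of uniform noise, and 8 junk columns
covered by the emitted mask.  Construction guarantees that, at zero
noise, strict scanning recovers every planted column exactly: the
sharing groups' sets are built around a guaranteed common symbol and
fully covered by their taxa, excluded groups draw from disjoint
leftover symbols, and the groups flanking an ONLY column get mutually
disjoint two-symbol sets so no second category can apply.  A
per-cell noise rate flips symbols uniformly; a single seed drives one
RNG stream, so a seed reproduces the dataset byte for byte.

What the generator deliberately does **not** emulate: phylogenetic
correlation among taxa (no tree; every taxon draws independently),
realistic substitution processes (no transition/transversion bias, no
rate variation), indel length distributions (indels are single
columns), and secondary-structure covariation.  Exact recovery on
this generator therefore shows that the scanner's set algebra and
bookkeeping are correct — not that real rDNA alignments will yield
any particular number of signatures.  Column-independence is the
right level for that check because the classification itself is
purely per-column.

## Problem sizes and numerical choices

The shipped analyses run at desk scale: the hand-built demo alignment
is 12 taxa × 40 columns with every category represented and
hand-verified coordinates; the simulator runs at the full 507-taxon
group sizes over 224 columns; the classifier is proved against a
brute-force oracle over all 29,791 ordered set triples; coordinate
round trips are checked on 1,000 random gapped references.  All of
this completes in seconds.  There is no floating-point content
anywhere in the core — every decision is set algebra on five symbols —
so there are no tolerances to tune; determinism is exact.

## Limitations

* The published headline counts (26 archaea+eukaryote signatures
  across SSU+LSU, one eukaryote+bacteria site, seven eukaryote
  synapomorphies) are properties of a specific 507/347-taxon GenBank
  alignment whose accession lists are not machine-readable here.
  Reproducing them requires re-downloading those sequences, masking
  variable regions by secondary-structure annotation, aligning
  (MUSCLE or similar), and running `run_scan()` with the E. coli and
  yeast reference rows and their published offsets.  The package
  automates everything after alignment; the shipped checks cover the
  transcribed published table rows and the simulator.
* No statistical significance is attached to a signature; the
  motivating analysis reports exclusive sharing as an observation,
  and with strict scanning a single deviant taxon removes a site.
* The intra-group consensus rule of the original BioEdit-based
  analysis is not published; strict conservation with the
  weakest-consistent PAIR rule is this package's documented choice,
  and the tolerance knob exposes the obvious relaxation.
* Functional annotations are user-supplied; the shipped annotation
  file is an illustrative synthetic fixture, not a curated map of the
  PTC, tRNA sites, or bridges.
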