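---
title: "Methods: column classification, the average mutation index, and masked-target export"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: column classification, the average mutation index, and masked-target export}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxamark)
```

## The question the package answers

Diagnostic LAMP primers are more specific when their ends cover positions
that separate the target taxon from its relatives. Given a multiple
sequence alignment containing several strains for each of several taxa,
which alignment columns are *taxon-specific* — conserved across every
strain of one group and absent from everything else — and where along the
alignment are they dense enough to anchor a primer set?

Three properties make this harder than scanning for differences:

* **within-group variation must be excluded.** A column where the target
  species itself is polymorphic cannot guarantee primer annealing across
  strains, however different it looks from the outgroups;
* **specificity must be strict.** A primer-end mismatch is only guaranteed
  against *every* off-target strain if the signature character occurs in
  none of them — being different from each outgroup's consensus is not
  enough;
* **density matters, not just existence.** A single specific SNP rarely
  survives primer-design constraints; practitioners need the region where
  several such SNPs fall inside one amplicon-sized window.

## Column classification

Let a column carry one character per record over the alphabet
A/C/G/T, the IUPAC ambiguity codes, and the gap `-`. For each taxon group
$G$ the column is **taxon-specific for $G$** iff

1. all members of $G$ carry the same character $c$ (no strain
   polymorphism, no within-group ambiguity),
2. $c$ is an unambiguous base or the gap character,
3. $c$ occurs in no record outside $G$, and
4. if $c$ is the gap, every non-$G$ record carries an unambiguous base —
   the conserved deletion itself is then the signature.

A column is **conserved-common** iff every record shows the same single
unambiguous base (the Clustal `*` convention: gaps and ambiguity codes
disqualify).

Two decisions here were genuinely open and are ours:

* **Outgroup ambiguity codes.** An outgroup `R` *could* be an `A`; whether
  that defeats an `A` signature is not dictated by the definitions above.
  We treat any IUPAC code whose expansion contains the signature base as a
  match, i.e. as disqualifying. This is the conservative direction: it can
  only cost candidate columns, never admit a column that might fail in the
  assay.
* **Gap signatures.** A deletion conserved in the focal group and absent
  outside it is accepted as taxon-specific — it is exactly the kind of
  variation that shows up as a gap block in orthologue alignments — but it
  cannot carry a mark on the exported *ungapped* target (the position does
  not exist there). Such columns therefore count in profiles and plots and
  are logged, but contribute no `-` to the mask.

Classification is a pure function of the column contents and the grouping:
permuting groups, or adding a strain identical to its group consensus,
never changes a verdict (both properties are tested).

## The average mutation index

The alignment is tiled into consecutive, non-overlapping **fragments of 20
columns** — the length of a primer annealing site, which is why counts are
reported "per 20 nt". With $M_f$ the number of taxon-specific columns in
fragment $f$, the **average mutation index** is the simple moving average
over a window of $w$ fragments,

$$\bar S_f \;=\; \frac{1}{w}\sum_{i=0}^{w-1} M_{f-i},$$

computed in practice by the recurrence
$\bar S_f = \bar S_{f-1} - M_{f-w}/w + M_f/w$ (first window summed
directly). The two forms are algebraically identical; the test suite holds
their divergence under $10^{-9}$ across 1,000 random inputs, and the
direct form is additionally checked against an independent rolling-mean
implementation.

Anchoring and edges follow from the window semantics:

* **the window slides by one fragment, not one column** — the recurrence
  removes and adds whole-fragment counts, so the profile's resolution is
  per-fragment;
* **$w$ must be odd** so each value anchors to the central fragment of its
  window rather than an abstract locus; the default window of 300 columns
  over 20-column fragments gives $w = 15$. 300 bp is an amplicon-scale
  span: LAMP is most efficient below that amplicon length;
* **no padding.** $\bar S$ is undefined for the first and last $(w-1)/2$
  full fragments; padding would bias the edges toward zero. A trailing
  fragment shorter than 20 columns is counted and flagged `partial` but
  excluded from the SMA, since it would break the per-20-nt normalisation;
* an alignment with fewer than $w$ full fragments (300 columns at the
  defaults) cannot support a single window and is rejected with the
  minimum length in the message.

## Region selection and export

Regions qualify where $\bar S_f \ge 2$ — at least two taxon-specific
mutations per annealing-site length on average across the window, enough
to place mutations on several primer ends. The selected region is a window
of at most **2,000 columns** (the downstream primer-design input limit)
centred on the maximum $\bar S_f$, leftmost on ties (deterministic and
documented — the tie-break was not externally specified), clamped to the
alignment. The end-to-end driver falls back to the whole alignment when no
window qualifies but the alignment fits the limit.

The exported target is the **focal-group majority consensus** over the
region, not an arbitrary first strain: the file should represent the
taxon, and a consensus is deterministic. Per column, the most frequent
unambiguous base among focal members wins, ties broken alphabetically
(A<C<G<T, logged). Columns whose plurality character is the gap are
dropped from the ungapped target; columns offering no unambiguous base at
all are dropped with a warning, never silently substituted. The annotation
line carries `*` under conserved-common columns and `-` under the focal
group's taxon-specific columns, wrapped at 60 characters with the
annotation interleaved under each sequence line so the marks stay aligned
both visually and programmatically; the header states the 1-based
inclusive alignment coordinates. Internally the package indexes columns
1-based inclusive as well (the natural R convention), so no coordinate
translation exists to get wrong.

## Input conventions

Headers split on a configurable delimiter, **em-dash by default** as in
the header convention above. No automatic fallback onto the plain hyphen
is attempted: accessions routinely contain hyphens, and a silently
mis-split header that moves a strain into the wrong group is strictly
worse than an error naming the offending header. Sequences are uppercased
on ingest and RNA `U` is transliterated to `T` (logged once). Both Clustal
dialects — plain, and ClustalW with cumulative residue counts at the end
of each line — and aligned FASTA are accepted and yield identical results
on the same data (tested record-for-record). Input order is preserved;
strains group strictly by identical taxon ID.

## The synthetic-data generator

`plant_plan()`/`generate_alignment()` build alignments whose truth is
exact by construction: a uniform random A/C/G/T backbone shared by all
records; per-group planted signature columns whose base is chosen different
from the backbone (hence absent outside the group); optional conserved
deletion blocks; strain noise that flips at most one strain per group per
column, only in groups with two or more strains and only at unstructured
columns, so a noise column is always group-polymorphic and never
taxon-specific; and an adversarial `spoiled` mode that leaks a would-be
signature into one outgroup strain, which the classifier must reject.

One consequence of the strict-exclusion definition is encoded in the
truth: with exactly two groups, a column planted for one group is
automatically specific for the other as well (its conserved backbone base
occurs nowhere outside it). The generator records these reciprocal calls,
and the recovery tests assert precision and recall of exactly 1.0 against
the complete truth — an exact, not statistical, guarantee, which is why
noise placement is constrained rather than free.

What the generator does **not** emulate: realistic substitution processes
(no transition/transversion bias, no rate heterogeneity), indels beyond
planted blocks, alignment errors, or phylogenetic correlation between
strains. Passing tests therefore demonstrate correctness of the
*classification and profiling logic* under clean group structure, not
robustness to misalignment or to sampling artefacts in real orthologue
sets — on real data, the quality of the upstream alignment and the choice
of strains remain the user's responsibility.

## Problem sizes and reproducibility

The validation suite runs 200 seeded generator plans spanning 2–5 groups,
1–6 strains per group and 400–5,000 columns, plus 1,000 random
fragment-count vectors (lengths 15–500, odd windows 3–31) for the SMA
equivalence property; these sizes give full coverage of the tiling and
window edge cases while keeping the suite fast. All randomness is seeded;
two pipeline runs with a pinned project ID produce byte-identical text
outputs, which the suite asserts. Graphics are rendered at a fixed figure
size in all five supported formats (eps, pdf, png, svg, tiff). ZIP
bundling writes standard deflate archives via a small in-package writer
(deflate streams and CRC-32 obtained from the gzip container R itself
produces), with entry timestamps fixed so archive bytes do not depend on
the clock.

## Known limitations

* Nucleotide alignments only; no protein or codon-aware logic, and no
  phylogenetic weighting — every strain counts equally in the exclusion
  test, so a single mislabelled record can veto a column.
* Strict exclusion plus conservative ambiguity handling means heavily
  N-padded outgroup records can suppress most candidate columns; curate
  inputs accordingly.
* The density profile has fragment resolution (20 columns); peaks are
  localised to a fragment, not a column.
* Primer design itself — melting temperatures, GC content, dimer checks —
  is out of scope by design; the masked target is the hand-off point.
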