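---
title: "Phylogenetic alignment and haplogrouping of mtDNA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic alignment and haplogrouping of mtDNA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthap)
```

## The problem

Human mtDNA haplotypes are reported as lists of differences to the rCRS, a
16,569 bp circular reference. Insertions and deletions in homopolymers and
repeats admit several equivalent spellings (`303del` vs `309del`,
`16192.1T` vs `16191.1C 16192T`), so two laboratories can submit the same
molecule under different notations. `mthap` makes haplogrouping immune to
this: costs are computed between *expanded sequences*, and the query's
alignment is re-derived from the nearest haplogroup motif, which pins the
notation to the phylogeny rather than to the submitter's aligner.

## Data model

* A **reading range** is a 1-based inclusive interval; `start > end` wraps
  the circular origin (control region: `16024-576`). All coordinate
  arithmetic is modular.
* A **variant** is a substitution (`73G`), insertion (`309.1C`) or deletion
  (`524del`, with `524d` accepted on input). IUPAC ambiguity codes denote
  point heteroplasmy (`16093Y`) in queries and widened symbols in motifs;
  lowercase marks *optional* symbols (`315.1c` = C or gap). A trailing
  lowercase `d` always reads as a deletion; the IUPAC code D (A/G/T) must
  be written in uppercase, so no printed token is ambiguous.
* A **haplotype** is a reading range plus an ordered variant list, and
  doubles as an alignment. A **motif** is a haplogroup's defining
  haplotype; starred names (`HV*`) denote unnamed subclades and sit as
  ordinary children of their base haplogroup in the tree, so MRCA queries
  fold them in naturally.

## Search

`condense_db()` restricts every motif to the query's range and merges
identical restrictions (keying on the exact token list including
optionality). `neighbor_cost()` aligns the expanded query against each
condensed entry with weighted global alignment:

* resolving a motif ambiguity code to a base it covers, or an optional
  symbol to present/absent, costs 0 (this is how the universal `16519Y`
  completion makes the frequent T16519C transition free);
* any true edit costs its weight from the weight table (all 1 by default;
  an external table keyed by position and mutation descriptor or class can
  be supplied — the package consumes such tables, it does not derive them).

The entry's reported cost is the summed weight of its *essential* private
mutations: heteroplasmies (ambiguous observed symbol) and length variants
(indels anchored in configured length-variable regions) are reported as
privates but contribute 0. `rank_neighbors()` clusters costs with a margin
(default 0.5): rank 1 is everything within the margin of the global
minimum; rank 2 is everything within the margin of the *remainder's*
minimum. The margin rule is anchored at the remainder minimum rather than
at `min + margin` exactly — with the default margin, integer unit costs
make the two readings coincide, and the remainder anchoring extends more
gracefully to fractional weight tables. Each rank is summarized by the
MRCA of its haplogroup names; rank-2 estimates are deliberately reported
alongside rank 1, because with a richly subdivided motif database the
rank-1 estimate can be sharper than the evidence warrants.

## The transcript engine

`best_transcript()` runs Needleman–Wunsch on coordinate-tagged symbol
strings, so every emitted op carries an rCRS-anchored coordinate
(insertion coordinates such as `309.1` included). Ties are broken in a
fixed order while backtracking from the 3′ end:

1. zero-cost resolution diagonal (keep the motif's ambiguity/optional
   features),
2. deletion, then insertion (pushes indels 3′-most, the forensic
   convention for homopolymers and the AC repeat),
3. plain diagonal.

Insertions placed before the first symbol of the range carry an
infinitesimal surcharge (`1e-7` per symbol, stripped from reported costs,
which are re-summed from the emitted ops). This never changes a real cost
comparison — weight tables are coarser by orders of magnitude — but on
exact ties it steers the engine away from frames the rCRS-relative
notation cannot anchor inside the range. A query that genuinely extends 5′
of its declared range relative to the motif remains unrepresentable and
fails loudly; declaring a range that covers the query is the remedy.

Equality of floating-point scores uses an absolute tolerance of `1e-9`
during backtracking.

## The five-step rewriting

`apply_transcript()` converts the nearest motif's variant list into the
query's alignment:

1. normalize the transcript to single-symbol ops, ascending coordinates,
   applied from the 3′ end (so positions never shift underneath);
2. apply substitutions and deletions to the variant list (a substitution
   whose target equals the reference base removes the variant; deleting a
   motif insertion removes it; deleting a substituted or reference
   position leaves a deletion variant);
3. move the alignment's insertion variants into the op list, anchored
   after their predecessor coordinate;
4. move list insertions 5′ over deletion gaps, so every insertion is
   anchored at an existing symbol followed directly by its deletion run;
5. combine same-position insertions; without a following deletion run they
   become insertion variants (`p.1`, `p.2`, …); otherwise a unit-cost
   auxiliary alignment of the inserted string against the *reference*
   symbols of the deleted run decides, column by column: match → cancel
   the deletion (the position reverts to the reference, which is exactly
   what cancellation restores — hence reference symbols, not motif
   symbols), mismatch → deletion becomes a substitution, unmatched
   inserted symbols become insertions after the last live position,
   unmatched deletions survive. Auxiliary ties push leftovers 3′.

Because steps 2–5 only touch coordinates named by the transcript, motif
variants with zero-cost resolutions or no ops at all appear verbatim in
the output — the phylogenetic preference that keeps `455.1T 459del` over
the shorter spelling `456T`.

Intermediate states after each step are exposed
(`apply_transcript(..., keep_steps = TRUE)`) and tested against the known
worked example; the master invariant, checked on a thousand seeded random
cases per test run, is string conservation: expanding the rewritten
alignment reproduces the query sequence character for character.

## Curation helpers

* `vet_mitogenome()`: a mitogenome passes with length ≥ 16,539 bp and at
  most nine ambiguous symbols; both rules are always evaluated so reports
  list every violated rule.
* `widen_motif()`: a position is widened to the minimal covering IUPAC
  code when an alternative base occurs in ≥ 25 % of member haplotypes
  (configurable; the threshold is a package choice — only the mechanism,
  not the historical evidence for specific widenings, is automatable) and
  in at least two members. Widening can only lower member costs, a
  property the tests verify.
* `detect_subclades()`: maximal sets of ≥ 3 shared essential extra
  variants carried by ≥ 2 members, computed as closed sets under
  carrier-intersection; nested candidates are allowed and named
  `base*`, `base*1`, with letter suffixes for nesting. Single-carrier
  candidates require an explicit override flag.
* `complete_pt17_motif()` applies the standard completions (16519Y except
  for B2m; optional 315.1c; 16182M/16183M except that the haplogroup
  bearing 16182T gets only 16183M — the printed source for that exception
  contains an impossible position, 18183, which the package reads as
  16183) and is idempotent.

## Synthetic fixtures and what they show

`fixture_spec()` fixes seed, reference length (default 1 kb in the module,
300 bp in most tests), tree size and depth, a minimum motif separation,
and per-query rates of planted privates, heteroplasmies and length
variants. `make_reference()` plants a bounded C homopolymer inside a
configured length-variant region (exercising 3′ placement);
`make_motif_tree()` grows each child motif by ≥ separation substitutions
at globally unused positions, so all pairwise motif distances meet the
separation bound, and includes one starred subclade and one
ambiguity-widened motif. With separation 3 and one planted private,
rank-1 recovery is provably exact, and the tests require 100 %.

`make_rcrs_like_reference()` is a 16,569 bp synthetic stand-in: true rCRS
bases at the control-region positions that notation conventions and the
worked examples exercise (the 303–315 and 16184–16193 C-stretches, the AC
repeat 515–524 and its non-repeat continuation, and the classic diagnostic
sites), seeded filler elsewhere. Passing tests on these fixtures show that
the notation, engine and rewriting behave correctly — they do not certify
base-level agreement with the real rCRS outside the pinned positions, and
they say nothing about mutation-rate realism, which the generator does not
attempt.

Problem sizes in the shipped tests and acceptance script — 300 bp
references, ≤ 11 motifs, 40-query batches, 1000 conservation cases at
30 bp — were chosen to make every property suite run in well under a
minute while still covering wrap-around ranges, homopolymers, ambiguity
codes and optional symbols.

## Known limitations

* Full-scale database statistics (motif counts in the thousands,
  control-region condensation ratios) require the complete revised motif
  table, which is external data the package reads but does not ship.
* Gap costs are linear (no affine or codon-aware scoring), matching the
  unit-cost reading of the search; weight tables should keep substitution
  weights below twice the indel weight if substitutions are to be
  preferred over indel pairs.
* Insertions 5′ of the reading-range start are not representable (see
  above).
* Nuclear genomes and multi-record references are out of scope; one
  circular reference per analysis.
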