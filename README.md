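# mthap — haplogroup estimation and phylogenetic alignment of human mtDNA

Mitochondrial DNA haplotypes are reported as differences to the revised
Cambridge Reference Sequence (rCRS), and the same sequence can be written in
several equivalent variant notations. That ambiguity breaks naive
database lookups in medical, population and forensic genetics. `mthap`
implements an *alignment-immune* workflow: queries are compared to
haplogroup-defining motifs at the sequence level, so the estimate does not
depend on how either side was aligned, and the query's final rCRS-relative
alignment is derived *from the nearest motif* — phylogenetically plausible
rather than merely most parsimonious.

It is aimed at forensic and population geneticists who work with
EMPOP-style variant tables (e.g. control-region sequences over the
wrap-around range 16024–576) and with Phylotree-style haplogroup motif
tables.

## The method

For a query haplotype *q* with reading range *R*:

1. **Condense** every motif *m* of the database to *R* and deduplicate
   identical restrictions (for the control region this almost halves the
   database).
2. **Cost** each condensed entry by weighted global alignment of the
   expanded sequences. Resolutions of motif IUPAC codes (`16519Y` → `T`)
   and optional symbols (`315.1c` present or absent) cost 0; true edits
   cost *w*(position, mutation), and the entry's cost is the summed weight
   of its **essential** private mutations — point heteroplasmies (`16093Y`)
   and length variants (`309.1C`) count 0.
3. **Cluster** costs with a margin of 0.5 into rank-1 and rank-2 neighbor
   sets and report the MRCA of each set on the haplogroup tree as a
   single-haplogroup estimate.
4. **Align**: compute the best edit transcript from the nearest motif's
   sequence to the query sequence and rewrite the motif's variant list with
   the five-step transcript-application algorithm (normalize to
   single-symbol 3′-ordered ops; apply substitutions/deletions; move motif
   insertions into the op list; shift insertions 5′ over deletion gaps;
   reconcile combined insertions against deletion runs via an auxiliary
   alignment). Motif variants untouched by the transcript survive verbatim.

## Worked example

Haplogrouping and aligning the classic Navajo control-region haplotype
against a miniature motif database:

```r
library(mthap)
ref <- make_rcrs_like_reference(1)
cr  <- reading_range(16024, 576)

q <- parse_haplotype(
  "16111T 16189C 16192.1T 16223T 16290T 16319A 16362C 73G 146C 153G 235G 263G 309.1C 315.1C",
  cr, "USA.154.000067")
res <- align_query(q, db, ref)   # db: motif_db with A2+(64)+16189, B4a1a1, ...
res$search
#> <search_result>
#>  rank 1: A2+(64)+16189 (cost 0, MRCA A2+(64)+16189)
#>  rank 2: B4a1a1 (MRCA B4a1a1)
serialize_transcript(res$transcript)
#> [1] "M16182A M16183A 16191insC Y16192T Y16519T Y64C 309insC c315.1C"
format(res$alignment)
#> [1] "16111T 16189C 16191.1C 16192T 16223T 16290T 16319A 16362C 73G 146C 153G 235G 263G 309.1C 315.1C"
```

The search cost is 0: the two insertions the query carries relative to the
motif are length variants inside the 16184–16193 and 303–315 C-stretches,
and everything else is a zero-cost resolution of the motif's ambiguity
codes. The final alignment keeps the motif's structure (`16191.1C 16192T`
instead of the query's own `16192.1T` spelling) — that is the phylogenetic
alignment.

A command-line front end wraps the same functions
(`inst/cli/mthap.R`; subcommands `haplogroup`, `condense`, `vet`,
`subclades`, `fixtures`).

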