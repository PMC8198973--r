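Package: mthap
Title: Haplogroup Estimation and Phylogenetic Alignment of Human mtDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-immune haplogrouping and phylogenetic alignment of
    human mitochondrial DNA sequences. Haplogroup-defining motifs are stored
    as rCRS-relative variant lists, condensed to an arbitrary reading range
    (including wrap-around ranges such as the control region 16024-576), and
    queried by a weighted nearest-motif search that scores essential private
    mutations and clusters neighbors into rank-1/rank-2 sets with MRCA
    estimates on the haplogroup tree. A query sequence is aligned to the
    rCRS by computing the best edit transcript to the nearest motif and
    rewriting that motif's alignment with a five-step transcript-application
    algorithm, yielding a phylogenetically plausible (rather than merely
    most parsimonious) variant representation. Includes tools for motif
    curation (mitogenome vetting, motif widening with IUPAC codes, detection
    of unnamed subclades) and seeded synthetic fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
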