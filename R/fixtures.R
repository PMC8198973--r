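## Seeded synthetic fixtures: toy circular references, toy motif trees and
## simulated queries, so that every part of the pipeline is testable
## without any downloads. Fixtures serialize to the same FASTA/TSV dialects
## the real pipeline reads.

## run code with a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic fixture
#'
#' @param seed integer; identical seeds give identical fixtures.
#' @param ref_length toy reference length (circular), >= 100.
#' @param n_haplogroups number of named haplogroups (tree nodes).
#' @param tree_depth maximum tree depth below the root.
#' @param motif_separation minimum number of new variants per child motif;
#'   pairwise motif distances are then at least this value, which must
#'   exceed twice the planted privates for recovery experiments.
#' @param private_rate expected planted essential privates per query.
#' @param heteroplasmy_rate,length_variant_rate per-query probabilities of
#'   an added point heteroplasmy / length variant.
#' @param c_stretch length of the planted homopolymer (exercises 3'
#'   placement of indels).
#' @return A `fixture_spec` list; `length_variant_regions` holds the region
#'   around the planted homopolymer.
#' @export
fixture_spec <- function(seed = 1L, ref_length = 1000L, n_haplogroups = 12L,
                         tree_depth = 3L, motif_separation = 3L,
                         private_rate = 1, heteroplasmy_rate = 0,
                         length_variant_rate = 0, c_stretch = 8L) {
  stopifnot(ref_length >= 100L, n_haplogroups >= 1L, motif_separation >= 1L)
  cs_start <- as.integer(ref_length %/% 2L)
  structure(list(seed = as.integer(seed), ref_length = as.integer(ref_length),
                 n_haplogroups = as.integer(n_haplogroups),
                 tree_depth = as.integer(tree_depth),
                 motif_separation = as.integer(motif_separation),
                 private_rate = private_rate,
                 heteroplasmy_rate = heteroplasmy_rate,
                 length_variant_rate = length_variant_rate,
                 c_stretch = as.integer(c_stretch),
                 cs_start = cs_start,
                 length_variant_regions = list(
                   reading_range(cs_start - 2L, cs_start + c_stretch + 2L))),
            class = "fixture_spec")
}

#' Deterministic toy circular reference
#'
#' Contains a planted C homopolymer of length `c_stretch` (bounded by
#' non-C symbols) inside the configured length-variant region.
#'
#' @param spec a [fixture_spec()].
#' @return A [ref_sequence()].
#' @export
make_reference <- function(spec) {
  with_seed(spec$seed, {
    sym <- sample(c("A", "C", "G", "T"), spec$ref_length, replace = TRUE)
    cs <- spec$cs_start:(spec$cs_start + spec$c_stretch - 1L)
    sym[cs] <- "C"
    sym[spec$cs_start - 1L] <- "T"
    sym[spec$cs_start + spec$c_stretch] <- "G"
    ref_sequence(paste0("toyref-", spec$seed), sym, circular = TRUE)
  })
}

## Bases of the rCRS at positions commonly referenced in control-region
## nomenclature (C-stretches, the AC repeat, classic diagnostic sites).
.rcrs_known_bases <- c(
  `42` = "T", `63` = "T", `64` = "C", `65` = "T", `66` = "G", `67` = "G",
  `73` = "A",
  `146` = "T", `152` = "T", `153` = "A", `195` = "T", `235` = "A",
  `263` = "A", `302` = "A", `303` = "C", `304` = "C", `305` = "C",
  `306` = "C", `307` = "C", `308` = "C", `309` = "C", `310` = "T",
  `311` = "C", `312` = "C", `313` = "C", `314` = "C", `315` = "C",
  `316` = "G", `455` = "T", `456` = "C", `459` = "C", `489` = "T",
  `515` = "A", `516` = "C", `517` = "A", `518` = "C", `519` = "A",
  `520` = "C", `521` = "A", `522` = "C", `523` = "A", `524` = "C",
  `525` = "T",
  `16093` = "T", `16111` = "C", `16172` = "T", `16176` = "C",
  `16182` = "A", `16183` = "A", `16184` = "C", `16185` = "C",
  `16186` = "C", `16187` = "C", `16188` = "C", `16189` = "T",
  `16190` = "C", `16191` = "C", `16192` = "C", `16193` = "C",
  `16194` = "A", `16217` = "T", `16223` = "C", `16247` = "A",
  `16261` = "C", `16290` = "C", `16295` = "C", `16311` = "T",
  `16319` = "G", `16362` = "T", `16519` = "T")

#' Synthetic rCRS-like reference
#'
#' A 16,569 bp circular reference whose bases at the control-region
#' positions commonly cited in mtDNA nomenclature (the 303-315 and
#' 16184-16193 C-stretches, the AC repeat at 515-524, classic diagnostic
#' sites) equal the rCRS, with seeded filler elsewhere. This is a synthetic
#' stand-in sufficient for notation-level work and for the worked examples;
#' real analyses should load the actual rCRS from FASTA via [read_fasta()].
#'
#' @param seed filler seed.
#' @return A [ref_sequence()] of length 16,569.
#' @export
make_rcrs_like_reference <- function(seed = 1L) {
  with_seed(seed, {
    sym <- sample(c("A", "C", "G", "T"), 16569L, replace = TRUE)
    sym[as.integer(names(.rcrs_known_bases))] <- unname(.rcrs_known_bases)
    ref_sequence("rCRS-like-synthetic", sym, circular = TRUE)
  })
}

#' Deterministic toy motif tree
#'
#' Builds a rooted haplogroup tree where every child motif extends its
#' parent by at least `motif_separation` substitutions at globally unused
#' positions (so all pairwise motif distances are >= the separation).
#' Includes one starred subclade and one ambiguity-widened motif.
#'
#' @param spec a [fixture_spec()].
#' @param ref the toy reference from [make_reference()].
#' @return A `motif_db`; attribute `used_positions` lists the planted
#'   positions (queries should plant privates elsewhere).
#' @export
make_motif_tree <- function(spec, ref) {
  with_seed(spec$seed + 1L, {
    L <- ref$length
    rng <- full_range(ref)
    lv <- spec$length_variant_regions[[1]]
    avail <- setdiff(seq_len(L), range_positions(lv, L))
    avail <- sample(avail)
    used <- integer(0)
    take <- function(n) {
      p <- avail[seq_len(n)]
      avail <<- avail[-seq_len(n)]
      used <<- c(used, p)
      p
    }
    alt_base <- function(p) {
      b <- ref_base(ref, p)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }
    motifs <- list(motif("HG0", NA_character_, haplotype("HG0", rng, L = L)))
    depth <- c(HG0 = 0L)
    n_extra <- max(spec$n_haplogroups - 1L, 0L)
    for (i in seq_len(n_extra)) {
      eligible <- names(depth)[depth < spec$tree_depth]
      par <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      pm <- motifs[[match(par, vapply(motifs, `[[`, character(1), "haplogroup"))]]
      pos <- take(spec$motif_separation)
      newv <- do.call(rbind, lapply(pos, function(p)
        variant_row("sub", p, 0L, alt_base(p))))
      nm <- paste0("HG", i)
      motifs[[length(motifs) + 1L]] <-
        motif(nm, par, haplotype(nm, rng, rbind(pm$haplotype$variants, newv), L = L))
      depth[nm] <- depth[[par]] + 1L
    }
    ## one starred subclade of the last non-root node
    if (n_extra >= 1L) {
      base_nm <- paste0("HG", n_extra)
      bm <- motifs[[match(base_nm, vapply(motifs, `[[`, character(1), "haplogroup"))]]
      pos <- take(max(3L, spec$motif_separation))
      newv <- do.call(rbind, lapply(pos, function(p)
        variant_row("sub", p, 0L, alt_base(p))))
      nm <- paste0(base_nm, "*")
      motifs[[length(motifs) + 1L]] <-
        motif(nm, base_nm, haplotype(nm, rng, rbind(bm$haplotype$variants, newv), L = L))
    }
    ## widen one motif: first variant of HG1 becomes an ambiguity code
    if (n_extra >= 1L) {
      i1 <- match("HG1", vapply(motifs, `[[`, character(1), "haplogroup"))
      v <- motifs[[i1]]$haplotype$variants
      v$obs[1] <- iupac_union(c(v$obs[1], ref_base(ref, v$pos[1])))
      motifs[[i1]]$haplotype <- haplotype("HG1", rng, v, L = L)
    }
    db <- motif_db(motifs)
    attr(db, "used_positions") <- sort(used)
    db
  })
}

#' Simulate a query from a motif
#'
#' The query is the motif plus planted essential private substitutions at
#' unused positions, plus (per the spec's rates) a point heteroplasmy and a
#' length variant (a C inserted 3' of the planted homopolymer). The ground
#' truth records the source haplogroup and the planted tokens.
#'
#' @param m source `motif`.
#' @param spec a [fixture_spec()].
#' @param ref the toy reference.
#' @param db the fixture `motif_db` (for its `used_positions` bookkeeping).
#' @param n_private planted essential privates; `NULL` draws Poisson with
#'   mean `spec$private_rate`.
#' @param seed per-query seed (defaults to `spec$seed`).
#' @return list with `query` (a [haplotype()]) and `truth`
#'   (`haplogroup`, `planted` tokens).
#' @export
sample_query <- function(m, spec, ref, db, n_private = NULL,
                         seed = spec$seed) {
  with_seed(seed, {
    L <- ref$length
    used <- attr(db, "used_positions")
    lv <- spec$length_variant_regions[[1]]
    avail <- setdiff(seq_len(L), c(used, range_positions(lv, L)))
    if (is.null(n_private)) n_private <- stats::rpois(1L, spec$private_rate)
    v <- m$haplotype$variants
    planted <- empty_variants()
    if (n_private > 0L) {
      pos <- sample(avail, n_private)
      avail <- setdiff(avail, pos)
      for (p in pos) {
        b <- sample(setdiff(c("A", "C", "G", "T"), ref_base(ref, p)), 1L)
        planted <- rbind(planted, variant_row("sub", p, 0L, b))
      }
    }
    if (stats::runif(1) < spec$heteroplasmy_rate) {
      p <- sample(avail, 1L)
      b <- sample(setdiff(c("A", "C", "G", "T"), ref_base(ref, p)), 1L)
      planted <- rbind(planted, variant_row("sub", p, 0L,
                                            iupac_union(c(ref_base(ref, p), b))))
    }
    if (stats::runif(1) < spec$length_variant_rate) {
      planted <- rbind(planted,
                       variant_row("ins", spec$cs_start + spec$c_stretch - 1L,
                                   1L, "C"))
    }
    q <- haplotype(paste0("q_", m$haplogroup, "_", seed), m$haplotype$range,
                   rbind(v, planted), L = L)
    list(query = q,
         truth = list(haplogroup = m$haplogroup,
                      planted = serialize_variant(planted)))
  })
}

#' Write a complete fixture set to disk
#'
#' Emits the toy reference (FASTA), the motif table (TSV), a batch of
#' queries (EMPOP-style TSV) and their ground truth (TSV).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @param n_queries queries to simulate (motifs cycled through).
#' @return invisibly, the list of file paths.
#' @export
write_fixtures <- function(spec, dir, n_queries = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(spec)
  db <- make_motif_tree(spec, ref)
  paths <- list(reference = file.path(dir, "reference.fasta"),
                motifs = file.path(dir, "motifs.tsv"),
                queries = file.path(dir, "queries.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_fasta(ref, paths$reference)
  write_motif_table(db, paths$motifs)
  nms <- names(db$motifs)
  rows <- lapply(seq_len(n_queries), function(i) {
    m <- db$motifs[[nms[(i - 1L) %% length(nms) + 1L]]]
    sq <- sample_query(m, spec, ref, db, seed = spec$seed + i)
    data.frame(sample_id = sq$query$sample_id,
               range = format(sq$query$range),
               variants = format(sq$query),
               haplogroup = sq$truth$haplogroup,
               planted = paste(sq$truth$planted, collapse = " "),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab[, c("sample_id", "range", "variants")], paths$queries,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tab[, c("sample_id", "haplogroup", "planted")], paths$truth,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
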