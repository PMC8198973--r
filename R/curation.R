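## Automatable parts of the motif-revision procedure: quality vetting of
## full mitogenomes, widening of motifs with IUPAC codes to absorb frequent
## within-haplogroup mutations, and detection of apparent yet unnamed
## subclades from shared essential private mutations.

#' Vet a mitogenome sequence
#'
#' A mitogenome passes if its length is at least 16,539 bp (30 bp below the
#' standard 16,569) and it harbors at most nine IUPAC-ambiguous symbols
#' (e.g. N, Y, M). Both rules are always evaluated.
#'
#' @param seq sequence string (or character vector of single symbols).
#' @param id sample identifier for the report.
#' @param min_length,max_ambiguous the two thresholds.
#' @return A `vetting_report`: list with `sample_id`, `length`,
#'   `ambiguous_count`, `passed`, `reasons`.
#' @export
vet_mitogenome <- function(seq, id = "", min_length = 16539L, max_ambiguous = 9L) {
  if (length(seq) == 1L) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(seq)
  bad <- setdiff(unique(seq), names(.iupac_mask))
  if (length(bad))
    stop("non-IUPAC symbol(s) in sequence ", id, ": ", paste(bad, collapse = ","))
  len <- length(seq)
  amb <- sum(iupac_ambiguous(seq))
  reasons <- character(0)
  if (len < min_length)
    reasons <- c(reasons, sprintf("length %d < %d", len, min_length))
  if (amb > max_ambiguous)
    reasons <- c(reasons, sprintf("%d ambiguous symbols > %d", amb, max_ambiguous))
  structure(list(sample_id = id, length = len, ambiguous_count = amb,
                 passed = !length(reasons), reasons = reasons),
            class = "vetting_report")
}

#' Vet a batch of sequences and tabulate the reports
#' @param seqs list of `ref_sequence` objects (e.g. from [read_fasta()]).
#' @param ... passed to [vet_mitogenome()].
#' @return data.frame with one row per sequence.
#' @export
vet_batch <- function(seqs, ...) {
  rep <- lapply(seqs, function(s) vet_mitogenome(s$symbols, s$name, ...))
  data.frame(
    sample_id = vapply(rep, `[[`, character(1), "sample_id"),
    length = vapply(rep, `[[`, integer(1), "length"),
    ambiguous_count = vapply(rep, `[[`, integer(1), "ambiguous_count"),
    passed = vapply(rep, `[[`, logical(1), "passed"),
    reasons = vapply(rep, function(r) paste(r$reasons, collapse = "; "), character(1)),
    stringsAsFactors = FALSE)
}

## observed base of a haplotype at a full position (variant or reference)
.base_at <- function(h, pos, ref) {
  i <- which(h$variants$pos == pos & h$variants$ins == 0L)
  if (length(i)) {
    if (h$variants$kind[i] == "del") return(NA_character_)
    return(h$variants$obs[i])
  }
  ref_base(ref, pos)
}

#' Widen a motif to cover frequent mutations of its members
#'
#' For each position where an alternative base is observed in at least
#' `min_freq` of the member haplotypes (and in at least two members), the
#' motif symbol is replaced by the minimal IUPAC code covering both states
#' (e.g. a frequent G->A transition widens the motif symbol to R). Widening
#' can only lower search costs, never raise them.
#'
#' @param m a `motif`.
#' @param member_haplotypes list of [haplotype()] assigned to the motif's
#'   haplogroup, over the motif's range.
#' @param ref a [ref_sequence()].
#' @param min_freq minimum member fraction; default 0.25.
#' @param min_carriers minimum member count; default 2.
#' @return The widened `motif`.
#' @export
widen_motif <- function(m, member_haplotypes, ref, min_freq = 0.25,
                        min_carriers = 2L) {
  h <- m$haplotype
  nmem <- length(member_haplotypes)
  if (!nmem) return(m)
  ## candidate positions: substitution variants seen in any member
  cand <- unique(unlist(lapply(member_haplotypes, function(mh)
    mh$variants$pos[mh$variants$kind == "sub"])))
  v <- h$variants
  for (p in cand) {
    motif_base <- .base_at(h, p, ref)
    if (is.na(motif_base)) next
    obs <- vapply(member_haplotypes, .base_at, character(1), pos = p, ref = ref)
    obs <- obs[!is.na(obs)]
    alt <- obs[!vapply(obs, iupac_subset, logical(1), b = motif_base)]
    if (!length(alt)) next
    tab <- table(alt)
    for (b in names(tab)) {
      if (tab[[b]] >= min_carriers && tab[[b]] / nmem >= min_freq) {
        widened <- iupac_union(c(motif_base, b))
        i <- which(v$pos == p & v$ins == 0L)
        if (length(i)) { v$obs[i] <- widened
        } else v <- rbind(v, variant_row("sub", p, 0L, widened))
      }
    }
  }
  motif(m$haplogroup, m$parent, haplotype(h$sample_id, h$range, v, L = h$L))
}

## essential extra variant tokens of a member relative to the base motif
.extra_tokens <- function(mh, base_h, length_variant_regions, L) {
  mt <- serialize_variant(base_h$variants)
  v <- mh$variants
  if (!nrow(v)) return(character(0))
  tok <- serialize_variant(v)
  extra <- v[!(tok %in% mt), , drop = FALSE]
  if (!nrow(extra)) return(character(0))
  cls <- classify_variant(extra, length_variant_regions, L)
  serialize_variant(extra[cls == "essential", , drop = FALSE])
}

#' Detect apparent, yet unnamed, subclades of a haplogroup
#'
#' Finds maximal sets of at least `min_variants` shared essential extra
#' variants (relative to the base motif) carried by at least `min_carriers`
#' member haplotypes. Nested candidates (sub-subclades) are allowed; names
#' are generated as `base*`, `base*1`, ... with letter suffixes for nesting
#' (`base*1a`).
#'
#' @param base a `motif`.
#' @param member_haplotypes list of [haplotype()] over the motif's range.
#' @param min_variants minimum shared extra variants; default 3.
#' @param min_carriers minimum carriers; default 2. Single-carrier
#'   candidates require `allow_single_carrier = TRUE`.
#' @param allow_single_carrier override for the documented exceptional
#'   single-mitogenome subclades.
#' @param length_variant_regions see [classify_variant()].
#' @return list of `subclade_candidate` objects: `base_haplogroup`,
#'   `extra_variants` (tokens), `carriers`, `proposed_name`.
#' @export
detect_subclades <- function(base, member_haplotypes, min_variants = 3L,
                             min_carriers = 2L, allow_single_carrier = FALSE,
                             length_variant_regions = default_length_variant_regions()) {
  if (allow_single_carrier) min_carriers <- 1L
  L <- base$haplotype$L
  ids <- vapply(seq_along(member_haplotypes), function(i) {
    id <- member_haplotypes[[i]]$sample_id
    if (nzchar(id)) id else paste0("member", i)
  }, character(1))
  extras <- lapply(member_haplotypes, .extra_tokens, base_h = base$haplotype,
                   length_variant_regions = length_variant_regions, L = L)
  names(extras) <- ids

  carriers_of <- function(S) ids[vapply(extras, function(e) all(S %in% e), logical(1))]
  closure_of <- function(carriers) Reduce(intersect, extras[carriers])

  ## closed shared-variant sets: start from each member's extra set and
  ## close under pairwise intersection
  pool <- unique(lapply(extras[lengths(extras) > 0], sort))
  repeat {
    grew <- FALSE
    for (a in seq_along(pool)) for (b in seq_along(pool)) {
      s <- sort(intersect(pool[[a]], pool[[b]]))
      if (length(s) && !any(vapply(pool, identical, logical(1), y = s))) {
        pool[[length(pool) + 1L]] <- s; grew <- TRUE
      }
    }
    if (!grew) break
  }
  cand <- list()
  for (S in pool) {
    if (length(S) < min_variants) next
    carr <- carriers_of(S)
    if (length(carr) < min_carriers) next
    if (!identical(sort(closure_of(carr)), S)) next  # not maximal for its carriers
    cand[[length(cand) + 1L]] <- list(extra_variants = S, carriers = carr)
  }
  if (!length(cand)) return(list())
  ## deterministic order: larger carrier sets (broader clades) first
  ord <- order(-vapply(cand, function(x) length(x$carriers), integer(1)),
               vapply(cand, function(x) length(x$extra_variants), integer(1)),
               vapply(cand, function(x) paste(x$extra_variants, collapse = " "),
                      character(1)))
  cand <- cand[ord]
  ## name top-level candidates base*, base*1, ...; nested ones get letters
  names_out <- character(length(cand))
  top_ct <- 0L
  for (i in seq_along(cand)) {
    parent <- NA_integer_
    for (j in seq_len(i - 1L)) {
      if (all(cand[[j]]$extra_variants %in% cand[[i]]$extra_variants) &&
          length(cand[[j]]$extra_variants) < length(cand[[i]]$extra_variants))
        parent <- j  # last (most specific) enclosing candidate wins
    }
    if (is.na(parent)) {
      top_ct <- top_ct + 1L
      names_out[i] <- if (top_ct == 1L) paste0(base$haplogroup, "*")
                      else paste0(base$haplogroup, "*", top_ct)
    } else {
      kids <- sum(startsWith(names_out[seq_len(i - 1L)], names_out[parent]) ) - 1L
      names_out[i] <- paste0(names_out[parent], letters[kids + 1L])
    }
  }
  lapply(seq_along(cand), function(i) {
    structure(list(base_haplogroup = base$haplogroup,
                   extra_variants = cand[[i]]$extra_variants,
                   carriers = cand[[i]]$carriers,
                   proposed_name = names_out[i]),
              class = "subclade_candidate")
  })
}

#' @export
print.subclade_candidate <- function(x, ...) {
  cat("<subclade_candidate> ", x$proposed_name, ": ",
      paste(x$extra_variants, collapse = " "), " [", length(x$carriers),
      " carriers]\n", sep = "")
  invisible(x)
}
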