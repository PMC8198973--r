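## Weighted nearest-motif search over a condensed motif database.
##
## The cost of a query against a motif is the summed weight of its
## essential private mutations: differences that are neither resolutions of
## motif ambiguity/optional symbols, nor point heteroplasmies (ambiguous
## observed symbol), nor length variants (indels in configured
## length-variable regions). Costs are clustered by a margin into rank-1
## and rank-2 neighbor sets, each folded into a single-haplogroup estimate
## by the MRCA on the haplogroup tree.

## transcript ops (non-resolutions) -> private-variant table
.ops_to_variants <- function(ops) {
  if (!nrow(ops)) return(empty_variants())
  do.call(rbind, lapply(seq_len(nrow(ops)), function(i) {
    r <- ops[i, ]
    switch(r$kind,
           sub = variant_row("sub", r$pos, r$ins, r$to),
           ins = variant_row("ins", r$pos, r$ins + 1L, r$to),
           del = variant_row("del", r$pos, r$ins))
  }))
}

#' Cost of a query against one condensed motif entry
#'
#' Runs [best_transcript()] and scores the true edits: each private variant
#' is classified via [classify_variant()]; only essential privates
#' contribute their weight, heteroplasmies and length variants contribute
#' zero, and pure ambiguity/optional resolutions are not privates at all.
#'
#' @param query a [haplotype()].
#' @param entry_h condensed motif haplotype (or a `condensed_db` entry).
#' @param ref a [ref_sequence()].
#' @param range common reading range (defaults to the query's).
#' @param weights a [weight_table()].
#' @param length_variant_regions see [classify_variant()].
#' @return A `costed_neighbor`: list with `haplogroups`, `cost`,
#'   `privates` (variant table with a `class` column), `n_essential`,
#'   and `transcript`.
#' @export
neighbor_cost <- function(query, entry_h, ref, range = query$range,
                          weights = weight_table(),
                          length_variant_regions = default_length_variant_regions()) {
  haplogroups <- character(0)
  if (is.list(entry_h) && !inherits(entry_h, "haplotype") &&
      !is.null(entry_h$haplotype)) {
    haplogroups <- entry_h$haplogroups %||% character(0)
    entry_h <- entry_h$haplotype
  }
  t <- best_transcript(query, entry_h, ref, range, weights)
  pr_ops <- t$ops[!t$ops$resolution, , drop = FALSE]
  privates <- .ops_to_variants(pr_ops)
  cls <- classify_variant(privates, length_variant_regions, L = ref$length)
  privates$class <- cls
  cost <- if (nrow(pr_ops)) sum(pr_ops$cost[cls == "essential"]) else 0
  structure(list(haplogroups = haplogroups, cost = cost, privates = privates,
                 n_essential = sum(cls == "essential"), transcript = t),
            class = "costed_neighbor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count the essential private mutations of a query against a motif
#'
#' @inheritParams neighbor_cost
#' @param motif_h motif haplotype (or `motif`).
#' @return integer count.
#' @export
count_essential_privates <- function(query, motif_h, ref, range = query$range,
                                     weights = weight_table(),
                                     length_variant_regions = default_length_variant_regions()) {
  if (inherits(motif_h, "motif")) motif_h <- motif_h$haplotype
  neighbor_cost(query, motif_h, ref, range, weights, length_variant_regions)$n_essential
}

#' Cluster costed neighbors into rank-1/rank-2 sets with MRCA estimates
#'
#' Rank 1 collects all neighbors within `margin` of the global minimum
#' cost; rank 2 collects, among the remainder, all neighbors within
#' `margin` of the remainder's minimum. Each rank is folded into a single
#' haplogroup estimate by [mrca()] over the union of its names.
#'
#' @param neighbors non-empty list of `costed_neighbor` objects.
#' @param db the `motif_db` (for MRCA queries).
#' @param margin clustering margin; default 0.5.
#' @return A `search_result`: `rank1`, `rank2` (lists of neighbors, sorted
#'   by cost), `mrca_rank1`, `mrca_rank2` (or `NA` if rank 2 is empty).
#' @export
rank_neighbors <- function(neighbors, db, margin = 0.5) {
  if (!length(neighbors)) stop("rank_neighbors: empty neighbor list")
  costs <- vapply(neighbors, function(x) x$cost, numeric(1))
  cmin <- min(costs)
  r1 <- which(costs <= cmin + margin)
  rest <- setdiff(seq_along(neighbors), r1)
  r2 <- if (length(rest)) {
    c2 <- min(costs[rest])
    rest[costs[rest] <= c2 + margin]
  } else integer(0)
  names1 <- unlist(lapply(neighbors[r1], function(x) x$haplogroups))
  names2 <- unlist(lapply(neighbors[r2], function(x) x$haplogroups))
  structure(list(
    rank1 = neighbors[r1[order(costs[r1])]],
    rank2 = neighbors[r2[order(costs[r2])]],
    rank1_names = sort(unique(names1)),
    rank2_names = sort(unique(names2)),
    mrca_rank1 = if (length(names1)) mrca(db, names1) else NA_character_,
    mrca_rank2 = if (length(names2)) mrca(db, names2) else NA_character_),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>\n",
      " rank 1: ", paste(x$rank1_names, collapse = ", "),
      " (cost ", signif(x$rank1[[1]]$cost, 4), ", MRCA ", x$mrca_rank1, ")\n",
      sep = "")
  if (length(x$rank2))
    cat(" rank 2: ", paste(x$rank2_names, collapse = ", "),
        " (MRCA ", x$mrca_rank2, ")\n", sep = "")
  invisible(x)
}

#' Nearest-motif haplogroup search for one query
#'
#' Condenses the motif database to the query's reading range, costs every
#' distinct condensed entry and clusters the results.
#'
#' @param query a [haplotype()].
#' @param db a `motif_db`.
#' @param ref a [ref_sequence()].
#' @param weights a [weight_table()].
#' @param margin rank-clustering margin.
#' @param length_variant_regions see [classify_variant()].
#' @param cdb optionally a pre-computed `condensed_db` for `query$range`
#'   (avoids re-condensing in batch runs).
#' @return A `search_result`.
#' @export
search_haplogroups <- function(query, db, ref, weights = weight_table(),
                               margin = 0.5,
                               length_variant_regions = default_length_variant_regions(),
                               cdb = NULL) {
  if (!length(db$motifs)) stop("empty motif database")
  if (is.null(cdb)) cdb <- condense_db(db, query$range)
  neighbors <- lapply(cdb$entries, function(e)
    neighbor_cost(query, e, ref, query$range, weights, length_variant_regions))
  rank_neighbors(neighbors, db, margin)
}

#' Haplogroup estimation plus phylogenetic alignment for one query
#'
#' Runs the nearest-motif search, computes the best transcript to the
#' rank-1 nearest motif (alphabetically first haplogroup on cost ties) and
#' rewrites that motif's alignment via [apply_transcript()].
#'
#' @inheritParams search_haplogroups
#' @return list with `search` (a `search_result`), `nearest` (haplogroup
#'   name used for the alignment), `transcript`, and `alignment` (the
#'   query's phylogenetic alignment as a [haplotype()]).
#' @export
align_query <- function(query, db, ref, weights = weight_table(),
                        margin = 0.5,
                        length_variant_regions = default_length_variant_regions(),
                        cdb = NULL) {
  res <- search_haplogroups(query, db, ref, weights, margin,
                            length_variant_regions, cdb)
  costs <- vapply(res$rank1, function(x) x$cost, numeric(1))
  nearest <- res$rank1[costs <= min(costs) + 1e-9]
  firsts <- vapply(nearest, function(x) sort(x$haplogroups)[1], character(1))
  pick <- nearest[[order(firsts)[1]]]
  entry_h <- condense_haplotype(
    db$motifs[[sort(pick$haplogroups)[1]]]$haplotype, query$range)
  entry_h$sample_id <- query$sample_id
  alignment <- apply_transcript(entry_h, pick$transcript, ref)
  list(search = res, nearest = sort(pick$haplogroups)[1],
       transcript = pick$transcript, alignment = alignment)
}
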