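## Haplogroup motif database: named motifs on a rooted haplogroup tree.
##
## A motif is a haplogroup's defining haplotype, expressed as differences to
## the rCRS over the full mitogenome range. Starred names ("HV*", "L2a5*1a")
## denote unnamed subclades and are ordinary children of their base
## haplogroup; "+"-suffixed names ("A2+(64)+16189") are opaque text.

motif <- function(haplogroup, parent, haplotype) {
  structure(list(haplogroup = haplogroup, parent = parent, haplotype = haplotype),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif> ", x$haplogroup,
      if (!is.na(x$parent) && nzchar(x$parent)) paste0(" (parent ", x$parent, ")"),
      ": ", format(x$haplotype), "\n", sep = "")
  invisible(x)
}

#' Build a motif database from motifs
#'
#' Validates that parent links form a single rooted tree (exactly one root,
#' no cycles, no unknown parents).
#'
#' @param motifs list of motif objects (name, parent, haplotype).
#' @return An object of class `motif_db` with fields `motifs` (named list),
#'   `parent` (named character vector, `NA` at the root) and `root`.
#' @export
motif_db <- function(motifs) {
  names(motifs) <- vapply(motifs, function(m) m$haplogroup, character(1))
  if (anyDuplicated(names(motifs)))
    stop("duplicate haplogroup names: ",
         paste(unique(names(motifs)[duplicated(names(motifs))]), collapse = ", "))
  parent <- vapply(motifs, function(m) {
    p <- m$parent
    if (is.null(p) || is.na(p) || !nzchar(p)) NA_character_ else p
  }, character(1))
  roots <- names(parent)[is.na(parent)]
  if (length(roots) != 1L)
    stop("motif table must have exactly one root; found ", length(roots))
  unknown <- setdiff(parent[!is.na(parent)], names(motifs))
  if (length(unknown))
    stop("unknown parent haplogroup(s): ", paste(unknown, collapse = ", "))
  ## cycle check: walk each node to the root
  for (n in names(motifs)) {
    seen <- character(); cur <- n
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("cycle in haplogroup tree at ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(list(motifs = motifs, parent = parent, root = roots), class = "motif_db")
}

#' @export
print.motif_db <- function(x, ...) {
  starred <- sum(grepl("\\*", names(x$motifs)))
  cat("<motif_db> ", length(x$motifs), " motifs (", starred,
      " starred subclades), root ", x$root, "\n", sep = "")
  invisible(x)
}

#' Number of motifs in a database
#' @param db a `motif_db`.
#' @export
n_motifs <- function(db) length(db$motifs)

#' Load a motif table from TSV
#'
#' Expected dialect: tab-separated with header `haplogroup`, `parent`,
#' `variants` (space-separated rCRS-relative tokens; empty at the root).
#' An empty `parent` field marks the root.
#'
#' @param path TSV file.
#' @param L reference length (16569 for the rCRS).
#' @param range reading range the motifs are expressed over; defaults to the
#'   full mitogenome `1-L`.
#' @param quiet suppress the loaded-count message.
#' @return A `motif_db`.
#' @export
load_motif_table <- function(path, L = 16569L, range = reading_range(1L, L),
                             quiet = FALSE) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("haplogroup", "parent", "variants")
  if (!all(need %in% names(tab)))
    stop("motif table needs columns: ", paste(need, collapse = ", "))
  motifs <- lapply(seq_len(nrow(tab)), function(i) {
    motif(tab$haplogroup[i], tab$parent[i],
          parse_haplotype(tab$variants[i], range, tab$haplogroup[i], L = L))
  })
  db <- motif_db(motifs)
  if (!quiet) {
    starred <- sum(grepl("\\*", names(db$motifs)))
    message("loaded ", n_motifs(db), " motifs (", starred, " starred subclades)")
  }
  db
}

#' Write a motif database in the same TSV dialect the loader reads
#' @param db a `motif_db`.
#' @param path output file.
#' @export
write_motif_table <- function(db, path) {
  tab <- data.frame(
    haplogroup = names(db$motifs),
    parent = ifelse(is.na(db$parent), "", db$parent),
    variants = vapply(db$motifs, function(m) format(m$haplotype), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Complete a raw Phylotree-style motif with the standard notation
#'
#' Phylotree disregards some near-universal control-region features, so raw
#' motifs are completed before use: `16519Y` is added to ignore the frequent
#' transition T16519C (except for haplogroup B2m, which bears 16519A); the
#' possible insertion `315.1c` (C or gap) is added; `16182M 16183M` are
#' added to absorb the common A/C transversions next to 16189 (for
#' B4a1a1a16, which bears 16182T, only `16183M` is added). A variant already
#' present at a position is never duplicated; the operation is idempotent.
#'
#' @param m a motif.
#' @return The completed motif.
#' @export
complete_pt17_motif <- function(m) {
  h <- m$haplotype
  has <- function(pos, ins = 0L) any(h$variants$pos == pos & h$variants$ins == ins)
  add <- list()
  if (!identical(m$haplogroup, "B2m") && !has(16519L))
    add <- c(add, list(variant_row("sub", 16519L, obs = "Y")))
  if (!has(315L, 1L))
    add <- c(add, list(variant_row("ins", 315L, 1L, "C", optional = TRUE)))
  if (!identical(m$haplogroup, "B4a1a1a16") && !has(16182L))
    add <- c(add, list(variant_row("sub", 16182L, obs = "M")))
  if (!has(16183L))
    add <- c(add, list(variant_row("sub", 16183L, obs = "M")))
  if (length(add)) {
    v <- rbind(h$variants, do.call(rbind, add))
    h <- haplotype(h$sample_id, h$range, v, L = h$L)
  }
  motif(m$haplogroup, m$parent, h)
}

#' Condense a motif database to a reading range
#'
#' Every motif is condensed via [condense_haplotype()]; identical condensed
#' variant lists (including optionality flags) are merged into one entry
#' mapping to the set of haplogroup names that share it. This is what makes
#' the neighbor search over a reduced reading range cheap: e.g. restriction
#' to the control region almost halves the database.
#'
#' @param db a `motif_db`.
#' @param range target [reading_range()].
#' @return An object of class `condensed_db`: fields `range` and `entries`,
#'   a list of `list(haplotype =, haplogroups =)` with pairwise distinct
#'   variant lists.
#' @export
condense_db <- function(db, range) {
  keys <- character(0)
  entries <- list()
  for (nm in names(db$motifs)) {
    ch <- condense_haplotype(db$motifs[[nm]]$haplotype, range)
    key <- format(ch)
    i <- match(key, keys)
    if (is.na(i)) {
      keys <- c(keys, key)
      entries[[length(entries) + 1L]] <- list(haplotype = ch, haplogroups = nm)
    } else {
      entries[[i]]$haplogroups <- c(entries[[i]]$haplogroups, nm)
    }
  }
  structure(list(range = range, entries = entries), class = "condensed_db")
}

#' @export
print.condensed_db <- function(x, ...) {
  cat("<condensed_db> ", length(x$entries), " distinct entries over ",
      format(x$range), "\n", sep = "")
  invisible(x)
}

## path from root to a node, inclusive
.root_path <- function(db, name) {
  path <- name; cur <- name
  while (!is.na(db$parent[[cur]])) {
    cur <- db$parent[[cur]]
    path <- c(cur, path)
  }
  path
}

#' Most recent common ancestor of haplogroups
#'
#' The deepest node of the haplogroup tree that is ancestor-or-equal of
#' every name in the set. Used to fold rank-1/rank-2 neighbor sets into
#' single-haplogroup estimates.
#'
#' @param db a `motif_db`.
#' @param names non-empty character vector of haplogroup names in `db`.
#' @return A haplogroup name.
#' @export
mrca <- function(db, names) {
  names <- unique(names)
  if (!length(names)) stop("mrca of an empty set")
  missing <- setdiff(names, names(db$motifs))
  if (length(missing))
    stop("unknown haplogroup(s): ", paste(missing, collapse = ", "))
  paths <- lapply(names, .root_path, db = db)
  common <- paths[[1]]
  for (p in paths[-1]) {
    n <- min(length(common), length(p))
    eq <- common[seq_len(n)] == p[seq_len(n)]
    k <- if (all(eq)) n else which(!eq)[1] - 1L
    if (k == 0L) stop("haplogroups share no common ancestor")
    common <- common[seq_len(k)]
  }
  common[length(common)]
}
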