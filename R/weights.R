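## Mutation weight tables.
##
## Weights come from an external ranking of position-specific mutation
## rates; the package consumes them as data and never derives them. The
## default table weights every mutation 1, which reduces the search cost to
## a count of essential private mutations.

#' Construct a mutation weight table
#'
#' @param entries `NULL` (unit weights) or a data.frame with columns
#'   `position` (integer; `NA` matches any position), `mutation` (an exact
#'   descriptor such as `"A73G"`, `"309insC"`, `"524del"`, or a class:
#'   `"transition"`, `"transversion"`, `"substitution"`, `"insertion"`,
#'   `"deletion"`) and `weight` (> 0).
#' @param default positive fallback weight for unlisted mutations.
#' @return An object of class `weight_table`.
#' @export
weight_table <- function(entries = NULL, default = 1) {
  if (!is.null(entries)) {
    need <- c("position", "mutation", "weight")
    if (!all(need %in% names(entries)))
      stop("weight table needs columns: ", paste(need, collapse = ", "))
    entries$position <- suppressWarnings(as.integer(entries$position))
    entries$weight <- as.numeric(entries$weight)
    if (any(!is.finite(entries$weight) | entries$weight <= 0))
      stop("weights must be positive")
  }
  if (!is.finite(default) || default <= 0) stop("default weight must be positive")
  structure(list(entries = entries, default = default), class = "weight_table")
}

#' Read a weight table from TSV (columns position, mutation, weight)
#' @param path TSV file; an empty `position` field matches any position.
#' @param default fallback weight.
#' @export
read_weight_table <- function(path, default = 1) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  weight_table(tab, default = default)
}

## weight of a single mutation; descriptor candidates are tried from most
## to least specific, position-matched before position-free rows
lookup_weight <- function(wt, pos, candidates) {
  e <- wt$entries
  if (is.null(e) || !nrow(e)) return(wt$default)
  for (posmatch in c(TRUE, FALSE)) {
    rows <- if (posmatch) e[!is.na(e$position) & e$position == pos, , drop = FALSE]
            else e[is.na(e$position), , drop = FALSE]
    if (!nrow(rows)) next
    for (cand in candidates) {
      hit <- match(cand, rows$mutation)
      if (!is.na(hit)) return(rows$weight[hit])
    }
  }
  wt$default
}

sub_weight <- function(wt, pos, from, to) {
  cls <- if (!iupac_ambiguous(from) && !iupac_ambiguous(to)) {
    if (is_transition(from, to)) "transition" else "transversion"
  } else "substitution"
  lookup_weight(wt, pos, c(paste0(from, pos, to), paste0(pos, to),
                           cls, "substitution"))
}

ins_weight <- function(wt, pos, base) {
  lookup_weight(wt, pos, c(paste0(pos, "ins", base), "insertion", "indel"))
}

del_weight <- function(wt, pos, base) {
  lookup_weight(wt, pos, c(paste0(pos, "del"), paste0(pos, "del", base),
                           "deletion", "indel"))
}
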