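## rCRS-relative variant notation.
##
## A variant table is a data.frame with one row per variant and columns
##   kind     "sub" | "ins" | "del"
##   pos      1-based anchor position
##   ins      insertion index (309.1 -> 1); 0 for non-insertions
##   obs      observed IUPAC symbol, uppercase; NA for deletions
##   optional logical; lowercase notation (symbol may also be absent)

empty_variants <- function() {
  data.frame(kind = character(), pos = integer(), ins = integer(),
             obs = character(), optional = logical(), stringsAsFactors = FALSE)
}

variant_row <- function(kind, pos, ins = 0L, obs = NA_character_, optional = FALSE) {
  data.frame(kind = kind, pos = as.integer(pos), ins = as.integer(ins),
             obs = obs, optional = optional, stringsAsFactors = FALSE)
}

#' Parse one rCRS-relative variant token
#'
#' Accepted grammar (forensic EMPOP-style notation):
#' \itemize{
#'   \item `73G` substitution; IUPAC ambiguity codes denote point
#'     heteroplasmy (`16093Y`); a lowercase base marks an optional symbol.
#'   \item `309.1C` insertion after anchor 309, index 1; `315.1c` optional
#'     insertion (C or gap).
#'   \item `524del` or `524d` deletion (lowercase `d`; uppercase `D` is the
#'     IUPAC code A/G/T and reads as a substitution).
#' }
#'
#' @param token character scalar.
#' @param L optional reference length for position validation.
#' @return One-row variant data.frame.
#' @examples
#' parse_variant_token("309.1C")
#' parse_variant_token("315.1c")  # optional insertion
#' parse_variant_token("524d")
#' @export
parse_variant_token <- function(token, L = NULL) {
  tk <- trimws(token)
  check_pos <- function(p) {
    if (p < 1L || (!is.null(L) && p > L))
      stop("position out of range in variant token: ", tk)
    p
  }
  m <- regmatches(tk, regexec("^([0-9]+)(del|DEL|d)$", tk))[[1]]
  if (length(m)) {
    return(variant_row("del", check_pos(as.integer(m[2]))))
  }
  m <- regmatches(tk, regexec("^([0-9]+)\\.([0-9]+)([A-Za-z])$", tk))[[1]]
  if (length(m)) {
    k <- as.integer(m[3])
    if (k < 1L) stop("insertion index must be >= 1: ", tk)
    if (!iupac_ok(m[4])) stop("not an IUPAC symbol in token: ", tk)
    return(variant_row("ins", check_pos(as.integer(m[2])), k,
                       toupper(m[4]), optional = m[4] %in% letters))
  }
  m <- regmatches(tk, regexec("^([0-9]+)([A-Za-z])$", tk))[[1]]
  if (length(m)) {
    if (!iupac_ok(m[3])) stop("not an IUPAC symbol in token: ", tk)
    return(variant_row("sub", check_pos(as.integer(m[2])), 0L,
                       toupper(m[3]), optional = m[3] %in% letters))
  }
  stop("malformed variant token: ", tk)
}

#' Serialize a variant to its text token
#'
#' Inverse of [parse_variant_token()]; deletions serialize canonically as
#' `"<pos>del"` (input `"d"` normalizes to `"del"`), optional symbols print
#' lowercase.
#'
#' @param v variant data.frame (one or more rows).
#' @return character vector of tokens.
#' @export
serialize_variant <- function(v) {
  vapply(seq_len(nrow(v)), function(i) {
    r <- v[i, ]
    obs <- if (isTRUE(r$optional)) tolower(r$obs) else r$obs
    switch(r$kind,
           sub = paste0(r$pos, obs),
           ins = paste0(r$pos, ".", r$ins, obs),
           del = paste0(r$pos, "del"),
           stop("unknown variant kind: ", r$kind))
  }, character(1))
}

## sort variants in circular range order; validate uniqueness/containment
order_variants <- function(v, range, L) {
  if (!nrow(v)) return(v)
  key <- range_offset(v$pos, range, L) * 1e6 + v$ins
  v <- v[order(key), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Haplotypes: a reading range plus an ordered variant list
#'
#' A haplotype doubles as an alignment: it is the rCRS-relative variant
#' representation of a sequence over its reading range.
#'
#' @param sample_id text identifier.
#' @param range a [reading_range()].
#' @param variants variant data.frame (see [parse_variant_token()]).
#' @param L reference length used for circular ordering and containment
#'   checks (defaults to 16569, the rCRS).
#' @return An object of class `haplotype`.
#' @export
haplotype <- function(sample_id, range, variants = empty_variants(), L = 16569L) {
  stopifnot(inherits(range, "reading_range"))
  if (nrow(variants)) {
    out <- !in_range(variants$pos, range, L)
    if (any(out))
      stop("variant outside reading range ", format(range), ": ",
           paste(serialize_variant(variants[out, , drop = FALSE]), collapse = " "))
    key <- paste(variants$pos, variants$ins)
    if (anyDuplicated(key))
      stop("duplicate variant position: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    bad <- variants$kind == "ins" & variants$ins == 0L
    if (any(bad)) stop("insertion with index 0")
    variants <- order_variants(variants, range, L)
  }
  structure(list(sample_id = sample_id, range = range, variants = variants, L = L),
            class = "haplotype")
}

#' Parse a whitespace-separated variant list into a haplotype
#'
#' @param line text such as `"16111T 16189C 16192.1T 73G"`; the empty string
#'   yields a reference-identical haplotype.
#' @param range the declared reading range.
#' @param sample_id identifier stored on the haplotype.
#' @param L reference length.
#' @return A `haplotype`.
#' @export
parse_haplotype <- function(line, range, sample_id = "", L = 16569L) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  v <- if (length(toks)) do.call(rbind, lapply(toks, parse_variant_token, L = L))
       else empty_variants()
  haplotype(sample_id, range, v, L = L)
}

#' @export
format.haplotype <- function(x, ...) {
  paste(serialize_variant(x$variants), collapse = " ")
}

#' Serialize a haplotype's variant list
#' @param h a `haplotype`.
#' @return single string of space-separated tokens (empty if none).
#' @export
serialize_haplotype <- function(h) format(h)

#' @export
print.haplotype <- function(x, ...) {
  cat("<haplotype> ", x$sample_id, " [", format(x$range), "] ",
      if (nrow(x$variants)) format(x) else "(rCRS)", "\n", sep = "")
  invisible(x)
}

#' Condense a haplotype to a sub-range
#'
#' Restricts the variant list to positions inside `sub` and replaces the
#' reading range. Used to condense full-mitogenome motifs to, e.g., the
#' control region.
#'
#' @param h a `haplotype`.
#' @param sub a [reading_range()] contained in `h$range`.
#' @return The condensed `haplotype`.
#' @export
condense_haplotype <- function(h, sub) {
  if (!range_contains(h$range, sub, h$L))
    stop("sub-range ", format(sub), " not contained in ", format(h$range))
  keep <- in_range(h$variants$pos, sub, h$L)
  haplotype(h$sample_id, sub, h$variants[keep, , drop = FALSE], L = h$L)
}

#' Default length-variant regions of the mitochondrial genome
#'
#' The known length-variable stretches (poly-C tracts, the AC repeat and
#' related regions) inside which insertions/deletions are treated as length
#' variants rather than essential private mutations. Configurable in every
#' consumer; these defaults cover the commonly reported stretches around
#' 16189, CSB2, the 515-524 AC repeat, and the homopolymers near 960, 5898
#' and 8285.
#'
#' @return list of [reading_range()] objects.
#' @export
default_length_variant_regions <- function() {
  list(reading_range(16180, 16195),
       reading_range(302, 316),
       reading_range(513, 526),
       reading_range(955, 966),
       reading_range(5895, 5900),
       reading_range(8270, 8289))
}

#' Classify a variant as essential, heteroplasmy or length variant
#'
#' A private mutation is essential if it is neither a point heteroplasmy
#' (IUPAC-ambiguous observed symbol, e.g. `16093Y`) nor a length variant
#' (an indel anchored inside a configured length-variant region, e.g.
#' `309.1C`).
#'
#' @param v variant data.frame (any number of rows).
#' @param length_variant_regions list of [reading_range()]; defaults to
#'   [default_length_variant_regions()].
#' @param L reference length.
#' @return character vector: `"essential"`, `"heteroplasmy"` or
#'   `"length_variant"` per row.
#' @export
classify_variant <- function(v, length_variant_regions = default_length_variant_regions(),
                             L = 16569L) {
  if (!nrow(v)) return(character())
  het <- !is.na(v$obs) & iupac_ambiguous(v$obs)
  in_lv <- rep(FALSE, nrow(v))
  for (r in length_variant_regions)
    in_lv <- in_lv | in_range(v$pos, r, L)
  lv <- v$kind %in% c("ins", "del") & in_lv
  ifelse(het, "heteroplasmy", ifelse(lv, "length_variant", "essential"))
}
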