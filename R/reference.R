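#' Reading ranges on a circular reference
#'
#' A reading range is a pair of 1-based inclusive positions on a (possibly
#' circular) reference. `start > end` is legal and denotes a wrap-around
#' range, e.g. the mtDNA control region `16024-576`.
#'
#' @param start,end 1-based inclusive positions.
#' @return An object of class `reading_range`.
#' @examples
#' reading_range(16024, 576)   # the control region, wrapping the origin
#' @export
reading_range <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("reading range needs scalar start and end")
  if (start < 1L || end < 1L) stop("reading range positions must be >= 1")
  structure(list(start = start, end = end), class = "reading_range")
}

#' Parse a range string such as "16024-576"
#' @param x character scalar `"start-end"`.
#' @return A `reading_range`.
#' @export
parse_range <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)[-–]([0-9]+)$", x))[[1]]
  if (length(m) != 3L) stop("malformed range: ", x)
  reading_range(as.integer(m[2]), as.integer(m[3]))
}

#' @export
format.reading_range <- function(x, ...) paste0(x$start, "-", x$end)

#' @export
print.reading_range <- function(x, ...) {
  cat("<reading_range> ", format(x), "\n", sep = ""); invisible(x)
}

## positions covered by a range, in range order (wraps modulo L)
range_positions <- function(range, L) {
  if (range$start > L || range$end > L) stop("range exceeds reference length")
  if (range$start <= range$end) range$start:range$end
  else c(range$start:L, 1:range$end)
}

range_length <- function(range, L) {
  if (range$start <= range$end) range$end - range$start + 1L
  else L - range$start + 1L + range$end
}

## offset of position p from range start, modulo L; vectorized over p
range_offset <- function(p, range, L) (p - range$start) %% L

## is position p inside the (circular) range? vectorized
in_range <- function(p, range, L) {
  range_offset(p, range, L) < range_length(range, L)
}

## is `sub` contained in `range` (circular containment)? a range covering
## the whole circle contains every sub-range
range_contains <- function(range, sub, L) {
  if (sub$start > L || sub$end > L) return(FALSE)
  if (range_length(range, L) == L) return(TRUE)
  in_range(sub$start, range, L) &&
    range_offset(sub$start, range, L) + range_length(sub, L) <= range_length(range, L)
}

## circular successor / predecessor of a position
pos_succ <- function(p, L) p %% L + 1L
pos_pred <- function(p, L) (p - 2L) %% L + 1L

#' Reference sequences
#'
#' A light container for a single (circular) reference such as the rCRS:
#' a name, a vector of base symbols in `{A,C,G,T,N}` and a circularity flag.
#'
#' @param name text identifier.
#' @param symbols character vector of single bases, 1-based positions.
#' @param circular logical; `TRUE` for mtDNA.
#' @return An object of class `ref_sequence` with fields `name`, `symbols`,
#'   `circular` and `length`.
#' @export
ref_sequence <- function(name, symbols, circular = TRUE) {
  if (length(symbols) == 1L && nchar(symbols[1]) > 1L)
    symbols <- strsplit(symbols, "")[[1]]
  symbols <- toupper(symbols)
  bad <- setdiff(unique(symbols), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("reference symbols must be A/C/G/T/N; found: ", paste(bad, collapse = ","))
  if (!length(symbols)) stop("empty reference")
  structure(list(name = name, symbols = symbols, circular = isTRUE(circular),
                 length = length(symbols)),
            class = "ref_sequence")
}

#' @export
print.ref_sequence <- function(x, ...) {
  cat("<ref_sequence> ", x$name, ": ", x$length, " bp",
      if (x$circular) " (circular)", "\n", sep = "")
  invisible(x)
}

## base at position p (vectorized)
ref_base <- function(ref, p) ref$symbols[p]

#' Full reading range 1..L of a reference
#' @param ref a [ref_sequence()].
#' @return A [reading_range()] covering the whole reference.
#' @export
full_range <- function(ref) reading_range(1L, ref$length)

#' Read a reference (or query sequences) from FASTA
#'
#' @param path FASTA file; single- or multi-record.
#' @param circular circularity flag applied to every record.
#' @return A list of `ref_sequence` objects (length one for a single record).
#' @export
read_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  lapply(seq_along(ss), function(i) {
    ref_sequence(names(ss)[i], strsplit(as.character(ss[[i]]), "")[[1]],
                 circular = circular)
  })
}

#' Write sequences to FASTA
#' @param seqs a `ref_sequence` or list of them (or named character vector).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "ref_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) {
    if (inherits(s, "ref_sequence")) {
      c(paste0(">", s$name), paste(s$symbols, collapse = ""))
    } else stop("write_fasta expects ref_sequence objects")
  }))
  writeLines(lines, path)
  invisible(path)
}
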