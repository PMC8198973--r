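## Edit transcripts: ordered edit scripts converting a motif-implied
## sequence into a query sequence, written in rCRS-anchored coordinates.
##
## Token grammar (as printed in forensic reports):
##   G73A          substitution at 73 (from may be IUPAC-ambiguous or
##                 lowercase-optional, e.g. Y64C, M16182A, c315.1C);
##   63insC        insertion after position 63 (multi-base allowed);
##   42delT        single-symbol deletion;
##   308-309delCC  range deletion (hyphen or en dash), one symbol per
##                 coordinate of the span.
##
## Internally a transcript is a data.frame of ops with columns kind, pos,
## ins, pos2, ins2 (range-deletion end, NA otherwise), from, to, opt,
## cost, resolution. Ops are kept in ascending coordinate order; they are
## applied from the 3' end so coordinates never shift underneath.

.parse_coord <- function(x) {
  p <- strsplit(x, ".", fixed = TRUE)[[1]]
  c(pos = as.integer(p[1]), ins = if (length(p) > 1L) as.integer(p[2]) else 0L)
}

op_row <- function(kind, pos, ins = 0L, pos2 = NA_integer_, ins2 = NA_integer_,
                   from = NA_character_, to = NA_character_, opt = FALSE,
                   cost = NA_real_, resolution = NA) {
  data.frame(kind = kind, pos = as.integer(pos), ins = as.integer(ins),
             pos2 = as.integer(pos2), ins2 = as.integer(ins2),
             from = from, to = to, opt = opt, cost = cost,
             resolution = resolution, stringsAsFactors = FALSE)
}

empty_ops <- function() {
  data.frame(kind = character(), pos = integer(), ins = integer(),
             pos2 = integer(), ins2 = integer(), from = character(),
             to = character(), opt = logical(), cost = numeric(),
             resolution = logical(), stringsAsFactors = FALSE)
}

new_transcript <- function(ops) {
  rownames(ops) <- NULL
  structure(list(ops = ops), class = "transcript")
}

#' Parse an edit transcript
#'
#' @param tokens whitespace-separated token string (or character vector of
#'   tokens). See the grammar in the package details; both hyphen and en
#'   dash are accepted in range deletions.
#' @return An object of class `transcript`. Multi-symbol range deletions are
#'   kept intact until [normalize_transcript()].
#' @examples
#' parse_transcript("42delT 63insC 63insC G73A 309-309.1delCC")
#' @export
parse_transcript <- function(tokens) {
  if (length(tokens) == 1L) {
    tokens <- strsplit(trimws(tokens), "[[:space:]]+")[[1]]
  }
  tokens <- tokens[nzchar(tokens)]
  rows <- lapply(tokens, function(tk) {
    cnum <- "[0-9]+(?:\\.[0-9]+)?"
    m <- regmatches(tk, regexec(paste0("^(", cnum, ")[-–](", cnum, ")(?:del|DEL)([A-Za-z]+)$"), tk, perl = TRUE))[[1]]
    if (length(m)) {
      a <- .parse_coord(m[2]); b <- .parse_coord(m[3])
      return(op_row("del", a["pos"], a["ins"], b["pos"], b["ins"], from = m[4],
                    opt = grepl("[a-z]", m[4])))
    }
    m <- regmatches(tk, regexec(paste0("^(", cnum, ")(?:del|DEL)([A-Za-z])$"), tk, perl = TRUE))[[1]]
    if (length(m)) {
      a <- .parse_coord(m[2])
      if (!iupac_ok(m[3])) stop("not an IUPAC symbol in transcript token: ", tk)
      return(op_row("del", a["pos"], a["ins"], from = toupper(m[3]),
                    opt = m[3] %in% letters))
    }
    m <- regmatches(tk, regexec(paste0("^(", cnum, ")ins([A-Za-z]+)$"), tk, perl = TRUE))[[1]]
    if (length(m)) {
      a <- .parse_coord(m[2])
      if (!all(strsplit(m[3], "")[[1]] %in% c(names(.iupac_mask), tolower(names(.iupac_mask)))))
        stop("not an IUPAC symbol in transcript token: ", tk)
      return(op_row("ins", a["pos"], a["ins"], to = toupper(m[3])))
    }
    m <- regmatches(tk, regexec(paste0("^([A-Za-z])(", cnum, ")([A-Za-z])$"), tk, perl = TRUE))[[1]]
    if (length(m)) {
      if (!iupac_ok(m[2]) || !iupac_ok(m[4]))
        stop("not an IUPAC symbol in transcript token: ", tk)
      a <- .parse_coord(m[3])
      return(op_row("sub", a["pos"], a["ins"], from = toupper(m[2]),
                    to = toupper(m[4]), opt = m[2] %in% letters))
    }
    stop("malformed transcript token: ", tk)
  })
  new_transcript(if (length(rows)) do.call(rbind, rows) else empty_ops())
}

## enumerate the single-symbol coordinates of a range deletion; the number
## of deleted symbols must match the span
.expand_range_del <- function(r, L) {
  syms <- strsplit(r$from, "")[[1]]
  n <- length(syms)
  coords <- matrix(NA_integer_, nrow = n, ncol = 2L)
  cur <- c(r$pos, r$ins)
  for (i in seq_len(n)) {
    coords[i, ] <- cur
    cur <- if (cur[1] == r$pos2) c(cur[1], cur[2] + 1L) else c(pos_succ(cur[1], L), 0L)
  }
  if (!(coords[n, 1] == r$pos2 && coords[n, 2] == r$ins2))
    stop("range deletion ", coord_label(r$pos, r$ins), "-",
         coord_label(r$pos2, r$ins2), "del", r$from,
         ": symbol count does not match the span")
  do.call(rbind, lapply(seq_len(n), function(i) {
    op_row("del", coords[i, 1], coords[i, 2], from = toupper(syms[i]),
           opt = syms[i] %in% letters, cost = r$cost, resolution = r$resolution)
  }))
}

## ascending coordinate order; insertions sort after symbol ops on the same
## anchor; stable for runs of equal keys (63insC 63insC keeps its order)
.sort_ops <- function(ops, range = NULL, L = 16569L) {
  if (!nrow(ops)) return(ops)
  off <- if (is.null(range)) ops$pos else range_offset(ops$pos, range, L)
  ops[order(off, ops$ins, ops$kind == "ins"), , drop = FALSE]
}

#' Normalize a transcript to single-symbol ops in 3' application order
#'
#' Range deletions are split into per-coordinate single-symbol deletions and
#' multi-base insertions into single-base ones; ops are sorted by ascending
#' coordinate (the printed form) and applied from the 3' end. Idempotent.
#'
#' @param t a `transcript`.
#' @param range optional [reading_range()] fixing the circular coordinate
#'   order (needed when the transcript spans the origin, e.g. over the
#'   control region); plain ascending order otherwise.
#' @param L reference length.
#' @return The normalized `transcript`.
#' @export
normalize_transcript <- function(t, range = NULL, L = 16569L) {
  ops <- t$ops
  out <- lapply(seq_len(nrow(ops)), function(i) {
    r <- ops[i, ]
    if (r$kind == "del" && !is.na(r$pos2)) return(.expand_range_del(r, L))
    if (r$kind == "ins" && nchar(r$to) > 1L) {
      return(do.call(rbind, lapply(strsplit(r$to, "")[[1]], function(b)
        op_row("ins", r$pos, r$ins, to = b, cost = r$cost, resolution = r$resolution))))
    }
    r
  })
  out <- if (length(out)) do.call(rbind, out) else empty_ops()
  new_transcript(.sort_ops(out, range, L))
}

#' Serialize a transcript to its token string
#'
#' Adjacent single-symbol deletions merge back into range form
#' (`309-309.1delCC`) unless `merge_dels = FALSE`.
#'
#' @param t a `transcript`.
#' @param merge_dels merge consecutive deletions into range tokens.
#' @param L reference length (adjacency wraps at the origin).
#' @return character scalar (empty string for an empty transcript).
#' @export
serialize_transcript <- function(t, merge_dels = TRUE, L = 16569L) {
  ops <- t$ops
  if (!nrow(ops)) return("")
  disp <- function(sym, opt) ifelse(opt, tolower(sym), sym)
  toks <- character(0)
  i <- 1L
  while (i <= nrow(ops)) {
    r <- ops[i, ]
    if (r$kind == "sub") {
      toks <- c(toks, paste0(disp(r$from, r$opt), coord_label(r$pos, r$ins), r$to))
      i <- i + 1L
    } else if (r$kind == "ins") {
      toks <- c(toks, paste0(coord_label(r$pos, r$ins), "ins", r$to))
      i <- i + 1L
    } else if (!is.na(r$pos2)) { # unnormalized range deletion
      toks <- c(toks, paste0(coord_label(r$pos, r$ins), "-",
                             coord_label(r$pos2, r$ins2), "del", r$from))
      i <- i + 1L
    } else {
      j <- i
      if (merge_dels) {
        while (j + 1L <= nrow(ops) && ops$kind[j + 1L] == "del" &&
               is.na(ops$pos2[j + 1L]) &&
               ((ops$pos[j + 1L] == ops$pos[j] && ops$ins[j + 1L] == ops$ins[j] + 1L) ||
                (ops$pos[j + 1L] == pos_succ(ops$pos[j], L) && ops$ins[j + 1L] == 0L)))
          j <- j + 1L
      }
      if (j > i) {
        run <- ops[i:j, ]
        toks <- c(toks, paste0(coord_label(r$pos, r$ins), "-",
                               coord_label(run$pos[nrow(run)], run$ins[nrow(run)]),
                               "del", paste(disp(run$from, run$opt), collapse = "")))
      } else {
        toks <- c(toks, paste0(coord_label(r$pos, r$ins), "del", disp(r$from, r$opt)))
      }
      i <- j + 1L
    }
  }
  paste(toks, collapse = " ")
}

#' @export
format.transcript <- function(x, ...) serialize_transcript(x, ...)

#' @export
print.transcript <- function(x, ...) {
  s <- serialize_transcript(x)
  cat("<transcript> ", if (nzchar(s)) s else "(empty)", "\n", sep = "")
  invisible(x)
}

## Apply a normalized transcript to an expansion data.frame (sym/pos/ins/opt)
## by plain string editing, 3' -> 5'. This is the string-level ground truth
## the five-step alignment rewriting must conserve.
string_edit <- function(expansion, t, range, L) {
  ops <- normalize_transcript(t, range, L)$ops
  df <- expansion
  key <- function(p, k) range_offset(p, range, L) * 1e6 + k
  for (i in rev(seq_len(nrow(ops)))) {
    r <- ops[i, ]
    idx <- which(df$pos == r$pos & df$ins == r$ins)
    if (r$kind == "sub") {
      if (!length(idx)) stop("substitution at absent coordinate ",
                             coord_label(r$pos, r$ins))
      df$sym[idx] <- r$to
      df$opt[idx] <- FALSE
    } else if (r$kind == "del") {
      if (!length(idx)) stop("deletion at absent coordinate ",
                             coord_label(r$pos, r$ins))
      df <- df[-idx, , drop = FALSE]
    } else { # insertion after anchor (pos, ins)
      at <- if (range_offset(r$pos, range, L) >= range_length(range, L)) {
        0L  # anchored before the range start (wrapped predecessor)
      } else sum(key(df$pos, df$ins) <= key(r$pos, r$ins))
      newrow <- data.frame(sym = r$to, pos = r$pos, ins = r$ins + 1L,
                           opt = FALSE, stringsAsFactors = FALSE)
      df <- if (at == 0L) rbind(newrow, df)
            else if (at == nrow(df)) rbind(df, newrow)
            else rbind(df[seq_len(at), ], newrow, df[(at + 1L):nrow(df), ])
    }
  }
  rownames(df) <- NULL
  df
}
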