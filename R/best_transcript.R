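## Best edit transcript between a motif and a query over a reading range.
##
## Both haplotypes are expanded to coordinate-tagged symbol strings and
## aligned by weighted global alignment (Needleman-Wunsch). Resolutions of
## motif ambiguity codes (IUPAC -> concrete base covered by the code) and of
## optional symbols (present or absent) cost zero; true edits cost their
## weight from the weight table. Among equal-cost scripts, resolutions are
## preferred over edits and indels are placed 3'-most, matching forensic
## reporting conventions.

## cummin-based row update: cur[j] = min(base[j], min_k<j base[k] + sum ic)
.row_scan <- function(base, csum) {
  csum + cummin(base - csum)
}

#' Best transcript from a motif to a query
#'
#' Computes a minimal-cost edit script converting the expanded motif
#' sequence into the expanded query sequence over a common reading range.
#' The emitted ops carry rCRS-anchored coordinates of the motif alignment
#' (insertion coordinates such as `309.1` included), so the transcript can
#' be replayed on the motif's variant list by [apply_transcript()].
#'
#' @param query a [haplotype()] (condensed to `range`).
#' @param motif_h the motif's haplotype (condensed to `range`); a `motif`
#'   object is also accepted.
#' @param ref a [ref_sequence()].
#' @param range common [reading_range()]; defaults to the query's range.
#' @param weights a [weight_table()].
#' @return A `transcript` whose ops carry per-op `cost` and a `resolution`
#'   flag (zero-cost ambiguity/optional resolutions).
#' @export
best_transcript <- function(query, motif_h, ref, range = query$range,
                            weights = weight_table()) {
  if (inherits(motif_h, "motif")) motif_h <- motif_h$haplotype
  L <- ref$length
  if (range_length(query$range, L) != range_length(range, L) ||
      query$range$start != range$start)
    query <- condense_haplotype(query, range)
  if (motif_h$range$start != range$start ||
      range_length(motif_h$range, L) != range_length(range, L))
    motif_h <- condense_haplotype(motif_h, range)

  M <- expand_with_coords(motif_h, ref)
  Q <- expand_with_coords(query, ref)
  .bt_core(M, Q, ref, range, weights)
}

## alignment of a motif against a raw symbol string (no query coordinates)
best_transcript_raw <- function(qsym, motif_h, ref, range,
                                weights = weight_table()) {
  if (inherits(motif_h, "motif")) motif_h <- motif_h$haplotype
  M <- expand_with_coords(motif_h, ref)
  Q <- data.frame(sym = toupper(qsym), pos = 0L, ins = 0L, opt = FALSE,
                  stringsAsFactors = FALSE)
  .bt_core(M, Q, ref, range, weights)
}

.bt_core <- function(M, Q, ref, range, weights) {
  L <- ref$length
  n <- nrow(M); m <- nrow(Q)

  mmask <- iupac_mask(M$sym)
  qmask <- iupac_mask(Q$sym)
  compat <- outer(mmask, qmask, function(a, b) bitwAnd(b, bitwNot(a)) == 0L)
  exact <- outer(M$sym, Q$sym, "==") & !M$opt

  unit <- is.null(weights$entries)
  ## per-op weights (unit fast path avoids per-cell lookups)
  del_w <- if (unit) rep(1, n) else
    vapply(seq_len(n), function(i) del_weight(weights, M$pos[i], M$sym[i]), numeric(1))
  del_w[M$opt] <- 0
  ins_w <- if (unit) rep(1, m) else
    vapply(seq_len(m), function(j) ins_weight(weights, Q$pos[j], Q$sym[j]), numeric(1))
  subw <- if (unit) matrix(1, n, m) else {
    w <- matrix(0, n, m)
    for (i in seq_len(n)) for (j in seq_len(m))
      w[i, j] <- sub_weight(weights, M$pos[i], M$sym[i], Q$sym[j])
    w
  }
  subM <- ifelse(compat, 0, subw)

  ## forward pass; insertions before the first motif symbol carry an
  ## infinitesimal extra cost so that, on true ties, the engine prefers a
  ## frame without before-range-start insertions (which the rCRS-relative
  ## notation cannot anchor inside the range)
  lead_eps <- 1e-7
  S <- matrix(0, n + 1L, m + 1L)
  csum <- c(0, cumsum(ins_w))
  S[1L, ] <- csum + lead_eps * (0:m)
  for (i in seq_len(n)) {
    prev <- S[i, ]
    base <- c(prev[1L] + del_w[i],
              pmin(prev[seq_len(m)] + subM[i, ], prev[2L:(m + 1L)] + del_w[i]))
    S[i + 1L, ] <- .row_scan(base, csum)
  }

  ## backtrack; preference on ties: resolution-diagonal (keep motif
  ## features) > deletion > insertion (3'-most indels) > plain diagonal
  eps <- 1e-9
  i <- n; j <- m
  rows <- list()
  emit <- function(r) rows[[length(rows) + 1L]] <<- r
  while (i > 0L || j > 0L) {
    s <- S[i + 1L, j + 1L]
    diag_ok <- i > 0L && j > 0L && abs(S[i, j] + subM[i, j] - s) < eps
    diag_res <- diag_ok && compat[i, j] && !exact[i, j]
    up_ok <- i > 0L && abs(S[i, j + 1L] + del_w[i] - s) < eps
    left_ok <- j > 0L &&
      abs(S[i + 1L, j] + ins_w[j] + (if (i == 0L) lead_eps else 0) - s) < eps
    if (diag_res) {
      emit(op_row("sub", M$pos[i], M$ins[i], from = M$sym[i], to = Q$sym[j],
                  opt = M$opt[i], cost = 0, resolution = TRUE))
      i <- i - 1L; j <- j - 1L
    } else if (up_ok) {
      emit(op_row("del", M$pos[i], M$ins[i], from = M$sym[i], opt = M$opt[i],
                  cost = del_w[i], resolution = M$opt[i]))
      i <- i - 1L
    } else if (left_ok) {
      anchor <- if (i > 0L) c(M$pos[i], M$ins[i]) else c(pos_pred(range$start, L), 0L)
      emit(op_row("ins", anchor[1], anchor[2], to = Q$sym[j],
                  cost = ins_w[j], resolution = FALSE))
      j <- j - 1L
    } else if (diag_ok) {
      if (!exact[i, j])  # true substitution (compatible pairs emit nothing
                         # here; they are taken by the resolution branch)
        emit(op_row("sub", M$pos[i], M$ins[i], from = M$sym[i], to = Q$sym[j],
                    opt = M$opt[i], cost = subM[i, j], resolution = FALSE))
      i <- i - 1L; j <- j - 1L
    } else stop("alignment backtrack failed (internal error)")
  }
  ops <- if (length(rows)) do.call(rbind, rev(rows)) else empty_ops()
  t <- new_transcript(.sort_ops(ops, range, L))
  attr(t, "cost") <- if (nrow(ops)) sum(ops$cost) else 0
  t
}

#' Total weighted cost of a transcript's ops
#' @param t a `transcript` produced by [best_transcript()].
#' @return numeric; sum of per-op costs.
#' @export
transcript_cost <- function(t) {
  if (!nrow(t$ops)) return(0)
  sum(t$ops$cost, na.rm = TRUE)
}
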