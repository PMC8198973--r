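## The five-step alignment rewriting algorithm.
##
## Given the rCRS-relative alignment of the nearest haplogroup motif and the
## best transcript from the motif sequence to the query sequence, the
## algorithm rewrites the motif's alignment into an alignment of the query
## with respect to the rCRS. Because untouched motif variants are carried
## over verbatim, the result is phylogenetically plausible rather than
## merely most parsimonious.
##
## Step 1  normalize the transcript to single-symbol ops in 3' order.
## Step 2  apply substitutions and deletions to the alignment, remove them
##         from the list.
## Step 3  move the insertions of the current alignment into the list (in
##         3' order), removing them from the alignment.
## Step 4  move list insertions 5' over gaps in the alignment caused by
##         deletions.
## Step 5  combine same-position insertions; emit them as insertions unless
##         followed 3' by deletions, in which case an auxiliary alignment of
##         the inserted string to the deleted (reference) string decides
##         which deletions are cancelled, turned into substitutions, or kept.

.op_token <- function(r) serialize_transcript(new_transcript(r), merge_dels = FALSE)

.find_variant <- function(v, pos, ins) which(v$pos == pos & v$ins == ins)

## Step 2 kernel: one substitution or deletion applied to the variant table
.apply_sub_del <- function(v, r, ref) {
  idx <- .find_variant(v, r$pos, r$ins)
  if (r$kind == "sub") {
    if (r$ins > 0L) {
      if (!length(idx) || v$kind[idx] != "ins")
        stop("transcript inconsistent with alignment: no insertion at ",
             coord_label(r$pos, r$ins), " for op ", .op_token(r))
      v$obs[idx] <- r$to
      v$optional[idx] <- FALSE
    } else if (length(idx)) {
      if (v$kind[idx] == "del")
        stop("transcript inconsistent with alignment: substitution at deleted position ",
             r$pos, " (op ", .op_token(r), ")")
      if (r$to == ref_base(ref, r$pos)) v <- v[-idx, , drop = FALSE]
      else { v$obs[idx] <- r$to; v$optional[idx] <- FALSE }
    } else if (r$to != ref_base(ref, r$pos)) {
      v <- rbind(v, variant_row("sub", r$pos, 0L, r$to))
    }
  } else { # deletion
    if (r$ins > 0L) {
      if (!length(idx) || v$kind[idx] != "ins")
        stop("transcript inconsistent with alignment: no insertion at ",
             coord_label(r$pos, r$ins), " for op ", .op_token(r))
      v <- v[-idx, , drop = FALSE]
    } else if (length(idx)) {
      if (v$kind[idx] == "del")
        stop("transcript inconsistent with alignment: position ", r$pos,
             " already deleted (op ", .op_token(r), ")")
      v$kind[idx] <- "del"; v$obs[idx] <- NA_character_; v$optional[idx] <- FALSE
    } else {
      v <- rbind(v, variant_row("del", r$pos))
    }
  }
  v
}

## unit-cost global alignment of the inserted string to the deleted
## (reference) string; ties: unmatched insertions and remaining deletions
## are pushed 3'-most, pairings otherwise
.aux_align <- function(ins_syms, del_syms) {
  n <- length(ins_syms); m <- length(del_syms)
  S <- matrix(0, n + 1L, m + 1L)
  S[1L, ] <- 0:m
  for (i in seq_len(n)) {
    S[i + 1L, 1L] <- i
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- min(S[i, j] + (ins_syms[i] != del_syms[j]),
                               S[i, j + 1L] + 1, S[i + 1L, j] + 1)
    }
  }
  i <- n; j <- m
  cols <- list()
  while (i > 0L || j > 0L) {
    s <- S[i + 1L, j + 1L]
    if (i > 0L && S[i, j + 1L] + 1 == s) {
      cols[[length(cols) + 1L]] <- c(i, NA); i <- i - 1L
    } else if (j > 0L && S[i + 1L, j] + 1 == s) {
      cols[[length(cols) + 1L]] <- c(NA, j); j <- j - 1L
    } else {
      cols[[length(cols) + 1L]] <- c(i, j); i <- i - 1L; j <- j - 1L
    }
  }
  rev(cols)
}

#' Apply a transcript to a motif's alignment (five-step algorithm)
#'
#' Rewrites the rCRS-relative variant list of a haplogroup motif by an edit
#' transcript, producing the phylogenetic alignment of the query. Motif
#' variants untouched by the transcript are preserved verbatim; the output
#' is in 3' form (indels placed 3'-most).
#'
#' @param motif_alignment a [haplotype()] (the motif's condensed alignment).
#' @param t a `transcript` (normalized or not).
#' @param ref a [ref_sequence()].
#' @param keep_steps return the intermediate state after every step
#'   (for inspection and testing).
#' @return The rewritten `haplotype`, or (with `keep_steps = TRUE`) a list
#'   with elements `step1` ... `step4`, each holding the alignment and the
#'   remaining op list, and `final`.
#' @export
apply_transcript <- function(motif_alignment, t, ref, keep_steps = FALSE) {
  h <- motif_alignment
  range <- h$range; L <- ref$length
  steps <- list()

  ## Step 1: single-symbol ops, ascending coordinates, applied 3'->5'
  tn <- normalize_transcript(t, range, L)
  ops <- tn$ops
  if (keep_steps) steps$step1 <- tn

  ## Step 2: substitutions and deletions -> alignment
  v <- h$variants
  sd <- which(ops$kind %in% c("sub", "del"))
  for (i in rev(sd)) v <- .apply_sub_del(v, ops[i, ], ref)
  ops <- ops[setdiff(seq_len(nrow(ops)), sd), , drop = FALSE]
  if (keep_steps)
    steps$step2 <- list(alignment = haplotype(h$sample_id, range, v, L = L),
                        list = new_transcript(ops))

  ## Step 3: alignment insertions -> list (anchored after their predecessor)
  insv <- which(v$kind == "ins")
  if (length(insv)) {
    conv <- do.call(rbind, lapply(insv, function(k) {
      op_row("ins", v$pos[k], v$ins[k] - 1L, to = v$obs[k], opt = v$optional[k])
    }))
    v <- v[-insv, , drop = FALSE]
    ## existing list ops on an equal anchor stay first (they were emitted 5'
    ## of the motif symbol that produced the converted op)
    ops <- .sort_ops(rbind(ops, conv), range, L)
  }
  if (keep_steps)
    steps$step3 <- list(alignment = haplotype(h$sample_id, range, v, L = L),
                        list = new_transcript(ops))

  ## Step 4: move list insertions 5' over deletion gaps
  if (nrow(ops)) {
    del_pos <- v$pos[v$kind == "del"]
    for (i in seq_len(nrow(ops))) {
      p <- ops$pos[i]; k <- ops$ins[i]; guard <- 0L
      while (p %in% del_pos) {
        p <- pos_pred(p, L); k <- 0L
        guard <- guard + 1L
        if (guard > L) stop("insertion cannot be anchored: all positions deleted")
      }
      ops$pos[i] <- p; ops$ins[i] <- k
    }
    ops <- .sort_ops(ops, range, L)
  }
  if (keep_steps)
    steps$step4 <- list(alignment = haplotype(h$sample_id, range, v, L = L),
                        list = new_transcript(ops))

  ## Step 5: combine same-position insertions and reconcile with deletions
  if (nrow(ops)) {
    for (p in unique(ops$pos[order(range_offset(ops$pos, range, L))])) {
      grp <- ops[ops$pos == p, , drop = FALSE]
      ins_syms <- grp$to
      ins_opt <- grp$opt
      ## deletion run immediately 3' of the joint position
      run <- integer(0)
      q <- pos_succ(p, L)
      while (in_range(q, range, L) && length(.find_variant(v, q, 0L)) &&
             v$kind[.find_variant(v, q, 0L)] == "del") {
        run <- c(run, q)
        q <- pos_succ(q, L)
        if (length(run) > L) stop("degenerate deletion run")
      }
      if (!length(run)) {
        add <- do.call(rbind, lapply(seq_along(ins_syms), function(k)
          variant_row("ins", p, k, ins_syms[k], optional = ins_opt[k])))
        v <- rbind(v, add)
      } else {
        cols <- .aux_align(ins_syms, ref_base(ref, run))
        anchor <- p; kctr <- 0L
        for (cl in cols) {
          xi <- cl[1]; qi <- cl[2]
          if (!is.na(xi) && !is.na(qi)) {       # inserted symbol vs deletion
            qpos <- run[qi]
            di <- .find_variant(v, qpos, 0L)
            if (ins_syms[xi] == ref_base(ref, qpos)) {
              v <- v[-di, , drop = FALSE]       # cancel: back to reference
            } else {                            # deletion -> substitution
              v$kind[di] <- "sub"; v$obs[di] <- ins_syms[xi]
              v$optional[di] <- FALSE
            }
            anchor <- qpos; kctr <- 0L
          } else if (!is.na(xi)) {              # leftover inserted symbol
            kctr <- kctr + 1L
            v <- rbind(v, variant_row("ins", anchor, kctr, ins_syms[xi],
                                      optional = ins_opt[xi]))
          }                                     # leftover deletion: keep
        }
      }
    }
  }
  final <- haplotype(h$sample_id, range, v, L = L)
  if (keep_steps) { steps$final <- final; steps } else final
}
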