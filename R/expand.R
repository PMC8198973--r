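## Expansion of a haplotype to its symbol string over the reading range,
## keeping per-symbol coordinates (pos, ins) and optionality flags so that
## edit transcripts can be expressed in rCRS-anchored coordinates.

expand_with_coords <- function(h, ref) {
  L <- ref$length
  P <- range_positions(h$range, L)
  sym <- ref_base(ref, P)
  opt <- rep(FALSE, length(P))
  keep <- rep(TRUE, length(P))
  v <- h$variants
  if (nrow(v)) {
    ip <- range_offset(v$pos, h$range, L) + 1L
    subs <- which(v$kind == "sub")
    sym[ip[subs]] <- v$obs[subs]
    opt[ip[subs]] <- v$optional[subs]
    dels <- which(v$kind == "del")
    keep[ip[dels]] <- FALSE
  }
  base <- data.frame(sym = sym[keep], pos = P[keep], ins = 0L,
                     opt = opt[keep], stringsAsFactors = FALSE)
  insr <- v[v$kind == "ins", , drop = FALSE]
  if (nrow(insr)) {
    extra <- data.frame(sym = insr$obs, pos = insr$pos, ins = insr$ins,
                        opt = insr$optional, stringsAsFactors = FALSE)
    base <- rbind(base, extra)
    key <- range_offset(base$pos, h$range, L) * 1e6 + base$ins
    base <- base[order(key), , drop = FALSE]
  }
  rownames(base) <- NULL
  base
}

#' Expand a haplotype to its sequence string
#'
#' Applies the variant list to the reference over the haplotype's reading
#' range: substitutions replace the base, deletions remove it, insertions
#' add symbols after their anchor. IUPAC ambiguity codes are rendered
#' verbatim (resolution happens only in transcripts); optional symbols are
#' expanded in their "present" state.
#'
#' @param h a [haplotype()].
#' @param ref a [ref_sequence()].
#' @return character scalar, the expanded sequence.
#' @export
expand_haplotype <- function(h, ref) {
  paste(expand_with_coords(h, ref)$sym, collapse = "")
}

## display form of a coordinate: "309" or "309.1"
coord_label <- function(pos, ins) {
  ifelse(ins > 0L, paste0(pos, ".", ins), as.character(pos))
}
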