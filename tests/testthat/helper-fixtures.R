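# Shared fixtures and independent oracles.

# synthetic rCRS-like reference used by all notation-level tests
rcrs <- make_rcrs_like_reference(1)
CR <- reading_range(16024, 576)

toy10 <- ref_sequence("toy10", "ACGTACGTAC")
toy20 <- ref_sequence("toy20", "ACGTACGTACGTACGTACGT")

# a small control-region motif database containing the published motifs the
# alignment examples revolve around, plus a root
mini_cr_db <- function() {
  rng <- reading_range(1, 16569)
  mk <- function(name, parent, tokens)
    mthap:::motif(name, parent, parse_haplotype(tokens, rng, name))
  motif_db(list(
    mk("mt-MRCA", NA, ""),
    mk("A2", "mt-MRCA",
       "16111T 16182M 16183M 16189C 16192Y 16223T 16290T 16319A 16362C 16519Y 64Y 73G 146C 153G 235G 263G 315.1c"),
    mk("A2+(64)+16189", "A2",
       "16111T 16182M 16183M 16189C 16192Y 16223T 16290T 16319A 16362C 16519Y 64Y 73G 146C 153G 235G 263G 315.1c"),
    mk("B4a1a1", "mt-MRCA",
       "16182M 16183M 16189C 16217C 16247R 16261T 16519Y 73G 146C 263G 315.1c"),
    mk("I1a1", "mt-MRCA", "455.1T 16519Y 315.1c")))
}

# --- independent oracle: weighted edit distance by plain dynamic
# programming (no vector tricks, cost model restated from scratch) ---

.oracle_sets <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_edit_cost <- function(msym, mopt, qsym) {
  n <- length(msym); m <- length(qsym)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  delc <- ifelse(mopt, 0, 1)
  for (i in seq_len(n)) D[i + 1, 1] <- D[i, 1] + delc[i]
  for (j in seq_len(m)) D[1, j + 1] <- D[1, j] + 1
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      covered <- all(.oracle_sets[[qsym[j]]] %in% .oracle_sets[[msym[i]]])
      D[i + 1, j + 1] <- min(D[i, j] + if (covered) 0 else 1,
                             D[i, j + 1] + delc[i],
                             D[i + 1, j] + 1)
    }
  }
  D[n + 1, m + 1]
}

# random haplotype over a range of a toy reference
random_haplotype <- function(ref, range, n_sub = 2, n_ins = 1, n_del = 1,
                             ambiguous = FALSE, optional = FALSE) {
  # the range start stays undeletable: a motif deleting its first position
  # can force an insertion that the rCRS-relative notation cannot anchor
  # inside the range
  P <- mthap:::range_positions(range, ref$length)
  pool <- sample(P[-1])
  v <- mthap:::empty_variants()
  take <- function(n) {
    if (n == 0) return(integer(0))
    p <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; p
  }
  for (p in take(n_sub)) {
    b <- sample(setdiff(c("A", "C", "G", "T"), ref$symbols[p]), 1)
    if (ambiguous && stats::runif(1) < 0.5)
      b <- sample(c("R", "Y", "M", "K"), 1)
    v <- rbind(v, mthap:::variant_row("sub", p, 0L, b))
  }
  for (p in take(n_ins)) {
    opt <- optional && stats::runif(1) < 0.5
    v <- rbind(v, mthap:::variant_row("ins", p, 1L, sample(c("A", "C", "G", "T"), 1),
                                      optional = opt))
  }
  for (p in take(n_del)) v <- rbind(v, mthap:::variant_row("del", p))
  haplotype("rnd", range, v, L = ref$length)
}
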