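## IUPAC nucleotide ambiguity codes as bitmasks over {A=1, C=2, G=4, T=8}.

.iupac_mask <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.iupac_letter <- {
  x <- character(15L)
  x[.iupac_mask] <- names(.iupac_mask)
  x
}

iupac_ok <- function(sym) toupper(sym) %in% names(.iupac_mask)

iupac_mask <- function(sym) unname(.iupac_mask[toupper(sym)])

## TRUE iff every base denoted by `a` is also denoted by `b` (a subset of b)
iupac_subset <- function(a, b) {
  bitwAnd(iupac_mask(a), bitwNot(iupac_mask(b))) == 0L
}

## minimal IUPAC code covering the union of the given symbols
iupac_union <- function(syms) {
  m <- Reduce(bitwOr, iupac_mask(syms))
  .iupac_letter[m]
}

## ambiguous = denotes more than one base
iupac_ambiguous <- function(sym) {
  m <- iupac_mask(sym)
  !is.na(m) & bitwAnd(m, m - 1L) != 0L
}

is_transition <- function(from, to) {
  paste0(toupper(from), toupper(to)) %in% c("AG", "GA", "CT", "TC")
}
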