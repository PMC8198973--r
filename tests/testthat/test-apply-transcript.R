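test_that("five-step rewriting exposes the documented intermediates", {
  rng <- reading_range(1, 600)
  motif_h <- parse_haplotype("42.1A 64del 65del 73G 309.1C", rng, "toy")
  t <- parse_transcript("42delT 63insC 63insC G73A 309-309.1delCC")
  st <- apply_transcript(motif_h, t, rcrs, keep_steps = TRUE)
  expect_identical(serialize_transcript(st$step1, merge_dels = FALSE),
                   "42delT 63insC 63insC G73A 309delC 309.1delC")
  expect_identical(format(st$step2$alignment), "42del 42.1A 64del 65del 309del")
  expect_identical(serialize_transcript(st$step2$list), "63insC 63insC")
  expect_identical(serialize_transcript(st$step3$list), "42insA 63insC 63insC")
  expect_identical(format(st$step3$alignment), "42del 64del 65del 309del")
  expect_identical(serialize_transcript(st$step4$list), "41insA 63insC 63insC")
  expect_identical(format(st$final), "42A 65C 309del")
})

test_that("an empty transcript leaves any alignment unchanged", {
  rng <- reading_range(1, 600)
  for (toks in c("", "42.1A 64del 65del 73G 309.1C",
                 "100T 309.1C 309.2C 315.1c")) {
    h <- parse_haplotype(toks, rng, "m")
    expect_identical(format(apply_transcript(h, parse_transcript(""), rcrs)),
                     format(h))
  }
})

test_that("inconsistent transcripts are rejected with the offending op named", {
  rng <- reading_range(1, 600)
  h <- parse_haplotype("64del", rng, "m")
  expect_error(apply_transcript(h, parse_transcript("64delC"), rcrs),
               "already deleted")
  expect_error(apply_transcript(h, parse_transcript("A64C"), rcrs),
               "deleted position")
  expect_error(apply_transcript(h, parse_transcript("c315.1C"), rcrs),
               "no insertion at 315.1")
  expect_error(apply_transcript(h, parse_transcript("309.1delC"), rcrs),
               "no insertion at 309.1")
})

test_that("untouched motif variants survive verbatim (phylogenetic preference)", {
  # the motif's 455.1T is kept even though 456T would be more parsimonious
  rng <- reading_range(451, 464)
  m <- parse_haplotype("455.1T", rng, "I1a1")
  out <- apply_transcript(m, parse_transcript("459delC"), rcrs)
  expect_identical(format(out), "455.1T 459del")
})

test_that("string conservation holds on randomized cases (master oracle)", {
  # expand(apply_transcript(m, t)) must equal the plain string edit of the
  # expanded motif, with t = best_transcript(query, m); and both must equal
  # the expanded query
  set.seed(7)
  rng <- reading_range(1, 40)
  ref40 <- make_reference(fixture_spec(seed = 3, ref_length = 100))
  n_cases <- 400
  for (case in seq_len(n_cases)) {
    mh <- random_haplotype(ref40, rng, n_sub = sample(0:3, 1),
                           n_ins = sample(0:2, 1), n_del = sample(0:2, 1),
                           ambiguous = TRUE, optional = TRUE)
    qh <- random_haplotype(ref40, rng, n_sub = sample(0:3, 1),
                           n_ins = sample(0:2, 1), n_del = sample(0:2, 1))
    t <- best_transcript(qh, mh, ref40, rng)
    out <- apply_transcript(mh, t, ref40)
    qs <- expand_haplotype(qh, ref40)
    expect_identical(expand_haplotype(out, ref40), qs, info = paste("case", case))
    # independent string-editing route
    edited <- mthap:::string_edit(mthap:::expand_with_coords(mh, ref40),
                                  t, rng, ref40$length)
    expect_identical(paste(edited$sym, collapse = ""), qs,
                     info = paste("string-edit case", case))
  }
})

test_that("conservation holds across the wrap-around origin", {
  set.seed(11)
  L <- 60L
  refw <- ref_sequence("wrap", paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                                     collapse = ""))
  rng <- reading_range(45, 20)  # wraps 45..60, 1..20
  for (case in 1:50) {
    mh <- random_haplotype(refw, rng, n_sub = 2, n_ins = 1, n_del = 1)
    qh <- random_haplotype(refw, rng, n_sub = 2, n_ins = 1, n_del = 1)
    t <- best_transcript(qh, mh, refw, rng)
    out <- apply_transcript(mh, t, refw)
    expect_identical(expand_haplotype(out, refw), expand_haplotype(qh, refw),
                     info = paste("wrap case", case))
  }
})

test_that("the output is in 3' form in homopolymers", {
  # a C deleted from the planted C-stretch is reported at the stretch's 3' end
  spec <- fixture_spec(seed = 5, ref_length = 200)
  ref <- make_reference(spec)
  rng <- reading_range(1, 200)
  cs_end <- spec$cs_start + spec$c_stretch - 1L
  m <- parse_haplotype("", rng, "root", L = 200)
  q <- haplotype("q", rng, mthap:::variant_row("del", spec$cs_start), L = 200)
  t <- best_transcript(q, m, ref, rng)
  expect_equal(t$ops$pos, cs_end)   # deletion placed 3'-most
  out <- apply_transcript(m, t, ref)
  expect_identical(format(out), paste0(cs_end, "del"))
})
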