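test_that("mitogenome vetting applies both rules and always evaluates both", {
  ok <- vet_mitogenome(strrep("ACGT", 4200), "ok")  # 16,800 bp, clean
  expect_true(ok$passed)

  short <- vet_mitogenome(strrep("A", 16538), "short")
  expect_false(short$passed)
  expect_match(short$reasons, "length")

  ambig <- vet_mitogenome(paste0(strrep("A", 16559), strrep("N", 10)), "ambig")
  expect_false(ambig$passed)
  expect_match(ambig$reasons, "ambiguous")

  both <- vet_mitogenome(paste0(strrep("A", 100), strrep("Y", 10)), "both")
  expect_equal(length(both$reasons), 2L)

  # boundary cases: 16,539 bp and exactly nine ambiguous symbols pass
  edge <- vet_mitogenome(paste0(strrep("A", 16530), strrep("M", 9)), "edge")
  expect_true(edge$passed)

  expect_error(vet_mitogenome("ACGTX", "bad"), "non-IUPAC")
})

test_that("vetting a batch is deterministic and order-independent", {
  seqs <- list(ref_sequence("a", strrep("A", 200)),
               ref_sequence("b", strrep("C", 300)))
  t1 <- vet_batch(seqs)
  t2 <- vet_batch(rev(seqs))
  expect_equal(t1[order(t1$sample_id), ], t2[order(t2$sample_id), ],
               ignore_attr = TRUE)
})

test_that("motif widening follows the frequency rule and never raises member costs", {
  spec <- fixture_spec(seed = 21, ref_length = 300, n_haplogroups = 4)
  ref <- make_reference(spec)
  db <- make_motif_tree(spec, ref)
  m <- db$motifs[["HG2"]]
  rng <- m$haplotype$range
  # 4 of 7 members carry an alternative base at a fresh position
  p <- setdiff(seq_len(300), attr(db, "used_positions"))[5]
  refb <- mthap:::ref_base(ref, p)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  members <- lapply(1:7, function(i) {
    v <- m$haplotype$variants
    if (i <= 4) v <- rbind(v, mthap:::variant_row("sub", p, 0L, altb))
    haplotype(paste0("mem", i), rng, v, L = ref$length)
  })
  wide <- widen_motif(m, members, ref, min_freq = 0.25)
  i <- which(wide$haplotype$variants$pos == p)
  expect_equal(length(i), 1L)
  expect_identical(wide$haplotype$variants$obs[i],
                   mthap:::iupac_union(c(refb, altb)))

  # no member variation: unchanged
  same <- widen_motif(m, members[5:7], ref, min_freq = 0.25)
  expect_identical(format(same$haplotype), format(m$haplotype))

  # below the frequency threshold: unchanged
  rare <- widen_motif(m, members, ref, min_freq = 0.7)
  expect_identical(format(rare$haplotype), format(m$haplotype))

  # widening can only lower search costs for the members
  for (mem in members) {
    before <- neighbor_cost(mem, m$haplotype, ref,
                            length_variant_regions = spec$length_variant_regions)$cost
    after <- neighbor_cost(mem, wide$haplotype, ref,
                           length_variant_regions = spec$length_variant_regions)$cost
    expect_lte(after, before)
  }
})

test_that("planted subclades are detected with their defining variants", {
  spec <- fixture_spec(seed = 23, ref_length = 300, n_haplogroups = 3)
  ref <- make_reference(spec)
  db <- make_motif_tree(spec, ref)
  base <- db$motifs[["HG1"]]
  rng <- base$haplotype$range
  fresh <- setdiff(seq_len(300), c(attr(db, "used_positions"),
                                   mthap:::range_positions(spec$length_variant_regions[[1]], 300)))
  extra <- fresh[1:3]
  extok <- vapply(extra, function(p) {
    paste0(p, setdiff(c("A", "C", "G", "T"), mthap:::ref_base(ref, p))[1])
  }, character(1))
  members <- lapply(1:3, function(i) {
    v <- rbind(base$haplotype$variants,
               do.call(rbind, lapply(extok, parse_variant_token)))
    haplotype(paste0("s", i), rng, v, L = ref$length)
  })
  cands <- detect_subclades(base, members)
  expect_equal(length(cands), 1L)
  expect_setequal(cands[[1]]$extra_variants, extok)
  expect_equal(cands[[1]]$proposed_name, "HG1*")
  expect_setequal(cands[[1]]$carriers, c("s1", "s2", "s3"))

  # members with no shared extras: nothing detected
  expect_equal(length(detect_subclades(base, list(members[[1]]))), 0L)
  plain <- lapply(1:2, function(i)
    haplotype(paste0("p", i), rng, base$haplotype$variants, L = ref$length))
  expect_equal(length(detect_subclades(base, plain)), 0L)
})

test_that("subclade candidates equal brute-force closed-set enumeration", {
  set.seed(31)
  spec <- fixture_spec(seed = 25, ref_length = 300, n_haplogroups = 2)
  ref <- make_reference(spec)
  db <- make_motif_tree(spec, ref)
  base <- db$motifs[["HG1"]]
  rng <- base$haplotype$range
  fresh <- setdiff(seq_len(300), c(attr(db, "used_positions"),
                                   mthap:::range_positions(spec$length_variant_regions[[1]], 300)))
  universe <- vapply(fresh[1:8], function(p) {
    paste0(p, setdiff(c("A", "C", "G", "T"), mthap:::ref_base(ref, p))[1])
  }, character(1))
  for (rep in 1:5) {
    members <- lapply(1:6, function(i) {
      toks <- sample(universe, sample(3:6, 1))
      v <- rbind(base$haplotype$variants,
                 do.call(rbind, lapply(toks, parse_variant_token)))
      haplotype(paste0("m", i), rng, v, L = ref$length)
    })
    got <- detect_subclades(base, members, min_variants = 3, min_carriers = 2)
    got_sets <- lapply(got, function(x) sort(x$extra_variants))

    # oracle: every subset of the variant universe meeting the thresholds
    # whose carriers' intersection is exactly the subset (maximality)
    extras <- lapply(members, function(mh)
      setdiff(serialize_variant(mh$variants), serialize_variant(base$haplotype$variants)))
    want <- list()
    for (k in 3:length(universe)) {
      for (idx in utils::combn(length(universe), k, simplify = FALSE)) {
        S <- sort(universe[idx])
        carr <- which(vapply(extras, function(e) all(S %in% e), logical(1)))
        if (length(carr) < 2) next
        if (!identical(sort(Reduce(intersect, extras[carr])), S)) next
        want[[length(want) + 1L]] <- S
      }
    }
    expect_setequal(lapply(got_sets, paste, collapse = " "),
                    lapply(want, paste, collapse = " "))
  }
})

test_that("nested subclade candidates get nested names and supersets of variants", {
  spec <- fixture_spec(seed = 27, ref_length = 300, n_haplogroups = 2)
  ref <- make_reference(spec)
  db <- make_motif_tree(spec, ref)
  base <- db$motifs[["HG1"]]
  rng <- base$haplotype$range
  fresh <- setdiff(seq_len(300), c(attr(db, "used_positions"),
                                   mthap:::range_positions(spec$length_variant_regions[[1]], 300)))
  toks <- vapply(fresh[1:5], function(p) {
    paste0(p, setdiff(c("A", "C", "G", "T"), mthap:::ref_base(ref, p))[1])
  }, character(1))
  # four members share toks[1:3]; two of them additionally share toks[4:5]
  members <- lapply(1:4, function(i) {
    tk <- if (i <= 2) toks else toks[1:3]
    v <- rbind(base$haplotype$variants, do.call(rbind, lapply(tk, parse_variant_token)))
    haplotype(paste0("n", i), rng, v, L = ref$length)
  })
  cands <- detect_subclades(base, members)
  expect_equal(length(cands), 2L)
  top <- cands[[which(vapply(cands, function(x) length(x$extra_variants), integer(1)) == 3)]]
  sub <- cands[[which(vapply(cands, function(x) length(x$extra_variants), integer(1)) == 5)]]
  expect_equal(top$proposed_name, "HG1*")
  expect_match(sub$proposed_name, "^HG1\\*[a-z]$")
  expect_true(all(top$extra_variants %in% sub$extra_variants))
  expect_setequal(sub$carriers, c("n1", "n2"))
})
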