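toy_search_fixture <- function(seed = 2) {
  spec <- fixture_spec(seed = seed, ref_length = 300, n_haplogroups = 8,
                       motif_separation = 3)
  ref <- make_reference(spec)
  db <- make_motif_tree(spec, ref)
  list(spec = spec, ref = ref, db = db)
}

test_that("neighbor cost is zero for the motif itself and additive for planted privates", {
  fx <- toy_search_fixture()
  m <- fx$db$motifs[["HG3"]]
  q0 <- m$haplotype; q0$sample_id <- "self"
  nc <- neighbor_cost(q0, m$haplotype, fx$ref,
                      length_variant_regions = fx$spec$length_variant_regions)
  expect_equal(nc$cost, 0)
  expect_equal(nrow(nc$privates), 0L)

  sq <- sample_query(m, fx$spec, fx$ref, fx$db, n_private = 1, seed = 99)
  nc1 <- neighbor_cost(sq$query, m$haplotype, fx$ref,
                       length_variant_regions = fx$spec$length_variant_regions)
  expect_equal(nc1$cost, 1)
  expect_identical(serialize_variant(nc1$privates), sq$truth$planted)

  # a custom weight makes the planted private cost exactly that weight
  pv <- parse_variant_token(sq$truth$planted)
  wt <- weight_table(data.frame(position = pv$pos,
                                mutation = paste0(pv$pos, pv$obs), weight = 1.75))
  nc2 <- neighbor_cost(sq$query, m$haplotype, fx$ref, weights = wt,
                       length_variant_regions = fx$spec$length_variant_regions)
  expect_equal(nc2$cost, 1.75)
})

test_that("heteroplasmies and length variants are costless but reported as privates", {
  fx <- toy_search_fixture()
  spec2 <- fx$spec
  spec2$heteroplasmy_rate <- 1; spec2$length_variant_rate <- 1
  m <- fx$db$motifs[["HG2"]]
  sq <- sample_query(m, spec2, fx$ref, fx$db, n_private = 0, seed = 123)
  nc <- neighbor_cost(sq$query, m$haplotype, fx$ref,
                      length_variant_regions = spec2$length_variant_regions)
  expect_equal(nc$cost, 0)
  expect_equal(nc$n_essential, 0L)
  expect_setequal(nc$privates$class, c("heteroplasmy", "length_variant"))
})

test_that("essential private counts match a set-difference oracle on planted queries", {
  fx <- toy_search_fixture(seed = 4)
  for (i in 1:10) {
    nm <- sample(names(fx$db$motifs), 1)
    m <- fx$db$motifs[[nm]]
    n_priv <- sample(0:3, 1)
    sq <- sample_query(m, fx$spec, fx$ref, fx$db, n_private = n_priv,
                       seed = 1000 + i)
    # oracle: planted substitutions at fresh positions are exactly the
    # essential set difference from the motif
    expect_equal(
      count_essential_privates(sq$query, m$haplotype, fx$ref,
                               length_variant_regions = fx$spec$length_variant_regions),
      n_priv, info = paste("query", i))
  }
})

test_that("rank clustering follows the margin rule", {
  mk <- function(cost, name) structure(list(haplogroups = name, cost = cost,
                                            privates = NULL, n_essential = 0L,
                                            transcript = NULL),
                                       class = "costed_neighbor")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("haplogroup\tparent\tvariants", "R\t\t", "A\tR\t73G", "B\tR\t146C",
               "C\tR\t263G", "D\tR\t152C", "E\tR\t195C"), path)
  db <- load_motif_table(path, quiet = TRUE)
  nb <- list(mk(1.0, "A"), mk(1.3, "B"), mk(2.4, "C"), mk(2.6, "D"), mk(5.0, "E"))
  res <- rank_neighbors(nb, db, margin = 0.5)
  expect_setequal(res$rank1_names, c("A", "B"))
  expect_setequal(res$rank2_names, c("C", "D"))
  expect_equal(res$mrca_rank1, "R")
  # single zero-cost neighbor: rank 1 only
  res0 <- rank_neighbors(list(mk(0, "A")), db)
  expect_equal(res0$rank1_names, "A")
  expect_equal(length(res0$rank2), 0L)
  expect_true(is.na(res0$mrca_rank2))
  expect_error(rank_neighbors(list(), db), "empty")
})

test_that("planted queries are always recovered at rank 1 (separation > noise)", {
  fx <- toy_search_fixture(seed = 6)
  cdb <- condense_db(fx$db, full_range(fx$ref))
  hits <- 0L; total <- 0L
  for (nm in names(fx$db$motifs)) {
    for (k in 1:3) {
      sq <- sample_query(fx$db$motifs[[nm]], fx$spec, fx$ref, fx$db,
                         n_private = 1, seed = 10 * k + total)
      res <- search_haplogroups(sq$query, fx$db, fx$ref,
                                length_variant_regions = fx$spec$length_variant_regions,
                                cdb = cdb)
      total <- total + 1L
      if (nm %in% res$rank1_names) hits <- hits + 1L
      # the true haplogroup must be the unique minimum-cost neighbor
      expect_equal(res$rank1[[1]]$cost, 1, info = nm)
    }
  }
  expect_equal(hits, total)
})

test_that("widening a motif position to an IUPAC code never increases a query's cost", {
  fx <- toy_search_fixture(seed = 8)
  m <- fx$db$motifs[["HG4"]]
  sq <- sample_query(m, fx$spec, fx$ref, fx$db, n_private = 2, seed = 77)
  before <- neighbor_cost(sq$query, m$haplotype, fx$ref,
                          length_variant_regions = fx$spec$length_variant_regions)$cost
  # widen every motif substitution to cover one extra base
  v <- m$haplotype$variants
  for (i in which(v$kind == "sub")) {
    v$obs[i] <- mthap:::iupac_union(c(v$obs[i], mthap:::ref_base(fx$ref, v$pos[i])))
  }
  wide <- haplotype("wide", m$haplotype$range, v, L = fx$ref$length)
  after <- neighbor_cost(sq$query, wide, fx$ref,
                         length_variant_regions = fx$spec$length_variant_regions)$cost
  expect_lte(after, before)
})

test_that("reduced query reading ranges condense the motifs before costing", {
  fx <- toy_search_fixture(seed = 9)
  # restrict a query to a sub-range that excludes some diagnostic positions
  sub <- reading_range(1, 150)
  m <- fx$db$motifs[["HG5"]]
  q <- condense_haplotype(m$haplotype, sub); q$sample_id <- "reduced"
  res <- search_haplogroups(q, fx$db, fx$ref,
                            length_variant_regions = fx$spec$length_variant_regions)
  expect_true("HG5" %in% res$rank1_names)
  expect_equal(min(vapply(res$rank1, `[[`, numeric(1), "cost")), 0)
})

test_that("align_query recovers the motif alignment plus the planted private", {
  fx <- toy_search_fixture(seed = 12)
  m <- fx$db$motifs[["HG6"]]
  sq <- sample_query(m, fx$spec, fx$ref, fx$db, n_private = 1, seed = 5)
  res <- align_query(sq$query, fx$db, fx$ref,
                     length_variant_regions = fx$spec$length_variant_regions)
  expect_equal(res$nearest, "HG6")
  expect_setequal(serialize_variant(res$alignment$variants),
                  c(serialize_variant(m$haplotype$variants), sq$truth$planted))
  # query identical to a motif: cost 0 and the motif's own alignment
  q0 <- m$haplotype; q0$sample_id <- "self"
  res0 <- align_query(q0, fx$db, fx$ref,
                      length_variant_regions = fx$spec$length_variant_regions)
  expect_equal(res0$search$rank1[[1]]$cost, 0)
  expect_identical(format(res0$alignment), format(m$haplotype))
})
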