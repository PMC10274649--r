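test_that("a linear 3-chain has exactly 6 connected subgraphs", {
  g <- parse_iupac("Neua2-6Galb1-4GlcNAc")
  em <- enumerate_motifs(g, max_size = 5)
  expect_equal(sum(em$count), 6L)                # 3 singletons + 2 edges + 1 triple
  expect_equal(sum(em$count[em$size == 1]), 3L)
  expect_equal(sum(em$count[em$size == 2]), 2L)
  expect_equal(sum(em$count[em$size == 3]), 1L)
})

test_that("a single-edge glycan yields its three context motifs", {
  em <- enumerate_motifs(parse_iupac("Galb1-4GlcNAc"), max_size = 5)
  expect_setequal(em$motif, c("Galb1-X", "X-GlcNAc", "Galb1-4GlcNAc"))
})

test_that("terminal and internal motifs are distinct identities", {
  g <- parse_iupac("Neua2-6Galb1-4GlcNAcb1-3Galb1-4Glc")
  em <- enumerate_motifs(g, 5)
  expect_true("X-Galb1-4GlcNAcb1-X" %in% em$motif)   # internal LacNAc
  expect_false("Galb1-4GlcNAcb1-X" %in% em$motif)    # terminal form absent here
  g2 <- parse_iupac("Galb1-4GlcNAcb1-3Galb1-4Glc")
  expect_true("Galb1-4GlcNAcb1-X" %in% enumerate_motifs(g2, 5)$motif)
})

test_that("enumeration matches brute-force connected-subset counts", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    ft <- random_flat_tree(n)
    g <- flat_to_glycan(ft)
    for (ms in c(3L, 7L)) {
      expect_equal(sum(enumerate_motifs(g, ms)$count),
                   brute_connected_subsets(ft$parent, ms),
                   info = sprintf("n=%d max_size=%d", n, ms))
    }
  }
})

test_that("motif strings round-trip through the motif parser", {
  g <- parse_iupac(fixture_structures()[2])
  for (s in enumerate_motifs(g, 4)$motif) {
    expect_identical(motif_string(parse_motif(s)), s)
  }
})

test_that("every enumerated motif matches its host glycan, and matching is
           consistent with enumeration on other glycans", {
  corpus <- fixture_corpus()
  gs <- corpus$tree
  host <- gs[[2]]
  motifs <- enumerate_motifs(host, 4)$motif
  for (s in motifs) {
    expect_true(match_motif(host, s), info = s)
  }
  # dual route: recursive matcher vs constructive enumeration membership
  other <- gs[[1]]
  other_strs <- enumerate_motifs(other, 4)$motif
  for (s in motifs) {
    expect_identical(match_motif(other, s), s %in% other_strs, info = s)
  }
})

test_that("exact open-slot semantics distinguish terminal from substituted", {
  sialylated <- parse_iupac("Neua2-6Galb1-4GlcNAc")
  # terminal-Gal motif (no open child slot on Gal) must not match a Gal
  # carrying a sialic acid
  expect_false(match_motif(sialylated, "Galb1-4GlcNAc"))
  expect_true(match_motif(parse_iupac("Galb1-4GlcNAc"), "Galb1-4GlcNAc"))
})

test_that("match is invariant under canonicalization of the glycan", {
  g1 <- parse_iupac("Mana1-3(Mana1-6)Manb1-4GlcNAcb1-4GlcNAc")
  g2 <- parse_iupac("Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAc")
  for (s in enumerate_motifs(g1, 3)$motif) {
    expect_identical(match_motif(g1, s), match_motif(g2, s))
  }
})

test_that("catalog applies the presence-count and size filters", {
  co6 <- glycan_corpus(rep("Neua2-6Galb1-4GlcNAc", 6))
  cat6 <- build_catalog(co6)
  expect_equal(nrow(cat6), 6L)               # all motifs, each in 6 glycans
  expect_true(all(cat6$count == 6L))

  co5 <- glycan_corpus(rep("Neua2-6Galb1-4GlcNAc", 5))
  expect_warning(cat5 <- build_catalog(co5), "empty")
  expect_equal(nrow(cat5), 0L)               # "more than 5" is strict

  co7 <- glycan_corpus(rep(fixture_structures()[1], 6))  # 7-residue glycan
  cat7 <- build_catalog(co7, max_size = 5)
  expect_true(all(cat7$size <= 5L))
})

test_that("catalog is monotone in its thresholds", {
  corpus <- fixture_corpus(3)
  lo <- build_catalog(corpus, max_size = 4, min_count = 3)
  hi <- build_catalog(corpus, max_size = 4, min_count = 6)
  expect_true(all(hi$motif %in% lo$motif))
  small <- build_catalog(corpus, max_size = 3, min_count = 3)
  expect_true(all(small$motif %in% lo$motif))
})

test_that("motif matrix agrees with independent per-glycan matching", {
  corpus <- fixture_corpus()
  catalog <- build_catalog(corpus, max_size = 3, min_count = 2)
  M <- motif_matrix(corpus, catalog)
  expect_identical(dim(M), c(nrow(corpus), nrow(catalog)))
  # column sums equal catalog counts (counts are glycan-level presence)
  expect_equal(unname(colSums(M)), catalog$count)
  # independent route: recursive matcher per cell
  for (k in seq_len(nrow(catalog))) {
    m <- parse_motif(catalog$motif[k])
    expect_equal(unname(M[, k]),
                 vapply(corpus$tree, function(g) as.integer(match_motif(g, m)),
                        integer(1)),
                 info = catalog$motif[k])
  }
})

test_that("catalog CSV round-trips", {
  corpus <- fixture_corpus()
  catalog <- build_catalog(corpus, max_size = 3, min_count = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog_csv(catalog, path)
  back <- read_catalog_csv(path)
  expect_equal(back$motif, catalog$motif)
  expect_equal(back$count, catalog$count)
})
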