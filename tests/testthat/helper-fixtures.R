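# Shared fixtures: small corpora and independent brute-force oracles.

# a small, structurally varied corpus (N-glycan core, LacNAc extensions,
# O-glycan-like cores) used across module tests
fixture_structures <- function() {
  c("Galb1-4GlcNAcb1-2Mana1-3(Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
    "Neua2-6Galb1-4GlcNAcb1-2Mana1-3(Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
    "Mana1-3(Mana1-6)Manb1-4GlcNAcb1-4GlcNAc",
    "Neua2-3Galb1-3GalNAc",
    "Galb1-3(GlcNAcb1-6)GalNAc",
    "Fuca1-2Galb1-4GlcNAc",
    "Neua2-6Galb1-4GlcNAc",
    "Galb1-4GlcNAcb1-3Galb1-4GlcNAc")
}

fixture_corpus <- function(n_copies = 1) {
  glycan_corpus(rep(fixture_structures(), n_copies))
}

# random rooted labeled tree, built independently of the package's
# generator: returns list(parent = int vector (NA root), label = list of
# (name, anomer, cpos, ppos))
random_flat_tree <- function(n_nodes, alphabet = c("Gal", "Man", "Fuc", "Neu",
                                                   "GlcNAc", "GalNAc", "Glc")) {
  parent <- c(NA_integer_, vapply(seq_len(n_nodes - 1L) + 1L, function(i) {
    sample.int(i - 1L, 1)
  }, integer(1)))
  name <- sample(alphabet, n_nodes, replace = TRUE)
  anomer <- sample(c("a", "b"), n_nodes, replace = TRUE)
  ppos <- as.character(sample(2:6, n_nodes, replace = TRUE))
  list(parent = parent, name = name, anomer = anomer, ppos = ppos)
}

# convert a flat tree to a glycan string (via nested construction + the
# package writer, which the round-trip tests validate separately)
flat_to_glycan <- function(ft) {
  n <- length(ft$parent)
  kids <- split(seq_len(n)[-1], ft$parent[-1])
  build <- function(i) {
    ks <- kids[[as.character(i)]]
    ch <- if (is.null(ks)) list() else lapply(ks, build)
    lectinseq:::.new_node(ft$name[i],
                          if (i == 1L) "?" else ft$anomer[i],
                          if (i == 1L) "?" else "1",
                          if (i == 1L) NA_character_ else ft$ppos[i],
                          children = ch)
  }
  canonicalize(lectinseq:::.as_glycan(build(1L)))
}

# brute-force count of connected node subsets of size <= max_size in a
# rooted tree given as a parent vector (independent of the enumeration
# code under test)
brute_connected_subsets <- function(parent, max_size) {
  n <- length(parent)
  count <- 0L
  for (mask in seq_len(2^n - 1L)) {
    nodes <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(nodes) > max_size) next
    # connected iff exactly one node's parent is outside the subset
    outside <- vapply(nodes, function(v) {
      is.na(parent[v]) || !(parent[v] %in% nodes)
    }, logical(1))
    if (sum(outside) == 1L) count <- count + 1L
  }
  count
}

# tiny binding table fixture: 3 glycans x 2 conditions
fixture_binding <- function() {
  tibble::tibble(glycan_id = c("G0001", "G0002", "G0003"),
                 spacer_id = c("Sp0", "Sp8", "Sp14"),
                 `AAL@10ug` = c(15000, 500, 2500),
                 `SNA@10ug` = c(999, 20001, 5000))
}
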