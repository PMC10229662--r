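# Molecular graph model, SMILES round-trips and featurization.

test_that("SMILES parse/write round-trips agree with Open Babel canonicalization", {
  cases <- c("CC(=O)O", "[CH3:1][C:2](=[O:3])[NH:5][CH3:6]", "c1ccccc1",
             "OC(=O)c1ccc(Cl)cc1", "CC(=O)O.NC", "C1CC1C#N",
             "c1ccc2ccccc2c1", "[O-]C(=O)C", "[nH]1cccc1", "c1ccoc1",
             "c1ccsc1", "CC(C)(C)OC(=O)N", "c1ccncc1", "Cc1ccccc1N",
             "[NH3+]CC([O-])=O", "ClC(Cl)(Cl)Cl", "CC(=O)c1ccccc1",
             "c1ccccc1c1ccccc1")
  for (s in cases) {
    g <- parse_smiles(s)
    expect_identical(canonical_smiles(write_smiles(g)), canonical_smiles(s),
                     info = s)
  }
})

test_that("atom maps survive a parse/write round trip", {
  s <- "[CH3:1][C:2](=[O:3])[NH:5][CH3:6]"
  g <- parse_smiles(s)
  expect_identical(sort(g$atoms$map), c(1L, 2L, 3L, 5L, 6L))
  g2 <- parse_smiles(write_smiles(g, include_maps = TRUE))
  expect_identical(g2$atoms$map[order(g2$atoms$map)],
                   g$atoms$map[order(g$atoms$map)])
})

test_that("implicit hydrogens follow standard valences", {
  g <- parse_smiles("CC(=O)N")
  expect_identical(g$atoms$nH, c(3L, 0L, 0L, 2L))
  z <- parse_smiles("[NH3+]CC([O-])=O")
  expect_identical(z$atoms$nH, c(3L, 2L, 0L, 0L, 0L))
})

test_that("invalid inputs are rejected", {
  expect_error(parse_smiles("garbage!!"), "unexpected character")
  expect_error(parse_smiles("C(C"), "unbalanced")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_smiles(""), "empty")
})

test_that("ring and aromatic annotation", {
  g <- parse_smiles("c1ccccc1CC1CC1")
  expect_true(all(g$bonds$in_ring[g$bonds$order == 4L]))
  arom_atoms <- which(g$atoms$aromatic)
  expect_length(arom_atoms, 6L)
  chain <- which(!g$atoms$in_ring)
  expect_length(chain, 1L)  # only the CH2 bridge carbon is acyclic
})

test_that("kekulized orders alternate and respect heteroatom pi capacity", {
  expect_identical(sort(mg_kekulized_orders(parse_smiles("c1ccccc1"))),
                   c(1L, 1L, 1L, 2L, 2L, 2L))
  kek_pyrrole <- mg_kekulized_orders(parse_smiles("[nH]1cccc1"))
  g <- parse_smiles("[nH]1cccc1")
  n_idx <- which(g$atoms$element == "N")
  at_n <- g$bonds$i == n_idx | g$bonds$j == n_idx
  expect_true(all(kek_pyrrole[at_n] == 1L))   # N-H contributes no double bond
  expect_identical(sum(kek_pyrrole == 2L), 2L)
})

test_that("featurize encodes the stated atom and bond blocks", {
  g <- parse_smiles("C")
  f <- featurize(g)
  expect_identical(ncol(f$atom), atom_feature_dim())
  # element one-hot = C, H-count one-hot = 4, no flags
  expect_equal(f$atom[1, 1], 1)                 # C slot
  expect_equal(sum(f$atom[1, 1:11]), 1)
  hblock <- f$atom[1, 24:28]
  expect_equal(which(hblock == 1), 5L)          # 4 hydrogens
  expect_equal(f$atom[1, 29:30], c(0, 0))       # not in ring, not aromatic

  gb <- parse_smiles("c1ccccc1")
  fb <- featurize(gb)
  expect_true(all(fb$atom[, 29] == 1))          # in-ring flag
  expect_true(all(fb$atom[, 30] == 1))          # aromatic flag
  expect_true(all(rowSums(fb$bond[, 1:4]) == 1))
})

test_that("reaction-type block is all-zero when absent and differs only there", {
  g <- parse_smiles("CC(=O)N")
  f0 <- featurize(g)
  f3 <- featurize(g, reaction_type = 3L)
  base <- seq_len(atom_feature_dim() - 10L)
  expect_identical(f0$atom[, base], f3$atom[, base])
  expect_true(all(f0$atom[, -base] == 0))
  expect_true(all(f3$atom[, atom_feature_dim() - 10L + 3L] == 1))
  expect_equal(sum(f3$atom[, -base]), nrow(g$atoms))
})

test_that("unknown elements map to the reserved slot instead of failing", {
  g <- parse_smiles("[Si](C)(C)C")
  f <- featurize(g)
  expect_equal(f$atom[1, 11], 1)   # "other" slot
})

test_that("canonical ranks are invariant to atom relabeling", {
  g <- parse_smiles("CC(=O)Nc1ccccc1")
  r1 <- sort(mg_canon_rank(g))
  g2 <- parse_smiles("c1ccccc1NC(C)=O")  # same molecule, different order
  r2 <- sort(mg_canon_rank(g2))
  expect_identical(r1, r2)
})
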