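# Message-passing encoder: hand-unrolled oracle, conservation, additivity,
# permutation invariance, receptive-field locality and bond symmetry.

encode_vals <- function(g, P, cfg, rt = NULL) {
  tape <- ad_tape()
  pn <- param_nodes(tape, P)
  es <- encode_graph(tape, g, pn, cfg, rt)
  list(atom = es$atom$val, graph = es$graph$val, bond = es$bond$val, es = es)
}

test_that("two-atom encoding matches a hand-unrolled recurrence", {
  cfg <- tiny_cfg(hidden = 3L, ta = 2L)
  set.seed(9)
  P <- encoder_params(cfg)
  g <- parse_smiles("CO")
  f <- featurize(g)
  x1 <- f$atom[1, ]; x2 <- f$atom[2, ]; xb <- f$bond[1, ]
  relu <- function(v) pmax(v, 0)
  # directed messages; no other neighbors, so the aggregation term stays 0
  m12 <- rep(0, 3); m21 <- rep(0, 3)
  for (t in 1:2) {
    m12_new <- P$W1a %*% relu(P$W2a %*% x1 + P$W3a %*% xb + P$W4a %*% rep(0, 3))
    m21_new <- P$W1a %*% relu(P$W2a %*% x2 + P$W3a %*% xb + P$W4a %*% rep(0, 3))
    m12 <- m12_new; m21 <- m21_new
  }
  # messages are constant over iterations here; concatenation stacks them
  a1 <- P$U1a %*% relu(P$U2a %*% x1 + P$U3a %*% c(m21, m21))
  a2 <- P$U1a %*% relu(P$U2a %*% x2 + P$U3a %*% c(m12, m12))
  ev <- encode_vals(g, P, cfg)
  expect_equal(as.numeric(ev$atom[1, ]), as.numeric(a1), tolerance = 1e-12)
  expect_equal(as.numeric(ev$atom[2, ]), as.numeric(a2), tolerance = 1e-12)
  expect_equal(as.numeric(ev$graph), as.numeric(a1 + a2), tolerance = 1e-12)
  # Eq 7 on the single bond, by hand
  b <- P$U1b %*% relu(P$U2b %*% xb + P$U3b %*% (a1 + a2) +
                        P$U4b %*% abs(a1 - a2))
  expect_equal(as.numeric(ev$bond[1, ]), as.numeric(b), tolerance = 1e-12)
})

test_that("graph embedding is exactly the sum of atom embeddings", {
  cfg <- tiny_cfg()
  set.seed(1)
  P <- encoder_params(cfg)
  ev <- encode_vals(parse_smiles("CC(=O)Nc1ccccc1"), P, cfg)
  expect_equal(as.numeric(ev$graph), colSums(ev$atom))
})

test_that("disconnected graphs encode additively", {
  cfg <- tiny_cfg()
  set.seed(2)
  P <- encoder_params(cfg)
  hx <- encode_vals(parse_smiles("CC(=O)O"), P, cfg)$graph
  hy <- encode_vals(parse_smiles("NCc1ccccc1"), P, cfg)$graph
  hxy <- encode_vals(parse_smiles("CC(=O)O.NCc1ccccc1"), P, cfg)$graph
  expect_equal(as.numeric(hxy), as.numeric(hx + hy))
})

test_that("single-atom graph reduces to the no-message readout", {
  cfg <- tiny_cfg(hidden = 4L, ta = 3L)
  set.seed(3)
  P <- encoder_params(cfg)
  g <- parse_smiles("C")
  ev <- encode_vals(g, P, cfg)
  x <- featurize(g)$atom[1, ]
  a <- P$U1a %*% pmax(P$U2a %*% x, 0)
  expect_equal(as.numeric(ev$atom[1, ]), as.numeric(a))
})

test_that("relabeling atoms permutes atom embeddings and preserves h", {
  cfg <- tiny_cfg()
  set.seed(4)
  P <- encoder_params(cfg)
  g1 <- parse_smiles("CC(=O)NC")
  g2 <- parse_smiles("CNC(=O)C")   # same molecule, reversed traversal
  e1 <- encode_vals(g1, P, cfg)
  e2 <- encode_vals(g2, P, cfg)
  expect_equal(as.numeric(e1$graph), as.numeric(e2$graph), tolerance = 1e-10)
  rows_sorted <- function(m) m[do.call(order, as.data.frame(m)), ]
  expect_equal(rows_sorted(e1$atom), rows_sorted(e2$atom), tolerance = 1e-10)
})

test_that("an atom's embedding has a bounded receptive field", {
  cfg <- tiny_cfg(hidden = 6L, ta = 2L)
  set.seed(5)
  P <- encoder_params(cfg)
  # atom 1 in a long chain; edit further than ta+1 bonds away
  near <- encode_vals(parse_smiles("CCCCCCO"), P, cfg)
  far <- encode_vals(parse_smiles("CCCCCCN"), P, cfg)
  expect_equal(near$atom[1, ], far$atom[1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(near$atom[6, ], far$atom[6, ])))
})

test_that("bond embeddings are invariant to endpoint order", {
  cfg <- tiny_cfg()
  set.seed(6)
  P <- encoder_params(cfg)
  ev <- encode_vals(parse_smiles("CC(=O)N"), P, cfg)
  expect_identical(bond_embed(ev$es, 1, 2), bond_embed(ev$es, 2, 1))
  expect_error(bond_embed(ev$es, 1, 4), "not in graph")
})

test_that("encoding an empty graph errors", {
  cfg <- tiny_cfg()
  set.seed(7)
  P <- encoder_params(cfg)
  g <- mol_graph(data.frame(element = character(), charge = integer(),
                            nH = integer(), aromatic = logical(),
                            map = integer()))
  tape <- ad_tape()
  expect_error(encode_graph(tape, g, param_nodes(tape, P), cfg), "empty")
})
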