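# Synthon completion heads and teacher-forced training.

make_synthon <- function(vocab = shared_vocab(), cfg = tiny_cfg(), seed = 1L) {
  synthon_model(vocab, cfg, seed)
}

test_that("synthon embedding is additive over components, bitwise", {
  m <- make_synthon(seed = 2L)
  tape <- ad_tape(); pn <- param_nodes(tape, m$params)
  h1 <- synthon_embedding(tape, parse_smiles("CC(=O)O"), pn, m$cfg)$val
  h2 <- synthon_embedding(tape, parse_smiles("NC"), pn, m$cfg)$val
  h12 <- synthon_embedding(tape, parse_smiles("CC(=O)O.NC"), pn, m$cfg)$val
  h21 <- synthon_embedding(tape, parse_smiles("NC.CC(=O)O"), pn, m$cfg)$val
  expect_identical(h12, h21)
  expect_equal(h12, h1 + h2, tolerance = 1e-12)
})

test_that("continuity prediction is a proper probability, 0.5 at zero", {
  m <- make_synthon()
  g <- parse_smiles("CC(=O)O")
  p <- predict_continue(m, g, 2L, g, g)
  expect_gt(p, 0); expect_lt(p, 1)
  m0 <- m; m0$params <- zero_params(m0$params)
  expect_equal(predict_continue(m0, g, 2L, g, g), 0.5)
  expect_error(predict_continue(m, g, 99L, g, g), class = "rs_anchor_error")
})

test_that("substructure distribution sums to one; uniform at zero; |Z|=1 is certain", {
  m <- make_synthon()
  g <- parse_smiles("CC(=O)O")
  p <- predict_substructure(m, g, 2L, g, g)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  m0 <- m; m0$params <- zero_params(m0$params)
  p0 <- predict_substructure(m0, g, 2L, g, g)
  expect_equal(as.numeric(p0), rep(1 / length(p0), length(p0)),
               tolerance = 1e-12)
  v1 <- build_vocabulary(list(parse_reaction(amide_rxn)))
  m1 <- synthon_model(v1, tiny_cfg(), seed = 1L)
  expect_equal(as.numeric(predict_substructure(m1, g, 2L, g, g)), 1)
})

test_that("attaching a hydroxyl to the acyl synthon reconstructs the acid", {
  rec <- parse_reaction(amide_rxn)
  s <- apply_p2s(rec$product, label_center(rec))
  acyl <- mg_subgraph(s$graph, 1:3)$graph
  res <- attach_substructure(acyl, 2L, sub_bond(1L, "O"))
  out <- finalize_hydrogens(res$graph)
  expect_identical(canonical_smiles(out), canonical_smiles("CC(=O)O"))
  expect_equal(res$new_atoms, 4L)
})

test_that("attaching a six-ring grows the frontier by the ring atoms", {
  g <- parse_smiles("CC")
  phenyl <- sub_ring(
    data.frame(element = rep("C", 6), charge = 0L, aromatic = TRUE),
    data.frame(i = 1:6, j = c(2:6, 1L), order = 4L))
  res <- attach_substructure(g, 1L, phenyl)
  expect_length(res$new_atoms, 6L)
  expect_identical(canonical_smiles(finalize_hydrogens(res$graph)),
                   canonical_smiles("CCc1ccccc1"))
})

test_that("valence-violating attachments are rejected with a typed error", {
  g <- parse_smiles("C(F)(F)(F)F")
  expect_error(attach_substructure(g, 1L, sub_bond(1L, "O")),
               class = "rs_valence_error")
})

test_that("one uniform type decision costs log |Z| and training reduces the loss", {
  recs <- shared_records()
  vocab <- shared_vocab()
  data <- completion_training_data(recs)
  m <- make_synthon()
  m$params <- zero_params(m$params)
  # a path with a single attachment: loss = BCE(0.5) per decision + log |Z|
  one <- Filter(function(it) it$path$n_attach == 1L, data)[[1]]
  tape <- ad_tape(); pn <- param_nodes(tape, m$params)
  loss <- retrosynth:::synthon_loss_one(tape, pn, m, one$synthons, one$path,
                                        one$product)
  n_dec <- length(one$path$steps)
  expect_equal(loss$val[1], n_dec * log(2) + log(vocab_size(vocab)),
               tolerance = 1e-10)

  m2 <- make_synthon(seed = 9L)
  m2 <- train_synthon_model(m2, data[1:8], epochs = 8L, lr = 5e-3,
                            batch_size = 8L)
  h <- attr(m2, "loss_history")
  expect_lt(h[length(h)], h[1])
})

test_that("a path substructure outside the vocabulary is a typed error", {
  v1 <- build_vocabulary(list(parse_reaction(amide_rxn)))  # only "-O"
  m1 <- synthon_model(v1, tiny_cfg(), seed = 1L)
  rec <- parse_reaction("C[O:2][CH3:3]>>[OH:2][CH3:3]")  # needs "-C"
  data <- completion_training_data(list(rec))
  expect_error(train_synthon_model(m1, data, epochs = 1L),
               class = "rs_vocab_error")
})

test_that("teacher-forced replay terminates on the exact reactants", {
  data <- completion_training_data(shared_records())
  expect_equal(attr(data, "skipped"), 0L)
  for (it in data[1:5]) {
    done <- replay_path(it$synthons, it$path)
    expect_lte(it$path$n_attach, 30L)
  }
})
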