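# Reaction parsing, center labeling, product-to-synthon transformation,
# completion paths and the substructure vocabulary.

test_that("parse_reaction builds the map-number bookkeeping", {
  rec <- parse_reaction(amide_rxn)
  expect_s3_class(rec, "reaction_record")
  expect_equal(max(mg_components(rec$reactants)), 2L)
  pm <- rec$product$atoms$map
  expect_identical(sort(pm), c(1L, 2L, 3L, 5L, 6L))
  expect_true(all(pm %in% rec$reactants$atoms$map))
})

test_that("degenerate identity reactions parse; garbage does not", {
  rec <- parse_reaction("[CH4:1]>>[CH4:1]")
  expect_s3_class(rec, "reaction_record")
  expect_error(parse_reaction("garbage!>>"), class = "rs_parse_error")
  expect_error(parse_reaction("CC"), class = "rs_parse_error")
  # a mapped product atom with no reactant counterpart is a parse error
  expect_error(parse_reaction("[CH4:9]>>[CH4:1]"), class = "rs_parse_error")
})

test_that("amide coupling labels as a BF center with the right leaving group", {
  rec <- parse_reaction(amide_rxn)
  lab <- label_center(rec)
  expect_identical(lab$kind, "BF")
  maps <- rec$product$atoms$map[lab$atoms]
  expect_setequal(maps, c(2L, 5L))
  s <- apply_p2s(rec$product, lab)
  comp <- mg_components(s$graph)
  expect_identical(sort(table(comp), decreasing = TRUE) |> as.integer(),
                   c(3L, 2L))  # acyl fragment and amine fragment
})

test_that("a retro hydrogenation labels as BC with the original order", {
  rec <- parse_reaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")
  lab <- label_center(rec)
  expect_identical(lab$kind, "BC")
  expect_identical(lab$bc_order, 2L)
  s <- apply_p2s(rec$product, lab)
  expect_equal(max(mg_components(s$graph)), 1L)
  expect_identical(canonical_smiles(s$graph), canonical_smiles("C=C"))
})

test_that("a demethylation labels as an A center and the synthon is the product", {
  rec <- parse_reaction("C[O:2][CH3:3]>>[OH:2][CH3:3]")
  lab <- label_center(rec)
  expect_identical(lab$kind, "A")
  expect_identical(rec$product$atoms$element[lab$atoms], "O")
  s <- apply_p2s(rec$product, lab)
  expect_identical(write_smiles(s$graph), write_smiles(rec$product))
})

test_that("reactions with two newly formed bonds are uncovered", {
  rec <- parse_reaction("[OH2:1].[CH4:2].[CH4:3]>>[CH3:2][O:1][CH3:3]")
  expect_identical(label_center(rec)$kind, "UNCOVERED")
  expect_error(apply_p2s(rec$product, label_center(rec)),
               class = "rs_label_error")
})

test_that("labeling is invariant to reactant order and atom ordering", {
  rec1 <- parse_reaction(amide_rxn)
  rec2 <- parse_reaction(paste0("[NH2:5][CH3:6].[CH3:1][C:2](=[O:3])[OH:4]",
                                ">>[CH3:1][C:2](=[O:3])[NH:5][CH3:6]"))
  rec3 <- parse_reaction(paste0("[CH3:6][NH2:5].[OH:4][C:2]([CH3:1])=[O:3]",
                                ">>[CH3:6][NH:5][C:2]([CH3:1])=[O:3]"))
  l1 <- label_center(rec1); l2 <- label_center(rec2); l3 <- label_center(rec3)
  expect_identical(l1$kind, "BF")
  expect_identical(l2$kind, "BF")
  expect_identical(l3$kind, "BF")
  m <- function(rec, l) sort(rec$product$atoms$map[l$atoms])
  expect_identical(m(rec1, l1), m(rec2, l2))
  expect_identical(m(rec1, l1), m(rec3, l3))
})

test_that("every record maps to exactly one center kind", {
  for (fx in shared_fixtures()) {
    lab <- label_center(fx$record)
    expect_true(lab$kind %in% c("BF", "BC", "A", "UNCOVERED"))
  }
})

test_that("completion-path replay reproduces the reactants on all covered fixtures", {
  for (fx in shared_fixtures()) {
    rec <- fx$record
    lab <- label_center(rec)
    if (lab$kind == "UNCOVERED") next
    s <- apply_p2s(rec$product, lab)
    path <- derive_completion_path(s$graph, rec$reactants, s$frontier)
    expect_identical(canonical_smiles(replay_path(s$graph, path)),
                     canonical_smiles(rec$reactants), info = fx$smiles)
  }
})

test_that("an unchanged synthon yields an empty path with stops only", {
  rec <- parse_reaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")
  s <- apply_p2s(rec$product, label_center(rec))
  path <- derive_completion_path(s$graph, rec$reactants, s$frontier)
  expect_equal(path$n_attach, 0L)
  expect_true(all(vapply(path$steps, `[[`, "", "action") == "stop"))
})

test_that("one-bond and ring differences produce one substructure step each", {
  # acyl synthon CH3-C(=O)* completed into the acid chloride: one bond step
  syn <- apply_p2s(parse_reaction(amide_rxn)$product,
                   label_center(parse_reaction(amide_rxn)))
  acyl <- mg_subgraph(syn$graph, 1:3)$graph   # CH3-C(=O) fragment
  reactant <- parse_smiles("Cl[C:2](=[O:3])[CH3:1]")
  path <- derive_completion_path(acyl, reactant, which(acyl$atoms$map == 2L))
  expect_equal(path$n_attach, 1L)
  at <- Filter(function(s) s$action == "attach", path$steps)[[1]]
  expect_identical(substructure_key(at$sub), "-Cl")

  # phenyl completion is one aromatic-ring step, not six bond steps
  rec4 <- parse_reaction("[CH3:1][CH2:2]c1ccccc1>>[CH3:1][CH3:2]")
  s4 <- apply_p2s(rec4$product, label_center(rec4))
  p4 <- derive_completion_path(s4$graph, rec4$reactants, s4$frontier)
  expect_equal(p4$n_attach, 1L)
  at4 <- Filter(function(s) s$action == "attach", p4$steps)[[1]]
  expect_identical(at4$sub$kind, "ring")
  expect_equal(nrow(at4$sub$atoms), 6L)
})

test_that("vocabulary extraction collects exactly the leaving pieces", {
  rec <- parse_reaction(amide_rxn)
  v1 <- build_vocabulary(list(rec))
  expect_identical(names(v1$entries), "-O")   # the hydroxyl leaving group
  v0 <- build_vocabulary(list())
  expect_equal(vocab_size(v0), 0L)
})

test_that("every training completion step's key is in the vocabulary", {
  recs <- shared_records()
  vocab <- shared_vocab()
  for (rec in recs) {
    lab <- label_center(rec)
    if (lab$kind == "UNCOVERED") next
    s <- apply_p2s(rec$product, lab)
    path <- derive_completion_path(s$graph, rec$reactants, s$frontier)
    for (st in path$steps) {
      if (st$action != "attach") next
      expect_true(substructure_key(st$sub) %in% names(vocab$entries))
    }
  }
})

test_that("coverage counts the non-uncovered fraction", {
  covered <- parse_reaction(amide_rxn)
  multi <- parse_reaction("[OH2:1].[CH4:2].[CH4:3]>>[CH3:2][O:1][CH3:3]")
  expect_equal(coverage(list(covered, covered, covered)), 1.0)
  expect_equal(coverage(list(covered, covered, covered, multi)), 0.75)
})
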