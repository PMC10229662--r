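# Center-identification heads: joint normalization, candidate enumeration,
# neighbor-change and charge predictors, loss values and top-K selection.

make_center <- function(cfg = tiny_cfg(), seed = 1L) center_model(cfg, seed)

scored <- function(model, g, rt = NULL) {
  tape <- ad_tape()
  pn <- param_nodes(tape, model$params)
  es <- encode_graph(tape, g, pn, model$cfg, rt)
  list(sc = score_centers(tape, es, pn), es = es, pn = pn, tape = tape)
}

test_that("a two-atom single-bond product has 2 + 1 + 2 admissible candidates", {
  m <- make_center()
  r <- scored(m, parse_smiles("CO"))
  tab <- r$sc$table
  expect_equal(sum(tab$type == "BF"), 1L)
  expect_equal(sum(tab$type == "BC"), 2L)   # one slot zeroed (product order)
  expect_equal(sum(tab$type == "A"), 2L)
  expect_equal(nrow(tab), 5L)
})

test_that("joint likelihoods normalize to one and are uniform at zero parameters", {
  m <- make_center()
  g <- parse_smiles("CC(=O)NC")
  r <- scored(m, g)
  expect_equal(sum(exp(r$sc$loglik)), 1.0, tolerance = 1e-12)
  m0 <- m
  m0$params <- zero_params(m0$params)
  r0 <- scored(m0, g)
  C <- nrow(r0$sc$table)
  expect_equal(exp(r0$sc$loglik), rep(1 / C, C), tolerance = 1e-12)
})

test_that("BF neighbor-bond enumeration follows the degree arithmetic", {
  m <- make_center()
  # two-atom product: no neighbors
  r <- scored(m, parse_smiles("CO"))
  tape <- ad_tape(); pn <- param_nodes(tape, m$params)
  es <- encode_graph(tape, parse_smiles("CO"), pn, m$cfg)
  nc <- predict_neighbor_changes(tape, es, pn, 1L)
  expect_length(nc$neighbors, 0L)
  # center bond with endpoint degrees 3 and 2 has 3 neighbor bonds
  g <- parse_smiles("CC(C)NC")   # bond C2-N4: C2 has nbrs C1,C3; N has C5
  k <- mg_find_bond(g, 2L, 4L)
  tape <- ad_tape(); pn <- param_nodes(tape, m$params)
  es <- encode_graph(tape, g, pn, m$cfg)
  nc <- predict_neighbor_changes(tape, es, pn, k)
  expect_length(nc$neighbors, 3L)
  expect_equal(nrow(nc$logits$val), 3L)
  expect_error(predict_neighbor_changes(tape, es, pn, 99L),
               class = "rs_label_error")
})

test_that("transformation embedding cases: A is zero, BC matches hand evaluation", {
  m <- make_center(seed = 11L)
  g <- parse_smiles("CC=C")
  tape <- ad_tape(); pn <- param_nodes(tape, m$params)
  es <- encode_graph(tape, g, pn, m$cfg)
  labA <- structure(list(kind = "A", atoms = 1L, bc_order = NA_integer_,
                         bf_changes = NULL, charges = NULL),
                    class = "center_label")
  cA <- transformation_embedding(tape, es, pn, labA)
  expect_true(all(cA$val == 0))
  # BC center on the double bond with original single order
  labBC <- structure(list(kind = "BC", atoms = c(2L, 3L), bc_order = 1L,
                          bf_changes = NULL, charges = NULL),
                     class = "center_label")
  cBC <- transformation_embedding(tape, es, pn, labBC)
  k <- mg_find_bond(g, 2L, 3L)
  bkl <- es$bond$val[k, ]
  xp <- c(0, 1, 0, 0)
  P <- m$params
  hand <- P$Wc1 %*% pmax(P$Wc2 %*% xp + P$Wc3 %*% bkl, 0)
  expect_equal(as.numeric(cBC$val), as.numeric(hand), tolerance = 1e-12)
  # BF with no changed neighbors: exactly the center-bond term
  labBF <- structure(list(kind = "BF", atoms = c(1L, 2L),
                          bc_order = NA_integer_, bf_changes = NULL,
                          charges = NULL), class = "center_label")
  cBF <- transformation_embedding(tape, es, pn, labBF)
  k1 <- mg_find_bond(g, 1L, 2L)
  hand1 <- P$Wc1 %*% pmax(P$Wc2 %*% c(1, 0, 0, 0) + P$Wc3 %*% es$bond$val[k1, ], 0)
  expect_equal(as.numeric(cBF$val), as.numeric(hand1), tolerance = 1e-12)
})

test_that("charge head gives a proper 3-way distribution, uniform at zero", {
  m <- make_center()
  m$params <- zero_params(m$params)
  g <- parse_smiles("CC(=O)O")
  tape <- ad_tape(); pn <- param_nodes(tape, m$params)
  es <- encode_graph(tape, g, pn, m$cfg)
  cvec <- ad_const(tape, matrix(0, 1, m$cfg$hidden))
  lg <- predict_charges(tape, es, pn, cvec, c(1L, 2L))
  p <- exp(retrosynth:::logsoftmax_rows(lg$val))
  expect_equal(rowSums(p), c(1, 1))
  expect_equal(p, matrix(1 / 3, 2, 3), tolerance = 1e-12)
})

test_that("uniform predictions give log(C) center loss and training reduces it", {
  recs <- shared_records()
  labs <- lapply(recs, label_center)
  k <- which(vapply(labs, function(l) l$kind == "BC", logical(1)))[1]
  m <- make_center()
  m$params <- zero_params(m$params)
  tape <- ad_tape(); pn <- param_nodes(tape, m$params)
  es <- encode_graph(tape, recs[[k]]$product, pn, m$cfg)
  # BC record: no neighbor-change term; charge block adds uniform log(3) terms
  loss <- center_loss_one(tape, es, pn, labs[[k]])
  sc <- score_centers(tape, es, pn)
  C <- nrow(sc$table)
  n_inv <- length(retrosynth:::involved_atoms(labs[[k]]))
  expect_equal(loss$val[1], log(C) + n_inv * log(3), tolerance = 1e-10)

  m2 <- make_center(seed = 3L)
  m2 <- train_center_model(m2, recs[1:10], epochs = 8L, lr = 5e-3,
                           batch_size = 5L)
  h <- attr(m2, "loss_history")
  expect_lt(h[length(h)], h[1])
})

test_that("training refuses a batch with only uncovered records", {
  rec <- parse_reaction("[OH2:1].[CH4:2].[CH4:3]>>[CH3:2][O:1][CH3:3]")
  m <- make_center()
  expect_error(train_center_model(m, list(rec), epochs = 1L),
               class = "rs_train_error")
})

test_that("top-K selection is a ranked truncation of the joint likelihood", {
  m <- make_center(seed = 21L)
  g <- parse_smiles("CC(=O)NC")
  r <- scored(m, g)
  # K larger than the candidate count returns everything, ranked
  all_cand <- select_top_centers(m, g, K = 1000L)
  expect_equal(length(all_cand), nrow(r$sc$table))
  lls <- vapply(all_cand, `[[`, 0, "loglik")
  expect_true(all(diff(lls) <= 1e-12))
  expect_equal(sort(lls, decreasing = TRUE), sort(r$sc$loglik, decreasing = TRUE),
               tolerance = 1e-12)
  # K = 1 is the global argmax
  top1 <- select_top_centers(m, g, K = 1L)
  expect_length(top1, 1L)
  expect_equal(top1[[1]]$loglik, max(r$sc$loglik), tolerance = 1e-12)
})

test_that("ties at zero parameters break deterministically by type order", {
  m <- make_center()
  m$params <- zero_params(m$params)
  g <- parse_smiles("CCO")
  sel <- select_top_centers(m, g, K = 3L)
  expect_identical(vapply(sel, function(s) s$label$kind, ""),
                   c("BF", "BF", "BC"))
  sel2 <- select_top_centers(m, g, K = 3L)
  expect_identical(vapply(sel2, function(s) describe_center(s$label), ""),
                   vapply(sel, function(s) describe_center(s$label), ""))
})

test_that("reaction-type conditioning changes scores; zero block reproduces them", {
  m <- center_model(tiny_cfg(), seed = 31L, reaction_type_known = TRUE)
  g <- parse_smiles("CC(=O)NC")
  r1 <- scored(m, g, rt = 1L)
  r2 <- scored(m, g, rt = 7L)
  r0 <- scored(m, g, rt = NULL)
  expect_false(isTRUE(all.equal(r1$sc$loglik, r2$sc$loglik)))
  m_un <- m; m_un$reaction_type_known <- FALSE
  r3 <- scored(m_un, g)
  expect_equal(r0$sc$loglik, r3$sc$loglik, tolerance = 1e-12)
})
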