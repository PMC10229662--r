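# Top-k accounting, reaction similarity, diversity clustering.

test_that("top-k accuracy counts hit ranks correctly", {
  truth <- c("CC(=O)O.NC", "CCO", "CCN")
  preds <- list(
    c("NC.CC(=O)O"),                                  # hit at rank 1
    c("CC", "CCC", "OC", "CCO", "CO"),                # hit at rank 4
    c("CC", "CO")                                     # no hit
  )
  acc <- topk_accuracy(preds, truth, ks = c(1, 5, 10))
  expect_equal(as.numeric(acc), c(1 / 3, 2 / 3, 2 / 3))
})

test_that("matching ignores reactant order and atom maps", {
  acc <- topk_accuracy(list("[CH3:6][NH2:5].[CH3:1][C:2](=[O:3])[OH:4]"),
                       "CC(=O)O.NC", ks = 1)
  expect_equal(as.numeric(acc), 1)
})

test_that("reaction similarity is bounded, symmetric, and 1 on identity", {
  expect_equal(reaction_similarity("CCO", "CCO"), 1.0)
  pairs <- list(c("CCO", "CCN"),
                c("CC(=O)O.NC", "CC(=O)Cl.NC"),
                c("CCOC", "CC.OC"))
  for (p in pairs) {
    s12 <- reaction_similarity(p[1], p[2])
    s21 <- reaction_similarity(p[2], p[1])
    expect_equal(s12, s21)
    expect_gte(s12, 0); expect_lte(s12, 1)
  }
  expect_error(reaction_similarity("C.C.C", "CC"), class = "rs_similarity_error")
})

test_that("two-reactant similarity takes the better of the two pairings", {
  r1 <- c("CC(=O)O", "NCc1ccccc1")
  r2 <- c("NCc1ccccc1", "CC(=O)Cl")
  sim_m <- function(a, b) {
    fa <- morgan_fp(a); fb <- morgan_fp(b)
    sum(fa & fb) / sum(fa | fb)
  }
  straight <- sim_m(r1[1], r2[1]) + sim_m(r1[2], r2[2])
  crossed <- sim_m(r1[1], r2[2]) + sim_m(r1[2], r2[1])
  expect_equal(reaction_similarity(paste(r1, collapse = "."),
                                   paste(r2, collapse = ".")),
               0.5 * max(straight, crossed))
  expect_gt(crossed, straight)  # the crossing pairing is the better one here
})

test_that("one-vs-two similarity uses the composite disconnected molecule", {
  lhs <- reaction_similarity("CCOC(C)=O", "CCO.CC(=O)O")
  fa <- morgan_fp("CCOC(C)=O"); fb <- morgan_fp("CCO.CC(=O)O")
  expect_equal(lhs, sum(fa & fb) / sum(fa | fb))
})

test_that("similarity histograms bin counts over (0,1]", {
  h <- similarity_histogram(c(0.05, 0.15, 0.15, 0.95, 1.0), bins = 10)
  expect_equal(sum(h), 5L)
  expect_equal(h[1], 1L); expect_equal(h[2], 2L); expect_equal(h[10], 2L)
})

test_that("diversity clustering recovers separable groups deterministically", {
  lowsim <- t(replicate(8, c(5, 4, 1, 0, 0, 0, 0, 0, 0, 0)))
  highsim <- t(replicate(8, c(0, 0, 0, 0, 0, 0, 0, 1, 4, 5)))
  H <- rbind(lowsim, highsim)
  msim <- c(rep(0.15, 8), rep(0.9, 8))
  cl <- diversity_clusters(H, n_clusters = 2L, mean_similarity = msim,
                           n_centers = rep(c(4, 2), each = 8), seed = 5L)
  expect_length(unique(cl$assignment[1:8]), 1L)
  expect_length(unique(cl$assignment[9:16]), 1L)
  expect_false(cl$assignment[1] == cl$assignment[9])
  # clusters are reported in increasing mean-similarity order
  expect_lt(cl$summary$mean_similarity[1], cl$summary$mean_similarity[2])
  cl2 <- diversity_clusters(H, n_clusters = 2L, mean_similarity = msim,
                            n_centers = rep(c(4, 2), each = 8), seed = 5L)
  expect_identical(cl$assignment, cl2$assignment)
  expect_error(diversity_clusters(H[1:3, ], n_clusters = 10L),
               class = "rs_cluster_error")
})

test_that("identical histograms collapse to a single effective cluster", {
  H <- t(replicate(12, c(0, 0, 2, 6, 2, 0, 0, 0, 0, 0)))
  cl <- diversity_clusters(H, n_clusters = 10L, seed = 2L)
  expect_equal(cl$tot_withinss, 0)
  expect_length(unique(cl$assignment), 1L)
})

test_that("module protocol: completion from the true center bounds end-to-end", {
  recs <- shared_records()[1:6]
  vocab <- shared_vocab()
  cfg <- tiny_cfg()
  cm <- center_model(cfg, seed = 71L)
  sm <- synthon_model(vocab, cfg, seed = 72L)
  cm <- train_center_model(cm, recs, epochs = 6L, lr = 1e-2, batch_size = 6L)
  sm <- train_synthon_model(sm, completion_training_data(recs), epochs = 6L,
                            lr = 1e-2, batch_size = 6L)
  rep <- evaluate_models(cm, sm, recs, K = 3L, N = 5L, ks = c(1L, 3L, 5L))
  expect_true(all(diff(rep$end_to_end) >= 0))           # monotone in k
  expect_true(all(diff(rep$center_identification) >= 0))
  expect_true(all(rep$end_to_end <= rep$coverage + 1e-12))
  expect_gte(rep$synthon_completion["top5"], rep$end_to_end["top5"])
  # per-class breakdown partitions the record set
  expect_false(is.null(rep$by_class))
  expect_equal(sum(rep$by_class$n), rep$n)
})
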