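# Evaluation: top-k accuracy against canonical ground-truth reactant sets,
# module-level protocols (center identification alone; completion from the
# ground-truth center), reaction similarity from Morgan-fingerprint Tanimoto
# coefficients, and diversity clustering of per-product similarity
# histograms.

.fp_cache <- new.env(parent = emptyenv())

#' Morgan (extended-connectivity, radius 2) fingerprint of a molecule
#'
#' Computed with Open Babel's ECFP4 implementation and folded to 2048 bits.
#'
#' @param smiles molecule SMILES (may contain several components, which are
#'   fingerprinted as one composite molecule).
#' @return 0/1 integer vector of length 2048.
#' @export
morgan_fp <- function(smiles) {
  hit <- .fp_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  fp <- ChemmineOB::fingerprint_OB(mol, "ECFP4")
  fp <- as.integer(fp != 0)
  half <- length(fp) %/% 2L
  folded <- as.integer(fp[seq_len(half)] | fp[half + seq_len(half)])
  assign(smiles, folded, envir = .fp_cache)
  folded
}

tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  inter / uni
}

sim_mol <- function(s1, s2) tanimoto(morgan_fp(s1), morgan_fp(s2))

#' Similarity between two reactions sharing a product
#'
#' For two 2-reactant reactions, half the larger of the two pairings' summed
#' molecule similarities; for a 1-reactant vs a 2-reactant reaction, the
#' similarity of the single reactant to the composite disconnected molecule;
#' for two 1-reactant reactions, plain molecule similarity. Molecule
#' similarity is the Tanimoto coefficient over 2048-bit Morgan fingerprints.
#'
#' @param r1,r2 character vectors of reactant SMILES (length 1 or 2), or
#'   dot-joined strings.
#' @return similarity in [0, 1].
#' @export
reaction_similarity <- function(r1, r2) {
  split1 <- unlist(strsplit(r1, ".", fixed = TRUE))
  split2 <- unlist(strsplit(r2, ".", fixed = TRUE))
  n1 <- length(split1); n2 <- length(split2)
  if (n1 > 2L || n2 > 2L || n1 < 1L || n2 < 1L) {
    rs_error("reaction similarity is defined for 1- or 2-reactant reactions",
             "rs_similarity_error")
  }
  if (n1 == 2L && n2 == 2L) {
    0.5 * max(sim_mol(split1[1], split2[1]) + sim_mol(split1[2], split2[2]),
              sim_mol(split1[1], split2[2]) + sim_mol(split1[2], split2[1]))
  } else if (n1 == 1L && n2 == 1L) {
    sim_mol(split1, split2)
  } else {
    one <- if (n1 == 1L) split1 else split2
    two <- if (n1 == 1L) split2 else split1
    sim_mol(one, paste(two, collapse = "."))
  }
}

#' Histogram of pairwise prediction similarities for one product
#'
#' @param sims numeric vector of pairwise reaction similarities.
#' @param bins number of equal bins over (0, 1].
#' @return integer bin counts (values equal to 0 fall into the first bin).
#' @export
similarity_histogram <- function(sims, bins = 10L) {
  idx <- pmin(pmax(ceiling(sims * bins), 1L), bins)
  tabulate(idx, nbins = bins)
}

#' Top-k accuracy of ranked predictions
#'
#' A hit at rank r counts for every k >= r; matching compares canonical,
#' component-sorted reactant SMILES, so atom maps and reactant order are
#' ignored.
#'
#' @param predictions list (one per product) of character vectors of ranked
#'   predicted reactant SMILES.
#' @param truths character vector of ground-truth reactant SMILES.
#' @param ks accuracy cutoffs.
#' @return named numeric vector of accuracies.
#' @export
topk_accuracy <- function(predictions, truths, ks = c(1L, 3L, 5L, 10L)) {
  stopifnot(length(predictions) == length(truths))
  hit_rank <- mapply(function(preds, truth) {
    ct <- canonical_smiles(truth)
    cp <- vapply(preds, canonical_smiles, character(1))
    r <- which(cp == ct)
    if (length(r)) r[1L] else Inf
  }, predictions, truths)
  stats::setNames(vapply(ks, function(k) mean(hit_rank <= k), numeric(1)),
                  paste0("top", ks))
}

#' Cluster products by the shape of their prediction-similarity histograms
#'
#' K-means in Euclidean distance over the relative-frequency histograms of
#' pairwise prediction similarities, as used to separate high- from
#' low-reaction-diversity products.
#'
#' @param histograms matrix (products x bins) of similarity-histogram counts.
#' @param n_clusters number of clusters.
#' @param mean_similarity optional per-product mean pairwise similarity.
#' @param n_centers optional per-product count of distinct predicted centers.
#' @param seed RNG seed (k-means uses random restarts).
#' @return list with \code{assignment} and a per-cluster \code{summary}
#'   data.frame (size, mean similarity, mean number of centers), clusters
#'   ordered by increasing mean similarity.
#' @export
diversity_clusters <- function(histograms, n_clusters = 10L,
                               mean_similarity = NULL, n_centers = NULL,
                               seed = 1L) {
  histograms <- as.matrix(histograms)
  if (nrow(histograms) < n_clusters) {
    rs_error("fewer products than clusters", "rs_cluster_error")
  }
  tot <- rowSums(histograms)
  tot[tot == 0] <- 1
  freq <- histograms / tot
  set.seed(seed)
  uniq <- nrow(unique(freq))
  km <- stats::kmeans(freq, centers = min(n_clusters, uniq), nstart = 5L)
  cl <- km$cluster
  msim <- if (is.null(mean_similarity)) rep(NA_real_, nrow(freq)) else mean_similarity
  mcen <- if (is.null(n_centers)) rep(NA_real_, nrow(freq)) else n_centers
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    data.frame(cluster = k, size = sum(cl == k),
               mean_similarity = mean(msim[cl == k]),
               mean_centers = mean(mcen[cl == k]))
  }))
  ord <- order(summ$mean_similarity)
  summ <- summ[ord, , drop = FALSE]
  relabel <- match(summ$cluster, summ$cluster)
  summ$cluster <- seq_len(nrow(summ))
  rownames(summ) <- NULL
  list(assignment = match(cl, ord), summary = summ,
       tot_withinss = km$tot.withinss)
}

#' Compare two center labels on the same product
#'
#' Centers are compared up to graph automorphism: the kinds must agree, the
#' center atoms must occupy the same canonical-rank positions, and applying
#' both edits must yield identical canonical synthon graphs (which captures
#' the BC original order, BF neighbor changes and charge edits). Comparing
#' by automorphism class rather than raw atom index matters for symmetric
#' products, where two indistinguishable bonds describe the same
#' disconnection.
#'
#' @param a,b \code{center_label}s (not UNCOVERED).
#' @param product the product \code{mol_graph} both labels refer to.
#' @return logical.
#' @export
same_center <- function(a, b, product) {
  if (a$kind != b$kind) return(FALSE)
  if (a$kind == "BC" && a$bc_order != b$bc_order) return(FALSE)
  rank <- mg_canon_rank(product)
  if (!identical(sort(rank[a$atoms]), sort(rank[b$atoms]))) return(FALSE)
  sa <- tryCatch(canonical_smiles(apply_p2s(product, a)$graph),
                 error = function(e) NA_character_)
  sb <- tryCatch(canonical_smiles(apply_p2s(product, b)$graph),
                 error = function(e) NA_character_)
  !is.na(sa) && identical(sa, sb)
}

#' Module-level and end-to-end evaluation
#'
#' Computes (i) end-to-end top-k accuracy of predicted reactant sets,
#' (ii) center-identification top-k accuracy (is the ground-truth center
#' edit among the top-k selected centers), and (iii) synthon-completion
#' top-k accuracy with completion started from the ground-truth center.
#' Uncovered products count as misses everywhere.
#'
#' @param cmodel,smodel trained models.
#' @param records list of test \code{reaction_record}s.
#' @param K,N beam widths.
#' @param ks accuracy cutoffs.
#' @return list of class \code{eval_report}; when records carry reaction
#'   classes, \code{by_class} breaks the end-to-end accuracy down per class.
#' @export
evaluate_models <- function(cmodel, smodel, records, K = 5L, N = 10L,
                            ks = c(1L, 3L, 5L, 10L)) {
  labels <- lapply(records, label_center)
  covered <- vapply(labels, function(l) l$kind != "UNCOVERED", logical(1))
  n <- length(records)
  center_rank <- rep(Inf, n)
  e2e_rank <- rep(Inf, n)
  syn_rank <- rep(Inf, n)
  for (r in seq_len(n)) {
    rec <- records[[r]]
    truth <- canonical_smiles(rec$reactants)
    res <- predict_reactants(cmodel, smodel, rec$product, K = K, N = N,
                             reaction_type = rec$reaction_class)
    if (nrow(res)) {
      hit <- which(res$reactants == truth)
      if (length(hit)) e2e_rank[r] <- hit[1L]
    }
    if (covered[r]) {
      cands <- select_top_centers(cmodel, rec$product, K = K,
                                  reaction_type = rec$reaction_class)
      hit <- which(vapply(cands, function(cd)
        same_center(cd$label, labels[[r]], rec$product), logical(1)))
      if (length(hit)) center_rank[r] <- hit[1L]
      syn <- tryCatch(apply_p2s(rec$product, labels[[r]]),
                      rs_error = function(e) NULL)
      if (!is.null(syn)) {
        resg <- complete_from_center(smodel, rec$product, syn, N = N,
                                     reaction_type = rec$reaction_class)
        if (nrow(resg)) {
          hit <- which(resg$reactants == truth)
          if (length(hit)) syn_rank[r] <- hit[1L]
        }
      }
    }
  }
  mk <- function(rank) stats::setNames(
    vapply(ks, function(k) mean(rank <= k), numeric(1)), paste0("top", ks))
  classes <- vapply(records, function(r)
    if (is.null(r$reaction_class)) NA_integer_ else r$reaction_class,
    integer(1))
  by_class <- NULL
  if (any(!is.na(classes))) {
    by_class <- do.call(rbind, lapply(sort(unique(classes[!is.na(classes)])),
                                      function(cl) {
      sel <- which(classes == cl)
      cbind(data.frame(class = cl, n = length(sel)),
            as.data.frame(as.list(mk(e2e_rank[sel]))))
    }))
  }
  structure(list(
    n = n, coverage = mean(covered),
    end_to_end = mk(e2e_rank),
    center_identification = mk(center_rank),
    synthon_completion = mk(syn_rank),
    by_class = by_class,
    ks = ks), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d products (coverage %.3f)\n", x$n, x$coverage))
  cat("  end-to-end:        ", paste(sprintf("%s=%.3f", names(x$end_to_end),
                                             x$end_to_end), collapse = " "), "\n")
  cat("  center id:         ", paste(sprintf("%s=%.3f",
                                             names(x$center_identification),
                                             x$center_identification),
                                     collapse = " "), "\n")
  cat("  synthon completion:", paste(sprintf("%s=%.3f",
                                             names(x$synthon_completion),
                                             x$synthon_completion),
                                     collapse = " "), "\n")
  invisible(x)
}

#' Complete synthons from a given center (module-level protocol)
#'
#' Runs the beam search of \code{\link{predict_reactants}} starting from an
#' externally supplied synthon graph (typically the ground-truth center),
#' so the completion module is evaluated in isolation.
#'
#' @param smodel trained \code{synthon_model}.
#' @param product product graph.
#' @param synthons list with \code{graph} and \code{frontier} as returned by
#'   \code{\link{apply_p2s}}.
#' @param N beam width.
#' @param reaction_type optional class.
#' @param max_steps attachment-step cap per candidate.
#' @return data.frame like \code{\link{predict_reactants}}.
#' @export
complete_from_center <- function(smodel, product, synthons, N = 10L,
                                 reaction_type = NULL, max_steps = 30L) {
  rt <- if (isTRUE(smodel$reaction_type_known)) reaction_type else NULL
  params <- smodel$params
  cfg <- smodel$cfg
  keys <- names(smodel$vocab$entries)
  entries <- smodel$vocab$entries
  h_p <- encode_plain(product, params, cfg, rt)$graph
  es <- encode_plain(synthons$graph, params, cfg, rt)
  live <- list(list(graph = synthons$graph, es = es, h_s = es$graph,
                    stack = initial_stack(synthons$graph, synthons$frontier),
                    score = 0, t = 0L, touched = synthons$frontier,
                    center = structure(list(kind = "GIVEN",
                                            atoms = synthons$frontier),
                                       class = "center_label"), id = 1L))
  beam_complete(live, params, cfg, rt, entries, keys, h_p, N, max_steps)
}
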