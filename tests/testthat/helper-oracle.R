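# Independent exhaustive enumeration of all completion paths, mirroring the
# decision process: at each state the top-of-stack anchor either stops or
# receives one of the valence-admissible substructures (renormalized), with
# the attachment count capped. Probabilities come from the public one-step
# predictors rather than the beam internals.
enumerate_paths <- function(cmodel, smodel, product, K, max_steps) {
  centers <- select_top_centers(cmodel, product, K)
  entries <- smodel$vocab$entries
  keys <- names(entries)
  out <- new.env(parent = emptyenv()); out$res <- list()
  rec <- function(graph, synthons, stack, score, t, touched) {
    if (!length(stack)) {
      g <- finalize_hydrogens(graph, atoms = unique(touched))
      key <- canonical_smiles(g)
      prev <- out$res[[key]]
      if (is.null(prev) || prev < score) out$res[[key]] <- score
      return(invisible(NULL))
    }
    a <- stack[length(stack)]
    p <- predict_continue(smodel, graph, a, synthons, product)
    rec(graph, synthons, stack[-length(stack)], score + log(1 - p), t, touched)
    if (t >= max_steps) return(invisible(NULL))
    pz <- predict_substructure(smodel, graph, a, synthons, product)
    used <- retrosynth:::mg_sigma_sum(graph)[a] +
      retrosynth:::mg_pi_contrib(graph)[a]
    cap <- retrosynth:::rs_max_valence(graph$atoms$element[a],
                                       graph$atoms$charge[a])
    valid <- vapply(entries, function(e) {
      lk <- if (e$kind == "bond") e$order else 1L
      used + lk <= cap
    }, logical(1))
    if (!any(valid)) return(invisible(NULL))
    pv <- pz * valid
    pv <- pv / sum(pv)
    for (k in seq_along(keys)) {
      if (pv[k] <= 0) next
      res <- tryCatch(attach_substructure(graph, a, entries[[k]]),
                      error = function(e) NULL)
      if (is.null(res)) next
      rec(res$graph, synthons, c(stack, rev(res$new_atoms)),
          score + log(p) + log(as.numeric(pv[k])), t + 1L,
          c(touched, a, res$new_atoms))
    }
  }
  for (cd in centers) {
    init <- tryCatch(apply_p2s(product, cd$label), error = function(e) NULL)
    if (is.null(init)) next
    stack <- retrosynth:::initial_stack(init$graph, init$frontier)
    rec(init$graph, init$graph, stack, cd$loglik + cd$loglik_aux, 0L,
        init$frontier)
  }
  res <- unlist(as.list(out$res))
  sort(res, decreasing = TRUE)
}
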