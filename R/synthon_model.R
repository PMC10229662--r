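# Synthon completion: attachment-continuity prediction (whether a frontier
# atom receives another substructure), attachment-type prediction (which
# vocabulary substructure), and teacher-forced training along ground-truth
# completion paths. Both heads condition on the atom embedding over the
# current intermediate graph, the embedding of the initial synthons, and the
# product embedding.

#' Initialize completion-head parameters
#' @param cfg an \code{\link{encoder_config}}.
#' @param vocab_n vocabulary size (width of the type head).
#' @return named list of matrices.
#' @export
completion_heads <- function(cfg, vocab_n) {
  d <- cfg$hidden
  stopifnot(vocab_n >= 1L)
  list(Vo1 = xavier(1L, d), Vo2 = xavier(1L, d), Vo3 = xavier(1L, d),
       Vz1 = xavier(vocab_n, d), Vz2 = xavier(vocab_n, d),
       Vz3 = xavier(vocab_n, d))
}

#' Create an untrained synthon-completion model
#'
#' @param vocab a \code{substructure_vocab}.
#' @param cfg an \code{\link{encoder_config}}.
#' @param seed RNG seed for initialization.
#' @param reaction_type_known whether atom features carry the reaction class.
#' @return object of class \code{synthon_model}.
#' @export
synthon_model <- function(vocab, cfg = encoder_config(), seed = 1L,
                          reaction_type_known = FALSE) {
  if (vocab_size(vocab) == 0L) {
    rs_error("empty substructure vocabulary", "rs_train_error")
  }
  set.seed(seed)
  structure(list(params = c(encoder_params(cfg),
                            completion_heads(cfg, vocab_size(vocab))),
                 cfg = cfg, vocab = vocab,
                 reaction_type_known = reaction_type_known),
            class = "synthon_model")
}

#' Embedding of a (possibly disconnected) synthon graph
#'
#' The sum of all atom embeddings; equals the sum of the per-component
#' embeddings.
#'
#' @param tape autodiff tape.
#' @param g synthon \code{mol_graph}.
#' @param pn encoder parameter nodes.
#' @param cfg encoder configuration.
#' @param reaction_type optional class.
#' @return 1 x hidden node.
#' @export
synthon_embedding <- function(tape, g, pn, cfg, reaction_type = NULL) {
  encode_graph(tape, g, pn, cfg, reaction_type)$graph
}

# AACP logit node for one anchor.
aacp_logit <- function(tape, pn, a_t, h_s, h_p) {
  ad_sum_scalars(tape, list(
    ad_matmul(tape, a_t, ad_transpose(tape, pn$Vo1)),
    ad_matmul(tape, h_s, ad_transpose(tape, pn$Vo2)),
    ad_matmul(tape, h_p, ad_transpose(tape, pn$Vo3))))
}

# AATP logits node (1 x |vocab|) for one anchor.
aatp_logits <- function(tape, pn, a_t, h_s, h_p) {
  ad_add(tape,
         ad_add(tape,
                ad_matmul(tape, a_t, ad_transpose(tape, pn$Vz1)),
                ad_matmul(tape, h_s, ad_transpose(tape, pn$Vz2))),
         ad_matmul(tape, h_p, ad_transpose(tape, pn$Vz3)))
}

#' Probability that a frontier atom receives another substructure
#'
#' @param model a \code{synthon_model}.
#' @param graph current intermediate \code{mol_graph}.
#' @param anchor frontier atom index.
#' @param synthons initial synthon graph (its embedding is held fixed along
#'   the completion path).
#' @param product product graph.
#' @param reaction_type optional class.
#' @return scalar probability in (0, 1).
#' @export
predict_continue <- function(model, graph, anchor, synthons, product,
                             reaction_type = NULL) {
  if (anchor < 1L || anchor > nrow(graph$atoms)) {
    rs_error("anchor atom not in graph", "rs_anchor_error")
  }
  tape <- ad_tape()
  pn <- param_nodes(tape, model$params)
  rt <- if (isTRUE(model$reaction_type_known)) reaction_type else NULL
  es <- encode_graph(tape, graph, pn, model$cfg, rt)
  h_s <- synthon_embedding(tape, synthons, pn, model$cfg, rt)
  h_p <- encode_graph(tape, product, pn, model$cfg, rt)$graph
  a_t <- ad_rows(tape, es$atom, anchor)
  1 / (1 + exp(-aacp_logit(tape, pn, a_t, h_s, h_p)$val[1L]))
}

#' Distribution over vocabulary substructures at a frontier atom
#'
#' @inheritParams predict_continue
#' @return named probability vector over vocabulary keys (sums to 1).
#' @export
predict_substructure <- function(model, graph, anchor, synthons, product,
                                 reaction_type = NULL) {
  tape <- ad_tape()
  pn <- param_nodes(tape, model$params)
  rt <- if (isTRUE(model$reaction_type_known)) reaction_type else NULL
  es <- encode_graph(tape, graph, pn, model$cfg, rt)
  h_s <- synthon_embedding(tape, synthons, pn, model$cfg, rt)
  h_p <- encode_graph(tape, product, pn, model$cfg, rt)$graph
  a_t <- ad_rows(tape, es$atom, anchor)
  lg <- aatp_logits(tape, pn, a_t, h_s, h_p)$val
  p <- exp(logsoftmax_rows(lg))
  stats::setNames(as.numeric(p), names(model$vocab$entries))
}

# Teacher-forced loss for one completion path: binary cross entropy over
# continue/stop decisions plus cross entropy over attachment types, with
# ground-truth attachments applied to the intermediate graphs.
synthon_loss_one <- function(tape, pn, model, synthons, path, product,
                             reaction_type = NULL) {
  keys <- names(model$vocab$entries)
  rt <- if (isTRUE(model$reaction_type_known)) reaction_type else NULL
  h_s <- synthon_embedding(tape, synthons, pn, model$cfg, rt)
  h_p <- encode_graph(tape, product, pn, model$cfg, rt)$graph
  g <- synthons
  es <- encode_graph(tape, g, pn, model$cfg, rt)
  parts <- list()
  for (st in path$steps) {
    a_t <- ad_rows(tape, es$atom, st$anchor)
    logit <- aacp_logit(tape, pn, a_t, h_s, h_p)
    if (st$action == "attach") {
      parts <- c(parts, list(ad_bce_logits(tape, logit, 1)))
      key <- substructure_key(st$sub)
      target <- match(key, keys)
      if (is.na(target)) {
        rs_error(paste0("path substructure outside vocabulary: ", key),
                 "rs_vocab_error")
      }
      zl <- aatp_logits(tape, pn, a_t, h_s, h_p)
      parts <- c(parts, list(ad_ce_rows(tape, zl, target)))
      g <- attach_substructure(g, st$anchor, st$sub)$graph
      es <- encode_graph(tape, g, pn, model$cfg, rt)
    } else {
      parts <- c(parts, list(ad_bce_logits(tape, logit, 0)))
    }
  }
  ad_sum_scalars(tape, parts)
}

#' Prepare teacher-forcing data from labeled records
#'
#' @param records list of \code{reaction_record}s.
#' @return list of items (product, synthons, frontier, path, reaction_class);
#'   uncovered or undecomposable records are skipped and counted in the
#'   \code{skipped} attribute.
#' @export
completion_training_data <- function(records) {
  out <- list()
  skipped <- 0L
  for (rec in records) {
    lab <- label_center(rec)
    if (lab$kind == "UNCOVERED") { skipped <- skipped + 1L; next }
    item <- tryCatch({
      s <- apply_p2s(rec$product, lab)
      path <- derive_completion_path(s$graph, rec$reactants, s$frontier)
      list(product = rec$product, synthons = s$graph, frontier = s$frontier,
           path = path, reaction_class = rec$reaction_class)
    }, rs_error = function(e) NULL)
    if (is.null(item)) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- item
  }
  attr(out, "skipped") <- skipped
  out
}

#' Train the synthon-completion model with teacher forcing
#'
#' @param model a \code{synthon_model}.
#' @param data output of \code{\link{completion_training_data}}.
#' @param epochs passes over the data.
#' @param lr Adam learning rate.
#' @param batch_size gradient accumulation size.
#' @param verbose print progress.
#' @return trained model with a \code{loss_history} attribute.
#' @export
train_synthon_model <- function(model, data, epochs = 60L, lr = 1e-3,
                                batch_size = 16L, verbose = FALSE) {
  if (!length(data)) rs_error("no completion paths to train on",
                              "rs_train_error")
  params <- model$params
  opt <- adam_init(params, lr = lr)
  history <- numeric(epochs)
  nrec <- length(data)
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (start in seq(1L, nrec, by = batch_size)) {
      bidx <- start:min(start + batch_size - 1L, nrec)
      tape <- ad_tape()
      pn <- param_nodes(tape, params)
      losses <- lapply(data[bidx], function(it) {
        synthon_loss_one(tape, pn, model, it$synthons, it$path, it$product,
                         it$reaction_class)
      })
      total <- ad_sum_scalars(tape, losses)
      ad_backward(tape, total)
      upd <- adam_step(params, param_grads(pn), opt)
      params <- upd$params; opt <- upd$state
      tot <- tot + total$val[1L]
    }
    history[ep] <- tot / nrec
    if (verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("synthon epoch %d loss %.4f", ep, history[ep]))
    }
  }
  model$params <- params
  attr(model, "loss_history") <- history
  model
}
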