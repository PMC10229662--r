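# Reaction-center identification: scoring heads for bond-formation (BF),
# bond-change (BC) and atom (A) centers over the encoder embeddings, the
# induced neighbor-bond type-change predictor, the transformation embedding,
# the atom charge-change predictor, and the jointly normalized
# cross-entropy training objective.

#' Initialize center-head parameters
#' @param cfg an \code{\link{encoder_config}}.
#' @return named list of matrices.
#' @export
center_heads <- function(cfg) {
  d <- cfg$hidden
  list(
    qb = xavier(1L, d), Qb1 = xavier(d, d), Qb2 = xavier(d, d),
    Vb1 = xavier(4L, d), Vb2 = xavier(4L, d), Vb3 = xavier(4L, d),
    Qc1 = xavier(3L, d), Qc2 = xavier(d, d), Qc3 = xavier(d, d),
    qa = xavier(1L, d), Qa1 = xavier(d, d), Qa2 = xavier(d, d),
    Wc1 = xavier(d, d), Wc2 = xavier(d, 4L), Wc3 = xavier(d, d),
    Vc1 = xavier(3L, d), Vc2 = xavier(3L, d)
  )
}

# Admissible center candidates of a product graph, in deterministic order:
# BF candidates are the non-ring bonds (breaking them yields two synthons);
# BC candidates are (bond, original-order slot) pairs excluding the slot
# equal to the bond's kekulized product order; A candidates are all atoms.
center_candidates <- function(g) {
  nb <- nrow(g$bonds)
  kek <- if (nb) mg_kekulized_orders(g) else integer(0)
  bf <- if (nb) which(!g$bonds$in_ring) else integer(0)
  bc <- if (nb) {
    do.call(rbind, lapply(seq_len(nb), function(k) {
      slots <- setdiff(1:3, kek[k])
      data.frame(bond = k, slot = slots)
    }))
  } else data.frame(bond = integer(), slot = integer())
  list(bf = bf, bc = bc, atoms = seq_len(nrow(g$atoms)), kek = kek)
}

#' Score all reaction-center candidates of a product
#'
#' Computes the BF score per bond, the 3-slot BC score vector per bond (the
#' slot matching the product's kekulized order is inadmissible), and the A
#' score per atom, plus the joint likelihood over all admissible candidates,
#' normalized by a shared partition term.
#'
#' @param tape autodiff tape.
#' @param es embedding set of the product from \code{\link{encode_graph}}.
#' @param pn head parameter nodes (see \code{\link{param_nodes}}).
#' @return list with score nodes (\code{sb}, \code{sc}, \code{sa}), the
#'   joint score node \code{joint} (one row per candidate), the candidate
#'   table, and plain log-likelihoods \code{loglik}.
#' @export
score_centers <- function(tape, es, pn) {
  g <- es$graph_obj
  n <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  hp <- es$graph
  cand <- center_candidates(g)
  sa <- ad_matmul(tape,
                  ad_relu(tape, ad_add_rowvec(tape,
                    ad_matmul(tape, es$atom, ad_transpose(tape, pn$Qa1)),
                    ad_matmul(tape, hp, ad_transpose(tape, pn$Qa2)))),
                  ad_transpose(tape, pn$qa))
  if (nb) {
    sb <- ad_matmul(tape,
                    ad_relu(tape, ad_add_rowvec(tape,
                      ad_matmul(tape, es$bond, ad_transpose(tape, pn$Qb1)),
                      ad_matmul(tape, hp, ad_transpose(tape, pn$Qb2)))),
                    ad_transpose(tape, pn$qb))
    sc <- ad_matmul(tape,
                    ad_relu(tape, ad_add_rowvec(tape,
                      ad_matmul(tape, es$bond, ad_transpose(tape, pn$Qc2)),
                      ad_matmul(tape, hp, ad_transpose(tape, pn$Qc3)))),
                    ad_transpose(tape, pn$Qc1))
  } else {
    sb <- NULL; sc <- NULL
  }
  pieces <- list()
  table <- data.frame(type = character(), bond = integer(), atom = integer(),
                      slot = integer())
  if (length(cand$bf)) {
    pieces <- c(pieces, list(ad_rows(tape, sb, cand$bf)))
    table <- rbind(table, data.frame(type = "BF", bond = cand$bf,
                                     atom = NA_integer_, slot = NA_integer_))
  }
  if (nrow(cand$bc)) {
    pieces <- c(pieces, list(ad_gather(tape, sc, cand$bc$bond, cand$bc$slot)))
    table <- rbind(table, data.frame(type = "BC", bond = cand$bc$bond,
                                     atom = NA_integer_, slot = cand$bc$slot))
  }
  pieces <- c(pieces, list(sa))
  table <- rbind(table, data.frame(type = "A", bond = NA_integer_,
                                   atom = seq_len(n), slot = NA_integer_))
  joint <- ad_vcat(tape, pieces)
  lp <- as.numeric(logsoftmax_rows(t(joint$val)))
  list(sb = sb, sc = sc, sa = sa, joint = joint, table = table,
       candidates = cand, loglik = lp)
}

# BF-center neighbor bonds: bonds sharing exactly one endpoint with the
# center bond.
bf_neighbor_bonds <- function(g, bond_idx) {
  i <- g$bonds$i[bond_idx]; j <- g$bonds$j[bond_idx]
  nb <- which((g$bonds$i %in% c(i, j) | g$bonds$j %in% c(i, j)))
  setdiff(nb, bond_idx)
}

#' Predict induced type changes of BF-center neighbor bonds
#'
#' For each bond neighboring a designated BF center, computes the 4-slot
#' distribution (no change, or changed from single/double/triple in the
#' reactants).
#'
#' @param tape autodiff tape.
#' @param es product embedding set.
#' @param pn head parameter nodes.
#' @param bond_idx index of the BF-center bond.
#' @return list with \code{neighbors} (bond indices, possibly empty) and the
#'   logits node \code{logits} (one row per neighbor).
#' @export
predict_neighbor_changes <- function(tape, es, pn, bond_idx) {
  g <- es$graph_obj
  if (bond_idx < 1L || bond_idx > nrow(g$bonds)) {
    rs_error("BF bond index out of range", "rs_label_error")
  }
  nbrs <- bf_neighbor_bonds(g, bond_idx)
  if (!length(nbrs)) return(list(neighbors = integer(0), logits = NULL))
  logits <- ad_add_rowvec(tape,
    ad_add(tape,
      ad_matmul(tape, ad_rows(tape, es$bond, nbrs), ad_transpose(tape, pn$Vb1)),
      ad_matmul(tape,
                ad_rows(tape, es$bond, rep(bond_idx, length(nbrs))),
                ad_transpose(tape, pn$Vb2))),
    ad_matmul(tape, es$graph, ad_transpose(tape, pn$Vb3)))
  list(neighbors = nbrs, logits = logits)
}

#' Transformation embedding of a center label
#'
#' Encodes the product-to-synthon edit: for BF the sum over the center bond
#' and its changed neighbors with an edit one-hot (is-center, or
#' changed-from single/double/triple); for BC a single term; for A the zero
#' vector.
#'
#' @param tape autodiff tape.
#' @param es product embedding set.
#' @param pn head parameter nodes.
#' @param label a \code{center_label}.
#' @return a 1 x hidden node.
#' @export
transformation_embedding <- function(tape, es, pn, label) {
  d <- ncol(pn$Wc1$val)
  if (label$kind == "A") {
    return(ad_const(tape, matrix(0, 1L, d)))
  }
  g <- es$graph_obj
  if (label$kind == "BF") {
    kc <- mg_find_bond(g, label$atoms[1], label$atoms[2])
    bonds <- kc
    xp <- matrix(0, 1L, 4L); xp[1L, 1L] <- 1
    if (!is.null(label$bf_changes) && nrow(label$bf_changes)) {
      for (r in seq_len(nrow(label$bf_changes))) {
        k <- mg_find_bond(g, label$bf_changes$i[r], label$bf_changes$j[r])
        bonds <- c(bonds, k)
        row <- matrix(0, 1L, 4L)
        row[1L, 1L + label$bf_changes$order_react[r]] <- 1
        xp <- rbind(xp, row)
      }
    }
  } else {
    bonds <- mg_find_bond(g, label$atoms[1], label$atoms[2])
    xp <- matrix(0, 1L, 4L)
    xp[1L, 1L + label$bc_order] <- 1
  }
  terms <- ad_matmul(tape,
                     ad_relu(tape, ad_add(tape,
                       ad_matmul(tape, ad_const(tape, xp),
                                 ad_transpose(tape, pn$Wc2)),
                       ad_matmul(tape, ad_rows(tape, es$bond, bonds),
                                 ad_transpose(tape, pn$Wc3)))),
                     ad_transpose(tape, pn$Wc1))
  ad_colsum(tape, terms)
}

#' Predict charge-change classes for involved atoms
#'
#' Three-way distribution per atom (accept one electron, donate one
#' electron, no change), conditioned on the transformation embedding.
#'
#' @param tape autodiff tape.
#' @param es product embedding set.
#' @param pn head parameter nodes.
#' @param cvec transformation-embedding node (1 x hidden).
#' @param atoms atom indices involved in the center or its changed neighbors.
#' @return logits node (length(atoms) x 3).
#' @export
predict_charges <- function(tape, es, pn, cvec, atoms) {
  ad_add_rowvec(tape,
    ad_matmul(tape, ad_rows(tape, es$atom, atoms),
              ad_transpose(tape, pn$Vc1)),
    ad_matmul(tape, cvec, ad_transpose(tape, pn$Vc2)))
}

# Atoms whose charge classes are predicted for a label: center atoms plus
# endpoints of changed neighbor bonds.
involved_atoms <- function(label) {
  sort(unique(c(label$atoms,
                if (!is.null(label$bf_changes))
                  c(label$bf_changes$i, label$bf_changes$j))))
}

#' Per-record center-identification loss
#'
#' Jointly normalized cross entropy over all admissible candidates for the
#' true center, plus cross entropies for the neighbor-change and
#' charge-change predictors.
#'
#' @param tape autodiff tape.
#' @param es product embedding set.
#' @param pn head parameter nodes.
#' @param label ground-truth \code{center_label} (not UNCOVERED).
#' @return scalar loss node.
#' @export
center_loss_one <- function(tape, es, pn, label) {
  sc <- score_centers(tape, es, pn)
  g <- es$graph_obj
  target <- center_target_index(sc$table, g, label)
  if (is.na(target)) {
    rs_error("ground-truth center is not an admissible candidate",
             "rs_label_error")
  }
  loss <- ad_ce_vec(tape, sc$joint, target)
  parts <- list(loss)
  if (label$kind == "BF") {
    kc <- mg_find_bond(g, label$atoms[1], label$atoms[2])
    nc <- predict_neighbor_changes(tape, es, pn, kc)
    if (length(nc$neighbors)) {
      targ <- rep(1L, length(nc$neighbors))
      if (!is.null(label$bf_changes) && nrow(label$bf_changes)) {
        for (r in seq_len(nrow(label$bf_changes))) {
          k <- mg_find_bond(g, label$bf_changes$i[r], label$bf_changes$j[r])
          targ[match(k, nc$neighbors)] <- 1L + label$bf_changes$order_react[r]
        }
      }
      parts <- c(parts, list(ad_ce_rows(tape, nc$logits, targ)))
    }
  }
  atoms <- involved_atoms(label)
  cvec <- transformation_embedding(tape, es, pn, label)
  qlogits <- predict_charges(tape, es, pn, cvec, atoms)
  qtarg <- rep(3L, length(atoms))
  if (!is.null(label$charges)) {
    m <- match(atoms, label$charges$atom)
    qtarg[!is.na(m)] <- label$charges$class[m[!is.na(m)]]
  }
  parts <- c(parts, list(ad_ce_rows(tape, qlogits, qtarg)))
  ad_sum_scalars(tape, parts)
}

# Row index of the ground-truth center in the candidate table.
center_target_index <- function(table, g, label) {
  if (label$kind == "BF") {
    k <- mg_find_bond(g, label$atoms[1], label$atoms[2])
    which(table$type == "BF" & table$bond == k)[1L]
  } else if (label$kind == "BC") {
    k <- mg_find_bond(g, label$atoms[1], label$atoms[2])
    which(table$type == "BC" & table$bond == k & table$slot == label$bc_order)[1L]
  } else {
    which(table$type == "A" & table$atom == label$atoms[1])[1L]
  }
}

#' Create an untrained center-identification model
#'
#' @param cfg an \code{\link{encoder_config}}.
#' @param seed RNG seed for parameter initialization.
#' @param reaction_type_known whether atom features carry the reaction class.
#' @return object of class \code{center_model}.
#' @export
center_model <- function(cfg = encoder_config(), seed = 1L,
                         reaction_type_known = FALSE) {
  set.seed(seed)
  structure(list(params = c(encoder_params(cfg), center_heads(cfg)),
                 cfg = cfg, reaction_type_known = reaction_type_known),
            class = "center_model")
}

rec_rtype <- function(model, rec) {
  if (isTRUE(model$reaction_type_known)) rec$reaction_class else NULL
}

#' Train the center-identification model
#'
#' Minimizes the joint center, neighbor-change and charge-change cross
#' entropies with Adam. Records labeled UNCOVERED are rejected.
#'
#' @param model a \code{center_model}.
#' @param records list of \code{reaction_record}s.
#' @param epochs passes over the data.
#' @param lr Adam learning rate.
#' @param batch_size gradient accumulation size.
#' @param verbose print the loss every few epochs.
#' @return the trained model, with a \code{loss_history} attribute.
#' @export
train_center_model <- function(model, records, epochs = 60L, lr = 1e-3,
                               batch_size = 32L, verbose = FALSE) {
  labels <- lapply(records, label_center)
  keep <- vapply(labels, function(l) l$kind != "UNCOVERED", logical(1))
  if (!any(keep)) {
    rs_error("no covered records to train on", "rs_train_error")
  }
  records <- records[keep]; labels <- labels[keep]
  params <- model$params
  opt <- adam_init(params, lr = lr)
  history <- numeric(epochs)
  nrec <- length(records)
  for (ep in seq_len(epochs)) {
    tot <- 0
    idx <- seq_len(nrec)
    for (start in seq(1L, nrec, by = batch_size)) {
      bidx <- idx[start:min(start + batch_size - 1L, nrec)]
      tape <- ad_tape()
      pn <- param_nodes(tape, params)
      losses <- lapply(bidx, function(r) {
        es <- encode_graph(tape, records[[r]]$product, pn, model$cfg,
                           rec_rtype(model, records[[r]]))
        center_loss_one(tape, es, pn, labels[[r]])
      })
      total <- ad_sum_scalars(tape, losses)
      ad_backward(tape, total)
      upd <- adam_step(params, param_grads(pn), opt)
      params <- upd$params; opt <- upd$state
      tot <- tot + total$val[1L]
    }
    history[ep] <- tot / nrec
    if (verbose && (ep %% 10L == 0L || ep == 1L)) {
      message(sprintf("center epoch %d loss %.4f", ep, history[ep]))
    }
  }
  model$params <- params
  attr(model, "loss_history") <- history
  model
}

#' Select the top-K reaction centers of a product
#'
#' Takes the top-K candidates of each center type, merges the 3K candidates
#' and keeps the overall top-K by joint log-likelihood. Selected BF centers
#' are completed with argmax neighbor-bond changes; all centers get argmax
#' charge-change classes. Ties are broken by score, then type order BF, BC,
#' A, then candidate index.
#'
#' @param model a trained \code{center_model}.
#' @param product product \code{mol_graph}.
#' @param K beam width.
#' @param reaction_type optional class in 1..10 (used when the model was
#'   trained with known types).
#' @return list of candidates: each has \code{label} (a \code{center_label}),
#'   \code{loglik} (joint center log-likelihood) and \code{loglik_aux}
#'   (summed argmax log-probabilities of the neighbor-change and charge
#'   predictions).
#' @export
select_top_centers <- function(model, product, K = 10L, reaction_type = NULL) {
  stopifnot(K >= 1L)
  tape <- ad_tape()
  pn <- param_nodes(tape, model$params)
  rt <- if (isTRUE(model$reaction_type_known)) reaction_type else NULL
  es <- encode_graph(tape, product, pn, model$cfg, rt)
  sc <- score_centers(tape, es, pn)
  tab <- sc$table
  tab$loglik <- sc$loglik
  tab$idx <- seq_len(nrow(tab))
  tab$type_rank <- match(tab$type, c("BF", "BC", "A"))
  ord <- order(-tab$loglik, tab$type_rank, tab$idx)
  tab <- tab[ord, ]
  picked <- do.call(rbind, lapply(c("BF", "BC", "A"), function(tp) {
    sub <- tab[tab$type == tp, , drop = FALSE]
    utils::head(sub, K)
  }))
  picked <- picked[order(-picked$loglik, picked$type_rank, picked$idx), ,
                   drop = FALSE]
  picked <- utils::head(picked, K)
  g <- product
  out <- vector("list", nrow(picked))
  for (r in seq_len(nrow(picked))) {
    row <- picked[r, ]
    aux <- 0
    if (row$type == "BF") {
      k <- row$bond
      atoms <- c(g$bonds$i[k], g$bonds$j[k])
      nc <- predict_neighbor_changes(tape, es, pn, k)
      bf_changes <- NULL
      if (length(nc$neighbors)) {
        lp <- logsoftmax_rows(nc$logits$val)
        cls <- max.col(lp, ties.method = "first")
        aux <- aux + sum(lp[cbind(seq_along(cls), cls)])
        ch <- which(cls > 1L)
        if (length(ch)) {
          bf_changes <- data.frame(i = g$bonds$i[nc$neighbors[ch]],
                                   j = g$bonds$j[nc$neighbors[ch]],
                                   order_react = cls[ch] - 1L)
        }
      }
      label <- structure(list(kind = "BF", atoms = atoms,
                              bc_order = NA_integer_, bf_changes = bf_changes,
                              charges = NULL), class = "center_label")
    } else if (row$type == "BC") {
      k <- row$bond
      label <- structure(list(kind = "BC",
                              atoms = c(g$bonds$i[k], g$bonds$j[k]),
                              bc_order = row$slot, bf_changes = NULL,
                              charges = NULL), class = "center_label")
    } else {
      label <- structure(list(kind = "A", atoms = row$atom,
                              bc_order = NA_integer_, bf_changes = NULL,
                              charges = NULL), class = "center_label")
    }
    atoms <- involved_atoms(label)
    cvec <- transformation_embedding(tape, es, pn, label)
    qlog <- predict_charges(tape, es, pn, cvec, atoms)
    qlp <- logsoftmax_rows(qlog$val)
    qcls <- max.col(qlp, ties.method = "first")
    aux <- aux + sum(qlp[cbind(seq_along(qcls), qcls)])
    label$charges <- data.frame(atom = atoms, class = qcls)
    out[[r]] <- list(label = label, loglik = row$loglik, loglik_aux = aux)
  }
  out
}
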