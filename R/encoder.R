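# Graph message-passing encoder: directed bond messages, iterated t_a times
# with the reverse message excluded, atom embeddings from the concatenation
# of all iterations' incoming messages, graph embedding as the atom sum, and
# order-invariant bond embeddings from endpoint sums and absolute
# differences.

#' Encoder configuration
#'
#' @param hidden hidden width of messages and embeddings.
#' @param ta number of message-passing iterations (receptive field radius).
#' @return list of class \code{encoder_config}.
#' @export
encoder_config <- function(hidden = 300L, ta = 5L) {
  stopifnot(hidden >= 1L, ta >= 1L)
  structure(list(hidden = as.integer(hidden), ta = as.integer(ta)),
            class = "encoder_config")
}

xavier <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize encoder parameters
#'
#' Four message-update matrices, three atom-readout matrices and four
#' bond-readout matrices, sized for the configured hidden width and
#' iteration count.
#'
#' @param cfg an \code{\link{encoder_config}}.
#' @return named list of matrices.
#' @export
encoder_params <- function(cfg) {
  d <- cfg$hidden
  da <- atom_feature_dim()
  db <- bond_feature_dim()
  list(
    W1a = xavier(d, d), W2a = xavier(d, da), W3a = xavier(d, db),
    W4a = xavier(d, d),
    U1a = xavier(d, d), U2a = xavier(d, da), U3a = xavier(d, cfg$ta * d),
    U1b = xavier(d, d), U2b = xavier(d, db), U3b = xavier(d, d),
    U4b = xavier(d, d)
  )
}

# Directed-edge bookkeeping for a graph: edges 2k-1 and 2k are the two
# directions of bond k.
mg_directed <- function(g) {
  b <- g$bonds
  m <- nrow(b)
  if (m == 0L) {
    return(list(src = integer(0), dst = integer(0), bond = integer(0)))
  }
  list(src = as.integer(rbind(b$i, b$j)),
       dst = as.integer(rbind(b$j, b$i)),
       bond = rep(seq_len(m), each = 2L))
}

#' Encode a molecular graph
#'
#' Runs the message-passing encoder on \code{g}, recording the forward pass
#' on the supplied autodiff tape so that heads built on top of the
#' embeddings can be trained end to end.
#'
#' @param tape autodiff tape (\code{ad_tape()}); embeddings are returned as
#'   tape nodes whose \code{$val} holds the numeric matrices.
#' @param g a \code{\link{mol_graph}} with at least one atom.
#' @param pn named list of parameter nodes (see \code{\link{param_nodes}}).
#' @param cfg an \code{\link{encoder_config}}.
#' @param reaction_type optional reaction class in 1..10.
#' @return An embedding set: list with nodes \code{atom} (n x d),
#'   \code{graph} (1 x d), \code{bond} (m x d, undirected), the per-iteration
#'   message nodes \code{messages}, and the feature matrices.
#' @export
encode_graph <- function(tape, g, pn, cfg, reaction_type = NULL) {
  n <- nrow(g$atoms)
  if (n == 0L) stop("cannot encode an empty graph")
  d <- cfg$hidden
  feats <- featurize(g, reaction_type)
  de <- mg_directed(g)
  ne <- length(de$src)

  Xa <- ad_const(tape, feats$atom)
  msgs <- list()
  if (ne > 0L) {
    Xb_dir <- feats$bond[de$bond, , drop = FALSE]
    # aggregation: AGG[e, f] = 1 iff edge f feeds edge e (dst(f) = src(e))
    # excluding the reverse edge (src(f) = dst(e))
    AGG <- matrix(0, ne, ne)
    for (e in seq_len(ne)) {
      AGG[e, de$dst == de$src[e] & de$src != de$dst[e]] <- 1
    }
    INC <- matrix(0, n, ne)
    for (f in seq_len(ne)) INC[de$dst[f], f] <- 1
    AGGc <- ad_const(tape, AGG)
    INCc <- ad_const(tape, INC)
    Xsrc <- ad_const(tape, feats$atom[de$src, , drop = FALSE])
    Xbd <- ad_const(tape, Xb_dir)
    base <- ad_add(tape,
                   ad_matmul(tape, Xsrc, ad_transpose(tape, pn$W2a)),
                   ad_matmul(tape, Xbd, ad_transpose(tape, pn$W3a)))
    M <- ad_const(tape, matrix(0, ne, d))
    sums <- list()
    for (t in seq_len(cfg$ta)) {
      agg <- ad_matmul(tape, ad_matmul(tape, AGGc, M),
                       ad_transpose(tape, pn$W4a))
      M <- ad_matmul(tape, ad_relu(tape, ad_add(tape, base, agg)),
                     ad_transpose(tape, pn$W1a))
      msgs[[t]] <- M
      sums[[t]] <- ad_matmul(tape, INCc, M)
    }
    S <- ad_hcat(tape, sums)
  } else {
    S <- ad_const(tape, matrix(0, n, cfg$ta * d))
  }
  A <- ad_matmul(tape,
                 ad_relu(tape, ad_add(tape,
                   ad_matmul(tape, Xa, ad_transpose(tape, pn$U2a)),
                   ad_matmul(tape, S, ad_transpose(tape, pn$U3a)))),
                 ad_transpose(tape, pn$U1a))
  H <- ad_colsum(tape, A)

  nb <- nrow(g$bonds)
  if (nb > 0L) {
    Ai <- ad_rows(tape, A, g$bonds$i)
    Aj <- ad_rows(tape, A, g$bonds$j)
    Xb <- ad_const(tape, feats$bond)
    B <- ad_matmul(tape,
                   ad_relu(tape, ad_add(tape,
                     ad_add(tape,
                       ad_matmul(tape, Xb, ad_transpose(tape, pn$U2b)),
                       ad_matmul(tape, ad_add(tape, Ai, Aj),
                                 ad_transpose(tape, pn$U3b))),
                     ad_matmul(tape, ad_abs(tape, ad_sub(tape, Ai, Aj)),
                               ad_transpose(tape, pn$U4b)))),
                   ad_transpose(tape, pn$U1b))
  } else {
    B <- ad_const(tape, matrix(0, 0L, d))
  }
  structure(list(atom = A, graph = H, bond = B, messages = msgs,
                 features = feats, graph_obj = g, cfg = cfg,
                 reaction_type = reaction_type),
            class = "embedding_set")
}

#' Create tape nodes for a named parameter list
#'
#' @param tape autodiff tape.
#' @param params named list of matrices.
#' @return named list of parameter nodes; after \code{ad_backward}, gradients
#'   can be collected with \code{\link{param_grads}}.
#' @export
param_nodes <- function(tape, params) {
  lapply(params, function(p) ad_param(tape, p))
}

#' Collect gradients from parameter nodes
#' @param pn named list of nodes from \code{\link{param_nodes}}.
#' @return named list of gradient matrices (zero where unused).
#' @export
param_grads <- function(pn) {
  lapply(pn, function(nd) if (is.null(nd$grad)) nd$val * 0 else nd$grad)
}

#' Embedding of one bond
#'
#' Returns the encoder's representation of a bond, built from the bond
#' features and the sum and absolute difference of its endpoint atom
#' embeddings, hence invariant to endpoint order.
#'
#' @param es an embedding set from \code{\link{encode_graph}}.
#' @param i,j endpoint atom indices.
#' @return numeric vector of length \code{hidden}.
#' @export
bond_embed <- function(es, i, j) {
  k <- mg_find_bond(es$graph_obj, i, j)
  if (k == 0L) stop("bond (", i, ",", j, ") not in graph")
  as.numeric(es$bond$val[k, ])
}
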