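# Atom and bond featurization for the graph message-passing encoder.

N_REACTION_TYPES <- 10L

# one-hot helper with clamping into [lo, hi]
one_hot <- function(x, lo, hi) {
  x <- pmin(pmax(x, lo), hi)
  k <- hi - lo + 1L
  m <- matrix(0, length(x), k)
  m[cbind(seq_along(x), x - lo + 1L)] <- 1
  m
}

#' Atom feature width
#' @keywords internal
atom_feature_dim <- function() {
  length(RS_ELEMENTS) + 1L + 7L + 5L + 5L + 2L + N_REACTION_TYPES
}

#' Bond feature width
#' @keywords internal
bond_feature_dim <- function() 7L

#' Featurize a molecular graph
#'
#' Produces the per-atom feature matrix (element, valence, formal charge and
#' hydrogen-count one-hots, ring and aromatic flags, and an optional
#' reaction-class one-hot that is all-zero when the class is unknown) and the
#' per-bond feature matrix (bond-order one-hot plus conjugation, aromaticity
#' and ring flags).
#'
#' @param g a \code{\link{mol_graph}}.
#' @param reaction_type optional reaction class in 1..10; \code{NULL} leaves
#'   the class block all-zero.
#' @return list with \code{atom} (n x 40) and \code{bond} (m x 7) matrices.
#' @export
featurize <- function(g, reaction_type = NULL) {
  at <- g$atoms
  n <- nrow(at)
  el_idx <- match(at$element, RS_ELEMENTS)
  el_idx[is.na(el_idx)] <- length(RS_ELEMENTS) + 1L  # reserved "other" slot
  el <- matrix(0, n, length(RS_ELEMENTS) + 1L)
  el[cbind(seq_len(n), el_idx)] <- 1
  valence <- one_hot(mg_total_valence(g), 0L, 6L)
  charge <- one_hot(at$charge, -2L, 2L)
  hcount <- one_hot(at$nH, 0L, 4L)
  flags <- cbind(as.numeric(at$in_ring), as.numeric(at$aromatic))
  rt <- matrix(0, n, N_REACTION_TYPES)
  if (!is.null(reaction_type)) {
    stopifnot(reaction_type >= 1L, reaction_type <= N_REACTION_TYPES)
    rt[, reaction_type] <- 1
  }
  atom <- cbind(el, valence, charge, hcount, flags, rt)

  b <- g$bonds
  m <- nrow(b)
  if (m) {
    btype <- one_hot(b$order, 1L, 4L)
    bond <- cbind(btype, as.numeric(b$conjugated),
                  as.numeric(b$order == 4L), as.numeric(b$in_ring))
  } else {
    bond <- matrix(0, 0L, bond_feature_dim())
  }
  list(atom = atom, bond = bond)
}
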