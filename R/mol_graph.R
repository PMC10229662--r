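# Molecular graph data model. Graphs use implicit-hydrogen semantics: only
# heavy atoms are vertices; per-atom hydrogen counts are stored and recomputed
# from standard valences after graph edits.

# Elements recognized by the featurizer; anything else maps to "other".
RS_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

RS_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                I = 1, B = 3, Si = 4, H = 1)

#' Construct a molecular graph
#'
#' @param atoms data.frame with columns \code{element} (character),
#'   \code{charge} (integer), \code{nH} (integer implicit/explicit hydrogen
#'   count), \code{aromatic} (logical), \code{map} (integer atom-map number,
#'   0 when unmapped).
#' @param bonds data.frame with columns \code{i}, \code{j} (atom indices,
#'   \code{i < j}), \code{order} (1 single, 2 double, 3 triple, 4 aromatic).
#' @return An object of class \code{mol_graph} with derived ring and
#'   conjugation annotations.
#' @export
mol_graph <- function(atoms, bonds = NULL) {
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  atoms$element <- as.character(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$map)) atoms$map <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  swap <- bonds$i > bonds$j
  if (any(swap)) {
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  }
  n <- nrow(atoms)
  if (nrow(bonds)) {
    stopifnot(all(bonds$i >= 1L), all(bonds$j <= n), all(bonds$i != bonds$j))
    if (anyDuplicated(bonds[, c("i", "j")])) stop("duplicate bonds")
  }
  mp <- atoms$map[atoms$map > 0L]
  if (anyDuplicated(mp)) stop("duplicate atom-map numbers")
  g <- structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
  mg_annotate(g)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph: %d atoms, %d bonds> %s\n",
              nrow(x$atoms), nrow(x$bonds), write_smiles(x)))
  invisible(x)
}

# Adjacency list: for each atom, data.frame of (nbr, bond row index, order).
mg_adj <- function(g) {
  n <- nrow(g$atoms)
  m <- nrow(g$bonds)
  adj <- rep(list(data.frame(nbr = integer(), bond = integer(),
                             order = integer())), n)
  if (m) {
    b <- g$bonds
    at <- c(b$i, b$j)
    df <- data.frame(nbr = c(b$j, b$i), bond = rep(seq_len(m), 2L),
                     order = rep(b$order, 2L))
    sp <- split(seq_len(2L * m), at)
    for (nm in names(sp)) {
      adj[[as.integer(nm)]] <- df[sp[[nm]], , drop = FALSE]
    }
  }
  adj
}

# Connected component id per atom.
mg_components <- function(g) {
  n <- nrow(g$atoms)
  comp <- rep(0L, n)
  adj <- mg_adj(g)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      a <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[a] > 0L) next
      comp[a] <- cid
      nb <- adj[[a]]$nbr
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

# A bond is a ring bond iff it is not a bridge (Tarjan lowlink DFS).
mg_ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0L) return(logical(0))
  n <- nrow(g$atoms)
  adj <- mg_adj(g)
  disc <- rep(0L, n)
  low <- rep(0L, n)
  bridge <- logical(nb)
  counter <- 0L
  dfs <- function(u, parent_bond) {
    counter <<- counter + 1L
    disc[u] <<- counter
    low[u] <<- counter
    nbr <- adj[[u]]
    for (r in seq_len(nrow(nbr))) {
      v <- nbr$nbr[r]; e <- nbr$bond[r]
      if (e == parent_bond) next
      if (disc[v] == 0L) {
        dfs(v, e)
        low[u] <<- min(low[u], low[v])
        if (low[v] > disc[u]) bridge[e] <<- TRUE
      } else {
        low[u] <<- min(low[u], disc[v])
      }
    }
  }
  for (s in seq_len(n)) if (disc[s] == 0L) dfs(s, 0L)
  !bridge
}

# Effective valence allowance for an element given formal charge.
rs_valence <- function(element, charge) {
  v <- RS_VALENCE[element]
  v[is.na(v)] <- 4
  ifelse(element == "C", v - abs(charge), v + charge)
}

# Per-atom sigma-bond sum: aromatic bonds count 1, others their order.
mg_sigma_sum <- function(g) {
  n <- nrow(g$atoms)
  s <- numeric(n)
  b <- g$bonds
  if (nrow(b)) {
    o <- ifelse(b$order == 4L, 1L, b$order)
    for (k in seq_len(nrow(b))) {
      s[b$i[k]] <- s[b$i[k]] + o[k]
      s[b$j[k]] <- s[b$j[k]] + o[k]
    }
  }
  s
}

# Whether each atom contributes a pi electron pair (i.e. carries one double
# bond in a kekulized form) to an aromatic system. Aromatic C/B/P always do;
# aromatic N only when it has valence capacity left (pyridine yes, pyrrole
# N-H no); aromatic O/S contribute a lone pair instead.
mg_pi_contrib <- function(g) {
  n <- nrow(g$atoms)
  pi <- rep(0L, n)
  b <- g$bonds
  if (!nrow(b)) return(pi)
  arom_deg <- integer(n)
  ar <- b$order == 4L
  for (k in which(ar)) {
    arom_deg[b$i[k]] <- arom_deg[b$i[k]] + 1L
    arom_deg[b$j[k]] <- arom_deg[b$j[k]] + 1L
  }
  sigma <- mg_sigma_sum(g)
  cap <- rs_valence(g$atoms$element, g$atoms$charge)
  for (a in which(arom_deg > 0L)) {
    el <- g$atoms$element[a]
    if (el %in% c("C", "B", "P")) {
      pi[a] <- 1L
    } else if (el == "N") {
      h <- g$atoms$nH[a]
      if (is.na(h)) h <- 0L
      if (sigma[a] + h + 1 <= cap[a]) pi[a] <- 1L
    }
  }
  pi
}

# Used valence per atom (excluding hydrogens): sigma bonds plus aromatic
# pi contribution.
mg_bond_order_sum <- function(g) {
  as.integer(mg_sigma_sum(g) + mg_pi_contrib(g))
}

# Fill implicit hydrogens from valence for the given atoms (default: all
# atoms without an explicit H count).
mg_fill_h <- function(g, which_atoms = NULL) {
  used <- mg_bond_order_sum(g)
  val <- rs_valence(g$atoms$element, g$atoms$charge)
  if (is.null(which_atoms)) which_atoms <- seq_len(nrow(g$atoms))
  g$atoms$nH[which_atoms] <-
    pmax(0L, as.integer(val[which_atoms] - used[which_atoms]))
  g
}

# Recompute ring flags and conjugation after structural edits. Aromatic
# bonds not inside any ring are demoted to single bonds (e.g. a default
# bond written between two aromatic rings).
mg_annotate <- function(g) {
  ring <- mg_ring_bonds(g)
  if (any(g$bonds$order == 4L & !ring)) {
    g$bonds$order[g$bonds$order == 4L & !ring] <- 1L
    ring <- mg_ring_bonds(g)
  }
  g$bonds$in_ring <- ring
  n <- nrow(g$atoms)
  in_ring_atom <- rep(FALSE, n)
  arom_atom <- rep(FALSE, n)
  b <- g$bonds
  if (nrow(b)) {
    in_ring_atom[unique(c(b$i[ring], b$j[ring]))] <- TRUE
    arom <- b$order == 4L
    arom_atom[unique(c(b$i[arom], b$j[arom]))] <- TRUE
  }
  g$atoms$in_ring <- in_ring_atom
  # keep parser-declared aromatic atoms only if still in an aromatic ring
  g$atoms$aromatic <- arom_atom
  # conjugated: aromatic, or a multiple bond adjacent to another multiple
  # bond, or a single bond whose both endpoints carry a multiple bond.
  multi_at <- rep(FALSE, n)
  if (nrow(b)) {
    hi <- b$order >= 2L
    multi_at[unique(c(b$i[hi], b$j[hi]))] <- TRUE
    g$bonds$conjugated <- (b$order == 4L) |
      (b$order >= 2L & (vapply(seq_len(nrow(b)), function(k) {
        any(b$order[-k][(b$i[-k] %in% c(b$i[k], b$j[k])) |
                        (b$j[-k] %in% c(b$i[k], b$j[k]))] >= 2L)
      }, logical(1)))) |
      (b$order == 1L & multi_at[b$i] & multi_at[b$j])
  } else {
    g$bonds$conjugated <- logical(0)
  }
  g
}

# Find the bond row index between atoms a and b (0 if absent).
mg_find_bond <- function(g, a, b) {
  i <- min(a, b); j <- max(a, b)
  k <- which(g$bonds$i == i & g$bonds$j == j)
  if (length(k)) k[1L] else 0L
}

# Induced subgraph on a set of atoms; returns graph plus the index map
# (old index -> new index, 0 when dropped).
mg_subgraph <- function(g, keep) {
  keep <- sort(keep)
  idx <- integer(nrow(g$atoms))
  idx[keep] <- seq_along(keep)
  b <- g$bonds[g$bonds$i %in% keep & g$bonds$j %in% keep, , drop = FALSE]
  b$i <- idx[b$i]; b$j <- idx[b$j]
  g2 <- mol_graph(g$atoms[keep, , drop = FALSE], b)
  list(graph = g2, index = idx)
}

# Morgan-style canonical atom ranks: iterative neighborhood refinement over
# an initial invariant (element, charge, nH, aromaticity, degree). Ties left
# by symmetry are genuine automorphisms and harmless for tie-breaking.
mg_canon_rank <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) return(integer(0))
  adj <- mg_adj(g)
  deg <- vapply(adj, nrow, integer(1))
  key <- paste(match(g$atoms$element, c(RS_ELEMENTS, "other"), nomatch = 99L),
               g$atoms$charge, g$atoms$nH, as.integer(g$atoms$aromatic), deg)
  rank <- as.integer(factor(key))
  for (it in seq_len(n + 2L)) {
    nbr_sig <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      paste(sort(paste0(nb$order, ":", rank[nb$nbr])), collapse = ",")
    }, character(1))
    new_rank <- as.integer(factor(paste(rank, nbr_sig)))
    if (identical(new_rank, rank)) break
    rank <- new_rank
  }
  rank
}

# Kekulized order (1 or 2) for every bond: aromatic ring systems get a
# perfect matching of double bonds by backtracking; non-aromatic bonds keep
# their order. Aromatic atoms that already carry a full valence (e.g.
# pyrrole-type N-H, aromatic O/S) do not need a double bond.
mg_kekulized_orders <- function(g) {
  ord <- g$bonds$order
  arom <- which(ord == 4L)
  if (!length(arom)) return(ord)
  ord[arom] <- 1L
  atoms <- sort(unique(c(g$bonds$i[arom], g$bonds$j[arom])))
  # atoms that must carry exactly one double bond in the kekulized form
  need_set <- atoms[mg_pi_contrib(g)[atoms] == 1L]
  edges <- lapply(arom, function(k) c(g$bonds$i[k], g$bonds$j[k]))
  match_rec <- function(remaining, chosen) {
    if (!length(remaining)) return(chosen)
    a <- remaining[1L]
    cand <- which(vapply(seq_along(arom), function(e) {
      any(edges[[e]] == a) && all(edges[[e]] %in% c(a, remaining))
    }, logical(1)))
    for (e in cand) {
      other <- setdiff(edges[[e]], a)
      res <- match_rec(setdiff(remaining, c(a, other)), c(chosen, e))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  sol <- match_rec(need_set, integer(0))
  if (!is.null(sol)) ord[arom[sol]] <- 2L
  ord
}

#' Total used valence (bond orders plus hydrogens) per atom
#' @keywords internal
mg_total_valence <- function(g) {
  mg_bond_order_sum(g) + g$atoms$nH
}
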