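# Substructure vocabulary for synthon completion. A substructure is either a
# bond unit (one new atom joined to the anchor by a bond of a given order) or
# a ring unit (a single or polycyclic ring of new atoms joined to the anchor
# by a new single bond at a designated attachment atom). Substructures are
# mined from the difference between reactant graphs and synthon graphs in
# training data and deduplicated by a canonical key.

#' Construct a bond substructure
#' @param order bond order (1,2,3).
#' @param element,charge element symbol and formal charge of the new atom.
#' @return object of class \code{substructure}.
#' @export
sub_bond <- function(order, element, charge = 0L) {
  structure(list(kind = "bond", order = as.integer(order),
                 atoms = data.frame(element = element,
                                    charge = as.integer(charge),
                                    aromatic = FALSE),
                 bonds = NULL),
            class = "substructure")
}

#' Construct a ring substructure
#'
#' @param atoms data.frame(element, charge, aromatic); row 1 is the
#'   designated attachment atom, which is joined to the anchor by a new
#'   single bond.
#' @param bonds data.frame(i, j, order) over local indices.
#' @return object of class \code{substructure}.
#' @export
sub_ring <- function(atoms, bonds) {
  structure(list(kind = "ring", order = 1L, atoms = atoms, bonds = bonds),
            class = "substructure")
}

#' Canonical key of a substructure
#'
#' Bond units are keyed by the bond-order symbol and the new atom; ring units
#' by a canonical fragment SMILES in which the attachment atom carries the
#' reserved map number 1.
#'
#' @param sub a \code{substructure}.
#' @return character key.
#' @export
substructure_key <- function(sub) {
  if (sub$kind == "bond") {
    q <- sub$atoms$charge[1]
    qs <- if (q == 0L) "" else if (q > 0L) strrep("+", q) else strrep("-", -q)
    paste0(c("-", "=", "#")[sub$order], sub$atoms$element[1], qs)
  } else {
    g <- ring_sub_graph(sub)
    rank <- mg_canon_rank(g)
    # attachment atom (local index 1) always first in the traversal
    pr <- rank + 2L
    pr[1L] <- 1L
    write_smiles(g, include_maps = TRUE, order = pr)
  }
}

# Standalone graph of a ring substructure with map 1 on the attachment atom.
ring_sub_graph <- function(sub) {
  at <- sub$atoms
  at$map <- c(1L, rep(0L, nrow(at) - 1L))
  at$nH <- NA_integer_
  g <- mol_graph(at, sub$bonds)
  g <- mg_fill_h(g)
  # attachment atom holds one valence slot for the anchor bond
  g$atoms$nH[1L] <- max(0L, g$atoms$nH[1L] - 1L)
  g
}

#' @export
print.substructure <- function(x, ...) {
  cat("<substructure ", x$kind, ": ", substructure_key(x), ">\n", sep = "")
  invisible(x)
}

#' Attach a substructure to an anchor atom
#'
#' Adds the substructure's atoms and bonds to the graph, joined to
#' \code{anchor}: bond units by a bond of the unit's order, ring units by a
#' single bond to the ring's attachment atom. Hydrogens on the anchor are
#' recomputed (attachment may displace a hydrogen); an attachment that would
#' exceed the anchor's valence is rejected with a typed error.
#'
#' @param g mol_graph being completed.
#' @param anchor atom index in \code{g}.
#' @param sub a \code{substructure}.
#' @return list with \code{graph} and \code{new_atoms} (indices of the added
#'   atoms, attachment atom first).
#' @export
attach_substructure <- function(g, anchor, sub) {
  stopifnot(anchor >= 1L, anchor <= nrow(g$atoms))
  link_order <- if (sub$kind == "bond") sub$order else 1L
  used <- mg_sigma_sum(g) + mg_pi_contrib(g)
  cap <- rs_max_valence(g$atoms$element[anchor], g$atoms$charge[anchor])
  if (used[anchor] + link_order > cap) {
    rs_error(sprintf("attachment exceeds valence at atom %d (%s)", anchor,
                     g$atoms$element[anchor]), "rs_valence_error")
  }
  n0 <- nrow(g$atoms)
  na <- nrow(sub$atoms)
  new_atoms <- data.frame(element = sub$atoms$element,
                          charge = sub$atoms$charge,
                          nH = 0L,
                          aromatic = sub$atoms$aromatic,
                          map = 0L)
  atoms <- rbind(g$atoms[names(new_atoms)], new_atoms)
  extra <- data.frame(i = anchor, j = n0 + 1L, order = link_order)
  if (!is.null(sub$bonds) && nrow(sub$bonds)) {
    extra <- rbind(extra, data.frame(i = sub$bonds$i + n0,
                                     j = sub$bonds$j + n0,
                                     order = sub$bonds$order))
  }
  bonds <- rbind(g$bonds[, c("i", "j", "order")], extra)
  out <- mol_graph(atoms, bonds)
  new_idx <- n0 + seq_len(na)
  out <- mg_fill_h(out, which_atoms = new_idx)
  # anchor keeps at most its previous hydrogen count; attachment may displace
  capn <- rs_valence(out$atoms$element[anchor], out$atoms$charge[anchor])
  out$atoms$nH[anchor] <- max(0L, min(g$atoms$nH[anchor],
                                      as.integer(capn - mg_bond_order_sum(out)[anchor])))
  rs_check_valence(out, atoms = c(anchor, new_idx))
  list(graph = out, new_atoms = new_idx)
}

#' Fill open valence with hydrogens on the given atoms
#'
#' Used when a completed intermediate graph is finalized into reactants:
#' frontier atoms that received no attachment regain their hydrogens.
#'
#' @param g mol_graph.
#' @param atoms atom indices to refill (default all).
#' @return mol_graph.
#' @export
finalize_hydrogens <- function(g, atoms = NULL) {
  mg_fill_h(g, which_atoms = atoms)
}

# ---------------------------------------------------------------------------
# Ground-truth completion paths.

#' Derive the ground-truth completion path from synthons to reactants
#'
#' Decomposes the difference between the reactant graph and the synthon
#' graph into bond and ring substructures anchored at existing atoms,
#' ordered depth-first from the reaction-center atoms (ties broken by
#' canonical rank). Replaying the returned steps on the synthon graph
#' reproduces the reactant graph.
#'
#' @param synthons synthon \code{mol_graph} (mapped atoms).
#' @param reactants reactant \code{mol_graph} (mapped plus unmapped atoms).
#' @param frontier synthon atom indices of the reaction center.
#' @return A \code{completion_path}: list of steps, each
#'   \code{list(action = "attach", anchor = <index in the growing graph>,
#'   sub = <substructure>)} or \code{list(action = "stop", anchor = ...)}.
#' @export
derive_completion_path <- function(synthons, reactants, frontier) {
  smap <- synthons$atoms$map
  if (!all(smap[smap > 0L] %in% reactants$atoms$map)) {
    rs_error("synthon mapped atoms missing from reactants", "rs_path_error")
  }
  reactants$atoms$map[!(reactants$atoms$map %in% smap)] <- 0L
  rmap <- reactants$atoms$map
  r_of_s <- match(smap, rmap)            # synthon idx -> reactant idx
  s_of_r <- match(rmap, smap)            # reactant idx -> synthon idx (NA new)
  new_r <- which(is.na(s_of_r))
  # mapped skeleton must agree
  sb <- mapped_bond_table(synthons)
  rb <- mapped_bond_table(reactants)
  if (nrow(sb) != nrow(rb) ||
      !setequal(paste(sb$lo, sb$hi, sb$order), paste(rb$lo, rb$hi, rb$order))) {
    rs_error("synthon and reactant mapped skeletons differ", "rs_path_error")
  }

  radj <- mg_adj(reactants)
  rank <- mg_canon_rank(reactants)

  # ring systems among new atoms
  ring_flag <- mg_ring_bonds(reactants)
  rbonds <- reactants$bonds
  new_ring_bond <- which(ring_flag & rbonds$i %in% new_r & rbonds$j %in% new_r)
  ring_sys_of <- rep(NA_integer_, nrow(reactants$atoms))
  if (length(new_ring_bond)) {
    ring_atoms <- sort(unique(c(rbonds$i[new_ring_bond], rbonds$j[new_ring_bond])))
    sub <- mg_subgraph(reactants, ring_atoms)
    keepb <- sub$graph$bonds
    # only ring bonds define connectivity between systems
    lk <- mapply(function(i, j) {
      k <- mg_find_bond(reactants, ring_atoms[i], ring_atoms[j])
      ring_flag[k]
    }, keepb$i, keepb$j)
    g2 <- sub$graph
    g2$bonds <- g2$bonds[lk, , drop = FALSE]
    comp <- mg_components(g2)
    ring_sys_of[ring_atoms] <- comp
  }

  # parent search: BFS from mapped atoms over new atoms
  parent <- rep(NA_integer_, nrow(reactants$atoms))
  seen <- !is.na(s_of_r)
  queue <- which(seen)
  order_found <- integer(0)
  while (length(queue)) {
    a <- queue[1L]; queue <- queue[-1L]
    nbrs <- radj[[a]]
    if (!nrow(nbrs)) next
    for (b in nbrs$nbr[order(rank[nbrs$nbr])]) {
      if (seen[b]) next
      seen[b] <- TRUE
      parent[b] <- a
      order_found <- c(order_found, b)
      queue <- c(queue, b)
    }
  }
  if (!all(seen[new_r])) {
    rs_error("disconnected leaving atoms in reactants", "rs_path_error")
  }

  # group new atoms into attachment units
  unit_of <- rep(NA_integer_, nrow(reactants$atoms))
  units <- list()
  for (a in new_r) {
    if (!is.na(unit_of[a])) next
    if (!is.na(ring_sys_of[a])) {
      sys_atoms <- which(ring_sys_of == ring_sys_of[a] & is.na(unit_of))
      uid <- length(units) + 1L
      unit_of[sys_atoms] <- uid
      units[[uid]] <- list(kind = "ring", atoms = sys_atoms)
    } else {
      uid <- length(units) + 1L
      unit_of[a] <- uid
      units[[uid]] <- list(kind = "bond", atoms = a)
    }
  }

  # attachment atom and anchor (parent outside the unit) of each unit
  for (uid in seq_along(units)) {
    u <- units[[uid]]
    outside <- vapply(u$atoms, function(a) {
      pa <- parent[a]
      !is.na(pa) && (is.na(unit_of[pa]) || unit_of[pa] != uid)
    }, logical(1))
    entry <- u$atoms[outside]
    if (length(entry) != 1L) {
      rs_error("leaving-group unit with multiple or no entry points",
               "rs_path_error")
    }
    k <- mg_find_bond(reactants, entry, parent[entry])
    if (units[[uid]]$kind == "ring") {
      if (reactants$bonds$order[k] != 1L) {
        rs_error("ring unit attached by a non-single bond", "rs_path_error")
      }
    }
    units[[uid]]$entry <- entry
    units[[uid]]$anchor_r <- parent[entry]
    units[[uid]]$link_order <- reactants$bonds$order[k]
  }

  make_sub <- function(uid) {
    u <- units[[uid]]
    if (u$kind == "bond") {
      a <- u$atoms
      sub_bond(u$link_order, reactants$atoms$element[a],
               reactants$atoms$charge[a])
    } else {
      # local order: entry first, then DFS by canonical rank inside the unit
      loc <- dfs_unit_order(u$atoms, u$entry, reactants, rank)
      at <- reactants$atoms[loc, c("element", "charge", "aromatic")]
      idx <- match(seq_len(nrow(reactants$atoms)), loc)
      bsel <- reactants$bonds[reactants$bonds$i %in% loc &
                              reactants$bonds$j %in% loc, , drop = FALSE]
      bl <- data.frame(i = idx[bsel$i], j = idx[bsel$j], order = bsel$order)
      sub_ring(at, bl)
    }
  }

  # simulate the depth-first replay to emit anchored steps with indices in
  # the growing graph
  g <- synthons
  g_of_r <- s_of_r                       # reactant idx -> growing-graph idx
  pend <- lapply(seq_len(nrow(reactants$atoms)), function(a) {
    ids <- which(vapply(units, function(u) u$anchor_r == a, logical(1)))
    ids[order(rank[vapply(units[ids], `[[`, 0L, "entry")])]
  })
  stack <- frontier[order(mg_canon_rank(synthons)[frontier], decreasing = TRUE)]
  stack_r <- r_of_s[stack]               # reactant-side identity of stack atoms
  steps <- list()
  guard <- 0L
  while (length(stack)) {
    guard <- guard + 1L
    if (guard > 1000L) rs_error("completion path runaway", "rs_path_error")
    top <- length(stack)
    a_g <- stack[top]
    a_r <- stack_r[top]
    todo <- pend[[a_r]]
    if (length(todo)) {
      uid <- todo[1L]
      pend[[a_r]] <- todo[-1L]
      sub <- make_sub(uid)
      steps[[length(steps) + 1L]] <- list(action = "attach", anchor = a_g,
                                          sub = sub)
      res <- attach_substructure(g, a_g, sub)
      g <- res$graph
      u <- units[[uid]]
      loc <- if (u$kind == "ring") dfs_unit_order(u$atoms, u$entry,
                                                  reactants, rank) else u$atoms
      g_of_r[loc] <- res$new_atoms
      # push new atoms so the first-listed is processed first
      stack <- c(stack, rev(res$new_atoms))
      stack_r <- c(stack_r, rev(loc))
    } else {
      steps[[length(steps) + 1L]] <- list(action = "stop", anchor = a_g)
      stack <- stack[-top]
      stack_r <- stack_r[-top]
    }
  }
  path <- structure(list(steps = steps, n_attach = sum(vapply(steps, function(s)
    s$action == "attach", logical(1)))), class = "completion_path")
  # the replay must land exactly on the reactants; any cross-link the bond/
  # ring decomposition cannot express is caught here
  ok <- tryCatch(
    canonical_smiles(replay_path(synthons, path)) ==
      canonical_smiles(reactants),
    error = function(e) FALSE)
  if (!ok) {
    rs_error("difference not decomposable into bond/ring attachments",
             "rs_path_error")
  }
  path
}

# DFS ordering of a unit's atoms from its entry atom, ties by canonical rank.
dfs_unit_order <- function(atoms, entry, g, rank) {
  adj <- mg_adj(g)
  out <- integer(0)
  seen <- logical(nrow(g$atoms))
  rec <- function(a) {
    seen[a] <<- TRUE
    out <<- c(out, a)
    nb <- adj[[a]]$nbr
    nb <- nb[nb %in% atoms & !seen[nb]]
    for (b in nb[order(rank[nb])]) if (!seen[b]) rec(b)
  }
  rec(entry)
  out
}

#' Replay a completion path on a synthon graph
#'
#' @param synthons synthon \code{mol_graph}.
#' @param path a \code{completion_path}.
#' @return the completed \code{mol_graph} with hydrogens finalized.
#' @export
replay_path <- function(synthons, path) {
  g <- synthons
  touched <- integer(0)
  for (st in path$steps) {
    if (st$action == "attach") {
      res <- attach_substructure(g, st$anchor, st$sub)
      g <- res$graph
      touched <- c(touched, st$anchor, res$new_atoms)
    } else {
      touched <- c(touched, st$anchor)
    }
  }
  finalize_hydrogens(g, atoms = unique(touched))
}

#' Build the substructure vocabulary from training records
#'
#' Labels each record, applies the product-to-synthon transformation, derives
#' its completion path and collects the canonical-keyed union of all
#' attached substructures. Records that are uncovered or whose difference
#' cannot be decomposed are skipped and counted.
#'
#' @param records list of \code{reaction_record}s.
#' @return A \code{substructure_vocab}: list with \code{entries} (named list
#'   key -> substructure), \code{counts}, and skip statistics. Keys are
#'   sorted so vocabulary indices are stable.
#' @export
build_vocabulary <- function(records) {
  entries <- list()
  counts <- integer(0)
  n_uncovered <- 0L
  n_failed <- 0L
  for (rec in records) {
    lab <- label_center(rec)
    if (lab$kind == "UNCOVERED") { n_uncovered <- n_uncovered + 1L; next }
    path <- tryCatch({
      s <- apply_p2s(rec$product, lab)
      derive_completion_path(s$graph, rec$reactants, s$frontier)
    }, rs_error = function(e) NULL)
    if (is.null(path)) { n_failed <- n_failed + 1L; next }
    for (st in path$steps) {
      if (st$action != "attach") next
      key <- substructure_key(st$sub)
      if (is.null(entries[[key]])) {
        entries[[key]] <- st$sub
        counts[key] <- 0L
      }
      counts[key] <- counts[key] + 1L
    }
  }
  ord <- if (length(entries)) order(names(entries)) else integer(0)
  structure(list(entries = entries[ord], counts = counts[names(entries)[ord]],
                 n_uncovered = n_uncovered, n_failed = n_failed),
            class = "substructure_vocab")
}

#' @export
print.substructure_vocab <- function(x, ...) {
  cat(sprintf("<substructure_vocab: %d entries (%d uncovered, %d undecomposable skipped)>\n",
              length(x$entries), x$n_uncovered, x$n_failed))
  invisible(x)
}

#' Number of vocabulary entries
#' @param vocab a \code{substructure_vocab}.
#' @export
vocab_size <- function(vocab) length(vocab$entries)
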