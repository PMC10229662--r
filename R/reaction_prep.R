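# Reaction parsing and ground-truth derivation: typed reaction-center labels
# from the atom-mapped product/reactant graph difference, the product-to-
# synthon transformation, and completion paths used for teacher forcing.

rs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rs_error")))
}

#' Parse an atom-mapped reaction SMILES
#'
#' @param rxn_smiles string of the form \code{"reactants>>product"} (a
#'   \code{reactants>reagents>product} form is accepted; reagents are
#'   ignored). Every mapped product atom must have a matching map number on
#'   the reactant side.
#' @param reaction_class optional class label 1..10.
#' @return A \code{reaction_record}: product and reactant graphs (the
#'   reactant graph may have several components), the class, and the raw
#'   string.
#' @export
parse_reaction <- function(rxn_smiles, reaction_class = NULL) {
  parts <- strsplit(rxn_smiles, ">", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts) | seq_along(parts) == 2L]
  fields <- strsplit(rxn_smiles, ">", fixed = TRUE)[[1]]
  if (length(fields) == 3L) {
    react_s <- fields[1]; prod_s <- fields[3]
  } else if (length(fields) == 2L) {
    react_s <- fields[1]; prod_s <- fields[2]
  } else {
    rs_error(paste0("reaction SMILES must have a 'reactants>>product' shape: ",
                    rxn_smiles), "rs_parse_error")
  }
  if (!nzchar(react_s) || !nzchar(prod_s)) {
    rs_error(paste0("empty reaction side in: ", rxn_smiles), "rs_parse_error")
  }
  product <- tryCatch(parse_smiles(prod_s), error = function(e) {
    rs_error(paste0("cannot parse product: ", conditionMessage(e)),
             "rs_parse_error")
  })
  reactants <- tryCatch(parse_smiles(react_s), error = function(e) {
    rs_error(paste0("cannot parse reactants: ", conditionMessage(e)),
             "rs_parse_error")
  })
  pm <- product$atoms$map
  rm_ <- reactants$atoms$map
  missing <- setdiff(pm[pm > 0L], rm_[rm_ > 0L])
  if (length(missing)) {
    rs_error(paste0("product atoms with map numbers ",
                    paste(missing, collapse = ","),
                    " have no reactant match in: ", rxn_smiles),
             "rs_parse_error")
  }
  structure(list(product = product, reactants = reactants,
                 reaction_class = reaction_class, smiles = rxn_smiles),
            class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record: %d reactant component(s) -> %d-atom product>\n",
              max(mg_components(x$reactants)), nrow(x$product$atoms)))
  invisible(x)
}

# Map-number keyed bond table: rows (lo map, hi map, order) for bonds whose
# both endpoints are mapped.
mapped_bond_table <- function(g) {
  b <- g$bonds
  mp <- g$atoms$map
  keep <- which(mp[b$i] > 0L & mp[b$j] > 0L)
  data.frame(lo = pmin(mp[b$i[keep]], mp[b$j[keep]]),
             hi = pmax(mp[b$i[keep]], mp[b$j[keep]]),
             order = b$order[keep])
}

# Leaving fragments: connected components of unmapped reactant atoms, with
# the mapped atoms they attach to.
leaving_fragments <- function(reactants) {
  mp <- reactants$atoms$map
  unm <- which(mp == 0L)
  if (!length(unm)) return(list())
  sub <- mg_subgraph(reactants, unm)
  comp <- mg_components(sub$graph)
  adj <- mg_adj(reactants)
  lapply(seq_len(max(comp)), function(cid) {
    frag_atoms <- unm[comp == cid]
    attach <- unique(unlist(lapply(frag_atoms, function(a) {
      nb <- adj[[a]]$nbr
      nb[mp[nb] > 0L]
    })))
    list(atoms = frag_atoms, attach_mapped = attach)
  })
}

#' Derive the typed reaction-center label of a reaction
#'
#' Diffs the mapped product and reactant graphs. A single product bond with
#' no reactant counterpart whose endpoints lie in two different reactant
#' components is a bond-formation (BF) center, together with the neighboring
#' product bonds whose reactant order differs; a single bond present on both
#' sides with a changed order is a bond-change (BC) center carrying the
#' original reactant order; no bond edits but exactly one mapped atom bearing
#' unmapped reactant fragments is an atom (A) center. Per-atom charge-change
#' classes (accept one electron, donate one electron, no change) are derived
#' from the formal-charge difference. Anything else is UNCOVERED.
#'
#' @param rec a \code{reaction_record}.
#' @return A \code{center_label} with fields \code{kind} (\code{"BF"},
#'   \code{"BC"}, \code{"A"} or \code{"UNCOVERED"}), \code{atoms} (product
#'   atom indices of the center), \code{bc_order}, \code{bf_changes} (data
#'   frame of neighbor bonds with their original orders) and \code{charges}.
#' @export
label_center <- function(rec) {
  p <- rec$product; r <- rec$reactants
  uncovered <- structure(list(kind = "UNCOVERED", atoms = integer(0),
                              bc_order = NA_integer_,
                              bf_changes = NULL, charges = NULL),
                         class = "center_label")
  pm <- p$atoms$map
  if (any(pm == 0L)) return(uncovered)  # unmapped product atoms: no diff basis
  # reactant atoms whose map number never occurs in the product are leaving
  # atoms regardless of their map label
  r$atoms$map[!(r$atoms$map %in% pm)] <- 0L
  pb <- mapped_bond_table(p)
  rb <- mapped_bond_table(r)
  pk <- paste(pb$lo, pb$hi); rk <- paste(rb$lo, rb$hi)
  new_idx <- which(!(pk %in% rk))
  lost <- setdiff(rk, pk)       # reactant bond between mapped atoms lost
  common <- intersect(pk, rk)
  ord_p <- pb$order[match(common, pk)]
  ord_r <- rb$order[match(common, rk)]
  changed <- common[ord_p != ord_r]
  frags <- leaving_fragments(r)
  if (any(vapply(frags, function(f) length(f$attach_mapped) != 1L, logical(1)))) {
    return(uncovered)  # bridging or dangling leaving groups
  }
  pidx_of_map <- function(mapno) match(mapno, pm)
  frag_attach_maps <- vapply(frags, function(f) r$atoms$map[f$attach_mapped],
                             integer(1))

  # charge comparison on mapped atoms
  rmatch <- match(pm, r$atoms$map)
  dq <- r$atoms$charge[rmatch] - p$atoms$charge
  if (any(abs(dq) > 1L)) return(uncovered)
  charged <- which(dq != 0L)

  finish <- function(kind, atoms, bc_order = NA_integer_, bf_changes = NULL) {
    involved <- sort(unique(c(atoms,
                              if (!is.null(bf_changes)) c(bf_changes$i, bf_changes$j))))
    if (!all(charged %in% involved)) return(uncovered)
    charges <- data.frame(atom = involved,
                          class = ifelse(dq[involved] == -1L, 1L,
                                  ifelse(dq[involved] == 1L, 2L, 3L)))
    structure(list(kind = kind, atoms = atoms, bc_order = bc_order,
                   bf_changes = bf_changes, charges = charges),
              class = "center_label")
  }

  if (length(lost)) return(uncovered)  # mapped skeleton bond disappears
  if (length(new_idx) == 1L) {
    lo <- pb$lo[new_idx]; hi <- pb$hi[new_idx]
    i <- pidx_of_map(lo); j <- pidx_of_map(hi)
    rcomp <- mg_components(r)
    ri <- rmatch[i]; rj <- rmatch[j]
    if (rcomp[ri] == rcomp[rj]) return(uncovered)  # intramolecular closure
    # all changed bonds must neighbor the center
    if (length(changed)) {
      ends <- do.call(rbind, strsplit(changed, " "))
      touches <- apply(ends, 1L, function(e) any(as.integer(e) %in% c(lo, hi)))
      if (!all(touches)) return(uncovered)
      co_p <- ord_p[match(changed, common)]
      co_r <- ord_r[match(changed, common)]
      if (any(co_p > 3L) || any(co_r > 3L)) return(uncovered)
      bf_changes <- data.frame(
        i = vapply(seq_along(changed), function(k)
          pidx_of_map(as.integer(ends[k, 1L])), integer(1)),
        j = vapply(seq_along(changed), function(k)
          pidx_of_map(as.integer(ends[k, 2L])), integer(1)),
        order_react = co_r)
    } else bf_changes <- NULL
    # leaving groups may only hang off the two center atoms
    if (length(frags) &&
        !all(frag_attach_maps %in% c(lo, hi))) return(uncovered)
    return(finish("BF", c(i, j), bf_changes = bf_changes))
  }
  if (length(new_idx) > 1L) return(uncovered)
  if (length(changed) == 1L) {
    if (length(frags)) return(uncovered)
    o_p <- ord_p[match(changed, common)]
    o_r <- ord_r[match(changed, common)]
    if (o_p > 3L || o_r > 3L) return(uncovered)
    ends <- as.integer(strsplit(changed, " ")[[1]])
    return(finish("BC", c(pidx_of_map(ends[1]), pidx_of_map(ends[2])),
                  bc_order = o_r))
  }
  if (length(changed) > 1L) return(uncovered)
  if (length(frags)) {
    at <- unique(frag_attach_maps)
    if (length(at) != 1L) return(uncovered)
    return(finish("A", pidx_of_map(at)))
  }
  uncovered
}

#' Transform a product into its synthons
#'
#' Applies the product-to-synthon edit of a center label: BF deletes the
#' center bond and restores changed neighbor-bond orders, BC sets the center
#' bond to its original reactant order, and A leaves the graph unchanged
#' (the synthon is the product itself). Charge-change classes are applied.
#' Hydrogen counts are reduced where restored orders consume valence; open
#' valence at the center atoms is left unfilled until completion.
#'
#' @param product product \code{mol_graph}.
#' @param label a \code{center_label} with \code{kind != "UNCOVERED"}.
#' @return list with \code{graph} (the synthon graph, possibly two
#'   components) and \code{frontier} (center atom indices open for
#'   attachment).
#' @export
apply_p2s <- function(product, label) {
  if (label$kind == "UNCOVERED") {
    rs_error("cannot apply product-to-synthon edit of an UNCOVERED label",
             "rs_label_error")
  }
  g <- product
  if (any(label$atoms > nrow(g$atoms))) {
    rs_error("center label references atoms absent from the product",
             "rs_label_error")
  }
  bump <- function(g, i, j, new_order) {
    k <- mg_find_bond(g, i, j)
    if (k == 0L) rs_error("center label references a bond absent from the product",
                          "rs_label_error")
    old <- g$bonds$order[k]
    g$bonds$order[k] <- new_order
    d_old <- if (old == 4L) 1.5 else old
    d_new <- if (new_order == 4L) 1.5 else new_order
    inc <- ceiling(d_new - d_old)
    if (inc > 0L) {
      for (a in c(i, j)) g$atoms$nH[a] <- max(0L, g$atoms$nH[a] - inc)
    }
    g
  }
  if (label$kind == "BF") {
    k <- mg_find_bond(g, label$atoms[1], label$atoms[2])
    if (k == 0L) rs_error("BF center bond absent from the product",
                          "rs_label_error")
    g$bonds <- g$bonds[-k, , drop = FALSE]
    ch <- label$bf_changes
    if (!is.null(ch)) {
      for (r in seq_len(nrow(ch))) {
        g <- bump(g, ch$i[r], ch$j[r], ch$order_react[r])
      }
    }
  } else if (label$kind == "BC") {
    g <- bump(g, label$atoms[1], label$atoms[2], label$bc_order)
  }
  if (!is.null(label$charges)) {
    for (r in seq_len(nrow(label$charges))) {
      a <- label$charges$atom[r]
      cl <- label$charges$class[r]
      if (cl == 1L) g$atoms$charge[a] <- g$atoms$charge[a] - 1L
      if (cl == 2L) g$atoms$charge[a] <- g$atoms$charge[a] + 1L
      if (cl != 3L) {
        used <- mg_bond_order_sum(g)[a]
        cap <- rs_valence(g$atoms$element[a], g$atoms$charge[a])
        g$atoms$nH[a] <- max(0L, min(g$atoms$nH[a], as.integer(cap - used)))
      }
    }
  }
  g <- mg_annotate(g)
  list(graph = g, frontier = label$atoms)
}

#' Fraction of records covered by the typed center definition
#'
#' @param labels list of \code{center_label}s (or a list of records, which
#'   are labeled first).
#' @return fraction with \code{kind != "UNCOVERED"}.
#' @export
coverage <- function(labels) {
  if (length(labels) == 0L) return(NA_real_)
  if (inherits(labels[[1]], "reaction_record")) {
    labels <- lapply(labels, label_center)
  }
  mean(vapply(labels, function(l) l$kind != "UNCOVERED", logical(1)))
}
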