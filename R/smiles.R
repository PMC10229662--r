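# SMILES input/output with atom-map support. The parser covers the subset
# used in atom-mapped reaction datasets: organic-subset and bracket atoms,
# charges, explicit hydrogen counts, atom maps, aromatic lower-case forms,
# branches, ring closures (including %nn) and dot-separated components.
# Stereo descriptors are accepted and ignored (graphs here are 2D).
# Canonical equality checks are delegated to Open Babel via ChemmineOB.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles SMILES string, possibly multi-component (dot-separated) and
#'   atom-mapped (\code{[CH3:1]}).
#' @return A \code{\link{mol_graph}}. Atom-map numbers are preserved in the
#'   \code{map} column; implicit hydrogens are filled from standard valences
#'   for organic-subset atoms and taken literally for bracket atoms.
#' @export
parse_smiles <- function(smiles) {
  s <- gsub("[[:space:]]", "", smiles)
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "")[[1]]
  atoms <- list()
  bonds <- list()
  h_explicit <- logical(0)
  prev <- NA_integer_       # previous atom index
  pend <- NA_integer_       # pending bond order
  branch <- integer(0)      # branch stack of atom indices
  ring_open <- list()       # digit -> list(atom, order)
  pos <- 1L
  npos <- length(chars)

  add_atom <- function(element, aromatic, charge, nH, map, explicitH) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, nH = nH, map = map)
    h_explicit[length(atoms)] <<- explicitH
    idx <- length(atoms)
    if (!is.na(prev)) {
      o <- pend
      if (is.na(o)) o <- if (aromatic && atoms[[prev]]$aromatic) 4L else 1L
      bonds[[length(bonds) + 1L]] <<- c(min(prev, idx), max(prev, idx), o)
    }
    prev <<- idx
    pend <<- NA_integer_
    invisible(idx)
  }

  close_ring <- function(key) {
    info <- ring_open[[key]]
    a <- info$atom
    o <- pend
    if (is.na(o)) o <- info$order
    if (is.na(o)) o <- if (atoms[[a]]$aromatic && atoms[[prev]]$aromatic) 4L else 1L
    if (a == prev) stop("ring closure to self in SMILES: ", smiles)
    bonds[[length(bonds) + 1L]] <<- c(min(a, prev), max(a, prev), o)
    ring_open[[key]] <<- NULL
    pend <<- NA_integer_
  }

  while (pos <= npos) {
    ch <- chars[pos]
    if (ch == "[") {
      end <- pos
      while (end <= npos && chars[end] != "]") end <- end + 1L
      if (end > npos) stop("unterminated bracket atom in SMILES: ", smiles)
      body <- paste(chars[(pos + 1L):(end - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2}|@TH[12])?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:([0-9]+))?$",
        body))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", body, "] in: ", smiles)
      sym <- m[3]
      aromatic <- sym %in% c("c", "n", "o", "s", "p", "b", "se", "as")
      element <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      hspec <- m[5]
      nH <- if (!nzchar(hspec)) 0L else if (hspec == "H") 1L else
        as.integer(substring(hspec, 2))
      cspec <- m[6]
      charge <- if (!nzchar(cspec)) 0L
        else if (grepl("^[+-]+$", cspec)) {
          sum(ifelse(strsplit(cspec, "")[[1]] == "+", 1L, -1L))
        } else {
          sgn <- if (substr(cspec, 1, 1) == "+") 1L else -1L
          sgn * as.integer(substring(cspec, 2))
        }
      map <- if (nzchar(m[8])) as.integer(m[8]) else 0L
      add_atom(element, aromatic, charge, nH, map, TRUE)
      pos <- end + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "F", "I", "B")) {
      two <- if (pos < npos) paste0(ch, chars[pos + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, 0L, FALSE)
        pos <- pos + 2L
      } else {
        add_atom(ch, FALSE, 0L, NA_integer_, 0L, FALSE)
        pos <- pos + 1L
      }
    } else if (ch %in% c("c", "n", "o", "s", "p", "b")) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, FALSE)
      pos <- pos + 1L
    } else if (ch == "-") { pend <- 1L; pos <- pos + 1L
    } else if (ch == "=") { pend <- 2L; pos <- pos + 1L
    } else if (ch == "#") { pend <- 3L; pos <- pos + 1L
    } else if (ch == ":") { pend <- 4L; pos <- pos + 1L
    } else if (ch %in% c("/", "\\")) { pend <- 1L; pos <- pos + 1L
    } else if (ch == "(") {
      branch <- c(branch, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(branch)) stop("unbalanced parentheses in SMILES: ", smiles)
      prev <- branch[length(branch)]
      branch <- branch[-length(branch)]
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pend <- NA_integer_; pos <- pos + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        key <- paste(chars[(pos + 1L):(pos + 2L)], collapse = "")
        pos <- pos + 3L
      } else {
        key <- ch
        pos <- pos + 1L
      }
      if (is.na(prev)) stop("ring closure before any atom in SMILES: ", smiles)
      if (!is.null(ring_open[[key]])) close_ring(key) else {
        ring_open[[key]] <- list(atom = prev, order = pend)
        pend <- NA_integer_
      }
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
  }
  if (length(branch)) stop("unbalanced parentheses in SMILES: ", smiles)
  if (length(ring_open)) stop("unclosed ring bond in SMILES: ", smiles)
  if (!length(atoms)) stop("no atoms in SMILES: ", smiles)

  at <- data.frame(element = vapply(atoms, `[[`, "", "element"),
                   charge = vapply(atoms, `[[`, 0L, "charge"),
                   nH = vapply(atoms, `[[`, NA_integer_, "nH"),
                   aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
                   map = vapply(atoms, `[[`, 0L, "map"))
  bd <- if (length(bonds)) {
    as.data.frame(do.call(rbind, bonds)) |> stats::setNames(c("i", "j", "order"))
  } else NULL
  if (!is.null(bd) && anyDuplicated(bd[, c("i", "j")])) {
    stop("duplicate bond in SMILES: ", smiles)
  }
  g <- mol_graph(at, bd)
  g <- mg_fill_h(g, which_atoms = which(!h_explicit))
  rs_check_valence(g, smiles)
  g
}

# Maximum plausible valence, used only for sanitization.
rs_max_valence <- function(element, charge) {
  base <- rs_valence(element, charge)
  extra <- c(S = 6, P = 5, N = 4)[element]
  pmax(base, ifelse(is.na(extra), base, extra + charge))
}

rs_check_valence <- function(g, smiles = "", atoms = NULL) {
  used <- mg_total_valence(g)
  cap <- rs_max_valence(g$atoms$element, g$atoms$charge)
  bad <- which(used > cap)
  if (!is.null(atoms)) bad <- intersect(bad, atoms)
  if (length(bad)) {
    stop(sprintf("valence of atom %d (%s, used %d > allowed %d) in: %s",
                 bad[1L], g$atoms$element[bad[1L]], used[bad[1L]],
                 cap[bad[1L]], smiles))
  }
  invisible(g)
}

#' Write a molecular graph as SMILES
#'
#' @param g a \code{\link{mol_graph}}.
#' @param include_maps write atom-map numbers for atoms with \code{map > 0}.
#' @param order optional atom visiting priority (lower first) controlling the
#'   traversal; defaults to index order. Used to make fragment keys
#'   deterministic.
#' @return A SMILES string (dot-joined for disconnected graphs).
#' @export
write_smiles <- function(g, include_maps = TRUE, order = NULL) {
  n <- nrow(g$atoms)
  if (n == 0L) stop("cannot write SMILES of an empty graph")
  if (is.null(order)) order <- seq_len(n)
  adj <- mg_adj(g)
  # would-be implicit H count, to decide whether a bracket is needed
  used <- mg_bond_order_sum(g)
  val <- rs_valence(g$atoms$element, g$atoms$charge)
  implied <- pmax(0L, as.integer(val - used))

  visited <- rep(FALSE, n)
  ring_num <- 0L
  ring_lab <- rep(list(NULL), n)  # per-atom list of (digit, bond order, nbr)
  tree_child <- rep(list(integer(0)), n)
  tree_parent <- rep(NA_integer_, n)
  closed_pairs <- character(0)

  dfs_order <- function(a) {
    visited[a] <<- TRUE
    nb <- adj[[a]]
    if (nrow(nb)) {
      for (b in nb$nbr[order(order[nb$nbr])]) {
        if (!visited[b]) {
          tree_child[[a]] <<- c(tree_child[[a]], b)
          tree_parent[b] <<- a
          dfs_order(b)
        }
      }
    }
  }

  bond_sym <- function(o, ai, aj) {
    if (o == 2L) "=" else if (o == 3L) "#"
    else if (o == 1L && g$atoms$aromatic[ai] && g$atoms$aromatic[aj]) "-"
    else ""
  }

  atom_str <- function(a) {
    el <- g$atoms$element[a]
    arom <- g$atoms$aromatic[a]
    sym <- if (arom) tolower(el) else el
    mp <- if (include_maps) g$atoms$map[a] else 0L
    need_bracket <- g$atoms$charge[a] != 0L || mp > 0L ||
      !(el %in% ORGANIC_SUBSET) || g$atoms$nH[a] != implied[a] ||
      (arom && el == "N" && g$atoms$nH[a] > 0L)
    if (!need_bracket) return(sym)
    h <- g$atoms$nH[a]
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    q <- g$atoms$charge[a]
    qstr <- if (q == 0L) "" else if (q == 1L) "+" else if (q == -1L) "-"
      else sprintf("%+d", q)
    mstr <- if (mp > 0L) paste0(":", mp) else ""
    paste0("[", sym, hstr, qstr, mstr, "]")
  }

  emit <- function(a) {
    out <- atom_str(a)
    for (rl in ring_lab[[a]]) {
      sym <- bond_sym(rl$order, a, rl$nbr)
      dig <- if (rl$digit < 10L) as.character(rl$digit) else sprintf("%%%d", rl$digit)
      out <- paste0(out, sym, dig)
    }
    kids <- tree_child[[a]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        b <- kids[k]
        o <- adj[[a]]$order[adj[[a]]$nbr == b]
        piece <- paste0(bond_sym(o[1L], a, b), emit(b))
        if (k < length(kids)) piece <- paste0("(", piece, ")")
        out <- paste0(out, piece)
      }
    }
    out
  }

  parts <- character(0)
  roots <- seq_len(n)[order(order)]
  for (root in roots) {
    if (visited[root]) next
    dfs_order(root)
    # assign ring closure digits for non-tree edges inside this component
    for (k in seq_len(nrow(g$bonds))) {
      bi <- g$bonds$i[k]; bj <- g$bonds$j[k]
      if (!visited[bi] || !visited[bj]) next
      pr <- paste(bi, bj)
      if (pr %in% closed_pairs) next
      if (identical(tree_parent[bj], bi) || identical(tree_parent[bi], bj)) {
        closed_pairs <- c(closed_pairs, pr)
        next
      }
      closed_pairs <- c(closed_pairs, pr)
      ring_num <- ring_num + 1L
      o <- g$bonds$order[k]
      ring_lab[[bi]] <- c(ring_lab[[bi]],
                          list(list(digit = ring_num, order = o, nbr = bj)))
      ring_lab[[bj]] <- c(ring_lab[[bj]],
                          list(list(digit = ring_num, order = o, nbr = bi)))
    }
    parts <- c(parts, emit(root))
  }
  paste(parts, collapse = ".")
}

# Cache for Open Babel canonicalization (the beam search deduplicates
# candidates repeatedly on identical strings).
.canon_cache <- new.env(parent = emptyenv())

#' Canonical SMILES via Open Babel
#'
#' Atom maps are stripped, each component is canonicalized, and components
#' are sorted so that reactant-set comparison ignores component order.
#'
#' @param x a SMILES string or a \code{mol_graph}.
#' @return Canonical, dot-joined, component-sorted SMILES.
#' @export
canonical_smiles <- function(x) {
  s <- if (inherits(x, "mol_graph")) write_smiles(x, include_maps = FALSE) else x
  hit <- .canon_cache[[s]]
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", s),
    error = function(e) stop("canonicalization failed for: ", s)
  )
  out <- gsub("[[:space:]]", "", out)
  if (!nzchar(out)) stop("canonicalization produced empty output for: ", s)
  parts <- sort(strsplit(out, ".", fixed = TRUE)[[1]])
  res <- paste(parts, collapse = ".")
  assign(s, res, envir = .canon_cache)
  res
}
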