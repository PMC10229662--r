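# Synthetic reaction fixtures with known ground truth. Reactions are
# constructed in reverse: a small, chemically valid product is sampled from
# a curated scaffold pool, a center type is drawn from the configured mix,
# and the inverse edit is applied to build the reactant graph (splitting a
# bond and attaching leaving groups, raising or lowering a bond order, or
# appending a fragment at an atom). The generator and the labeler are
# independent code paths, so label closure is a meaningful test.

# Curated products: small molecules with amide/ester/ether/amine/aryl motifs
# so that sampled edits are guaranteed chemically valid.
FIXTURE_SCAFFOLDS <- c(
  "CC(=O)NC", "CC(=O)OC", "CCOC", "CCNC", "CCO", "CCS",
  "c1ccccc1C", "c1ccccc1CC", "c1ccccc1N", "CC(=O)c1ccccc1",
  "CC(C)O", "CCC#N", "c1ccncc1C", "CC(=O)NCC", "CCOC(C)=O", "NCCO"
)

default_leaving_pool <- function() {
  phenyl <- sub_ring(
    data.frame(element = rep("C", 6), charge = 0L, aromatic = TRUE),
    data.frame(i = 1:6, j = c(2:6, 1L), order = 4L))
  list(sub_bond(1L, "O"), sub_bond(1L, "Cl"), sub_bond(1L, "Br"),
       sub_bond(1L, "C"), sub_bond(1L, "N"), phenyl)
}

#' Specification for the synthetic reaction generator
#'
#' @param n number of reactions.
#' @param seed RNG seed; fixtures are byte-identical for a fixed seed.
#' @param mix named fractions over center kinds \code{BF}, \code{BC},
#'   \code{A}, \code{UNCOVERED}; must sum to 1. The default keeps 2.3
#'   percent of reactions outside the typed center definition, matching the
#'   share of multi-edit reactions in patent-derived benchmark data, with
#'   bond formation the dominant covered kind.
#' @param pool list of leaving-group \code{substructure}s.
#' @param p_attach probability that a freed BF valence carries a leaving
#'   group (rather than a hydrogen).
#' @param p_neighbor_change probability of an induced neighbor-bond change
#'   at a BF center.
#' @param p_charge probability of a charge-change edit at a BF center atom.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n = 50L, seed = 1L,
                         mix = c(BF = 0.557, BC = 0.12, A = 0.30,
                                 UNCOVERED = 0.023),
                         pool = default_leaving_pool(),
                         p_attach = 0.7, p_neighbor_change = 0.12,
                         p_charge = 0.08) {
  stopifnot(n >= 1L, abs(sum(mix) - 1) < 1e-8,
            all(names(mix) %in% c("BF", "BC", "A", "UNCOVERED")))
  structure(list(n = as.integer(n), seed = as.integer(seed), mix = mix,
                 pool = pool, p_attach = p_attach,
                 p_neighbor_change = p_neighbor_change, p_charge = p_charge),
            class = "fixture_spec")
}

# Attach a leaving substructure on the reactant side and return the graph.
fx_attach <- function(g, anchor, sub) {
  attach_substructure(g, anchor, sub)$graph
}

# Candidate non-ring, non-aromatic bonds of a product.
fx_breakable_bonds <- function(g) {
  which(!g$bonds$in_ring & g$bonds$order <= 3L)
}

# Build one reaction of the requested kind on the given product, or NULL if
# the scaffold does not support it.
fx_make <- function(product, kind, spec) {
  g <- product
  nb <- nrow(g$bonds)
  pool <- spec$pool
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  if (kind == "BF") {
    cand <- fx_breakable_bonds(g)
    if (!length(cand)) return(NULL)
    k <- pick(cand)
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    r <- g
    r$bonds <- r$bonds[-k, , drop = FALSE]
    r <- mg_annotate(r)
    intended_changes <- NULL
    # optional induced neighbor change: a single-order neighbor bond whose
    # endpoints both carry a hydrogen becomes a double bond in the reactants
    if (stats::runif(1) < spec$p_neighbor_change) {
      nbrs <- bf_neighbor_bonds(g, k)
      ok <- nbrs[vapply(nbrs, function(m) {
        g$bonds$order[m] == 1L && !g$bonds$in_ring[m] &&
          g$atoms$nH[g$bonds$i[m]] >= 1L && g$atoms$nH[g$bonds$j[m]] >= 1L
      }, logical(1))]
      if (length(ok)) {
        m <- pick(ok)
        km <- mg_find_bond(r, g$bonds$i[m], g$bonds$j[m])
        r$bonds$order[km] <- 2L
        for (a2 in c(g$bonds$i[m], g$bonds$j[m])) {
          r$atoms$nH[a2] <- max(0L, r$atoms$nH[a2] - 1L)
        }
        intended_changes <- data.frame(i = g$bonds$i[m], j = g$bonds$j[m],
                                       order_react = 2L)
      }
    }
    charges <- NULL
    attached <- logical(2)
    for (side in 1:2) {
      a <- c(i, j)[side]
      if (stats::runif(1) < spec$p_attach) {
        ok <- vapply(pool, function(s) {
          lk <- if (s$kind == "bond") s$order else 1L
          mg_sigma_sum(r)[a] + mg_pi_contrib(r)[a] + lk <=
            rs_max_valence(r$atoms$element[a], r$atoms$charge[a])
        }, logical(1))
        if (any(ok)) {
          r <- fx_attach(r, a, pool[[pick(which(ok))]])
          attached[side] <- TRUE
        }
      }
    }
    # optional charge edit on a bare O (carboxylate-like) or N (ammonium)
    if (stats::runif(1) < spec$p_charge) {
      for (side in sample(1:2)) {
        a <- c(i, j)[side]
        if (attached[side]) next
        el <- r$atoms$element[a]
        if (el == "O") {
          r$atoms$charge[a] <- -1L
          charges <- data.frame(atom = a, class = 1L)
          break
        }
        if (el == "N") {
          r$atoms$charge[a] <- 1L
          charges <- data.frame(atom = a, class = 2L)
          break
        }
      }
    }
    touch <- unique(c(i, j,
                      if (!is.null(intended_changes))
                        c(intended_changes$i, intended_changes$j)))
    r <- finalize_hydrogens(r, atoms = touch)
    label <- structure(list(kind = "BF", atoms = c(i, j),
                            bc_order = NA_integer_,
                            bf_changes = intended_changes, charges = charges),
                       class = "center_label")
    return(list(reactants = r, label = label))
  }
  if (kind == "BC") {
    cand <- fx_breakable_bonds(g)
    if (!length(cand)) return(NULL)
    opts <- list()
    for (k in cand) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      o <- g$bonds$order[k]
      if (o < 3L && g$atoms$nH[i] >= 1L && g$atoms$nH[j] >= 1L) {
        opts[[length(opts) + 1L]] <- c(k, o + 1L)  # reactant order higher
      }
      if (o > 1L) {
        opts[[length(opts) + 1L]] <- c(k, o - 1L)  # reactant order lower
      }
    }
    if (!length(opts)) return(NULL)
    ch <- opts[[pick(seq_along(opts))]]
    k <- ch[1L]; new_o <- ch[2L]
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    r <- g
    r$bonds$order[k] <- new_o
    r <- mg_annotate(r)
    r <- finalize_hydrogens(r, atoms = c(i, j))
    label <- structure(list(kind = "BC", atoms = c(i, j), bc_order = new_o,
                            bf_changes = NULL, charges = NULL),
                       class = "center_label")
    return(list(reactants = r, label = label))
  }
  if (kind == "A") {
    r <- g
    ok_atoms <- which(vapply(seq_len(nrow(g$atoms)), function(a) {
      any(vapply(pool, function(s) {
        lk <- if (s$kind == "bond") s$order else 1L
        g$atoms$nH[a] >= lk
      }, logical(1)))
    }, logical(1)))
    if (!length(ok_atoms)) return(NULL)
    a <- pick(ok_atoms)
    ok <- which(vapply(pool, function(s) {
      lk <- if (s$kind == "bond") s$order else 1L
      g$atoms$nH[a] >= lk
    }, logical(1)))
    sub <- pool[[pick(ok)]]
    # a plain methyl fragment on an O/N/C is the classic protecting-group case
    r <- fx_attach(r, a, sub)
    label <- structure(list(kind = "A", atoms = a, bc_order = NA_integer_,
                            bf_changes = NULL, charges = NULL),
                       class = "center_label")
    return(list(reactants = r, label = label))
  }
  # UNCOVERED: two independent bond splits (multiple new bonds)
  cand <- fx_breakable_bonds(g)
  if (length(cand) < 2L) return(NULL)
  ks <- sample(cand, 2L)
  i1 <- g$bonds$i[ks[1]]; j1 <- g$bonds$j[ks[1]]
  i2 <- g$bonds$i[ks[2]]; j2 <- g$bonds$j[ks[2]]
  r <- g
  r$bonds <- r$bonds[-ks, , drop = FALSE]
  r <- mg_annotate(r)
  r <- finalize_hydrogens(r, atoms = c(i1, j1, i2, j2))
  label <- structure(list(kind = "UNCOVERED", atoms = integer(0),
                          bc_order = NA_integer_, bf_changes = NULL,
                          charges = NULL), class = "center_label")
  list(reactants = r, label = label)
}

# Randomly decorate a scaffold with 0-2 small substituents so that sampled
# products are diverse (distinct products can then carry distinct centers).
fx_decorate <- function(g) {
  n_dec <- sample(0:2, 1L)
  decs <- c("C", "O", "Cl", "F")
  for (d in seq_len(n_dec)) {
    ok <- which(g$atoms$nH >= 1L & g$atoms$element %in% c("C", "N"))
    if (!length(ok)) break
    a <- if (length(ok) == 1L) ok else sample(ok, 1L)
    g <- tryCatch(
      attach_substructure(g, a, sub_bond(1L, sample(decs, 1L)))$graph,
      rs_error = function(e) g)
  }
  g
}

#' Generate synthetic atom-mapped reactions with known labels
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list of items, each with \code{record} (a
#'   \code{reaction_record}), \code{intended} (the generator's
#'   \code{center_label}) and \code{smiles}; deterministic for a fixed seed.
#' @export
generate_fixtures <- function(spec) {
  set.seed(spec$seed)
  kinds <- names(spec$mix)
  out <- vector("list", spec$n)
  for (r in seq_len(spec$n)) {
    kind <- sample(kinds, 1L, prob = as.numeric(spec$mix))
    made <- NULL
    for (try in 1:25) {
      smi <- sample(FIXTURE_SCAFFOLDS, 1L)
      product <- parse_smiles(smi)
      product <- fx_decorate(product)
      product$atoms$map <- seq_len(nrow(product$atoms))
      made <- fx_make(product, kind, spec)
      if (!is.null(made)) break
    }
    if (is.null(made)) {
      rs_error(paste0("could not realize a ", kind, " fixture"),
               "rs_fixture_error")
    }
    rxn <- paste0(write_smiles(made$reactants), ">>", write_smiles(product))
    rec <- parse_reaction(rxn, reaction_class = sample.int(10L, 1L))
    # the reparsed product orders atoms by SMILES traversal; express the
    # intended label in the record's indices via the map numbers (the
    # generator assigns map k to its k-th atom)
    remap <- function(idx) match(idx, rec$product$atoms$map)
    lab <- made$label
    lab$atoms <- remap(lab$atoms)
    if (!is.null(lab$bf_changes)) {
      lab$bf_changes$i <- remap(lab$bf_changes$i)
      lab$bf_changes$j <- remap(lab$bf_changes$j)
    }
    if (!is.null(lab$charges)) lab$charges$atom <- remap(lab$charges$atom)
    out[[r]] <- list(record = rec, intended = lab, smiles = rxn,
                     kind = kind)
  }
  out
}

#' Keep only fixtures with distinct products
#'
#' Two reactions with the same product but different centers make the
#' product-to-center mapping ambiguous; recovery experiments use fixture
#' sets filtered to unique products.
#'
#' @param fixtures output of \code{\link{generate_fixtures}}.
#' @return the subset with first occurrence of each canonical product.
#' @export
unique_product_fixtures <- function(fixtures) {
  keys <- vapply(fixtures, function(fx)
    canonical_smiles(fx$record$product), character(1))
  fixtures[!duplicated(keys)]
}

#' Check generator/labeler closure on a fixture set
#'
#' @param fixtures output of \code{\link{generate_fixtures}}.
#' @return fraction of fixtures whose independent label matches the
#'   generator's intent (kind, location and edit).
#' @export
fixture_label_agreement <- function(fixtures) {
  mean(vapply(fixtures, function(fx) {
    lab <- label_center(fx$record)
    if (fx$intended$kind == "UNCOVERED") return(lab$kind == "UNCOVERED")
    same_center(lab, fx$intended, fx$record$product)
  }, logical(1)))
}

#' Read reactions from a USPTO-style CSV file
#'
#' Expects columns for a reaction id, an optional class label (1..10) and an
#' atom-mapped reaction SMILES (the column containing \code{">>"} is
#' auto-detected when not named \code{rxn_smiles} or
#' \code{reactants>reagents>production}). Malformed rows are skipped and
#' counted.
#'
#' @param path CSV file path.
#' @return list of \code{reaction_record}s with attributes \code{n_rows} and
#'   \code{n_skipped}.
#' @export
read_uspto_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  smi_col <- NULL
  for (nm in c("rxn_smiles", "reactants>reagents>production", "smiles")) {
    if (nm %in% names(df)) { smi_col <- nm; break }
  }
  if (is.null(smi_col)) {
    has_rxn <- vapply(df, function(col)
      is.character(col) && any(grepl(">", col, fixed = TRUE)), logical(1))
    if (!any(has_rxn)) {
      rs_error("no reaction-SMILES column found", "rs_io_error")
    }
    smi_col <- names(df)[which(has_rxn)[1L]]
  }
  class_col <- intersect(c("class", "reaction_class"), names(df))[1]
  out <- list()
  skipped <- 0L
  for (r in seq_len(nrow(df))) {
    cls <- if (!is.na(class_col)) {
      cl <- suppressWarnings(as.integer(df[[class_col]][r]))
      if (!is.na(cl) && cl >= 1L && cl <= 10L) cl else NULL
    } else NULL
    rec <- tryCatch(parse_reaction(df[[smi_col]][r], reaction_class = cls),
                    error = function(e) NULL)
    if (is.null(rec)) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- rec
  }
  attr(out, "n_rows") <- nrow(df)
  attr(out, "n_skipped") <- skipped
  out
}

#' Write reaction records to a USPTO-style CSV file
#'
#' @param items list of \code{reaction_record}s or fixture items.
#' @param path output path.
#' @export
write_uspto_csv <- function(items, path) {
  rows <- lapply(seq_along(items), function(k) {
    it <- items[[k]]
    rec <- if (inherits(it, "reaction_record")) it else it$record
    data.frame(id = sprintf("RX%05d", k),
               class = if (is.null(rec$reaction_class)) NA_integer_ else
                 rec$reaction_class,
               rxn_smiles = rec$smiles)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean number of reactant components per record
#' @param records list of \code{reaction_record}s.
#' @export
mean_reactant_count <- function(records) {
  mean(vapply(records, function(rec) max(mg_components(rec$reactants)),
              integer(1)))
}
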