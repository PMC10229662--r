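# End-to-end inference: top-K reaction-center selection, greedy beam search
# over completion paths scored by summed log-likelihoods, and ranked top-N
# candidate reactant sets.

#' Log-likelihood of a sequence of decision probabilities
#'
#' @param probs numeric vector of probabilities in (0, 1]; a zero yields
#'   \code{-Inf} (the candidate is pruned).
#' @return sum of logs.
#' @export
score_path <- function(probs) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(probs == 0)) return(-Inf)
  sum(log(probs))
}

# Plain (value-only) encoding for inference.
encode_plain <- function(g, params, cfg, reaction_type = NULL) {
  tape <- ad_tape()
  pn <- param_nodes(tape, params)
  es <- encode_graph(tape, g, pn, cfg, reaction_type)
  list(atom = es$atom$val, graph = es$graph$val, bond = es$bond$val)
}

# Head evaluations on plain values.
aacp_prob_plain <- function(params, a_t, h_s, h_p) {
  x <- sum(a_t * params$Vo1) + sum(h_s * params$Vo2) + sum(h_p * params$Vo3)
  1 / (1 + exp(-x))
}

aatp_probs_plain <- function(params, a_t, h_s, h_p) {
  lg <- params$Vz1 %*% matrix(a_t) + params$Vz2 %*% matrix(h_s) +
    params$Vz3 %*% matrix(h_p)
  as.numeric(exp(logsoftmax_rows(t(lg))))
}

# Order in which center atoms seed the frontier stack (top of stack last;
# the lowest canonical rank is processed first).
initial_stack <- function(synthons, frontier) {
  frontier[order(mg_canon_rank(synthons)[frontier], decreasing = TRUE)]
}

# Shared greedy beam search over completion paths. `live` holds initial
# candidates (graph, es, h_s, stack, score, t, touched, center, id).
beam_complete <- function(live, params, cfg, rt, entries, keys, h_p, N,
                          max_steps) {
  done <- list()
  iter <- 0L
  next_id <- length(live)
  while (length(live)) {
    iter <- iter + 1L
    if (iter > 200L) break
    children <- list()
    for (cnd in live) {
      a <- cnd$stack[length(cnd$stack)]
      a_t <- cnd$es$atom[a, ]
      p_cont <- aacp_prob_plain(params, a_t, cnd$h_s, h_p)
      children[[length(children) + 1L]] <- list(
        parent = cnd, action = "stop",
        score = cnd$score + log(max(1 - p_cont, .Machine$double.xmin)))
      if (cnd$t < max_steps) {
        pz <- aatp_probs_plain(params, a_t, cnd$h_s, h_p)
        used <- mg_sigma_sum(cnd$graph)[a] + mg_pi_contrib(cnd$graph)[a]
        cap <- rs_max_valence(cnd$graph$atoms$element[a],
                              cnd$graph$atoms$charge[a])
        valid <- vapply(entries, function(e) {
          lk <- if (e$kind == "bond") e$order else 1L
          used + lk <= cap
        }, logical(1))
        if (any(valid)) {
          pv <- pz * valid
          pv <- pv / sum(pv)   # invalid attachments masked, renormalized
          top <- order(-pv)[seq_len(min(N, sum(valid)))]
          for (k in top) {
            if (pv[k] <= 0) next
            children[[length(children) + 1L]] <- list(
              parent = cnd, action = "attach", key = keys[k],
              score = cnd$score + log(p_cont) + log(pv[k]))
          }
        }
      }
    }
    if (!length(children)) break
    sc <- vapply(children, `[[`, 0, "score")
    children <- children[order(-sc)]
    if (length(done) >= N) {
      thr <- sort(vapply(done, `[[`, 0, "score"), decreasing = TRUE)[N]
      children <- Filter(function(ch) ch$score > thr, children)
    }
    children <- utils::head(children, N)
    new_live <- list()
    for (ch in children) {
      if (ch$action == "stop") {
        st <- ch$parent$stack
        st <- st[-length(st)]
        if (!length(st)) {
          done[[length(done) + 1L]] <- list(
            graph = ch$parent$graph, score = ch$score,
            center = ch$parent$center, touched = ch$parent$touched)
        } else {
          cnd <- ch$parent
          cnd$stack <- st
          cnd$score <- ch$score
          next_id <- next_id + 1L; cnd$id <- next_id
          new_live[[length(new_live) + 1L]] <- cnd
        }
      } else {
        cnd <- ch$parent
        a <- cnd$stack[length(cnd$stack)]
        res <- tryCatch(
          attach_substructure(cnd$graph, a, entries[[ch$key]]),
          rs_error = function(e) NULL)
        if (is.null(res)) next
        cnd$graph <- res$graph
        cnd$es <- encode_plain(res$graph, params, cfg, rt)
        cnd$stack <- c(cnd$stack, rev(res$new_atoms))
        cnd$score <- ch$score
        cnd$t <- cnd$t + 1L
        cnd$touched <- c(cnd$touched, a, res$new_atoms)
        next_id <- next_id + 1L; cnd$id <- next_id
        new_live[[length(new_live) + 1L]] <- cnd
      }
    }
    live <- new_live
    if (length(done) >= N) {
      thr <- sort(vapply(done, `[[`, 0, "score"), decreasing = TRUE)[N]
      live <- Filter(function(cnd) cnd$score > thr, live)
    }
  }

  if (!length(done)) return(empty_prediction())
  rows <- lapply(done, function(dn) {
    g <- finalize_hydrogens(dn$graph, atoms = unique(dn$touched))
    data.frame(reactants = canonical_smiles(g), loglik = dn$score,
               center = describe_center(dn$center))
  })
  df <- do.call(rbind, rows)
  labels <- lapply(done, `[[`, "center")
  # deduplicate identical reactant sets keeping the best score; ties broken
  # by canonical SMILES so ranking is reproducible
  ord <- order(-df$loglik, df$reactants)
  df <- df[ord, , drop = FALSE]
  labels <- labels[ord]
  keep <- !duplicated(df$reactants)
  df <- df[keep, , drop = FALSE]
  labels <- labels[keep]
  df <- utils::head(df, N)
  labels <- utils::head(labels, N)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df[, c("rank", "reactants", "loglik", "center")],
            labels = labels, class = c("prediction_result", "data.frame"))
}

#' Predict ranked reactant sets for a product
#'
#' Selects the top-K reaction centers, converts the product into synthons for
#' each, and completes the synthons with a greedy beam search: at each step
#' every live candidate spawns at most N+1 children (a stop at the current
#' frontier atom plus the top-N substructure attachments), the top-N scored
#' children survive, and search continues until N completed reactant graphs
#' exist and no incomplete candidate outscores the N-th completed one. Each
#' candidate's score is the sum of the log-likelihoods of every decision on
#' its path, initialized with the log-likelihoods of the center selection
#' and its induced-change predictions. Duplicate completed reactant sets
#' keep their best score.
#'
#' @param cmodel trained \code{center_model}.
#' @param smodel trained \code{synthon_model}.
#' @param product product \code{mol_graph} (or SMILES string).
#' @param K center beam width.
#' @param N reactant beam width / result list length.
#' @param reaction_type optional reaction class 1..10.
#' @param max_steps attachment-step cap per candidate.
#' @return A \code{prediction_result}: data.frame with columns \code{rank},
#'   \code{reactants} (canonical SMILES), \code{loglik}, \code{center}
#'   (description), with the selected \code{center_label}s as an attribute.
#' @export
predict_reactants <- function(cmodel, smodel, product, K = 10L, N = 10L,
                              reaction_type = NULL, max_steps = 30L) {
  stopifnot(K >= 1L, N >= 1L)
  if (is.character(product)) product <- parse_smiles(product)
  centers <- select_top_centers(cmodel, product, K, reaction_type)
  rt <- if (isTRUE(smodel$reaction_type_known)) reaction_type else NULL
  params <- smodel$params
  cfg <- smodel$cfg
  keys <- names(smodel$vocab$entries)
  entries <- smodel$vocab$entries
  h_p <- encode_plain(product, params, cfg, rt)$graph

  live <- list()
  made <- 0L
  for (cd in centers) {
    init <- tryCatch(apply_p2s(product, cd$label), rs_error = function(e) NULL)
    if (is.null(init)) next
    es <- encode_plain(init$graph, params, cfg, rt)
    made <- made + 1L
    live[[length(live) + 1L]] <- list(
      graph = init$graph, es = es, h_s = es$graph,
      stack = initial_stack(init$graph, init$frontier),
      score = cd$loglik + cd$loglik_aux, t = 0L,
      touched = init$frontier, center = cd$label, id = made)
  }
  if (!length(live)) {
    warning("no admissible reaction center for this product")
    return(empty_prediction())
  }
  beam_complete(live, params, cfg, rt, entries, keys, h_p, N, max_steps)
}

empty_prediction <- function() {
  structure(data.frame(rank = integer(), reactants = character(),
                       loglik = numeric(), center = character()),
            labels = list(), class = c("prediction_result", "data.frame"))
}

#' Short description of a center label
#' @param label a \code{center_label}.
#' @export
describe_center <- function(label) {
  if (label$kind == "A") {
    sprintf("A(%d)", label$atoms[1])
  } else if (label$kind == "BC") {
    sprintf("BC(%d-%d<-%d)", label$atoms[1], label$atoms[2], label$bc_order)
  } else if (label$kind == "BF") {
    sprintf("BF(%d-%d)", label$atoms[1], label$atoms[2])
  } else label$kind
}
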