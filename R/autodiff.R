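# Minimal tape-based reverse-mode automatic differentiation on dense matrices.
# All model forward passes (encoder and prediction heads) are built from these
# primitives; gradients are obtained by a single reverse sweep over the tape.

#' Create a fresh autodiff tape
#'
#' A tape records every node created during a forward pass in topological
#' order, so that \code{\link{ad_backward}} can run a single reverse sweep.
#'
#' @return An environment holding the node list.
#' @keywords internal
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

ad_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

new_ad_node <- function(tape, val, parents = NULL, backfn = NULL,
                        requires_grad = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$requires_grad <- requires_grad
  ad_push(tape, nd)
}

ad_accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Constant (non-differentiated) node
#' @keywords internal
ad_const <- function(tape, x) {
  new_ad_node(tape, as.matrix(x), requires_grad = FALSE)
}

#' Parameter node (gradient collected)
#' @keywords internal
ad_param <- function(tape, x) {
  new_ad_node(tape, as.matrix(x), requires_grad = TRUE)
}

#' Matrix product of two nodes
#' @keywords internal
ad_matmul <- function(tape, a, b) {
  new_ad_node(tape, a$val %*% b$val, parents = list(a, b),
              backfn = function(nd) {
                g <- nd$grad
                ad_accum(a, g %*% t(b$val))
                ad_accum(b, crossprod(a$val, g))
              })
}

#' Elementwise sum of equal-shaped nodes
#' @keywords internal
ad_add <- function(tape, a, b) {
  new_ad_node(tape, a$val + b$val, parents = list(a, b),
              backfn = function(nd) {
                ad_accum(a, nd$grad)
                ad_accum(b, nd$grad)
              })
}

#' Add a 1 x k row-vector node to every row of an n x k node
#' @keywords internal
ad_add_rowvec <- function(tape, a, v) {
  stopifnot(nrow(v$val) == 1L, ncol(a$val) == ncol(v$val))
  n <- nrow(a$val)
  new_ad_node(tape, a$val + matrix(v$val, n, ncol(a$val), byrow = TRUE),
              parents = list(a, v),
              backfn = function(nd) {
                ad_accum(a, nd$grad)
                ad_accum(v, matrix(colSums(nd$grad), 1L))
              })
}

#' Elementwise difference
#' @keywords internal
ad_sub <- function(tape, a, b) {
  new_ad_node(tape, a$val - b$val, parents = list(a, b),
              backfn = function(nd) {
                ad_accum(a, nd$grad)
                ad_accum(b, -nd$grad)
              })
}

#' Elementwise absolute value
#' @keywords internal
ad_abs <- function(tape, a) {
  new_ad_node(tape, abs(a$val), parents = list(a),
              backfn = function(nd) ad_accum(a, nd$grad * sign(a$val)))
}

#' Rectified linear activation
#' @keywords internal
ad_relu <- function(tape, a) {
  new_ad_node(tape, pmax(a$val, 0), parents = list(a),
              backfn = function(nd) ad_accum(a, nd$grad * (a$val > 0)))
}

#' Logistic sigmoid
#' @keywords internal
ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  new_ad_node(tape, s, parents = list(a),
              backfn = function(nd) ad_accum(a, nd$grad * s * (1 - s)))
}

#' Select rows of a node
#' @keywords internal
ad_rows <- function(tape, a, idx) {
  new_ad_node(tape, a$val[idx, , drop = FALSE], parents = list(a),
              backfn = function(nd) {
                g <- matrix(0, nrow(a$val), ncol(a$val))
                for (r in seq_along(idx)) {
                  g[idx[r], ] <- g[idx[r], ] + nd$grad[r, ]
                }
                ad_accum(a, g)
              })
}

#' Gather scattered entries of a node into a column vector
#' @keywords internal
ad_gather <- function(tape, a, rows, cols) {
  stopifnot(length(rows) == length(cols))
  idx <- cbind(rows, cols)
  new_ad_node(tape, matrix(a$val[idx], ncol = 1L), parents = list(a),
              backfn = function(nd) {
                g <- matrix(0, nrow(a$val), ncol(a$val))
                for (r in seq_len(nrow(idx))) {
                  g[idx[r, 1L], idx[r, 2L]] <- g[idx[r, 1L], idx[r, 2L]] + nd$grad[r, 1L]
                }
                ad_accum(a, g)
              })
}

#' Column-bind a list of nodes
#' @keywords internal
ad_hcat <- function(tape, lst) {
  widths <- vapply(lst, function(x) ncol(x$val), integer(1))
  new_ad_node(tape, do.call(cbind, lapply(lst, function(x) x$val)),
              parents = lst,
              backfn = function(nd) {
                off <- 0L
                for (k in seq_along(lst)) {
                  ad_accum(lst[[k]], nd$grad[, off + seq_len(widths[k]), drop = FALSE])
                  off <- off + widths[k]
                }
              })
}

#' Row-bind a list of nodes
#' @keywords internal
ad_vcat <- function(tape, lst) {
  heights <- vapply(lst, function(x) nrow(x$val), integer(1))
  new_ad_node(tape, do.call(rbind, lapply(lst, function(x) x$val)),
              parents = lst,
              backfn = function(nd) {
                off <- 0L
                for (k in seq_along(lst)) {
                  ad_accum(lst[[k]], nd$grad[off + seq_len(heights[k]), , drop = FALSE])
                  off <- off + heights[k]
                }
              })
}

#' Sum all rows into a single 1 x k row
#' @keywords internal
ad_colsum <- function(tape, a) {
  new_ad_node(tape, matrix(colSums(a$val), 1L), parents = list(a),
              backfn = function(nd) {
                ad_accum(a, matrix(nd$grad, nrow(a$val), ncol(a$val), byrow = TRUE))
              })
}

#' Sum of several scalar nodes
#' @keywords internal
ad_sum_scalars <- function(tape, lst) {
  new_ad_node(tape, matrix(sum(vapply(lst, function(x) x$val[1L], numeric(1)))),
              parents = lst,
              backfn = function(nd) {
                for (p in lst) ad_accum(p, nd$grad)
              })
}

#' Scale a node by a plain scalar
#' @keywords internal
ad_scale <- function(tape, a, s) {
  new_ad_node(tape, a$val * s, parents = list(a),
              backfn = function(nd) ad_accum(a, nd$grad * s))
}

# Numerically stable row-wise log-softmax.
logsoftmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  z <- x - m
  z - log(rowSums(exp(z)))
}

#' Row-wise cross-entropy of logits against integer targets
#'
#' Computes \code{-sum_r log softmax(logits[r, ])[target[r]]} as a scalar node.
#' @keywords internal
ad_ce_rows <- function(tape, logits, targets) {
  lp <- logsoftmax_rows(logits$val)
  n <- nrow(lp)
  stopifnot(length(targets) == n)
  loss <- -sum(lp[cbind(seq_len(n), targets)])
  new_ad_node(tape, matrix(loss), parents = list(logits),
              backfn = function(nd) {
                p <- exp(lp)
                p[cbind(seq_len(n), targets)] <- p[cbind(seq_len(n), targets)] - 1
                ad_accum(logits, nd$grad[1L] * p)
              })
}

#' Cross-entropy of a single score vector (column node) against one target
#' @keywords internal
ad_ce_vec <- function(tape, scores, target) {
  ad_ce_rows(tape, ad_transpose(tape, scores), target)
}

#' Transpose
#' @keywords internal
ad_transpose <- function(tape, a) {
  new_ad_node(tape, t(a$val), parents = list(a),
              backfn = function(nd) ad_accum(a, t(nd$grad)))
}

#' Binary cross-entropy on logits with 0/1 labels, summed over entries
#' @keywords internal
ad_bce_logits <- function(tape, logits, labels) {
  x <- logits$val
  # stable: log(1 + exp(-|x|)) + max(x, 0) - x * y
  loss <- sum(log1p(exp(-abs(x))) + pmax(x, 0) - x * labels)
  new_ad_node(tape, matrix(loss), parents = list(logits),
              backfn = function(nd) {
                p <- 1 / (1 + exp(-x))
                ad_accum(logits, nd$grad[1L] * (p - labels))
              })
}

#' Reverse sweep over the tape from a scalar node
#' @keywords internal
ad_backward <- function(tape, node) {
  stopifnot(length(node$val) == 1L)
  node$grad <- matrix(1)
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Adam optimizer over a named list of parameter matrices.

#' Create Adam optimizer state
#'
#' @param params named list of parameter matrices.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical floor.
#' @keywords internal
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

#' One Adam update
#'
#' @param params named list of matrices.
#' @param grads named list of gradient matrices (NULL entries are skipped).
#' @param state state from \code{adam_init}.
#' @return list(params, state).
#' @keywords internal
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}
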