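# Minimal reverse-mode automatic differentiation over matrices.
#
# Every op accepts either plain numeric matrices/vectors or `adnode` objects.
# With plain inputs an op just computes numerically, so the same forward code
# serves both inference (numbers in, numbers out) and training (leaves in,
# scalar loss node out, then ad_backward()). Nodes form a DAG ordered by a
# creation counter; backward walks reachable nodes in reverse creation order.
# Gradients are verified against finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

is_node <- function(x) inherits(x, "adnode")

#' Numeric value of an autodiff node (identity on plain numerics)
#' @param x An `adnode` or numeric.
#' @return The underlying numeric value.
#' @export
ad_value <- function(x) if (is_node(x)) x$value else x

new_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  e$id <- .ad$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  class(e) <- "adnode"
  e
}

#' Create an autodiff leaf (trainable parameter) node
#'
#' @param value Numeric matrix or vector.
#' @return An `adnode` whose `$grad` is populated by [ad_backward()].
#' @export
ad_leaf <- function(value) new_node(value)

accum_grad <- function(node, g) {
  if (is.null(node$grad)) {
    node$grad <- g
  } else {
    node$grad <- node$grad + g
  }
  invisible(NULL)
}

#' Backpropagate from a scalar node
#'
#' Seeds the root gradient with 1 and accumulates gradients into every
#' reachable node's `$grad` (leaves included) in reverse topological order.
#'
#' @param root An `adnode` holding a scalar value.
#' @return The root node, invisibly; every reachable node's `$grad` is filled.
#' @export
ad_backward <- function(root) {
  stopifnot(is_node(root), length(root$value) == 1)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  nodes <- list()
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  for (nd in nodes) nd$grad <- NULL
  root$grad <- 1
  for (k in ord) {
    nd <- nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    grads <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      if (!is.null(grads[[i]])) accum_grad(nd$parents[[i]], grads[[i]])
    }
  }
  invisible(root)
}

node_parents <- function(...) Filter(is_node, list(...))

# --- ops -------------------------------------------------------------------

ad_mm <- function(a, b) {
  va <- ad_value(a)
  vb <- ad_value(b)
  v <- va %*% vb
  if (!is_node(a) && !is_node(b)) return(v)
  new_node(v, node_parents(a, b), function(g) {
    out <- list()
    if (is_node(a)) out <- c(out, list(g %*% t(vb)))
    if (is_node(b)) out <- c(out, list(t(va) %*% g))
    out
  })
}

ad_add <- function(a, b) {
  va <- ad_value(a)
  vb <- ad_value(b)
  v <- va + vb
  if (!is_node(a) && !is_node(b)) return(v)
  shrink <- function(g, target) if (length(target) == 1) sum(g) else g
  new_node(v, node_parents(a, b), function(g) {
    out <- list()
    if (is_node(a)) out <- c(out, list(shrink(g, va)))
    if (is_node(b)) out <- c(out, list(shrink(g, vb)))
    out
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_scale <- function(a, s) {
  va <- ad_value(a)
  v <- va * s
  if (!is_node(a)) return(v)
  new_node(v, list(a), function(g) list(g * s))
}

ad_hadamard <- function(a, b) {
  va <- ad_value(a)
  vb <- ad_value(b)
  v <- va * vb
  if (!is_node(a) && !is_node(b)) return(v)
  new_node(v, node_parents(a, b), function(g) {
    out <- list()
    if (is_node(a)) out <- c(out, list(g * vb))
    if (is_node(b)) out <- c(out, list(g * va))
    out
  })
}

# add a length-d bias vector to every row of an n x d matrix
ad_add_bias <- function(a, b) {
  va <- ad_value(a)
  vb <- ad_value(b)
  v <- sweep(va, 2, vb, "+")
  if (!is_node(a) && !is_node(b)) return(v)
  new_node(v, node_parents(a, b), function(g) {
    out <- list()
    if (is_node(a)) out <- c(out, list(g))
    if (is_node(b)) out <- c(out, list(colSums(g)))
    out
  })
}

ad_relu <- function(a) {
  va <- ad_value(a)
  v <- pmax(va, 0)
  if (!is_node(a)) return(v)
  new_node(v, list(a), function(g) list(g * (va > 0)))
}

# row selection with duplicate indices allowed (embedding lookup / gather);
# backward scatter-adds
ad_rows <- function(a, idx) {
  va <- ad_value(a)
  v <- va[idx, , drop = FALSE]
  if (!is_node(a)) return(v)
  new_node(v, list(a), function(g) {
    gz <- matrix(0, nrow(va), ncol(va))
    rs <- rowsum(g, group = idx)
    gz[as.integer(rownames(rs)), ] <- rs
    list(gz)
  })
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_value)
  v <- do.call(cbind, vals)
  if (!any(vapply(args, is_node, logical(1)))) return(v)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_node(v, Filter(is_node, args), function(g) {
    out <- list()
    for (i in seq_along(args)) {
      if (is_node(args[[i]])) {
        out <- c(out, list(g[, starts[i]:ends[i], drop = FALSE]))
      }
    }
    out
  })
}

ad_rbind <- function(args) {
  vals <- lapply(args, ad_value)
  v <- do.call(rbind, vals)
  if (!any(vapply(args, is_node, logical(1)))) return(v)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  new_node(v, Filter(is_node, args), function(g) {
    out <- list()
    for (i in seq_along(args)) {
      if (is_node(args[[i]])) {
        out <- c(out, list(g[starts[i]:ends[i], , drop = FALSE]))
      }
    }
    out
  })
}

# column means of an n x d matrix -> 1 x d
ad_colmeans <- function(a) {
  va <- ad_value(a)
  v <- matrix(colMeans(va), 1)
  if (!is_node(a)) return(v)
  n <- nrow(va)
  new_node(v, list(a), function(g) {
    list(matrix(1 / n, n, 1) %*% g)
  })
}

ad_sum <- function(a) {
  va <- ad_value(a)
  v <- sum(va)
  if (!is_node(a)) return(v)
  new_node(v, list(a), function(g) list(array(g, dim = dim(va) %||% length(va))))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(ad_value(a)))

# numerically stable softplus log(1 + exp(x)), elementwise
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

ad_softplus <- function(a) {
  va <- ad_value(a)
  v <- softplus(va)
  if (!is_node(a)) return(v)
  new_node(v, list(a), function(g) list(g * stats::plogis(va)))
}

# rowwise dot product of two n x d matrices -> n x 1
ad_rowdot <- function(a, b) {
  va <- ad_value(a)
  vb <- ad_value(b)
  v <- matrix(rowSums(va * vb), ncol = 1)
  if (!is_node(a) && !is_node(b)) return(v)
  new_node(v, node_parents(a, b), function(g) {
    gv <- as.vector(g)
    out <- list()
    if (is_node(a)) out <- c(out, list(vb * gv))
    if (is_node(b)) out <- c(out, list(va * gv))
    out
  })
}

# fused mean cross-entropy of row-softmax against 1-based integer labels
ad_softmax_ce <- function(logits, labels) {
  vl <- ad_value(logits)
  n <- nrow(vl)
  mx <- apply(vl, 1, max)
  sh <- vl - mx
  lse <- log(rowSums(exp(sh)))
  logp <- sh - lse
  picked <- logp[cbind(seq_len(n), labels)]
  v <- -mean(picked)
  if (!is_node(logits)) return(v)
  P <- exp(logp)
  new_node(v, list(logits), function(g) {
    G <- P
    G[cbind(seq_len(n), labels)] <- G[cbind(seq_len(n), labels)] - 1
    list(G * (g / n))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- parameter-structure helpers -------------------------------------------

# params are nested named lists of numeric arrays; these helpers map the whole
# structure to/from leaves, flat vectors, and gradient structures

params_to_leaves <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, params_to_leaves)
    attributes(out) <- attributes(p)
    out
  } else {
    ad_leaf(p)
  }
}

leaves_grads <- function(lp) {
  if (is.list(lp)) {
    lapply(lp, leaves_grads)
  } else {
    g <- lp$grad
    if (is.null(g)) {
      v <- lp$value
      g <- if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else numeric(length(v))
    }
    g
  }
}

par_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, par_flatten), use.names = FALSE) else as.numeric(p)
}

par_unflatten <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(s) {
    if (is.list(s)) {
      out <- lapply(s, fill)
      attributes(out) <- attributes(s)
      out
    } else {
      n <- length(s)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(s)) dim(out) <- dim(s)
      out
    }
  }
  out <- fill(skeleton)
  stopifnot(pos == length(vec))
  out
}

par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(par_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

par_axpy <- function(a, b, alpha) par_map2(a, b, function(x, y) x + alpha * y)
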