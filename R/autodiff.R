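# Reverse-mode automatic differentiation on dense numeric arrays.
#
# Every backward rule is expressed in terms of the same graph operations, so
# gradients are themselves graph nodes and can be differentiated again.  The
# Wasserstein gradient penalty and the path-length regularizer both rely on
# this: their losses contain the norm of a gradient, and training needs the
# gradient of that norm with respect to the parameters.
#
# Nodes are immutable lists; a node's `vjp` is a function(self, g) returning
# one gradient node (or NULL) per parent.  Graphs stay small because feature
# maps are batched into single matrices, so the interpreter overhead is
# negligible next to the BLAS calls.

.ag_env <- new.env(parent = emptyenv())
.ag_env$id <- 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

ag_node <- function(value, parents = list(), vjp = NULL) {
  .ag_env$id <- .ag_env$id + 1L
  structure(list(id = .ag_env$id, value = value, parents = parents, vjp = vjp),
            class = "ag")
}

is_ag <- function(x) inherits(x, "ag")

#' @keywords internal
ag_const <- function(x) if (is_ag(x)) x else ag_node(x)

# A leaf that gradients are requested for; identical to a constant node but
# named for readability at call sites.
ag_leaf <- function(x) ag_node(x)

ag_value <- function(x) if (is_ag(x)) x$value else x

.ag_zeros_like <- function(x) {
  v <- x$value
  z <- array(0, dim = dim(v) %||% length(v))
  if (is.null(dim(v))) z <- as.numeric(z)
  ag_const(z)
}

# Reduce a gradient to a scalar when the forward input was scalar but was
# broadcast against an array.
.ag_fit <- function(g, ref_value) {
  if (length(ref_value) == 1L && length(ag_value(g)) > 1L) ag_sum(g) else g
}

# ---- arithmetic -------------------------------------------------------------

ag_add <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_node(a$value + b$value, list(a, b),
          function(self, g) list(.ag_fit(g, a$value), .ag_fit(g, b$value)))
}

ag_neg <- function(a) {
  a <- ag_const(a)
  ag_node(-a$value, list(a), function(self, g) list(ag_neg(g)))
}

ag_sub <- function(a, b) ag_add(a, ag_neg(b))

ag_mul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_node(a$value * b$value, list(a, b),
          function(self, g) list(.ag_fit(ag_mul(g, b), a$value),
                                 .ag_fit(ag_mul(g, a), b$value)))
}

ag_div <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  out <- ag_node(a$value / b$value, list(a, b), NULL)
  out$vjp <- function(self, g)
    list(.ag_fit(ag_div(g, b), a$value),
         .ag_fit(ag_neg(ag_div(ag_mul(g, self), b)), b$value))
  out
}

ag_sqrt <- function(a) {
  a <- ag_const(a)
  out <- ag_node(sqrt(a$value), list(a), NULL)
  out$vjp <- function(self, g) list(ag_div(ag_mul(g, 0.5), self))
  out
}

ag_tanh <- function(a) {
  a <- ag_const(a)
  out <- ag_node(tanh(a$value), list(a), NULL)
  out$vjp <- function(self, g)
    list(ag_mul(g, ag_sub(1, ag_mul(self, self))))
  out
}

# Leaky rectifier; the derivative mask is piecewise constant in the input, so
# treating it as data is exact almost everywhere (and at higher orders).
ag_leaky_relu <- function(a, slope = 0.2) {
  a <- ag_const(a)
  v <- a$value
  mask <- ifelse(v >= 0, 1, slope)
  out <- v * mask
  ag_node(out, list(a), function(self, g) list(ag_mul(g, ag_const(mask))))
}

# ---- linear algebra ---------------------------------------------------------

ag_t <- function(a) {
  a <- ag_const(a)
  ag_node(t(a$value), list(a), function(self, g) list(ag_t(g)))
}

ag_matmul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_node(a$value %*% b$value, list(a, b),
          function(self, g) list(ag_matmul(g, ag_t(b)), ag_matmul(ag_t(a), g)))
}

# ---- reductions and broadcasts ---------------------------------------------

ag_sum <- function(a) {
  a <- ag_const(a)
  dm <- dim(a$value) %||% length(a$value)
  ag_node(sum(a$value), list(a), function(self, g) list(ag_fill(g, dm)))
}

ag_mean <- function(a) ag_mul(ag_sum(a), 1 / length(ag_value(a)))

ag_fill <- function(s, dm) {
  s <- ag_const(s)
  ag_node(array(s$value, dim = dm), list(s), function(self, g) list(ag_sum(g)))
}

ag_rowsums <- function(a) {
  a <- ag_const(a)
  n <- ncol(a$value)
  ag_node(rowSums(a$value), list(a),
          function(self, g) list(ag_bcast_cols(g, n)))
}

ag_colsums <- function(a) {
  a <- ag_const(a)
  n <- nrow(a$value)
  ag_node(colSums(a$value), list(a),
          function(self, g) list(ag_bcast_rows(g, n)))
}

ag_bcast_cols <- function(v, n) {
  v <- ag_const(v)
  ag_node(matrix(v$value, length(v$value), n), list(v),
          function(self, g) list(ag_rowsums(g)))
}

ag_bcast_rows <- function(v, n) {
  v <- ag_const(v)
  ag_node(matrix(v$value, n, length(v$value), byrow = TRUE), list(v),
          function(self, g) list(ag_colsums(g)))
}

# Row-wise ops: `v` has one entry per matrix row (column-major recycling).
ag_add_rows <- function(x, v) {
  x <- ag_const(x); v <- ag_const(v)
  ag_node(x$value + v$value, list(x, v),
          function(self, g) list(g, ag_rowsums(g)))
}

ag_mul_rows <- function(x, v) {
  x <- ag_const(x); v <- ag_const(v)
  ag_node(x$value * v$value, list(x, v),
          function(self, g) list(ag_mul_rows(g, v),
                                 ag_rowsums(ag_mul(g, x))))
}

# Column-wise ops: `v` has one entry per matrix column.
ag_add_cols <- function(x, v) {
  x <- ag_const(x); v <- ag_const(v)
  ag_node(x$value + rep(v$value, each = nrow(x$value)), list(x, v),
          function(self, g) list(g, ag_colsums(g)))
}

ag_mul_cols <- function(x, v) {
  x <- ag_const(x); v <- ag_const(v)
  ag_node(x$value * rep(v$value, each = nrow(x$value)), list(x, v),
          function(self, g) list(ag_mul_cols(g, v),
                                 ag_colsums(ag_mul(g, x))))
}

# ---- structure --------------------------------------------------------------

ag_reshape <- function(a, dm) {
  a <- ag_const(a)
  old <- dim(a$value) %||% length(a$value)
  v <- a$value
  dim(v) <- dm
  ag_node(v, list(a), function(self, g) list(ag_reshape(g, old)))
}

ag_rows <- function(x, i) {
  x <- ag_const(x)
  n <- nrow(x$value)
  ag_node(x$value[i, , drop = FALSE], list(x),
          function(self, g) list(ag_scatter_rows(g, i, n)))
}

ag_scatter_rows <- function(g, i, n) {
  g <- ag_const(g)
  v <- matrix(0, n, ncol(g$value))
  v[i, ] <- g$value
  ag_node(v, list(g), function(self, gg) list(ag_rows(gg, i)))
}

ag_rbind <- function(xs) {
  xs <- lapply(xs, ag_const)
  nr <- vapply(xs, function(x) nrow(x$value), integer(1))
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ag_node(do.call(rbind, lapply(xs, `[[`, "value")), xs,
          function(self, g)
            lapply(seq_along(xs), function(j) ag_rows(g, starts[j]:ends[j])))
}

# ---- gather / scatter -------------------------------------------------------
#
# `map` objects (see gather_map) carry precomputed index vectors; index 0
# denotes an out-of-bounds (zero-padded) source position.  The scatter uses a
# duplicate-free partition of the indices so accumulation is a handful of
# vectorized adds, never a hash join.

gather_map <- function(idx, in_len, in_dim, out_dim) {
  take <- which(idx > 0L)
  src <- idx[take]
  groups <- list()
  if (length(src)) {
    o <- order(src)
    so <- src[o]
    occ <- integer(length(so))
    occ[o] <- sequence(rle(so)$lengths)
    for (k in seq_len(max(occ))) {
      sel <- occ == k
      groups[[k]] <- list(take = take[sel], src = src[sel])
    }
  }
  list(take = take, src = src, groups = groups,
       in_len = in_len, in_dim = in_dim, out_dim = out_dim)
}

ag_gather <- function(x, map) {
  x <- ag_const(x)
  v <- numeric(prod(map$out_dim))
  v[map$take] <- x$value[map$src]
  dim(v) <- map$out_dim
  ag_node(v, list(x), function(self, g) list(ag_scatter(g, map)))
}

ag_scatter <- function(g, map) {
  g <- ag_const(g)
  v <- numeric(map$in_len)
  gv <- as.numeric(g$value)
  for (grp in map$groups)
    v[grp$src] <- v[grp$src] + gv[grp$take]
  dim(v) <- map$in_dim
  ag_node(v, list(g), function(self, gg) list(ag_gather(gg, map)))
}

# ---- backward pass ----------------------------------------------------------

#' Gradients of a scalar graph output
#'
#' Traverses the graph in reverse topological order and accumulates
#' vector-Jacobian products.  The returned gradients are themselves graph
#' nodes, so they can enter further differentiable expressions
#' (double backpropagation).
#'
#' @param out scalar output node.
#' @param wrt a node or list of nodes to differentiate with respect to.
#' @return a list of gradient nodes aligned with `wrt` (or a single node if
#'   `wrt` was a single node).
#' @keywords internal
ag_grad <- function(out, wrt) {
  single <- is_ag(wrt)
  if (single) wrt <- list(wrt)
  stopifnot(is_ag(out), length(ag_value(out)) == 1L)

  # Topological order, parents before children.  Nodes are held only in
  # environments: assigning graph nodes into preallocated lists with `[[<-`
  # can trigger pathological deep duplication in R (see .res2net_node).
  topo <- new.env(parent = emptyenv())    # "1", "2", ... -> node
  snode <- new.env(parent = emptyenv())   # stack depth -> node
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  si <- integer(1)                        # per-depth parent cursor
  depth <- 1L
  snode[["1"]] <- out
  si[1] <- 0L
  assign(as.character(out$id), TRUE, envir = seen)
  while (depth > 0L) {
    nd <- snode[[as.character(depth)]]
    ps <- nd$parents
    if (si[depth] < length(ps)) {
      si[depth] <- si[depth] + 1L
      p <- ps[[si[depth]]]
      key <- as.character(p$id)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        depth <- depth + 1L
        snode[[as.character(depth)]] <- p
        si[depth] <- 0L
      }
    } else {
      ntopo <- ntopo + 1L
      topo[[as.character(ntopo)]] <- nd
      depth <- depth - 1L
    }
  }

  # Only nodes whose ancestry contains a target need gradients.
  needs <- new.env(parent = emptyenv())
  for (w in wrt) assign(as.character(w$id), TRUE, envir = needs)
  for (k in seq_len(ntopo)) {
    nd <- topo[[as.character(k)]]
    key <- as.character(nd$id)
    if (!exists(key, envir = needs, inherits = FALSE)) {
      for (p in nd$parents) {
        if (exists(as.character(p$id), envir = needs, inherits = FALSE)) {
          assign(key, TRUE, envir = needs)
          break
        }
      }
    }
  }

  grads <- new.env(parent = emptyenv())
  assign(as.character(out$id), ag_const(1), envir = grads)
  for (k in seq(ntopo, 1L)) {
    nd <- topo[[as.character(k)]]
    if (is.null(nd$vjp)) next
    key <- as.character(nd$id)
    if (!exists(key, envir = needs, inherits = FALSE)) next
    g <- get0(key, envir = grads, inherits = FALSE)
    if (is.null(g)) next
    pg <- nd$vjp(nd, g)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      pkey <- as.character(p$id)
      if (!exists(pkey, envir = needs, inherits = FALSE)) next
      gj <- pg[[j]]
      if (is.null(gj)) next
      cur <- get0(pkey, envir = grads, inherits = FALSE)
      assign(pkey, if (is.null(cur)) gj else ag_add(cur, gj), envir = grads)
    }
  }

  res <- lapply(wrt, function(w)
    get0(as.character(w$id), envir = grads, inherits = FALSE) %||%
      .ag_zeros_like(w))
  if (single) res[[1]] else res
}
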