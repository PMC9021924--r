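# Independent reference implementations used as oracles.  These are written
# as literal nested loops over the defining equations, deliberately sharing
# no code with the package internals.

# Direct 3x3 same-padding convolution on a (C, H, W) array.
naive_conv3 <- function(x, W_mat, b) {
  d <- dim(x); C <- d[1]; H <- d[2]; Wd <- d[3]
  Cout <- nrow(W_mat)
  out <- array(0, c(Cout, H, Wd))
  for (co in seq_len(Cout)) {
    for (h in seq_len(H)) for (w in seq_len(Wd)) {
      acc <- b[co]
      for (kh in 1:3) for (kw in 1:3) {
        ih <- h + kh - 2L; iw <- w + kw - 2L
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= Wd) {
          for (ci in seq_len(C)) {
            wcol <- ci + C * ((kh - 1L) + 3L * (kw - 1L))
            acc <- acc + W_mat[co, wcol] * x[ci, ih, iw]
          }
        }
      }
      out[co, h, w] <- acc
    }
  }
  out
}

# Literal evaluation of the Res2Net recursion: split into s groups,
# y1 = x1, y2 = K2(x2), yi = Ki(xi + y_{i-1}), concatenate, 1x1 fuse.
naive_res2net <- function(x, params, s) {
  d <- dim(x); C <- d[1]
  cs <- C / s
  splits <- lapply(seq_len(s), function(i)
    x[((i - 1) * cs + 1):(i * cs), , , drop = FALSE])
  ys <- list(splits[[1]])
  for (i in 2:s) {
    inp <- if (i == 2) splits[[2]] else {
      splits[[i]] + ys[[i - 1]]
    }
    ys <- c(ys, list(naive_conv3(inp, params$K[[i - 1]]$W,
                                 params$K[[i - 1]]$b)))
  }
  cat_y <- array(0, d)
  for (i in seq_len(s))
    cat_y[((i - 1) * cs + 1):(i * cs), , ] <- ys[[i]]
  out <- array(0, c(nrow(params$fuse$W), d[2], d[3]))
  for (h in seq_len(d[2])) for (w in seq_len(d[3]))
    out[, h, w] <- params$fuse$W %*% cat_y[, h, w] + params$fuse$b
  out
}

# Identity 3x3 kernel matrix (center tap 1) for cs channels.
identity_kernel3 <- function(cs) {
  W <- matrix(0, cs, cs * 9)
  for (c in seq_len(cs)) {
    # kernel position kh = 2, kw = 2 (center): column c + cs*((2-1) + 3*(2-1))
    W[c, c + cs * 4] <- 1
  }
  W
}

# Exhaustive best-assignment matcher for tiny detection instances: the
# maximum number of one-to-one prediction/ground-truth pairs with
# IoU >= threshold.
brute_force_max_tp <- function(gt, pred, thr) {
  ng <- length(gt); np <- length(pred)
  if (ng == 0L || np == 0L) return(0L)
  best <- 0L
  assign_rec <- function(p, used, count) {
    if (p > np) {
      best <<- max(best, count)
      return()
    }
    assign_rec(p + 1L, used, count)           # prediction p unmatched
    for (g in seq_len(ng)) {
      if (!used[g] && iou(pred[[p]], gt[[g]]) >= thr) {
        used[g] <- TRUE
        assign_rec(p + 1L, used, count + 1L)
        used[g] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, ng), 0L)
  best
}
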