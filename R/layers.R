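# Neural layers on the canonical feature layout.
#
# A batch of feature maps is one matrix of dimension (C, H*W*N): channels are
# rows; columns enumerate spatial position fastest (height, then width), then
# sample.  Convolutions become one gather (im2col) plus one BLAS matmul, and
# the convolution output lands directly in the same layout, so no transposes
# are ever needed.

.map_cache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  m <- get0(key, envir = .map_cache, inherits = FALSE)
  if (is.null(m)) {
    m <- build()
    assign(key, m, envir = .map_cache)
  }
  m
}

# Linear index of element (c, h, w, n) in the canonical layout.
.lin_index <- function(c, h, w, n, C, H, W) {
  c + C * ((h - 1) + H * ((w - 1) + W * (n - 1)))
}

# im2col gather map: output is a (C*k*k, OH*OW*N) matrix of input patches,
# with zero padding expressed as index 0.
im2col_map <- function(H, W, C, N, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  key <- paste("i2c", H, W, C, N, k, stride, pad, sep = "_")
  .cached(key, function() {
    OH <- (H + 2L * pad - k) %/% stride + 1L
    OW <- (W + 2L * pad - k) %/% stride + 1L
    rg <- expand.grid(c = seq_len(C), kh = seq_len(k), kw = seq_len(k))
    cg <- expand.grid(oh = seq_len(OH), ow = seq_len(OW), n = seq_len(N))
    R <- nrow(rg)
    Cn <- nrow(cg)
    ih <- outer(rg$kh, (cg$oh - 1L) * stride, `+`) - pad
    iw <- outer(rg$kw, (cg$ow - 1L) * stride, `+`) - pad
    valid <- ih >= 1L & ih <= H & iw >= 1L & iw <= W
    idx <- rg$c + C * ((ih - 1L) + H * ((iw - 1L) +
             W * rep(cg$n - 1L, each = R)))
    idx[!valid] <- 0L
    m <- gather_map(as.integer(idx), in_len = C * H * W * N,
                    in_dim = c(C, H * W * N),
                    out_dim = c(R, Cn))
    m$OH <- OH; m$OW <- OW
    m
  })
}

#' 2-D convolution on the canonical layout
#'
#' @param x node or matrix (C, H*W*N).
#' @param W_mat weight node or matrix (C_out, C*k*k); columns ordered channel
#'   fastest, then kernel row, then kernel column.
#' @param b bias node or vector of length C_out.
#' @keywords internal
ag_conv2d <- function(x, W_mat, b, H, W, C, N, k, stride = 1L,
                      pad = (k - 1L) %/% 2L) {
  map <- im2col_map(H, W, C, N, k, stride, pad)
  cols <- ag_gather(x, map)
  out <- ag_matmul(W_mat, cols)
  ag_add_rows(out, b)
}

conv_out_size <- function(H, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  (H + 2L * pad - k) %/% stride + 1L
}

# Nearest-neighbor 2x upsampling as a gather.
upsample2_map <- function(H, W, C, N) {
  key <- paste("up2", H, W, C, N, sep = "_")
  .cached(key, function() {
    OH <- 2L * H; OW <- 2L * W
    cg <- expand.grid(c = seq_len(C), oh = seq_len(OH), ow = seq_len(OW),
                      n = seq_len(N))
    idx <- .lin_index(cg$c, (cg$oh + 1L) %/% 2L, (cg$ow + 1L) %/% 2L, cg$n,
                      C, H, W)
    gather_map(as.integer(idx), in_len = C * H * W * N,
               in_dim = c(C, H * W * N),
               out_dim = c(C, OH * OW * N))
  })
}

ag_upsample2 <- function(x, H, W, C, N) ag_gather(x, upsample2_map(H, W, C, N))

# Block-indicator pooling matrix (H*W*N x N): matmul with it sums each
# sample's spatial positions, giving per-(channel, sample) reductions.
pool_mat <- function(HW, N) {
  key <- paste("pool", HW, N, sep = "_")
  .cached(key, function() kronecker(diag(N), matrix(1, HW, 1)))
}

# Per-(channel, sample) mean of a (C, HW*N) feature matrix -> (C, N).
ag_sample_mean <- function(x, HW, N) {
  ag_mul(ag_matmul(x, ag_const(pool_mat(HW, N))), 1 / HW)
}

# Broadcast a (C, N) per-sample statistic back over spatial positions.
ag_sample_bcast <- function(s, HW, N) {
  ag_matmul(s, ag_const(t(pool_mat(HW, N))))
}

# Per-sample Euclidean norms of the columns of a (D, N) matrix -> (1, N).
ag_col_norms <- function(x, eps = 0) {
  sq <- ag_mul(x, x)
  ss <- ag_matmul(ag_const(matrix(1, 1, nrow(ag_value(x)))), sq)
  if (eps > 0) ss <- ag_add(ss, eps)
  ag_sqrt(ss)
}

# Dense layer: W (out, in) %*% x (in, N) + b.
ag_dense <- function(x, W_mat, b) ag_add_rows(ag_matmul(W_mat, x), b)

# ---- layout helpers (plain values) -----------------------------------------

# Convert an array (C, H, W) or (C, H, W, N) to the canonical matrix and back.
to_canon <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) d <- c(d, 1L)
  stopifnot(length(d) == 4L)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  # (C,H,W,N) array is already in canonical element order.
  m <- x
  dim(m) <- c(C, H * W * N)
  attr(m, "hwn") <- c(H, W, N)
  m
}

from_canon <- function(m, H, W, N = NULL, drop = TRUE) {
  C <- nrow(m)
  if (is.null(N)) N <- ncol(m) / (H * W)
  a <- as.numeric(m)
  dim(a) <- c(C, H, W, N)
  if (drop && N == 1L) {
    dim(a) <- c(C, H, W)
  }
  a
}

# Gaussian weight init used throughout (common GAN practice).
init_mat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)
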