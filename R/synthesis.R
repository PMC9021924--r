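# Style-modulated synthesis network.
#
# The generator starts from a learned constant 4x4 block and doubles the
# resolution per stage up to the target.  Each stage applies
# convolution -> noise injection -> leaky rectifier -> AdaIN twice, then a
# Res2Net multi-scale block; stages are joined by nearest-neighbor 2x
# upsampling whose following 3x3 convolution is the next stage's first
# convolution.  A final 1x1 convolution maps to 3 channels and a hyperbolic
# tangent places pixels in [-1, 1].

#' Channel schedule of the synthesis / critic networks
#'
#' Channels per resolution: `min(channels_max, channels_base / resolution)`,
#' floored to a multiple of the Res2Net scale `s` (and at least `s`) so every
#' stage can host a Res2Net block.
#'
#' @param resolutions integer vector of stage resolutions.
#' @param channels_max,channels_base schedule parameters.
#' @param s Res2Net scale (split count).
#' @return integer vector of channel counts.
#' @export
channel_schedule <- function(resolutions, channels_max = 128L,
                             channels_base = 2048L, s = 4L) {
  raw <- pmin(channels_max, channels_base / resolutions)
  ch <- pmax(as.integer(raw %/% s) * s, s)
  as.integer(ch)
}

#' Generator configuration
#'
#' @param resolution target resolution, a power of two in `[8, 512]`.
#' @param L latent dimensionality.
#' @param s Res2Net scale.
#' @param channels_max,channels_base channel schedule parameters.
#' @param noise whether per-layer noise injection is enabled.
#' @param slope leaky rectifier slope.
#' @param eps AdaIN variance floor.
#' @return a list of class `fg_genconfig`.
#' @export
generator_config <- function(resolution = 32L, L = 512L, s = 4L,
                             channels_max = 128L, channels_base = 2048L,
                             noise = TRUE, slope = 0.2, eps = 1e-8) {
  resolution <- as.integer(resolution)
  if (resolution < 8L || resolution > 512L ||
      bitwAnd(resolution, resolution - 1L) != 0L)
    stop("resolution must be a power of two in [8, 512]")
  if (s < 2L) stop("res2net scale s must be >= 2")
  resolutions <- as.integer(2^(2:as.integer(log2(resolution))))
  channels <- channel_schedule(resolutions, channels_max, channels_base, s)
  structure(list(resolution = resolution, L = as.integer(L), s = as.integer(s),
                 resolutions = resolutions, channels = channels,
                 noise = noise, slope = slope, eps = eps),
            class = "fg_genconfig")
}

.conv_init <- function(cin, cout, k) {
  list(W = init_mat(cout, cin * k * k), b = numeric(cout))
}

#' Initialize Res2Net block parameters
#'
#' `s - 1` 3x3 convolutions on the channel splits (the first split is passed
#' through untouched) plus a 1x1 fusion convolution over the re-concatenated
#' splits.
#'
#' @param C channel count (must be divisible by `s`).
#' @param s split count.
#' @param seed optional seed.
#' @return list with elements `K` (length `s - 1`) and `fuse`.
#' @export
res2net_init <- function(C, s = 4L, seed = NULL) {
  if (C %% s != 0L) stop("channel count must be divisible by s")
  cs <- C %/% s
  draw <- function() list(
    K = lapply(seq_len(s - 1L), function(i) .conv_init(cs, cs, 3L)),
    fuse = list(W = init_mat(C, C), b = numeric(C)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Initialize the synthesis network
#'
#' @param config an `fg_genconfig` (or arguments for [generator_config()]).
#' @param seed optional seed for reproducible initialization.
#' @return object of class `fg_generator`.
#' @export
generator_init <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "fg_genconfig"))
  L <- config$L
  draw <- function() {
    stages <- vector("list", length(config$resolutions))
    for (t in seq_along(config$resolutions)) {
      C <- config$channels[t]
      Cin <- if (t == 1L) C else config$channels[t - 1L]
      stages[[t]] <- list(
        convA = .conv_init(Cin, C, 3L),
        noiseA = matrix(0, C, 1),          # learned per-channel noise scale
        affineA = list(Ws = init_mat(C, L), bs = rep(1, C),
                       Wb = init_mat(C, L), bb = numeric(C)),
        convB = .conv_init(C, C, 3L),
        noiseB = matrix(0, C, 1),
        affineB = list(Ws = init_mat(C, L), bs = rep(1, C),
                       Wb = init_mat(C, L), bb = numeric(C)),
        res2net = res2net_init(C, config$s))
    }
    list(const = matrix(rnorm(config$channels[1] * 16), config$channels[1], 16),
         stages = stages,
         to_rgb = list(W = init_mat(3L, config$channels[length(config$channels)]),
                       b = numeric(3L)))
  }
  pars <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(c(pars, list(config = config)), class = "fg_generator")
}

#' Number of style inputs of a generator
#'
#' Two AdaIN style inputs per resolution stage.
#' @param generator an `fg_generator` or `fg_genconfig`.
#' @export
n_style_layers <- function(generator) {
  cfg <- if (inherits(generator, "fg_generator")) generator$config else generator
  2L * length(cfg$resolutions)
}

# ---- core operations (graph mode) ------------------------------------------

.adain_node <- function(x, ys, yb, HW, N, eps) {
  mu <- ag_sample_mean(x, HW, N)
  xc <- ag_sub(x, ag_sample_bcast(mu, HW, N))
  v <- ag_sample_mean(ag_mul(xc, xc), HW, N)
  sdv <- ag_sqrt(ag_add(v, eps))
  xn <- ag_div(xc, ag_sample_bcast(sdv, HW, N))
  ag_add(ag_mul(xn, ag_sample_bcast(ys, HW, N)),
         ag_sample_bcast(yb, HW, N))
}

.noise_node <- function(x, B, noise) {
  # B: (C,1) node; noise: (1, HW*N) constant; single channel broadcast.
  ag_add(x, ag_matmul(B, ag_const(noise)))
}

# NB: the split outputs are accumulated with c(), never assigned into a
# preallocated list: `[[<-` on a list holding ancestors of the assigned node
# triggers pathological deep duplication in R and makes stacked blocks
# exponentially slow.
.res2net_node <- function(x, pars, s, H, W, N) {
  C <- nrow(ag_value(x))
  cs <- C %/% s
  ys <- list(ag_rows(x, seq_len(cs)))
  prev <- NULL
  for (i in 2:s) {
    xi <- ag_rows(x, ((i - 1L) * cs + 1L):(i * cs))
    inp <- if (i == 2L) xi else ag_add(xi, prev)
    ki <- pars$K[[i - 1L]]
    prev <- ag_conv2d(inp, ag_const(ki$W), ag_const(ki$b), H, W, cs, N, 3L)
    ys <- c(ys, list(prev))
  }
  ag_dense(ag_rbind(ys), ag_const(pars$fuse$W), ag_const(pars$fuse$b))
}

# Graph-mode res2net with externally supplied parameter nodes (training).
.res2net_node_p <- function(x, pn, s, H, W, N) {
  C <- nrow(ag_value(x))
  cs <- C %/% s
  ys <- list(ag_rows(x, seq_len(cs)))
  prev <- NULL
  for (i in 2:s) {
    xi <- ag_rows(x, ((i - 1L) * cs + 1L):(i * cs))
    inp <- if (i == 2L) xi else ag_add(xi, prev)
    ki <- pn$K[[i - 1L]]
    prev <- ag_conv2d(inp, ki$W, ki$b, H, W, cs, N, 3L)
    ys <- c(ys, list(prev))
  }
  ag_dense(ag_rbind(ys), pn$fuse$W, pn$fuse$b)
}

# ---- public single-shot operations -----------------------------------------

.as_feature <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("feature map must be a (C, H, W) or (C, H, W, N) array")
  x
}

#' Adaptive instance normalization
#'
#' Normalizes each channel of a feature map to zero mean and unit variance
#' over its spatial extent, then applies the style scale `ys` and bias `yb`:
#' `ys[c] * (x[c] - mean) / sqrt(var + eps) + yb[c]`.  The variance is the
#' population variance over the channel's pixels.
#'
#' @param x feature map array `(C, H, W)` (or `(C, H, W, N)`, normalized per
#'   sample).
#' @param ys,yb numeric style vectors of length `C`.
#' @param eps variance floor.
#' @return array of the same shape.
#' @export
adain <- function(x, ys, yb, eps = 1e-8) {
  x <- .as_feature(x)
  if (eps <= 0) stop("eps must be positive")
  d <- dim(x); C <- d[1]
  if (length(ys) != C || length(yb) != C)
    stop("style vector length must equal channel count")
  N <- if (length(d) == 4L) d[4] else 1L
  HW <- d[2] * d[3]
  m <- to_canon(x)
  ysn <- ag_const(matrix(ys, C, N))
  ybn <- ag_const(matrix(yb, C, N))
  out <- ag_value(.adain_node(ag_const(m), ysn, ybn, HW, N, eps))
  from_canon(out, d[2], d[3], N, drop = length(d) == 3L)
}

#' Per-layer noise injection
#'
#' Adds a single-channel Gaussian noise image, scaled per channel by `B`, to
#' every channel of the feature map: `out[c] = x[c] + B[c] * noise`.
#'
#' @param x feature map array `(C, H, W)`.
#' @param noise matrix `(H, W)` (one channel, shared across feature channels).
#' @param B numeric vector of per-channel scales, length `C`.
#' @return array of the same shape as `x`.
#' @export
inject_noise <- function(x, noise, B) {
  x <- .as_feature(x)
  d <- dim(x)
  if (length(d) != 3L) stop("inject_noise expects a single (C, H, W) map")
  if (!all(dim(noise) == d[2:3])) stop("noise spatial size mismatch")
  if (length(B) != d[1]) stop("B length must equal channel count")
  m <- to_canon(x)
  nv <- matrix(as.numeric(noise), 1L)
  out <- ag_value(.noise_node(ag_const(m), ag_const(matrix(B, ncol = 1)), nv))
  from_canon(out, d[2], d[3], 1L)
}

#' Res2Net multi-scale block
#'
#' Splits the input uniformly into `s` channel groups `x_1..x_s`; the first
#' passes through unchanged, `y_2 = K_2(x_2)`, and each later group is summed
#' with the previous output before its 3x3 convolution,
#' `y_i = K_i(x_i + y_(i-1))`.  The concatenated groups are fused by a 1x1
#' convolution.  Spatial size and channel count are preserved.
#'
#' @param x feature map array `(C, H, W)` or `(C, H, W, N)`.
#' @param params block parameters from [res2net_init()].
#' @param s split count; `C` must be divisible by `s`.
#' @return array of the same shape.
#' @export
res2net_block <- function(x, params, s = 4L) {
  x <- .as_feature(x)
  d <- dim(x)
  if (d[1] %% s != 0L) stop("channel count must be divisible by s")
  N <- if (length(d) == 4L) d[4] else 1L
  out <- ag_value(.res2net_node(ag_const(to_canon(x)), params, s,
                                d[2], d[3], N))
  from_canon(out, d[2], d[3], N, drop = length(d) == 3L)
}

# ---- full generator forward -------------------------------------------------

# Draw the per-layer noise images for a generator at batch size N.
gen_noises <- function(generator, N, seed = NULL) {
  cfg <- generator$config
  draw <- function() {
    out <- list()
    for (t in seq_along(cfg$resolutions)) {
      r <- cfg$resolutions[t]
      out[[2L * t - 1L]] <- matrix(rnorm(r * r * N), 1L)
      out[[2L * t]] <- matrix(rnorm(r * r * N), 1L)
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Graph-mode generator forward.
#   w_layers: list of n_style_layers nodes, each (L, N)
#   noises:   list of 2*n_stages matrices (1, r^2*N), or NULL for none
#   pn:       optional parameter-node tree mirroring the generator (training)
#   styles:   optional explicit per-layer list(ys, yb) value matrices (C, N)
.g_fwd <- function(generator, w_layers, noises, N, pn = NULL, styles = NULL) {
  cfg <- generator$config
  s <- cfg$s
  x <- NULL
  li <- 0L
  for (t in seq_along(cfg$resolutions)) {
    r <- cfg$resolutions[t]
    HW <- r * r
    C <- cfg$channels[t]
    st <- generator$stages[[t]]
    stn <- if (is.null(pn)) NULL else pn$stages[[t]]
    if (t == 1L) {
      cn <- if (is.null(pn)) ag_const(generator$const) else pn$const
      # learned constant, tiled across the batch
      x <- ag_matmul(cn, ag_const(matrix(rep(diag(16), N), 16L)))
      Hin <- 4L; Cin <- C
    } else {
      rp <- cfg$resolutions[t - 1L]
      x <- ag_upsample2(x, rp, rp, cfg$channels[t - 1L], N)
      Hin <- r; Cin <- cfg$channels[t - 1L]
    }
    for (half in c("A", "B")) {
      li <- li + 1L
      conv <- st[[paste0("conv", half)]]
      convn <- if (is.null(pn)) NULL else stn[[paste0("conv", half)]]
      cin <- if (half == "A") Cin else C
      x <- ag_conv2d(x,
                     if (is.null(pn)) ag_const(conv$W) else convn$W,
                     if (is.null(pn)) ag_const(conv$b) else convn$b,
                     r, r, cin, N, 3L)
      if (cfg$noise && !is.null(noises)) {
        Bp <- st[[paste0("noise", half)]]
        Bn <- if (is.null(pn)) ag_const(Bp) else stn[[paste0("noise", half)]]
        x <- .noise_node(x, Bn, noises[[li]])
      }
      x <- ag_leaky_relu(x, cfg$slope)
      if (is.null(styles)) {
        af <- st[[paste0("affine", half)]]
        afn <- if (is.null(pn)) NULL else stn[[paste0("affine", half)]]
        wl <- w_layers[[li]]
        ys <- ag_dense(wl,
                       if (is.null(pn)) ag_const(af$Ws) else afn$Ws,
                       if (is.null(pn)) ag_const(af$bs) else afn$bs)
        yb <- ag_dense(wl,
                       if (is.null(pn)) ag_const(af$Wb) else afn$Wb,
                       if (is.null(pn)) ag_const(af$bb) else afn$bb)
      } else {
        ys <- ag_const(styles[[li]]$ys)
        yb <- ag_const(styles[[li]]$yb)
      }
      x <- .adain_node(x, ys, yb, HW, N, cfg$eps)
    }
    x <- if (is.null(pn))
      .res2net_node(x, st$res2net, s, r, r, N)
    else
      .res2net_node_p(x, stn$res2net, s, r, r, N)
  }
  rgb <- generator$to_rgb
  x <- ag_dense(x,
                if (is.null(pn)) ag_const(rgb$W) else pn$to_rgb$W,
                if (is.null(pn)) ag_const(rgb$b) else pn$to_rgb$b)
  ag_tanh(x)
}

# Normalize the many accepted `w` forms into a per-layer list of (L, N)
# matrices.
.w_to_layers <- function(w, L, n_layers) {
  if (is.list(w)) {
    stopifnot(length(w) == n_layers)
    return(lapply(w, function(wi) .as_latent_mat(wi, L)))
  }
  if (!is.null(attr(w, "source"))) {           # mix_styles() output
    stopifnot(ncol(w) == n_layers)
    return(lapply(seq_len(n_layers), function(i) matrix(w[, i], ncol = 1)))
  }
  wm <- .as_latent_mat(w, L)
  rep(list(wm), n_layers)
}

#' Synthesize images
#'
#' Runs the synthesis network.  Styles may be given as intermediate latents
#' `w` (a vector, a batch matrix `L x N`, a [mix_styles()] assignment, or a
#' per-layer list) or as an explicit per-layer list of `(ys, yb)` pairs.
#'
#' @param generator an `fg_generator`.
#' @param w intermediate latent(s); ignored when `styles` is given.
#' @param styles optional list (one per style layer) of `list(ys, yb)`
#'   numeric vectors.
#' @param noises optional list of noise matrices `(1, r^2*N)`, two per stage
#'   (see [gen_noises()]); drawn from `noise_seed` when omitted.
#' @param noise_seed seed for freshly drawn noise images.
#' @return image array `(3, R, R)` (or `(3, R, R, N)`) with values in
#'   `[-1, 1]`.
#' @export
synthesize <- function(generator, w = NULL, styles = NULL, noises = NULL,
                       noise_seed = 1L) {
  stopifnot(inherits(generator, "fg_generator"))
  cfg <- generator$config
  nl <- n_style_layers(generator)
  if (is.null(styles)) {
    if (is.null(w)) stop("either w or styles must be supplied")
    wl <- .w_to_layers(w, cfg$L, nl)
    N <- ncol(wl[[1]])
    wl <- lapply(wl, ag_const)
  } else {
    if (length(styles) != nl)
      stop("styles must supply one (ys, yb) pair per style layer")
    N <- 1L
    styles <- lapply(styles, function(sp)
      list(ys = matrix(sp$ys, ncol = 1), yb = matrix(sp$yb, ncol = 1)))
    wl <- NULL
  }
  if (is.null(noises) && cfg$noise)
    noises <- gen_noises(generator, N, seed = noise_seed)
  if (cfg$noise && length(noises) != 2L * length(cfg$resolutions))
    stop("one noise image is required per convolutional layer")
  out <- ag_value(.g_fwd(generator, wl, noises, N, styles = styles))
  from_canon(out, cfg$resolution, cfg$resolution, N, drop = N == 1L)
}
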