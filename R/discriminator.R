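# Convolutional Wasserstein critic.
#
# A 3-channel image at the target resolution is mapped down to 4x4 by strided
# 3x3 convolutions and flattened into a single unbounded realness score.
# Stages are CL blocks (convolution + leaky rectifier) by default; CBL
# (convolution + batch normalization + leaky rectifier) is available
# per stage, but batch normalization is off by default because it interacts
# poorly with gradient-penalty training.

#' Critic configuration
#'
#' @param resolution input resolution (power of two, >= 8).
#' @param channels_max,channels_base channel schedule parameters (see
#'   [channel_schedule()]).
#' @param block_types character vector, one of `"CL"`/`"CBL"` per
#'   downsampling stage (recycled if length 1).
#' @param slope leaky rectifier slope.
#' @return list of class `fg_discconfig`.
#' @export
discriminator_config <- function(resolution = 32L, channels_max = 128L,
                                 channels_base = 2048L, block_types = "CL",
                                 slope = 0.2) {
  resolution <- as.integer(resolution)
  if (resolution < 8L || bitwAnd(resolution, resolution - 1L) != 0L)
    stop("resolution must be a power of two >= 8")
  resolutions <- as.integer(2^(as.integer(log2(resolution)):2L))  # target ... 4
  channels <- channel_schedule(resolutions, channels_max, channels_base, s = 1L)
  n_stages <- length(resolutions) - 1L
  block_types <- rep(block_types, length.out = n_stages)
  if (!all(block_types %in% c("CL", "CBL")))
    stop("block types must be 'CL' or 'CBL'")
  structure(list(resolution = resolution, resolutions = resolutions,
                 channels = channels, block_types = block_types,
                 slope = slope),
            class = "fg_discconfig")
}

#' Initialize the critic
#'
#' @param config an `fg_discconfig`.
#' @param seed optional seed.
#' @return object of class `fg_discriminator`.
#' @export
discriminator_init <- function(config = discriminator_config(), seed = NULL) {
  stopifnot(inherits(config, "fg_discconfig"))
  draw <- function() {
    n_stages <- length(config$resolutions) - 1L
    stages <- lapply(seq_len(n_stages), function(t) {
      cin <- config$channels[t]
      cout <- config$channels[t + 1L]
      st <- list(conv = .conv_init(cin, cout, 3L))
      if (config$block_types[t] == "CBL")
        st$bn <- list(gamma = rep(1, cout), beta = numeric(cout),
                      rmean = numeric(cout), rvar = rep(1, cout))
      st
    })
    list(from_rgb = .conv_init(3L, config$channels[1], 3L),
         stages = stages,
         out = list(W = init_mat(1L, config$channels[length(config$channels)] * 16L),
                    b = 0))
  }
  pars <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(c(pars, list(config = config)), class = "fg_discriminator")
}

# Graph-mode critic forward -> (1, N) score node.
# `pn` supplies parameter nodes during critic training; `training` switches
# batch normalization (when present) between batch and running statistics.
.d_fwd <- function(disc, x, N, pn = NULL, training = FALSE) {
  cfg <- disc$config
  slope <- cfg$slope
  r <- cfg$resolution
  pget <- function(value, node) if (is.null(pn)) ag_const(value) else node
  fr <- disc$from_rgb
  frn <- if (is.null(pn)) NULL else pn$from_rgb
  x <- ag_conv2d(x, pget(fr$W, frn$W), pget(fr$b, frn$b), r, r, 3L, N, 3L)
  x <- ag_leaky_relu(x, slope)
  for (t in seq_along(disc$stages)) {
    st <- disc$stages[[t]]
    stn <- if (is.null(pn)) NULL else pn$stages[[t]]
    cin <- cfg$channels[t]
    x <- ag_conv2d(x, pget(st$conv$W, stn$conv$W), pget(st$conv$b, stn$conv$b),
                   r, r, cin, N, 3L, stride = 2L)
    r <- r %/% 2L
    if (cfg$block_types[t] == "CBL") {
      cout <- cfg$channels[t + 1L]
      if (training) {
        mu <- ag_mul(ag_rowsums(x), 1 / (r * r * N))
        xc <- ag_add_rows(x, ag_neg(mu))
        v <- ag_mul(ag_rowsums(ag_mul(xc, xc)), 1 / (r * r * N))
        xh <- ag_mul_rows(xc, ag_div(1, ag_sqrt(ag_add(v, 1e-8))))
      } else {
        xc <- ag_add_rows(x, ag_const(-st$bn$rmean))
        xh <- ag_mul_rows(xc, ag_const(1 / sqrt(st$bn$rvar + 1e-8)))
      }
      x <- ag_add_rows(ag_mul_rows(xh, pget(st$bn$gamma, stn$bn$gamma)),
                       pget(st$bn$beta, stn$bn$beta))
    }
    x <- ag_leaky_relu(x, slope)
  }
  xf <- ag_reshape(x, c(cfg$channels[length(cfg$channels)] * 16L, N))
  ag_dense(xf, pget(disc$out$W, if (is.null(pn)) NULL else pn$out$W),
           pget(disc$out$b, if (is.null(pn)) NULL else pn$out$b))
}

#' Score images with the critic
#'
#' @param image array `(3, R, R)` or `(3, R, R, N)` with `R` the configured
#'   resolution.
#' @param disc an `fg_discriminator`.
#' @param training logical; use batch statistics in CBL blocks.
#' @return numeric vector of one unbounded score per image.
#' @export
discriminate <- function(image, disc, training = FALSE) {
  stopifnot(inherits(disc, "fg_discriminator"))
  d <- dim(image)
  if (is.null(d) || d[1] != 3L || d[2] != disc$config$resolution ||
      d[3] != disc$config$resolution)
    stop("image must be 3 x ", disc$config$resolution, " x ",
         disc$config$resolution)
  N <- if (length(d) == 4L) d[4] else 1L
  s <- ag_value(.d_fwd(disc, ag_const(to_canon(image)), N,
                       training = training))
  as.numeric(s)
}
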