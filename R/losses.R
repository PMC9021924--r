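# Wasserstein adversarial losses, the gradient penalty, and path-length
# regularization with its self-calibrating scale constant.

#' Wasserstein critic loss
#'
#' `mean(fake_scores) - mean(real_scores)`: the critic is trained to push
#' real scores up and fake scores down.
#'
#' @param real_scores,fake_scores nonempty numeric vectors.
#' @return scalar loss.
#' @export
critic_loss <- function(real_scores, fake_scores) {
  if (!length(real_scores) || !length(fake_scores))
    stop("score vectors must be nonempty")
  mean(fake_scores) - mean(real_scores)
}

#' Wasserstein generator loss
#'
#' `-mean(fake_scores)`: the generator is trained to raise the critic's
#' scores of its samples.
#'
#' @param fake_scores nonempty numeric vector.
#' @return scalar loss.
#' @export
generator_loss <- function(fake_scores) {
  if (!length(fake_scores)) stop("score vector must be nonempty")
  -mean(fake_scores)
}

# Graph-mode gradient penalty.  Builds interpolates x_hat = u*real +
# (1-u)*fake, differentiates the critic at x_hat (the gradient is a graph
# node), and returns lambda * mean((||grad|| - 1)^2) as a node that can be
# differentiated again with respect to the critic parameters.
.gp_node <- function(disc, real_m, fake_m, u, lambda, N, pn = NULL,
                     training = FALSE) {
  HW <- disc$config$resolution^2
  ucol <- rep(u, each = HW)
  xhat <- ag_leaf(real_m * rep(ucol, each = 3L) +
                    fake_m * rep(1 - ucol, each = 3L))
  scores <- .d_fwd(disc, xhat, N, pn = pn, training = training)
  gx <- ag_grad(ag_sum(scores), xhat)
  norms <- ag_col_norms(ag_reshape(gx, c(3L * HW, N)), eps = 1e-24)
  dev <- ag_sub(norms, 1)
  list(node = ag_mul(ag_mean(ag_mul(dev, dev)), lambda),
       grad_norms = as.numeric(ag_value(norms)))
}

#' Wasserstein gradient penalty
#'
#' Samples per-image interpolates `x_hat = u*real + (1-u)*fake` with
#' `u ~ Uniform(0, 1)`, computes the critic's input gradient there by
#' backpropagation, and penalizes deviations of its Euclidean norm from 1:
#' `gp_lambda * mean((||grad|| - 1)^2)`.
#'
#' @param disc an `fg_discriminator`, or a function mapping a graph node of
#'   a `(D, N)` batch matrix (columns are samples) to a score node (for
#'   analysis of simple critics, e.g. linear functionals).
#' @param real,fake image arrays `(3, R, R)` or `(3, R, R, N)` of matching
#'   shape; for a function critic, `(D, N)` matrices.
#' @param gp_lambda penalty coefficient (default 10).
#' @param seed seed for the interpolation draws.
#' @return scalar penalty; attribute `"grad_norms"` carries the per-sample
#'   gradient norms.
#' @export
gradient_penalty <- function(disc, real, fake, gp_lambda = 10, seed = NULL) {
  if (!identical(dim(real), dim(fake))) stop("real/fake batch shape mismatch")
  if (is.function(disc)) {
    rm <- if (is.matrix(real)) real else matrix(real, ncol = 1)
    fm <- if (is.matrix(fake)) fake else matrix(fake, ncol = 1)
    N <- ncol(rm)
    u <- if (is.null(seed)) stats::runif(N) else
      withr::with_seed(seed, stats::runif(N))
    xhat <- ag_leaf(rm * rep(u, each = nrow(rm)) +
                      fm * rep(1 - u, each = nrow(fm)))
    gx <- ag_grad(ag_sum(disc(xhat)), xhat)
    norms <- as.numeric(ag_value(ag_col_norms(gx, eps = 1e-24)))
    return(structure(gp_lambda * mean((norms - 1)^2), grad_norms = norms))
  }
  stopifnot(inherits(disc, "fg_discriminator"))
  d <- dim(real)
  N <- if (length(d) == 4L) d[4] else 1L
  u <- if (is.null(seed)) stats::runif(N) else
    withr::with_seed(seed, stats::runif(N))
  gp <- .gp_node(disc, to_canon(real), to_canon(fake), u, gp_lambda, N)
  structure(ag_value(gp$node), grad_norms = gp$grad_norms)
}

#' Path-length regularizer state
#'
#' Running scale constant `a`, dynamically set to an exponential moving
#' average of observed path lengths so the optimization discovers the global
#' scale on its own.  `a` starts at 0: the first batch sets its own scale.
#'
#' @param decay EMA decay in (0, 1).
#' @param a initial constant.
#' @return list of class `fg_plr_state`.
#' @export
plr_state <- function(decay = 0.99, a = 0) {
  stopifnot(decay > 0, decay < 1, a >= 0)
  structure(list(a = a, decay = decay, steps = 0L), class = "fg_plr_state")
}

# Graph-mode path lengths for a synthesis generator: w is an (L, N) leaf
# node; returns the (1, N) node of lengths ||d/dw <g(w), y>||_2.
.plr_lengths_node <- function(generator, w_node, noises, N, y, pn = NULL) {
  nl <- n_style_layers(generator)
  img <- .g_fwd(generator, rep(list(w_node), nl), noises, N, pn = pn)
  dotv <- ag_sum(ag_mul(img, ag_const(y)))
  gw <- ag_grad(dotv, w_node)
  ag_col_norms(gw, eps = 1e-24)
}

#' Path-length penalty
#'
#' For each latent `w`, draws a random image `y` with normally distributed
#' pixel intensities and measures the length
#' `l = ||grad_w <g(w), y>||_2` by backpropagation (the Jacobian-transpose
#' product is never formed explicitly).  The penalty is `mean((l - a)^2)`
#' where `a` is the running EMA of observed lengths; the state is updated
#' with the batch mean.
#'
#' @param generator an `fg_generator`, or a function mapping a latent graph
#'   node `(L, N)` to an output node (for analysis of simple generators,
#'   e.g. linear maps).
#' @param w matrix (`L` x N) of intermediate latents (columns are samples),
#'   or a vector.
#' @param state an `fg_plr_state`.
#' @param seed seed for the `y` draws.
#' @param y optional explicit random image(s), matching the generator output
#'   layout; drawn from `seed` when omitted.
#' @param y_scale scale applied to `y`.  Default: `1/sqrt(H*W)` for an
#'   `fg_generator` (lengths comparable across resolutions), 1 for a custom
#'   generator function.
#' @param noises optional noise images for an `fg_generator` forward.
#' @return list with `penalty`, updated `state`, and the per-sample
#'   `lengths`.
#' @export
path_length_penalty <- function(generator, w, state, seed = NULL, y = NULL,
                                y_scale = NULL, noises = NULL) {
  stopifnot(inherits(state, "fg_plr_state"))
  wm <- if (is.matrix(w)) w else matrix(w, ncol = 1)
  N <- ncol(wm)
  wn <- ag_leaf(wm)
  if (inherits(generator, "fg_generator")) {
    cfg <- generator$config
    HW <- cfg$resolution^2
    if (is.null(y_scale)) y_scale <- 1 / sqrt(HW)
    if (is.null(y)) {
      y <- if (is.null(seed)) matrix(stats::rnorm(3L * HW * N), 3L) else
        withr::with_seed(seed, matrix(stats::rnorm(3L * HW * N), 3L))
    } else y <- to_canon(y)
    if (is.null(noises) && cfg$noise)
      noises <- gen_noises(generator, N,
                           seed = if (is.null(seed)) 0L else seed + 1L)
    lens_node <- .plr_lengths_node(generator, wn, noises, N, y * y_scale)
  } else if (is.function(generator)) {
    out <- generator(wn)
    ov <- ag_value(out)
    if (is.null(y_scale)) y_scale <- 1
    if (is.null(y)) {
      y <- if (is.null(seed)) array(stats::rnorm(length(ov)), dim(ov) %||% length(ov)) else
        withr::with_seed(seed, array(stats::rnorm(length(ov)), dim(ov) %||% length(ov)))
    }
    dotv <- ag_sum(ag_mul(out, ag_const(y * y_scale)))
    gw <- ag_grad(dotv, wn)
    lens_node <- ag_col_norms(gw, eps = 1e-24)
  } else stop("generator must be an fg_generator or a function")
  lengths <- as.numeric(ag_value(lens_node))
  dev <- lengths - state$a
  penalty <- mean(dev^2)
  state$a <- state$decay * state$a + (1 - state$decay) * mean(lengths)
  state$steps <- state$steps + 1L
  list(penalty = penalty, state = state, lengths = lengths)
}
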