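# Non-linear mapping network: a multilayer perceptron taking latent codes z
# (standard normal, length L) to intermediate latents w, plus the
# center-of-mass truncation trick and style-mixing regularization.

#' Initialize mapping-network weights
#'
#' A `depth`-layer fully connected network of constant width `L` with leaky
#' rectifier activations.  Weights are drawn normal(0, 0.02^2), biases start
#' at zero.
#'
#' @param L latent dimensionality (input, hidden and output width).
#' @param depth number of layers (default 4).
#' @param slope leaky rectifier negative slope.
#' @param seed optional integer seed for reproducible initialization.
#' @return an object of class `fg_mapping`.
#' @export
mapping_init <- function(L = 512L, depth = 4L, slope = 0.2, seed = NULL) {
  stopifnot(L >= 1L, depth >= 1L)
  draw <- function() lapply(seq_len(depth), function(i)
    list(W = init_mat(L, L), b = numeric(L)))
  layers <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(layers = layers, L = as.integer(L), depth = as.integer(depth),
                 slope = slope),
            class = "fg_mapping")
}

# Graph-mode forward; z_node is (L, N).
.map_fwd <- function(z_node, mapping, as_nodes = NULL) {
  h <- z_node
  for (i in seq_len(mapping$depth)) {
    ly <- if (is.null(as_nodes)) {
      list(W = ag_const(mapping$layers[[i]]$W),
           b = ag_const(mapping$layers[[i]]$b))
    } else as_nodes[[i]]
    h <- ag_leaky_relu(ag_dense(h, ly$W, ly$b), mapping$slope)
  }
  h
}

.as_latent_mat <- function(z, L) {
  if (is.matrix(z)) {
    if (nrow(z) != L) stop("latent dimension mismatch: expected length ", L)
    z
  } else {
    if (length(z) != L) stop("latent dimension mismatch: expected length ", L)
    matrix(z, ncol = 1)
  }
}

#' Map latent codes to the intermediate latent space
#'
#' @param z numeric vector of length `L`, or matrix (`L` x n) of codes in
#'   columns.
#' @param mapping an `fg_mapping` object.
#' @return intermediate latent(s) `w`, same shape as the input.
#' @export
map_latent <- function(z, mapping) {
  stopifnot(inherits(mapping, "fg_mapping"))
  zm <- .as_latent_mat(z, mapping$L)
  if (any(!is.finite(zm))) stop("latent code must be finite")
  w <- ag_value(.map_fwd(ag_const(zm), mapping))
  if (is.matrix(z)) w else as.numeric(w)
}

#' Center of mass of the intermediate latent space
#'
#' Maps a collection of latent codes through the network and returns the
#' elementwise mean of the mapped vectors -- the empirical expectation of w
#' under the latent prior, used as the anchor of the truncation trick.
#'
#' @param zs matrix (`L` x n) of latent codes in columns, or a list of
#'   vectors.
#' @param mapping an `fg_mapping` object.
#' @return numeric vector of length `L`.
#' @export
center_of_mass <- function(zs, mapping) {
  if (is.list(zs)) zs <- do.call(cbind, zs)
  if (is.null(dim(zs))) zs <- matrix(zs, ncol = 1)
  if (ncol(zs) < 1L) stop("at least one latent sample is required")
  rowMeans(map_latent(zs, mapping))
}

#' Truncate an intermediate latent toward the center of mass
#'
#' Shrinks `w` toward `w_bar` by the factor `psi`:
#' `w' = w_bar + psi * (w - w_bar)`.  `psi = 1` leaves `w` unchanged;
#' `psi = 0` collapses onto the center of mass.
#'
#' @param w intermediate latent vector (or matrix of columns).
#' @param w_bar center of mass, same length.
#' @param psi truncation factor (finite real; typical sampling value 0.7).
#' @return truncated latent(s), same shape as `w`.
#' @export
truncate_latent <- function(w, w_bar, psi) {
  if (!is.numeric(psi) || length(psi) != 1L || !is.finite(psi))
    stop("psi must be a single finite number")
  nw <- if (is.matrix(w)) nrow(w) else length(w)
  if (length(w_bar) != nw) stop("latent dimension mismatch between w and w_bar")
  w_bar + psi * (w - w_bar)
}

#' Assign two latents to generator style layers (style mixing)
#'
#' Layers strictly before the crossover index take `w1`; layers at or after
#' it take `w2`.  `crossover = n_layers` therefore uses `w1` everywhere and
#' `crossover = 0` uses `w2` everywhere.
#'
#' @param w1,w2 intermediate latent vectors of equal length.
#' @param crossover integer in `[0, n_layers]`.
#' @param n_layers number of style inputs of the synthesis network.
#' @return matrix (`L` x `n_layers`); attribute `"source"` records 1 or 2
#'   per layer.
#' @export
mix_styles <- function(w1, w2, crossover, n_layers) {
  if (length(w1) != length(w2)) stop("latent dimension mismatch")
  if (crossover < 0 || crossover > n_layers)
    stop("crossover must lie in [0, n_layers]")
  src <- ifelse(seq_len(n_layers) <= crossover, 1L, 2L)
  out <- vapply(src, function(s) if (s == 1L) w1 else w2, numeric(length(w1)))
  out <- matrix(out, nrow = length(w1))
  attr(out, "source") <- src
  out
}
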