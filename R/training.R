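# Alternating WGAN-GP optimization of the critic and the style-based
# generator, with lazy path-length regularization, style mixing, seeded
# sub-streams for every randomness consumer, and checkpointing.

# ---- parameter trees --------------------------------------------------------

# Trainable subtree of each component (running BN statistics excluded).
.trainable <- function(x) {
  if (inherits(x, "fg_mapping")) return(x["layers"])
  if (inherits(x, "fg_generator")) return(unclass(x)[c("const", "stages", "to_rgb")])
  if (inherits(x, "fg_discriminator")) return(unclass(x)[c("from_rgb", "stages", "out")])
  stop("unknown component")
}

.put_trainable <- function(x, tree) {
  for (nm in names(tree)) x[[nm]] <- tree[[nm]]
  x
}

.skip_leaf <- function(nm) nm %in% c("rmean", "rvar")

# Depth-first list of numeric leaves as (path, value); paths are integer
# vectors usable with tree_set().
tree_leaves <- function(x, path = integer(0)) {
  if (is.numeric(x)) return(list(list(path = path, value = x)))
  if (!is.list(x)) return(list())
  out <- list()
  nms <- names(x) %||% rep("", length(x))
  for (i in seq_along(x)) {
    if (.skip_leaf(nms[i])) next
    out <- c(out, tree_leaves(x[[i]], c(path, i)))
  }
  out
}

tree_set <- function(x, path, value) {
  if (!length(path)) return(value)
  x[[path[1]]] <- tree_set(x[[path[1]]], path[-1], value)
  x
}

tree_get <- function(x, path) {
  for (i in path) x <- x[[i]]
  x
}

# Wrap every numeric leaf in a graph leaf node (same traversal order as
# tree_leaves, so gradients align).
as_node_tree <- function(x) {
  if (is.numeric(x)) return(ag_leaf(x))
  if (!is.list(x)) return(x)
  nms <- names(x) %||% rep("", length(x))
  out <- lapply(seq_along(x), function(i)
    if (.skip_leaf(nms[i])) x[[i]] else as_node_tree(x[[i]]))
  names(out) <- names(x)
  out
}

node_tree_leaves <- function(x) {
  if (is_ag(x)) return(list(x))
  if (!is.list(x)) return(list())
  nms <- names(x) %||% rep("", length(x))
  out <- list()
  for (i in seq_along(x)) {
    if (.skip_leaf(nms[i])) next
    out <- c(out, node_tree_leaves(x[[i]]))
  }
  out
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(leaves) {
  list(m = lapply(leaves, function(l) array(0, dim(l$value) %||% length(l$value))),
       v = lapply(leaves, function(l) array(0, dim(l$value) %||% length(l$value))),
       t = 0L)
}

adam_step <- function(opt, grads, lr, beta1 = 0, beta2 = 0.99, eps = 1e-8) {
  opt$t <- opt$t + 1L
  upd <- vector("list", length(grads))
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * g
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * g * g
    mh <- opt$m[[i]] / (1 - beta1^opt$t)
    vh <- opt$v[[i]] / (1 - beta2^opt$t)
    upd[[i]] <- lr * mh / (sqrt(vh) + eps)
  }
  list(opt = opt, updates = upd)
}

# Parameter update preserving the parameter's exact shape attributes (Adam
# state is stored as arrays; subtracting an array from a bare vector must
# not leave a 1-D array behind).
.apply_update <- function(value, update) {
  nv <- value - update
  attributes(nv) <- attributes(value)
  nv
}

# ---- seeded sub-streams -----------------------------------------------------

# Deterministic derived seed for (master seed, consumer tag, counter); all
# randomness in training flows through this so runs are reproducible and
# consumers are independent.
substream_seed <- function(master, tag, counter = 0L) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  s <- (as.numeric(master) * 48271 + h * 1103 + as.numeric(counter) * 7919) %%
    2147483646
  as.integer(s) + 1L
}

.draw <- function(master, tag, counter, expr) {
  withr::with_seed(substream_seed(master, tag, counter), expr)
}

# ---- model ------------------------------------------------------------------

#' Initialize the full model (mapping + generator + critic)
#'
#' @param config a run configuration from [run_config()].
#' @return list of class `fg_model`.
#' @export
model_init <- function(config = run_config()) {
  stopifnot(inherits(config, "fg_runconfig"))
  seed <- config$seed
  gcfg <- generator_config(resolution = config$resolution, L = config$L,
                           s = config$s, channels_max = config$channels_max,
                           channels_base = config$channels_base,
                           noise = config$noise)
  dcfg <- discriminator_config(resolution = config$resolution,
                               channels_max = config$channels_max,
                               channels_base = config$channels_base,
                               block_types = config$block_types)
  structure(list(
    mapping = mapping_init(L = config$L, depth = config$mapping_depth,
                           seed = substream_seed(seed, "init_mapping")),
    generator = generator_init(gcfg, seed = substream_seed(seed, "init_gen")),
    critic = discriminator_init(dcfg, seed = substream_seed(seed, "init_disc")),
    plr = plr_state(decay = config$plr_decay),
    config = config,
    step = 0L), class = "fg_model")
}

# Mixed per-layer w nodes for a batch: two latent batches through the
# mapping, a per-sample crossover point, and per-layer 0/1 masks.
.mixed_w_nodes <- function(model, mn, N, master, step, tag) {
  cfg <- model$config
  L <- cfg$L
  nl <- n_style_layers(model$generator)
  z1 <- .draw(master, paste0(tag, "_z1"), step, matrix(stats::rnorm(L * N), L))
  z2 <- .draw(master, paste0(tag, "_z2"), step, matrix(stats::rnorm(L * N), L))
  mixed <- .draw(master, paste0(tag, "_mix"), step,
                 stats::runif(N) < cfg$mixing_prob)
  cross <- .draw(master, paste0(tag, "_cross"), step,
                 sample.int(nl + 1L, N, replace = TRUE) - 1L)
  cross[!mixed] <- nl  # unmixed samples use w1 everywhere
  w1 <- .map_fwd(ag_const(z1), model$mapping, as_nodes = mn)
  w2 <- .map_fwd(ag_const(z2), model$mapping, as_nodes = mn)
  lapply(seq_len(nl), function(l) {
    m <- as.numeric(l <= cross)
    if (all(m == 1)) w1
    else if (all(m == 0)) w2
    else ag_add(ag_mul_cols(w1, ag_const(m)), ag_mul_cols(w2, ag_const(1 - m)))
  })
}

#' One alternating training step
#'
#' Performs `critic_steps` critic updates (Wasserstein loss plus gradient
#' penalty) followed by one generator/mapping update (Wasserstein generator
#' loss, plus the path-length penalty every `plr_interval` steps).
#'
#' @param model an `fg_model`.
#' @param opt optimizer state from [optimizers_init()].
#' @param real image array `(3, R, R, N)`, values in `[-1, 1]`.
#' @return list with the updated `model`, `opt`, and a one-row data frame
#'   `record` of loss components.
#' @export
train_step <- function(model, opt, real) {
  cfg <- model$config
  master <- cfg$seed
  step <- model$step + 1L
  d <- dim(real)
  stopifnot(length(d) == 4L, d[1] == 3L, d[2] == cfg$resolution)
  if (any(abs(real) > 1 + 1e-9)) stop("real images must lie in [-1, 1]")
  N <- d[4]
  real_m <- to_canon(real)
  nl <- n_style_layers(model$generator)

  c_loss <- gp_val <- NA_real_
  for (cs in seq_len(cfg$critic_steps)) {
    # fake batch, constant w.r.t. the critic update
    wl <- .mixed_w_nodes(model, NULL, N, master, step * 10L + cs, "critic_fake")
    noises <- gen_noises(model$generator, N,
                         seed = substream_seed(master, "critic_noise",
                                               step * 10L + cs))
    fake_m <- ag_value(.g_fwd(model$generator, wl, noises, N))

    dtree <- .trainable(model$critic)
    dn <- as_node_tree(dtree)
    sr <- .d_fwd(model$critic, ag_const(real_m), N, pn = dn, training = TRUE)
    sf <- .d_fwd(model$critic, ag_const(fake_m), N, pn = dn, training = TRUE)
    wloss <- ag_sub(ag_mean(sf), ag_mean(sr))
    u <- .draw(master, "gp_u", step * 10L + cs, stats::runif(N))
    gp <- .gp_node(model$critic, real_m, fake_m, u, cfg$gp_lambda, N,
                   pn = dn, training = TRUE)
    total <- ag_add(wloss, gp$node)
    if (!is.finite(ag_value(total)))
      stop("non-finite critic loss at step ", step)
    leaves <- node_tree_leaves(dn)
    grads <- lapply(ag_grad(total, leaves), ag_value)
    st <- adam_step(opt$critic, grads, cfg$lr, cfg$beta1, cfg$beta2)
    opt$critic <- st$opt
    paths <- tree_leaves(dtree)
    for (i in seq_along(paths))
      dtree <- tree_set(dtree, paths[[i]]$path,
                        .apply_update(paths[[i]]$value, st$updates[[i]]))
    model$critic <- .put_trainable(model$critic, dtree)
    c_loss <- ag_value(wloss)
    gp_val <- ag_value(gp$node)
  }

  # generator + mapping update
  gtree <- .trainable(model$generator)
  mtree <- .trainable(model$mapping)
  gn <- as_node_tree(gtree)
  mn <- as_node_tree(mtree)$layers
  wl <- .mixed_w_nodes(model, mn, N, master, step, "gen_fake")
  noises <- gen_noises(model$generator, N,
                       seed = substream_seed(master, "gen_noise", step))
  fake <- .g_fwd(model$generator, wl, noises, N, pn = gn)
  sf <- .d_fwd(model$critic, fake, N)
  gloss <- ag_neg(ag_mean(sf))
  plr_val <- 0
  if (cfg$plr_weight > 0 && step %% cfg$plr_interval == 0L) {
    zp <- .draw(master, "plr_z", step, matrix(stats::rnorm(cfg$L * N), cfg$L))
    wp <- .map_fwd(ag_const(zp), model$mapping, as_nodes = mn)
    pnoises <- gen_noises(model$generator, N,
                          seed = substream_seed(master, "plr_noise", step))
    HW <- cfg$resolution^2
    y <- .draw(master, "plr_y", step,
               matrix(stats::rnorm(3L * HW * N), 3L)) / sqrt(HW)
    lens <- .plr_lengths_node(model$generator, wp, pnoises, N, y, pn = gn)
    devs <- ag_sub(lens, model$plr$a)
    pen <- ag_mean(ag_mul(devs, devs))
    gloss <- ag_add(gloss, ag_mul(pen, cfg$plr_weight))
    lvals <- as.numeric(ag_value(lens))
    model$plr$a <- model$plr$decay * model$plr$a +
      (1 - model$plr$decay) * mean(lvals)
    model$plr$steps <- model$plr$steps + 1L
    plr_val <- ag_value(pen)
  }
  if (!is.finite(ag_value(gloss)))
    stop("non-finite generator loss at step ", step)
  leaves <- c(node_tree_leaves(gn), node_tree_leaves(mn))
  grads <- lapply(ag_grad(gloss, leaves), ag_value)
  st <- adam_step(opt$generator, grads, cfg$lr, cfg$beta1, cfg$beta2)
  opt$generator <- st$opt
  gpaths <- tree_leaves(gtree)
  k <- 0L
  for (i in seq_along(gpaths)) {
    k <- k + 1L
    gtree <- tree_set(gtree, gpaths[[i]]$path,
                      .apply_update(gpaths[[i]]$value, st$updates[[k]]))
  }
  mpaths <- tree_leaves(mtree)
  for (i in seq_along(mpaths)) {
    k <- k + 1L
    mtree <- tree_set(mtree, mpaths[[i]]$path,
                      .apply_update(mpaths[[i]]$value, st$updates[[k]]))
  }
  model$generator <- .put_trainable(model$generator, gtree)
  model$mapping <- .put_trainable(model$mapping, mtree)
  model$step <- step

  record <- data.frame(step = step, critic_loss = c_loss, gp = gp_val,
                       gen_loss = ag_value(ag_neg(ag_mean(sf))),
                       plr = plr_val, plr_a = model$plr$a)
  list(model = model, opt = opt, record = record)
}

#' Initialize optimizer states for a model
#' @param model an `fg_model`.
#' @export
optimizers_init <- function(model) {
  list(critic = adam_init(tree_leaves(.trainable(model$critic))),
       generator = adam_init(c(tree_leaves(.trainable(model$generator)),
                               tree_leaves(.trainable(model$mapping)))))
}

#' Train the model
#'
#' @param data a directory of images, an array `(3, R, R, M)` in `[-1, 1]`,
#'   or a [scene_spec()] used to render `config$fixture_n` scenes.
#' @param config run configuration ([run_config()]).
#' @param resume path to a checkpoint to resume from.
#' @param steps optional hard cap on total steps (overrides epochs).
#' @return list of class `fg_fit`: `model`, `opt`, `log` (one row per step),
#'   and `checkpoint` (path, when `config$out_dir` is set).
#' @export
train <- function(data, config = run_config(), resume = NULL, steps = NULL) {
  stopifnot(inherits(config, "fg_runconfig"))
  imgs <- .resolve_training_data(data, config)
  M <- dim(imgs)[4]
  if (M < config$batch_size)
    stop("dataset must contain at least batch_size images")

  if (is.null(resume)) {
    model <- model_init(config)
    opt <- optimizers_init(model)
    log <- NULL
  } else {
    ck <- load_checkpoint(resume, expected_resolution = config$resolution)
    model <- ck$model
    opt <- ck$opt
    log <- ck$log
  }

  steps_per_epoch <- max(1L, M %/% config$batch_size)
  total <- if (is.null(steps)) config$epochs * steps_per_epoch else steps
  logs <- if (is.null(log)) list() else list(log)
  while (model$step < total) {
    step <- model$step + 1L
    epoch <- (step - 1L) %/% steps_per_epoch
    ord <- .draw(config$seed, "shuffle", epoch, sample.int(M))
    b <- (step - 1L) %% steps_per_epoch
    idx <- ord[(b * config$batch_size + 1L):((b + 1L) * config$batch_size)]
    res <- train_step(model, opt, imgs[, , , idx, drop = FALSE])
    model <- res$model
    opt <- res$opt
    logs <- c(logs, list(res$record))
  }
  log <- do.call(rbind, logs)
  out <- structure(list(model = model, opt = opt, log = log), class = "fg_fit")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(config$out_dir, "losses.csv"),
                     row.names = FALSE)
    ckpath <- file.path(config$out_dir, "checkpoint.rds")
    save_checkpoint(out, ckpath)
    out$checkpoint <- ckpath
  }
  out
}

.resolve_training_data <- function(data, config) {
  if (is.character(data) && length(data) == 1L)
    return(load_image_folder(data, config$resolution))
  if (inherits(data, "fg_scenespec")) {
    ds <- generate_dataset(config$fixture_n, data,
                           seed = substream_seed(config$seed, "fixtures"))
    arr <- vapply(ds$images, function(im) aperm(im, c(3, 1, 2)),
                  array(0, c(3, config$resolution, config$resolution)))
    return(arr * 2 - 1)
  }
  if (is.array(data) && length(dim(data)) == 4L) return(data)
  stop("data must be a directory, a (3, R, R, M) array, or a scene_spec")
}

#' Sample images from a trained model
#'
#' Draws latents, applies the truncation trick toward the mapping network's
#' center of mass, synthesizes images, and optionally writes them as 8-bit
#' PNG files.
#'
#' @param model an `fg_model` (or `fg_fit`).
#' @param n number of images.
#' @param psi truncation factor (default 0.7; 1 disables truncation).
#' @param seed seed controlling latents and noise.
#' @param out_dir optional output directory for PNG files.
#' @param w_bar_n number of latent samples for the center-of-mass estimate.
#' @return invisibly, an array `(3, R, R, n)` in `[-1, 1]`.
#' @export
generate_images <- function(model, n, psi = 0.7, seed = 1L, out_dir = NULL,
                            w_bar_n = 256L) {
  if (inherits(model, "fg_fit")) model <- model$model
  stopifnot(inherits(model, "fg_model"))
  L <- model$config$L
  zs <- withr::with_seed(substream_seed(seed, "gen_z"),
                         matrix(stats::rnorm(L * n), L))
  w <- map_latent(zs, model$mapping)
  if (psi != 1) {
    zb <- withr::with_seed(substream_seed(seed, "gen_wbar"),
                           matrix(stats::rnorm(L * w_bar_n), L))
    w_bar <- center_of_mass(zb, model$mapping)
    w <- truncate_latent(w, w_bar, psi)
  }
  imgs <- synthesize(model$generator, w = w,
                     noises = gen_noises(model$generator, n,
                                         seed = substream_seed(seed, "gen_noise")))
  if (n == 1L) dim(imgs) <- c(dim(imgs), 1L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      im <- aperm((imgs[, , , i] + 1) / 2, c(2, 3, 1))
      png::writePNG(pmin(pmax(im, 0), 1),
                    file.path(out_dir, sprintf("sample_%04d.png", i)))
    }
  }
  invisible(imgs)
}
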