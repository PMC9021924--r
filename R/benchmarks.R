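# Reproducible desk-scale benchmarks: a seeded smoke-training run against
# the bright-disk fixture distribution, and the convergence of the
# path-length EMA constant on a frozen generator.  Both are used by the
# test suite and by scripts/acceptance.R, so their conditions live in one
# place.

#' Seeded smoke-training benchmark
#'
#' Trains the full model on the bright-disk fixture distribution at 32x32
#' and reports the mean-image absolute error between generated samples and
#' the fixture mean, before and after training.  The mean image is taken
#' over `n_eval` untruncated samples; the error is the mean absolute pixel
#' difference in `[-1, 1]` units.
#'
#' @param steps training steps (default 300).
#' @param seed master training seed.
#' @param data_seed seed of the fixture dataset.
#' @param eval_seed seed of the evaluation sample draws.
#' @param n_eval generated samples per evaluation.
#' @param n_data fixture images.
#' @return list with `err_init`, `err_final`, `reduction_pct`, and the
#'   trained `fit`.
#' @export
smoke_train_benchmark <- function(steps = 300L, seed = 11L, data_seed = 21L,
                                  eval_seed = 33L, n_eval = 64L,
                                  n_data = 64L) {
  cfg <- run_config(resolution = 32, L = 32, channels_max = 32,
                    channels_base = 512, batch_size = 8, seed = seed,
                    fixture_n = n_data)
  ds <- generate_dataset(n_data, disk_fixture_spec(32), seed = data_seed)
  arr <- vapply(ds$images, function(im) aperm(im, c(3, 1, 2)),
                array(0, c(3, 32, 32))) * 2 - 1
  real_mean <- apply(arr, c(1, 2, 3), mean)
  mean_err <- function(model) {
    imgs <- generate_images(model, n = n_eval, psi = 1, seed = eval_seed)
    mean(abs(apply(imgs, c(1, 2, 3), mean) - real_mean))
  }
  err_init <- mean_err(model_init(cfg))
  fit <- train(arr, cfg, steps = steps)
  err_final <- mean_err(fit$model)
  list(err_init = err_init, err_final = err_final,
       reduction_pct = 100 * (1 - err_final / err_init), fit = fit)
}

#' Path-length EMA convergence benchmark
#'
#' Repeatedly evaluates the path-length regularizer on a frozen generator
#' (no weight updates) and compares the EMA constant `a` after `updates`
#' batches against the empirical mean of all observed lengths.
#'
#' @param updates number of EMA updates (default 500).
#' @param decay EMA decay (default 0.99).
#' @param batch latents per update.
#' @param seed seed controlling initialization and draws.
#' @return list with `a`, `empirical_mean`, `rel_dev_pct`.
#' @export
plr_ema_benchmark <- function(updates = 500L, decay = 0.99, batch = 16L,
                              seed = 41L) {
  g <- generator_init(generator_config(resolution = 8, L = 32, s = 4,
                                       channels_max = 16,
                                       channels_base = 128), seed = seed)
  m <- mapping_init(L = 32, seed = seed + 1L)
  st <- plr_state(decay = decay)
  lens <- numeric(0)
  for (i in seq_len(updates)) {
    z <- withr::with_seed(substream_seed(seed, "ema_z", i),
                          matrix(stats::rnorm(32L * batch), 32L))
    w <- map_latent(z, m)
    r <- path_length_penalty(g, w, st,
                             seed = substream_seed(seed, "ema_y", i))
    st <- r$state
    lens <- c(lens, r$lengths)
  }
  emp <- mean(lens)
  list(a = st$a, empirical_mean = emp,
       rel_dev_pct = 100 * abs(st$a - emp) / emp)
}
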