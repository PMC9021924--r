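# Synthesis network: AdaIN, noise injection, Res2Net blocks, and the full
# style-modulated generator.

test_that("adain normalizes, scales and shifts per channel", {
  set.seed(1)
  x <- array(rnorm(3 * 6 * 6, mean = 5, sd = 3), c(3, 6, 6))
  # pure normalization: unit scale, zero bias
  out <- adain(x, ys = rep(1, 3), yb = rep(0, 3))
  for (c in 1:3) {
    expect_equal(mean(out[c, , ]), 0, tolerance = 1e-7)
    expect_equal(mean(out[c, , ]^2), 1, tolerance = 1e-6)
  }
  # zero scale: constant bias output
  out <- adain(x, ys = rep(0, 3), yb = c(1, 2, 3))
  for (c in 1:3) expect_true(all(abs(out[c, , ] - c) < 1e-12))
  expect_error(adain(x, ys = rep(1, 2), yb = rep(0, 3)), "channel")
  expect_error(adain(x, rep(1, 3), rep(0, 3), eps = 0), "eps")
})

test_that("adain matches the hand-computed 2x2 worked example", {
  # one channel, [[0,0],[2,2]]: mean 1, population sd 1; scale 2, shift 1
  x <- array(c(0, 0, 2, 2), c(1, 2, 2))  # x[1,h,w]: rows (0,0),(2,2)
  out <- adain(x, ys = 2, yb = 1, eps = 1e-14)
  expect_equal(as.numeric(out), c(-1, -1, 3, 3), tolerance = 1e-6)
})

test_that("double adain with unit style equals a single one", {
  set.seed(2)
  x <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  once <- adain(x, rep(1, 4), rep(0, 4))
  twice <- adain(once, rep(1, 4), rep(0, 4))
  expect_equal(twice, once, tolerance = 1e-6)
})

test_that("noise injection is additive and respects B = 0", {
  set.seed(3)
  x <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  noise <- matrix(rnorm(36), 6)
  # B = 0: unchanged
  expect_equal(inject_noise(x, noise, rep(0, 4)), x, tolerance = 1e-15)
  # x = 0, B = 1: each channel equals the noise image
  z <- array(0, c(4, 6, 6))
  out <- inject_noise(z, noise, rep(1, 4))
  for (c in 1:4) expect_equal(out[c, , ], noise, tolerance = 1e-15)
  # additivity: the increment is independent of x
  B <- rnorm(4)
  d1 <- inject_noise(x, noise, B) - x
  d2 <- inject_noise(z, noise, B) - z
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_error(inject_noise(x, matrix(0, 5, 6), rep(1, 4)), "size")
  expect_error(inject_noise(x, noise, rep(1, 3)), "B length")
})

test_that("res2net block matches the unrolled recursion with identity kernels", {
  # all K_i identity, fusion identity, s = 3: output is (x1, x2, x2 + x3)
  C <- 6L; s <- 3L; cs <- 2L
  x <- array(rnorm(C * 4 * 4), c(C, 4, 4))
  p <- res2net_init(C, s, seed = 1)
  for (i in 1:(s - 1)) {
    p$K[[i]]$W <- identity_kernel3(cs)
    p$K[[i]]$b <- rep(0, cs)
  }
  p$fuse$W <- diag(C)
  p$fuse$b <- rep(0, C)
  out <- res2net_block(x, p, s)
  expect_equal(out[1:2, , ], x[1:2, , ], tolerance = 1e-12)
  expect_equal(out[3:4, , ], x[3:4, , ], tolerance = 1e-12)
  expect_equal(out[5:6, , ], x[3:4, , ] + x[5:6, , ], tolerance = 1e-12)

  # all K_i zero, fusion identity: only the untouched first split survives
  pz <- p
  for (i in 1:(s - 1)) pz$K[[i]]$W[] <- 0
  outz <- res2net_block(x, pz, s)
  expect_equal(outz[1:2, , ], x[1:2, , ], tolerance = 1e-12)
  expect_true(all(outz[3:6, , ] == 0))
})

test_that("res2net block equals an independently coded naive loop", {
  set.seed(5)
  x <- array(rnorm(8 * 5 * 5), c(8, 5, 5))
  p <- res2net_init(8L, 4L, seed = 2)
  got <- res2net_block(x, p, 4L)
  want <- naive_res2net(x, p, 4L)
  expect_lt(rel_err(got, want), 1e-6)
  expect_error(res2net_block(x, p, 3L), "divisible")
})

test_that("res2net preserves shape for any valid split count", {
  set.seed(6)
  for (s in c(2L, 4L, 6L)) {
    C <- 12L
    x <- array(rnorm(C * 7 * 7), c(C, 7, 7))
    out <- res2net_block(x, res2net_init(C, s, seed = s), s)
    expect_identical(dim(out), dim(x))
  }
})

test_that("later splits have wider receptive fields than earlier ones", {
  # perturbing one central input pixel must reach further (pre-fusion) in
  # split 4's path (three stacked 3x3 convolutions) than in split 2's (one)
  C <- 8L; s <- 4L; R <- 11L
  p <- res2net_init(C, s, seed = 3)
  p$fuse$W <- diag(C)  # keep per-split outputs separable
  p$fuse$b <- rep(0, C)
  x0 <- array(0, c(C, R, R))
  x1 <- x0
  x1[, 6, 6] <- 1   # central spike in every channel
  d <- abs(res2net_block(x1, p, s) - res2net_block(x0, p, s))
  radius <- function(ch) {
    nz <- which(apply(d[ch, , , drop = FALSE], c(2, 3), max) > 1e-12,
                arr.ind = TRUE)
    max(abs(nz - 6))
  }
  r2 <- radius(3:4)   # split 2 output channels
  r4 <- radius(7:8)   # split 4 output channels
  expect_gt(r4, r2)
  expect_equal(r2, 1)  # one 3x3: radius 1
  expect_equal(r4, 3)  # three chained 3x3: radius 3
})

test_that("the generator emits correctly shaped, deterministic images", {
  cfg <- generator_config(resolution = 16, L = 12, s = 4, channels_max = 16,
                          channels_base = 256)
  g <- generator_init(cfg, seed = 4)
  w <- rnorm(12)
  img <- synthesize(g, w = w, noise_seed = 9)
  expect_identical(dim(img), c(3L, 16L, 16L))
  expect_true(all(img >= -1 & img <= 1))
  expect_identical(img, synthesize(g, w = w, noise_seed = 9))
  # fixed noises: bitwise identical images
  nz <- gen_noises(g, 1L, seed = 2)
  expect_identical(synthesize(g, w = w, noises = nz),
                   synthesize(g, w = w, noises = nz))
})

test_that("with noise disabled the output ignores the noise seed", {
  cfg <- generator_config(resolution = 8, L = 8, s = 2, channels_max = 8,
                          channels_base = 64, noise = FALSE)
  g <- generator_init(cfg, seed = 5)
  w <- rnorm(8)
  expect_identical(synthesize(g, w = w, noise_seed = 1),
                   synthesize(g, w = w, noise_seed = 999))
})

test_that("missing styles or noises are rejected", {
  cfg <- generator_config(resolution = 8, L = 8, s = 2, channels_max = 8,
                          channels_base = 64)
  g <- generator_init(cfg, seed = 6)
  expect_error(synthesize(g), "either w or styles")
  expect_error(synthesize(g, w = rnorm(8),
                          noises = gen_noises(g, 1L)[1:3]),
               "noise image")
  expect_error(synthesize(g, styles = list(list(ys = 1, yb = 0))),
               "per style layer")
})

test_that("explicit styles reproduce the affine-derived styles", {
  cfg <- generator_config(resolution = 8, L = 8, s = 2, channels_max = 8,
                          channels_base = 64)
  g <- generator_init(cfg, seed = 7)
  w <- rnorm(8)
  nz <- gen_noises(g, 1L, seed = 3)
  styles <- lapply(seq_len(n_style_layers(g)), function(li) {
    t <- (li + 1L) %/% 2L
    af <- g$stages[[t]][[paste0("affine", if (li %% 2L) "A" else "B")]]
    list(ys = as.numeric(af$Ws %*% w + af$bs),
         yb = as.numeric(af$Wb %*% w + af$bb))
  })
  expect_equal(synthesize(g, styles = styles, noises = nz),
               synthesize(g, w = w, noises = nz), tolerance = 1e-12)
})

test_that("channel schedule respects the cap, base and divisibility", {
  ch <- channel_schedule(c(4, 8, 16, 32), channels_max = 128,
                         channels_base = 2048, s = 4)
  expect_true(all(ch %% 4 == 0))
  expect_true(all(ch <= 128))
  expect_equal(ch[4], 64)   # 2048 / 32
  expect_error(generator_config(resolution = 24), "power of two")
  expect_error(generator_config(resolution = 1024), "power of two")
})

test_that("a default-channel forward at 32x32 is fast on one CPU", {
  g <- generator_init(generator_config(resolution = 32), seed = 8)
  w <- rnorm(512)
  nz <- gen_noises(g, 1L, seed = 1)
  invisible(synthesize(g, w = w, noises = nz))  # warm the index caches
  t0 <- proc.time()[3]
  invisible(synthesize(g, w = w, noises = nz))
  expect_lt(proc.time()[3] - t0, 1)
})
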