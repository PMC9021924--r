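# Adversarial losses, gradient penalty, and path-length regularization.

test_that("critic and generator losses follow the Wasserstein forms", {
  expect_equal(critic_loss(c(1, 1), c(0, 0)), -1)
  expect_equal(critic_loss(c(0.4, 0.6), c(0.4, 0.6)), 0)
  expect_equal(critic_loss(2, 5), 3)
  expect_equal(critic_loss(c(1, 2), c(3, 4)), -critic_loss(c(3, 4), c(1, 2)))
  expect_error(critic_loss(numeric(0), 1), "nonempty")

  expect_equal(generator_loss(0), 0)
  expect_equal(generator_loss(c(1, 3)), -2)
  s <- c(0.2, -1.4, 3)
  expect_equal(generator_loss(s + 0.7), generator_loss(s) - 0.7)
  expect_error(generator_loss(numeric(0)), "nonempty")
})

test_that("gradient penalty closed forms hold for linear critics", {
  set.seed(1)
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  lin <- function(k) function(x)
    flowergan:::ag_matmul(flowergan:::ag_const(k * matrix(v, 1)), x)
  real <- matrix(rnorm(24), 12)
  fake <- matrix(rnorm(24), 12)
  # unit gradient: zero penalty
  expect_equal(as.numeric(gradient_penalty(lin(1), real, fake, 10, seed = 2)),
               0, tolerance = 1e-12)
  # gradient norm 2 everywhere: (2 - 1)^2 * lambda
  expect_equal(as.numeric(gradient_penalty(lin(2), real, fake, 10, seed = 2)),
               10, tolerance = 1e-10)
  expect_error(gradient_penalty(lin(1), real, matrix(0, 12, 3)), "shape")
})

test_that("gradient penalty is nonnegative and zero only at unit norms", {
  d <- discriminator_init(discriminator_config(resolution = 8,
                                               channels_max = 8,
                                               channels_base = 64), seed = 2)
  real <- array(tanh(rnorm(3 * 64 * 2)), c(3, 8, 8, 2))
  fake <- array(tanh(rnorm(3 * 64 * 2)), c(3, 8, 8, 2))
  gp <- gradient_penalty(d, real, fake, 10, seed = 3)
  norms <- attr(gp, "grad_norms")
  expect_gte(as.numeric(gp), 0)
  expect_equal(as.numeric(gp), 10 * mean((norms - 1)^2), tolerance = 1e-12)
})

test_that("critic input gradients match central finite differences", {
  # the penalty rests on the input gradient; check it against numerics on a
  # small critic at a fixed interpolate
  d <- discriminator_init(discriminator_config(resolution = 8,
                                               channels_max = 8,
                                               channels_base = 64), seed = 4)
  x <- array(tanh(rnorm(3 * 64)), c(3, 8, 8))
  xn <- flowergan:::ag_leaf(flowergan:::to_canon(x))
  score <- flowergan:::.d_fwd(d, xn, 1L)
  g <- flowergan:::ag_value(flowergan:::ag_grad(flowergan:::ag_sum(score), xn))
  f <- function(v) {
    xv <- x; xv[] <- v
    discriminate(xv, d)
  }
  idx <- withr::with_seed(5, sample(length(x), 25))
  num <- vapply(idx, function(i) {
    h <- 1e-4
    xp <- as.numeric(x); xm <- as.numeric(x)
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(as.numeric(g)[idx] - num)) /
              max(abs(num), 1e-12), 1e-4)
})

test_that("path lengths computed by backpropagation match the explicit Jacobian", {
  set.seed(6)
  L <- 7L
  M <- matrix(rnorm(L * L), L)
  lin <- function(wn) flowergan:::ag_matmul(flowergan:::ag_const(M), wn)
  st <- plr_state()
  y <- matrix(rnorm(L), ncol = 1)
  w <- rnorm(L)
  r <- path_length_penalty(lin, w, st, y = y)
  expect_lt(abs(r$lengths - sqrt(sum((t(M) %*% y)^2))) /
              sqrt(sum((t(M) %*% y)^2)), 1e-6)
})

test_that("path-length penalty closed forms hold", {
  L <- 5L
  st <- plr_state(a = 0.8)
  # constant generator: zero Jacobian, penalty a^2
  const_gen <- function(wn) flowergan:::ag_mul(wn, 0)
  r <- path_length_penalty(const_gen, rnorm(L), st, seed = 1)
  expect_equal(r$penalty, 0.8^2, tolerance = 1e-9)
  expect_equal(r$lengths, 0, tolerance = 1e-9)
  # linear scaling generator with a set to the exact length: zero penalty
  cc <- 1.7
  y <- matrix(rnorm(L), ncol = 1)
  len <- cc * sqrt(sum(y^2))
  st2 <- plr_state(a = len)
  scale_gen <- function(wn) flowergan:::ag_mul(wn, cc)
  r2 <- path_length_penalty(scale_gen, rnorm(L), st2, y = y)
  expect_equal(r2$penalty, 0, tolerance = 1e-10)
  expect_gte(r2$penalty, 0)
})

test_that("the EMA state tracks the stationary mean length", {
  st <- plr_state(decay = 0.9)
  lin <- function(wn) flowergan:::ag_mul(wn, 2)
  y <- matrix(rnorm(6), ncol = 1)
  len <- 2 * sqrt(sum(y^2))
  for (i in 1:100) {
    r <- path_length_penalty(lin, rnorm(6), st, y = y)
    st <- r$state
  }
  expect_equal(st$a, len, tolerance = 1e-3)
  expect_equal(st$steps, 100L)
})

test_that("equal-norm orthogonal Jacobians beat rank-skewed ones", {
  # among linear generators of equal Frobenius norm, the expected penalty
  # (at the stationary a) is minimized when all singular values are equal
  L <- 8L
  n_draw <- 1500L
  qr_q <- qr.Q(qr(withr::with_seed(7, matrix(rnorm(L * L), L))))
  M_orth <- qr_q * 2                      # singular values all 2
  sv <- c(rep(4, 2), rep(0.5, 6))
  sv <- sv * sqrt(sum((2 * rep(1, L))^2) / sum(sv^2))  # equal Frobenius norm
  M_skew <- qr_q %*% diag(sv)
  expect_equal(sum(M_orth^2), sum(M_skew^2), tolerance = 1e-9)

  penalty_mc <- function(M) {
    gen <- function(wn) flowergan:::ag_matmul(flowergan:::ag_const(M), wn)
    ws <- withr::with_seed(9, matrix(rnorm(L * n_draw), L))
    ys <- withr::with_seed(8, matrix(rnorm(L * n_draw), L))
    r <- path_length_penalty(gen, ws, plr_state(), y = ys)
    # sanity: backpropagated lengths match the explicit Jacobian product
    expect_lt(rel_err(r$lengths, sqrt(colSums(crossprod(M, ys)^2))), 1e-6)
    a <- mean(r$lengths)                   # stationary EMA value
    mean((r$lengths - a)^2)
  }
  expect_lt(penalty_mc(M_orth), penalty_mc(M_skew))
})

test_that("all loss components are finite on a seeded 16x16 batch", {
  cfg <- run_config(resolution = 16, L = 16, channels_max = 16,
                    channels_base = 256, batch_size = 2, seed = 5,
                    plr_interval = 1)
  model <- model_init(cfg)
  opt <- optimizers_init(model)
  real <- array(withr::with_seed(6, stats::runif(3 * 256 * 2, -1, 1)),
                c(3, 16, 16, 2))
  r <- train_step(model, opt, real)
  expect_true(all(is.finite(unlist(r$record))))
})
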