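# The differentiation engine is the substrate for every trainable component;
# these tests pin its gradients against central finite differences, including
# gradients of gradients (double backpropagation).

fg <- flowergan:::ag_grad
leaf <- flowergan:::ag_leaf

test_that("first-order gradients match finite differences across the op set", {
  set.seed(42)
  x <- matrix(rnorm(12), 3, 4)
  w <- matrix(rnorm(6), 2, 3)

  f_graph <- function(xv) {
    xn <- leaf(xv)
    h <- flowergan:::ag_matmul(flowergan:::ag_const(w), xn)
    h <- flowergan:::ag_leaky_relu(h, 0.2)
    h <- flowergan:::ag_tanh(h)
    h <- flowergan:::ag_div(h, flowergan:::ag_sqrt(flowergan:::ag_add(flowergan:::ag_mul(h, h), 0.5)))
    list(out = flowergan:::ag_sum(flowergan:::ag_mul(h, h)), x = xn)
  }
  g <- f_graph(x)
  gn <- fg(g$out, g$x)
  num <- num_grad(function(v) flowergan:::ag_value(f_graph(v)$out), x)
  expect_lt(rel_err(gn$value, num), 1e-6)
})

test_that("row/column broadcast ops differentiate correctly", {
  set.seed(7)
  x <- matrix(rnorm(20), 4, 5)
  rv <- rnorm(4)
  cv <- rnorm(5)
  build <- function(xv, rvv, cvv) {
    xn <- leaf(xv); rn <- leaf(rvv); cn <- leaf(cvv)
    h <- flowergan:::ag_add_rows(flowergan:::ag_mul_rows(xn, rn), rn)
    h <- flowergan:::ag_add_cols(flowergan:::ag_mul_cols(h, cn), cn)
    s <- flowergan:::ag_colsums(h)
    r <- flowergan:::ag_rowsums(flowergan:::ag_bcast_rows(s, 4))
    list(out = flowergan:::ag_sum(flowergan:::ag_mul(r, r)), x = xn, r = rn, c = cn)
  }
  b <- build(x, rv, cv)
  gs <- fg(b$out, list(b$x, b$r, b$c))
  expect_lt(rel_err(gs[[1]]$value,
                    num_grad(function(v) flowergan:::ag_value(build(v, rv, cv)$out), x)), 1e-6)
  expect_lt(rel_err(gs[[2]]$value,
                    num_grad(function(v) flowergan:::ag_value(build(x, v, cv)$out), rv)), 1e-6)
  expect_lt(rel_err(gs[[3]]$value,
                    num_grad(function(v) flowergan:::ag_value(build(x, rv, v)$out), cv)), 1e-6)
})

test_that("convolution and upsampling gradients match finite differences", {
  set.seed(11)
  H <- 4L; W <- 4L; C <- 2L; N <- 2L; Cout <- 3L; k <- 3L
  x <- matrix(rnorm(C * H * W * N), C)
  wt <- matrix(rnorm(Cout * C * k * k, sd = 0.3), Cout)
  b <- rnorm(Cout)

  build <- function(xv, wv, bv) {
    xn <- leaf(xv); wn <- leaf(wv); bn <- leaf(bv)
    h <- flowergan:::ag_conv2d(xn, wn, bn, H, W, C, N, k)
    h <- flowergan:::ag_upsample2(h, H, W, Cout, N)
    list(out = flowergan:::ag_sum(flowergan:::ag_mul(h, h)),
         x = xn, w = wn, b = bn)
  }
  bb <- build(x, wt, b)
  gs <- fg(bb$out, list(bb$x, bb$w, bb$b))
  expect_lt(rel_err(gs[[1]]$value,
                    num_grad(function(v) flowergan:::ag_value(build(v, wt, b)$out), x)), 1e-5)
  expect_lt(rel_err(gs[[2]]$value,
                    num_grad(function(v) flowergan:::ag_value(build(x, v, b)$out), wt)), 1e-5)
  expect_lt(rel_err(gs[[3]]$value,
                    num_grad(function(v) flowergan:::ag_value(build(x, wt, v)$out), b)), 1e-5)
})

test_that("strided convolution halves spatial size and differentiates", {
  set.seed(13)
  H <- 6L; W <- 6L; C <- 2L; N <- 1L; Cout <- 2L; k <- 3L
  x <- matrix(rnorm(C * H * W * N), C)
  wt <- matrix(rnorm(Cout * C * k * k, sd = 0.3), Cout)
  b <- rnorm(Cout)
  OH <- flowergan:::conv_out_size(H, k, stride = 2L)
  expect_equal(OH, 3L)
  build <- function(xv) {
    h <- flowergan:::ag_conv2d(leafx <- leaf(xv), flowergan:::ag_const(wt),
                               flowergan:::ag_const(b), H, W, C, N, k, stride = 2L)
    list(out = flowergan:::ag_sum(flowergan:::ag_mul(h, h)), x = leafx, h = h)
  }
  bb <- build(x)
  expect_equal(dim(flowergan:::ag_value(bb$h)), c(Cout, OH * OH * N))
  g <- fg(bb$out, bb$x)
  expect_lt(rel_err(g$value,
                    num_grad(function(v) flowergan:::ag_value(build(v)$out), x)), 1e-5)
})

test_that("gradients of gradient norms (double backprop) match finite differences", {
  # phi(x, w) = || d/dx [ sum(tanh(W x))^2 ] ||^2 ; check d phi / d w numerically.
  set.seed(23)
  x <- matrix(rnorm(6), 3, 2)
  w <- matrix(rnorm(6, sd = 0.7), 2, 3)

  phi <- function(wv) {
    xn <- leaf(x); wn <- leaf(wv)
    s <- flowergan:::ag_sum(flowergan:::ag_tanh(flowergan:::ag_matmul(wn, xn)))
    s2 <- flowergan:::ag_mul(s, s)
    gx <- fg(s2, xn)
    list(out = flowergan:::ag_sum(flowergan:::ag_mul(gx, gx)), w = wn)
  }
  p <- phi(w)
  gw <- fg(p$out, p$w)
  num <- num_grad(function(v) flowergan:::ag_value(phi(v)$out), w, h = 1e-5)
  expect_lt(rel_err(gw$value, num), 1e-5)
})

test_that("sample-wise pooling reductions are exact", {
  set.seed(5)
  HW <- 4L; N <- 3L; C <- 2L
  x <- matrix(rnorm(C * HW * N), C)
  m <- flowergan:::ag_value(flowergan:::ag_sample_mean(flowergan:::ag_const(x), HW, N))
  ref <- sapply(seq_len(N), function(n)
    rowMeans(x[, ((n - 1) * HW + 1):(n * HW), drop = FALSE]))
  expect_equal(m, ref, tolerance = 1e-12)
  norms <- flowergan:::ag_value(flowergan:::ag_col_norms(flowergan:::ag_const(x)))
  expect_equal(as.numeric(norms), apply(x, 2, function(v) sqrt(sum(v^2))),
               tolerance = 1e-12)
})
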