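# Central finite-difference gradient of a scalar function of one array.
num_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}
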