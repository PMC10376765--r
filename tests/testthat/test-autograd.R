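# Finite-difference verification of the autodiff engine and optimizer
# behavior. One parameterized loop covers every primitive op.

fd_check <- function(build_loss, param, n = 4, eps = 1e-6, tol = 1e-5) {
  tape <- fgscreen:::ag_tape()
  loss <- build_loss(tape)
  fgscreen:::ag_backward(loss, tape)
  g <- param$g
  set.seed(42)
  for (k in sample(length(param$v), min(n, length(param$v)))) {
    v0 <- param$v[k]
    param$v[k] <- v0 + eps
    lp <- build_loss(fgscreen:::ag_tape())$v
    param$v[k] <- v0 - eps
    lm <- build_loss(fgscreen:::ag_tape())$v
    param$v[k] <- v0
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - g[k]) / max(1, abs(num)), tol)
  }
}

test_that("gradients of every primitive op match finite differences", {
  set.seed(10)
  x <- rand_map(c(3, 8, 8))
  xn <- fgscreen:::ag_const(x)

  w <- fgscreen:::ag_param(fgscreen:::init_conv(2, 3, 3, 3))
  b <- fgscreen:::ag_param(rnorm(2))
  fd_check(function(tp) {
    h <- fgscreen:::ag_conv(xn, w, b, 3, 3, 2, 1, tp)
    h <- fgscreen:::ag_lrelu(h, tp)
    fgscreen:::ag_sum(fgscreen:::ag_mul(h, h, tp), tp)
  }, w)

  wf <- fgscreen:::ag_param(runif(2, 0.2, 1.5))
  fd_check(function(tp) {
    f <- fgscreen:::ag_fusion(list(xn, xn), wf, tp)
    fgscreen:::ag_sum(fgscreen:::ag_mul(f, f, tp), tp)
  }, wf)

  ws <- fgscreen:::ag_param(runif(3))
  fd_check(function(tp) {
    h <- fgscreen:::ag_scale_channels(xn, ws, tp)
    h <- fgscreen:::ag_maxpool2(h, tp)
    h <- fgscreen:::ag_sigmoid(h, tp)
    fgscreen:::ag_sum(h, tp)
  }, ws)

  wfc <- fgscreen:::ag_param(fgscreen:::init_fc(2, 3))
  bfc <- fgscreen:::ag_param(rnorm(2))
  fd_check(function(tp) {
    g <- fgscreen:::ag_gmp(xn, tp)
    h <- fgscreen:::ag_fc(g, wfc, bfc, tp)
    fgscreen:::ag_bce_logits(h, c(1, 0), tp)
  }, wfc)

  wg <- fgscreen:::ag_param(rnorm(1))
  fd_check(function(tp) {
    u <- fgscreen:::ag_resize_up2(xn, tp)
    d <- fgscreen:::ag_resize_down2(u, tp)
    s <- fgscreen:::ag_scalar_mul(d, wg, tp)
    g <- fgscreen:::ag_gap(s, tp)
    fgscreen:::ag_sum(g, tp)
  }, wg)
})

test_that("gathered-offset CIoU loss gradient matches finite differences", {
  set.seed(11)
  t4v <- rnorm(4, 0, 0.5)
  t4p <- fgscreen:::ag_param(t4v)
  gt <- c(cx = 30, cy = 42, w = 18, h = 12)
  build <- function(tp) {
    fgscreen:::ag_ciou(t4p, c(20, 14), c(3, 5), 8, gt, tp)
  }
  fd_check(build, t4p, n = 4, tol = 1e-3)
})

test_that("Adam drives a quadratic to its minimum", {
  p <- fgscreen:::ag_param(c(5, -3))
  for (t in 1:400) {
    fgscreen:::ag_zero_grad(list(p))
    tp <- fgscreen:::ag_tape()
    node <- fgscreen:::ag_node(sum((p$v - c(1, 2))^2), list(p),
                               function(g) list(g * 2 * (p$v - c(1, 2))), tp)
    fgscreen:::ag_backward(node, tp)
    fgscreen:::adam_step(list(p), 0.05, t)
  }
  expect_equal(p$v, c(1, 2), tolerance = 1e-2)
})
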