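# The neural operators against independent scalar-loop oracles and their
# algebraic properties.

test_that("fast-normalized fusion matches the loop oracle and special cases", {
  set.seed(1)
  m <- rand_map(c(2, 4, 4))
  one <- fast_normalized_fusion(list(m), 1)
  expect_equal(one, m / 1.0001, tolerance = 1e-12)
  two <- fast_normalized_fusion(list(m, m), c(1, 1))
  expect_equal(two, m * 2 / 2.0001, tolerance = 1e-12)
  for (k in 1:5) {
    maps <- lapply(1:3, function(i) rand_map(c(2, 4, 4)))
    w <- runif(3, 0, 2)
    expect_lt(max(abs(fast_normalized_fusion(maps, w) -
                        oracle_fusion(maps, w))), 1e-6)
  }
  # all-zero weights give the zero map (coefficients 0 / epsilon)
  expect_equal(fast_normalized_fusion(list(m, m), c(0, 0)),
               array(0, dim(m)))
  # negative raw weights are projected to zero before use
  expect_equal(fast_normalized_fusion(list(m, m), c(-5, 1)),
               fast_normalized_fusion(list(m, m), c(0, 1)))
})

test_that("fused coefficients sum to sum(w)/(eps + sum(w)) for random weights", {
  set.seed(2)
  for (k in 1:100) {
    n <- sample(2:5, 1)
    w <- runif(n, 0, 3)
    maps <- lapply(seq_len(n), function(i) array(1, c(1, 2, 2)))
    out <- fast_normalized_fusion(maps, w)
    expect_equal(out[1, 1, 1], sum(w) / (1e-4 + sum(w)), tolerance = 1e-12)
    expect_lt(out[1, 1, 1], 1)
  }
})

test_that("ECA block matches the loop oracle; constants and gamma behave", {
  set.seed(3)
  st <- eca_state(4, reduction = 2)
  x <- rand_map(c(4, 5, 5))
  expect_lt(max(abs(eca_block(x, st) - oracle_eca(x, st))), 1e-6)
  # constant channels: the pooled vector is exactly the channel constants
  cst <- array(rep(1:4, 25), c(4, 5, 5))
  expect_equal(rowMeans(matrix(cst, 4)), 1:4)
  st0 <- st; st0$gamma <- 0
  expect_equal(eca_block(x, st0), array(0, dim(x)))
  # conv1d variant runs and preserves shape
  stc <- eca_state(4, variant = "conv1d")
  expect_equal(dim(eca_block(x, stc)), dim(x))
})

test_that("CBAM matches the loop oracle, bounds, and the sigma(0) = 0.5 limit", {
  set.seed(4)
  st <- cbam_state(4, reduction = 2)
  x <- rand_map(c(4, 6, 6))
  expect_lt(max(abs(cbam_block(x, st) - oracle_cbam(x, st))), 1e-6)
  # non-negative input: both gates < 1 so output <= input elementwise
  xp <- rand_map(c(4, 6, 6), 0, 1)
  expect_true(all(cbam_block(xp, st) <= xp + 1e-12))
  # all-zero FC weights: both attention factors are exactly 0.5
  st0 <- cbam_state(4)
  st0$cam_fc1[] <- 0; st0$cam_fc2[] <- 0; st0$sam_fc[] <- 0
  expect_equal(cbam_block(x, st0), x / 4, tolerance = 1e-12)
  # canonical 7x7 spatial variant preserves shape
  st7 <- cbam_state(4, sam_variant = "conv7x7")
  expect_equal(dim(cbam_block(x, st7)), dim(x))
})

test_that("residual block is Y = X + F(X) with an identity gradient path", {
  set.seed(5)
  x <- rand_map(c(3, 4, 4))
  expect_equal(residual_block(x, function(z) z * 0), x)
  expect_equal(residual_block(x, identity), 2 * x)
  w <- fgscreen:::init_conv(3, 3, 3, 3)
  f <- function(z) fgscreen:::conv2d(z, w, numeric(3))
  expect_lt(max(abs(residual_block(x, f) - x - f(x))), 1e-6)
  # gradient of Y wrt X has an identity component: with F = 0 the gradient
  # of sum(Y) is exactly one everywhere (finite difference on a 2x2 map)
  x2 <- rand_map(c(1, 2, 2))
  eps <- 1e-6
  for (k in seq_along(x2)) {
    xp <- x2; xp[k] <- xp[k] + eps
    g <- (sum(residual_block(xp, function(z) z * 0)) -
            sum(residual_block(x2, function(z) z * 0))) / eps
    expect_equal(g, 1, tolerance = 1e-4)
  }
})

test_that("bifpn node composes fusion, resize and conv; shapes contract", {
  set.seed(6)
  f_l <- rand_map(c(2, 8, 8)); f_up <- rand_map(c(2, 4, 4))
  n_down <- rand_map(c(2, 16, 16))
  # zero cross-level weight with identity conv leaves F_l / (1 + eps)
  nd <- bifpn_node_params(2, conv = "identity")
  nd$td_w <- c(1, 0)
  out <- bifpn_node(f_l, f_up, n_down, nd)
  expect_equal(out$p, f_l / 1.0001, tolerance = 1e-12)
  # full node equals the hand-rolled composition
  nd2 <- bifpn_node_params(2, conv = "random")
  nd2$td_w <- runif(2); nd2$out_w <- runif(3)
  out2 <- bifpn_node(f_l, f_up, n_down, nd2)
  up <- fgscreen:::resize_nn_up2(f_up)
  p_ref <- fgscreen:::conv2d(fast_normalized_fusion(list(f_l, up), nd2$td_w),
                             nd2$conv_td, nd2$b_td)
  dn <- fgscreen:::resize_nn_down2(n_down)
  n_ref <- fgscreen:::conv2d(
    fast_normalized_fusion(list(f_l, p_ref, dn), nd2$out_w),
    nd2$conv_out, nd2$b_out)
  expect_lt(max(abs(out2$p - p_ref)), 1e-9)
  expect_lt(max(abs(out2$n - n_ref)), 1e-9)
  expect_equal(dim(out2$p)[2:3], dim(f_l)[2:3])
  expect_equal(dim(out2$n)[2:3], dim(f_l)[2:3])
  # incompatible strides are rejected
  expect_error(bifpn_node(f_l, rand_map(c(2, 3, 3)), n_down, nd2),
               "incompatible")
})

test_that("trainable autograd blocks agree with the functional forms", {
  set.seed(7)
  x <- rand_map(c(4, 6, 6))
  ps <- fgscreen:::new_param_store()
  fgscreen:::add_eca_params(ps, "e", 4, reduction = 2)
  st <- eca_state(4, reduction = 2)
  st$fc1 <- ps[["e.fc1.w"]]$v; st$b1 <- ps[["e.fc1.b"]]$v
  st$fc2 <- ps[["e.fc2.w"]]$v; st$b2 <- ps[["e.fc2.b"]]$v
  st$gamma <- ps[["e.gamma"]]$v
  tape <- ag_tape <- fgscreen:::ag_tape()
  out <- fgscreen:::eca_forward(fgscreen:::ag_const(x), ps, "e", tape)
  expect_lt(max(abs(out$v - eca_block(x, st))), 1e-10)

  fgscreen:::add_cbam_params(ps, "c", 4, reduction = 2)
  stc <- cbam_state(4, reduction = 2)
  stc$cam_fc1 <- ps[["c.cam1.w"]]$v; stc$cam_b1 <- ps[["c.cam1.b"]]$v
  stc$cam_fc2 <- ps[["c.cam2.w"]]$v; stc$cam_b2 <- ps[["c.cam2.b"]]$v
  stc$sam_fc <- ps[["c.sam.w"]]$v; stc$sam_b <- ps[["c.sam.b"]]$v
  out2 <- fgscreen:::cbam_forward(fgscreen:::ag_const(x), ps, "c", tape)
  expect_lt(max(abs(out2$v - cbam_block(x, stc))), 1e-10)
})
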