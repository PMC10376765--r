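# Tape-based reverse-mode autodiff over (C, H, W) arrays.
#
# A "tape" records operation nodes in creation order; since every node can only
# depend on nodes created before it, walking the tape backwards is a valid
# reverse topological order. Nodes are environments carrying the value ($v),
# the accumulated output gradient ($g), the parent nodes ($parents) and a
# backward closure ($bw) mapping the output gradient to per-parent gradients.
# Parameters are leaf nodes living outside the tape; their $g accumulates
# across the backward sweep and is consumed by the optimizer.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(v, parents = list(), bw = NULL, tape = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$parents <- parents
  e$bw <- bw
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
    tape$nodes[[tape$n]] <- e
  }
  e
}

ag_param <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$param <- TRUE
  e
}

ag_const <- function(v) ag_node(v)

ag_accumulate <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

ag_backward <- function(loss, tape) {
  loss$g <- if (length(loss$v) == 1L) 1 else array(1, dim(loss$v))
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$g) || is.null(nd$bw)) next
    gs <- nd$bw(nd$g)
    for (i in seq_along(nd$parents)) {
      if (!is.null(gs[[i]])) ag_accumulate(nd$parents[[i]], gs[[i]])
    }
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ag_conv <- function(x, w, b, kh, kw, stride, pad, tape) {
  v <- .conv2d_fw(x$v, w$v, as.numeric(b$v), kh, kw, stride, pad)
  ag_node(v, list(x, w, b), function(g) {
    r <- .conv2d_bw(x$v, w$v, g, kh, kw, stride, pad)
    list(r$dx, r$dw, as.numeric(r$db))
  }, tape)
}

ag_relu <- function(x, tape) {
  v <- pmax(x$v, 0)
  ag_node(v, list(x), function(g) list(g * (x$v > 0)), tape)
}

ag_lrelu <- function(x, tape, slope = 0.1) {
  pos <- x$v > 0
  v <- x$v * ifelse(pos, 1, slope)
  ag_node(v, list(x), function(g) list(g * ifelse(pos, 1, slope)), tape)
}

ag_sigmoid <- function(x, tape) {
  v <- stats::plogis(x$v)
  ag_node(v, list(x), function(g) list(g * v * (1 - v)), tape)
}

ag_add <- function(a, b, tape) {
  ag_node(a$v + b$v, list(a, b), function(g) list(g, g), tape)
}

ag_mul <- function(a, b, tape) {
  ag_node(a$v * b$v, list(a, b), function(g) list(g * b$v, g * a$v), tape)
}

ag_mul_const <- function(x, k, tape) {
  ag_node(x$v * k, list(x), function(g) list(g * k), tape)
}

# x: (C,H,W), w: length-C vector broadcast over space (R recycles over dim 1)
ag_scale_channels <- function(x, w, tape) {
  wv <- as.numeric(w$v)
  v <- x$v * wv
  ag_node(v, list(x, w), function(g) {
    C <- dim(x$v)[1]
    list(g * wv, rowSums(matrix(g * x$v, nrow = C)))
  }, tape)
}

ag_scalar_mul <- function(x, s, tape) {
  sv <- as.numeric(s$v)[1]
  ag_node(x$v * sv, list(x, s), function(g) list(g * sv, sum(g * x$v)), tape)
}

ag_gap <- function(x, tape) {
  d <- dim(x$v)
  v <- rowMeans(matrix(x$v, nrow = d[1]))
  ag_node(v, list(x), function(g) {
    list(array(g / (d[2] * d[3]), d))
  }, tape)
}

ag_gmp <- function(x, tape) {
  d <- dim(x$v)
  m <- matrix(x$v, nrow = d[1])
  idx <- max.col(m, ties.method = "first")
  v <- m[cbind(seq_len(d[1]), idx)]
  ag_node(v, list(x), function(g) {
    dm <- matrix(0, d[1], d[2] * d[3])
    dm[cbind(seq_len(d[1]), idx)] <- g
    list(array(dm, d))
  }, tape)
}

ag_fc <- function(x, w, b, tape) {
  v <- as.numeric(w$v %*% x$v + b$v)
  ag_node(v, list(x, w, b), function(g) {
    list(as.numeric(crossprod(w$v, g)), outer(g, as.numeric(x$v)), g)
  }, tape)
}

ag_flatten <- function(x, tape) {
  d <- dim(x$v)
  ag_node(as.numeric(x$v), list(x), function(g) list(array(g, d)), tape)
}

ag_maxpool2 <- function(x, tape) {
  d <- dim(x$v)
  stopifnot(d[2] %% 2 == 0, d[3] %% 2 == 0)
  i1 <- seq(1L, d[2], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3], 2L); j2 <- j1 + 1L
  a <- list(x$v[, i1, j1, drop = FALSE], x$v[, i2, j1, drop = FALSE],
            x$v[, i1, j2, drop = FALSE], x$v[, i2, j2, drop = FALSE])
  v <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  ag_node(v, list(x), function(g) {
    dx <- array(0, d)
    taken <- array(FALSE, dim(v))
    ii <- list(i1, i2, i1, i2); jj <- list(j1, j1, j2, j2)
    for (k in 1:4) {
      m <- (a[[k]] == v) & !taken
      taken <- taken | m
      dx[, ii[[k]], jj[[k]]] <- dx[, ii[[k]], jj[[k]]] + g * m
    }
    list(dx)
  }, tape)
}

ag_resize_up2 <- function(x, tape) {
  d <- dim(x$v)
  ri <- rep(seq_len(d[2]), each = 2L)
  rj <- rep(seq_len(d[3]), each = 2L)
  v <- x$v[, ri, rj, drop = FALSE]
  ag_node(v, list(x), function(g) {
    i1 <- seq(1L, 2L * d[2], 2L); j1 <- seq(1L, 2L * d[3], 2L)
    dx <- g[, i1, j1, drop = FALSE] + g[, i1 + 1L, j1, drop = FALSE] +
      g[, i1, j1 + 1L, drop = FALSE] + g[, i1 + 1L, j1 + 1L, drop = FALSE]
    list(dx)
  }, tape)
}

ag_resize_down2 <- function(x, tape) {
  d <- dim(x$v)
  i1 <- seq(1L, d[2], 2L); j1 <- seq(1L, d[3], 2L)
  v <- x$v[, i1, j1, drop = FALSE]
  ag_node(v, list(x), function(g) {
    dx <- array(0, d)
    dx[, i1, j1] <- g
    list(dx)
  }, tape)
}

# Fast-normalized weighted fusion with ReLU projection of the raw weights:
# O = sum_i u_i / (eps + sum_j u_j) * I_i,  u = max(w, 0)
ag_fusion <- function(maps, wpar, tape, eps = 1e-4) {
  u <- pmax(as.numeric(wpar$v), 0)
  D <- eps + sum(u)
  co <- u / D
  v <- array(0, dim(maps[[1]]$v))
  for (i in seq_along(maps)) v <- v + co[i] * maps[[i]]$v
  ag_node(v, c(maps, list(wpar)), function(g) {
    gs <- lapply(seq_along(maps), function(i) g * co[i])
    dw <- vapply(seq_along(maps), function(i) {
      if (wpar$v[i] > 0) sum(g * (maps[[i]]$v - v)) / D else 0
    }, numeric(1))
    c(gs, list(dw))
  }, tape)
}

# mean over a weight mask of stable binary cross-entropy with logits
ag_bce_logits <- function(z, y, tape, w = NULL, norm = NULL) {
  zv <- z$v
  if (is.null(w)) w <- 1
  if (is.null(norm)) norm <- length(zv)
  l <- pmax(zv, 0) - zv * y + log1p(exp(-abs(zv)))
  v <- sum(w * l) / norm
  ag_node(v, list(z), function(g) {
    list(g * w * (stats::plogis(zv) - y) / norm)
  }, tape)
}

ag_gather <- function(x, idx, tape) {
  v <- x$v[idx]
  ag_node(v, list(x), function(g) {
    dx <- array(0, dim(x$v) %||% length(x$v))
    for (k in seq_along(idx)) dx[idx[k]] <- dx[idx[k]] + g[k]
    list(dx)
  }, tape)
}

ag_sum <- function(x, tape) {
  d <- dim(x$v)
  ag_node(sum(x$v), list(x), function(g) {
    list(if (is.null(d)) rep(g, length(x$v)) else array(g, d))
  }, tape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- optimizer -------------------------------------------------------------

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip = NULL) {
  if (!is.null(clip)) {
    total <- sqrt(sum(vapply(params, function(p)
      if (is.null(p$g)) 0 else sum(p$g^2), numeric(1))))
    if (total > clip)
      for (p in params) if (!is.null(p$g)) p$g <- p$g * (clip / total)
  }
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$m)) { p$m <- p$g * 0; p$u <- p$g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$u <- beta2 * p$u + (1 - beta2) * p$g^2
    mh <- p$m / (1 - beta1^t)
    uh <- p$u / (1 - beta2^t)
    p$v <- p$v - lr * mh / (sqrt(uh) + eps)
  }
  invisible(NULL)
}

# He-style initializers ------------------------------------------------------

init_conv <- function(cout, cin, kh, kw, gain = 1) {
  fan_in <- cin * kh * kw
  w <- matrix(stats::rnorm(cout * fan_in, 0, gain * sqrt(2 / fan_in)),
              nrow = cout)
  w
}

init_fc <- function(nout, nin, gain = 1) {
  matrix(stats::rnorm(nout * nin, 0, gain * sqrt(2 / nin)), nrow = nout)
}
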